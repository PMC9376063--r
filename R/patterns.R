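# generalized Kullback-Leibler divergence D(V || WH)
kl_divergence <- function(V, WH, eps = .Machine$double.eps) {
  WH <- pmax(WH, eps)
  sum(ifelse(V > 0, V * log(V / WH), 0) - V + WH)
}

# one NMF run: multiplicative updates for the KL objective from a random init
nmf_single <- function(V, k, max_iter, tol, eps = .Machine$double.eps) {
  n <- nrow(V); s <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * s, 0.1, 1), k, s)
  obj <- kl_divergence(V, W %*% H)
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
    new_obj <- kl_divergence(V, W %*% H)
    if (abs(obj - new_obj) < tol * max(abs(obj), 1)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = W, H = H, objective = obj, iterations = it)
}

normalize_model <- function(W, H) {
  scale <- colSums(W)
  scale[scale == 0] <- 1
  W <- sweep(W, 2, scale, "/")
  H <- sweep(H, 1, scale, "*")
  list(W = W, H = H)
}

#' Non-negative matrix factorization of a mutation count matrix
#'
#' Factorises a 96 x samples count matrix V into `W %*% H` with k mutation
#' patterns (columns of W, each normalised to sum 1) and exposures H, by
#' multiplicative updates minimising the generalised Kullback-Leibler
#' divergence. The best of `restarts` random initialisations is kept;
#' results are bit-for-bit reproducible given (V, k, restarts, seed).
#'
#' @param V Non-negative matrix (classes x samples), no all-zero column.
#' @param k Rank (number of patterns), `1 <= k < ncol(V)`.
#' @param restarts Random initialisations.
#' @param seed Integer seed.
#' @param max_iter,tol Convergence controls: stop at `max_iter` or when the
#'   relative objective change drops below `tol`.
#' @return Object of class `pattern_model`: `patterns` (W), `exposures` (H),
#'   `rank`, `objective`, `restarts`, `seed`, `iterations`.
#' @export
nmf <- function(V, k, restarts = 10L, seed = 1L, max_iter = 10000L, tol = 1e-8) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  zero <- colSums(V) == 0
  if (any(zero)) stop("all-zero sample(s): ",
    paste(colnames(V)[zero], collapse = ", "))
  if (k < 1 || k >= ncol(V)) stop("need 1 <= k < number of samples")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seed * 1000L + r,
      nmf_single(V, k, max_iter, tol))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  nm <- normalize_model(best$W, best$H)
  rownames(nm$W) <- rownames(V)
  colnames(nm$W) <- paste0("MP", seq_len(k))
  rownames(nm$H) <- colnames(nm$W)
  colnames(nm$H) <- colnames(V)
  structure(list(patterns = nm$W, exposures = nm$H, rank = as.integer(k),
    objective = best$objective, restarts = as.integer(restarts),
    seed = as.integer(seed), iterations = best$iterations),
    class = "pattern_model")
}

#' Choose the NMF rank by cophenetic correlation of consensus clusterings
#'
#' For each candidate rank, samples are clustered by their dominant exposure
#' in each of `restarts` independently initialised factorizations; the
#' consensus matrix of pair co-clustering frequencies is converted to a
#' distance, hierarchically clustered (average linkage), and scored by the
#' cophenetic correlation between the two distance structures. The chosen
#' rank is the smallest k in the range whose coefficient exceeds the
#' coefficient at k + 1 (the point where stability starts to decrease); when
#' no decrease occurs the largest rank is returned with a warning flag. Ties
#' are treated as not decreasing.
#'
#' @param V Count matrix as in [nmf()].
#' @param rank_range Contiguous integer range of candidate ranks, min >= 2.
#' @param restarts Factorizations per rank.
#' @param seed Integer seed.
#' @param max_iter,tol Passed to the per-restart factorizations.
#' @return Object of class `rank_selection`: data frame `scores` (rank,
#'   cophenetic), `chosen`, `warning_flag`.
#' @export
select_rank <- function(V, rank_range = 2:6, restarts = 20L, seed = 1L,
                        max_iter = 2000L, tol = 1e-6) {
  V <- as.matrix(V)
  rank_range <- sort(unique(as.integer(rank_range)))
  if (length(rank_range) < 2) stop("rank_range must contain at least 2 ranks")
  if (any(diff(rank_range) != 1L)) stop("rank_range must be contiguous")
  if (min(rank_range) < 2) stop("minimum rank is 2")
  s <- ncol(V)
  # degenerate input: identical (proportional) samples carry no clustering
  # structure, so consensus stability cannot discriminate ranks
  F_ <- sweep(V, 2, pmax(colSums(V), .Machine$double.eps), "/")
  if (max(abs(F_ - F_[, 1])) < 1e-10) {
    warning("all samples have identical spectra; rank selection is undefined")
    return(structure(list(
      scores = data.frame(rank = rank_range,
        cophenetic = NA_real_),
      chosen = rank_range[length(rank_range)], warning_flag = TRUE),
      class = "rank_selection"))
  }
  coph <- numeric(length(rank_range))
  warn <- FALSE
  for (ri in seq_along(rank_range)) {
    k <- rank_range[ri]
    consensus <- matrix(0, s, s)
    for (r in seq_len(restarts)) {
      fit <- with_seed(seed * 10000L + k * 100L + r,
        nmf_single(V, k, max_iter, tol))
      assign_ <- apply(fit$H, 2, which.max)
      consensus <- consensus + outer(assign_, assign_, "==")
    }
    consensus <- consensus / restarts
    d <- stats::as.dist(1 - consensus)
    if (stats::sd(as.vector(d)) == 0) {
      # no clustering structure at all (e.g. identical samples)
      coph[ri] <- NA_real_
      warn <- TRUE
      next
    }
    hc <- stats::hclust(d, method = "average")
    cd <- stats::cophenetic(hc)
    coph[ri] <- suppressWarnings(stats::cor(as.vector(d), as.vector(cd)))
  }
  chosen <- NA_integer_
  for (ri in seq_len(length(rank_range) - 1)) {
    if (!is.na(coph[ri]) && !is.na(coph[ri + 1]) && coph[ri] > coph[ri + 1]) {
      chosen <- rank_range[ri]
      break
    }
  }
  if (is.na(chosen)) {
    chosen <- rank_range[length(rank_range)]
    warn <- TRUE
  }
  structure(list(
    scores = data.frame(rank = rank_range, cophenetic = coph),
    chosen = chosen, warning_flag = warn), class = "rank_selection")
}

#' Correlate extracted patterns with reference signatures
#'
#' Pearson correlation between each pattern (column of W) and each reference
#' signature over the shared 96-class label order. Zero-variance vectors give
#' an undefined r, reported as `NA`.
#'
#' @param model A `pattern_model` (or a 96 x k matrix).
#' @param references Matrix or data frame, 96 rows in [spectrum_contexts()]
#'   order, one column per reference signature.
#' @param display_threshold Correlations at or above this value are flagged
#'   in the `display` mask (the conventional reporting cutoff, 0.7).
#' @return List: `r` (patterns x references correlation matrix), `display`
#'   (logical mask, `r >= display_threshold`).
#' @export
correlate_signatures <- function(model, references, display_threshold = 0.7) {
  W <- if (inherits(model, "pattern_model")) model$patterns else as.matrix(model)
  R <- as.matrix(references)
  if (nrow(W) != nrow(R)) stop("patterns and references must share label order")
  r <- matrix(NA_real_, ncol(W), ncol(R),
    dimnames = list(colnames(W), colnames(R)))
  for (i in seq_len(ncol(W))) for (j in seq_len(ncol(R))) {
    if (stats::sd(W[, i]) == 0 || stats::sd(R[, j]) == 0) next
    r[i, j] <- stats::cor(W[, i], R[, j])
  }
  list(r = r, display = !is.na(r) & r >= display_threshold)
}

#' Cosine similarity between spectrum vectors
#'
#' @param a,b Non-negative numeric vectors of equal length.
#' @return Cosine of the angle between `a` and `b`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("NMF pattern model: rank %d, %d samples, KL divergence %.4g\n",
    x$rank, ncol(x$exposures), x$objective))
  invisible(x)
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("cophenetic rank selection: chosen rank", x$chosen,
    if (x$warning_flag) "(warning: no clear decrease)" else "", "\n")
  print(x$scores)
  invisible(x)
}
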