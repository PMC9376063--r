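#' Luria-Delbruck mutant-count probabilities
#'
#' Probability of observing k resistant mutants in a culture in which
#' mutational events arrive with mean m and each event founds a clone whose
#' size follows the Lea-Coulson size distribution, computed by the
#' Ma-Sandri-Sarkar recursion `p_0 = exp(-m)`,
#' `p_k = (m/k) * sum_{i<k} p_i / (k-i+1)`.
#'
#' @param m Expected number of mutational events per culture (>= 0).
#' @param k_max Largest count to evaluate.
#' @return Numeric vector `p[0..k_max]` (length `k_max + 1`).
#' @export
ld_pmf <- function(m, k_max) {
  stopifnot(length(m) == 1, length(k_max) == 1)
  if (m < 0) stop("m must be >= 0")
  k_max <- as.integer(k_max)
  if (m == 0) return(c(1, numeric(k_max)))
  .ld_pmf_cpp(m, k_max)
}

#' Fluctuation assay container
#'
#' @param counts Integer vector of mutant counts, one per selective culture.
#' @param n_final Final cells per culture at plating (Nt).
#' @param label Optional genotype/time tag.
#' @return Object of class `fluctuation_assay`.
#' @export
fluctuation_assay <- function(counts, n_final, label = "") {
  stopifnot(n_final >= 1, all(counts >= 0), all(counts == floor(counts)))
  structure(list(counts = as.numeric(counts), n_final = n_final, label = label),
    class = "fluctuation_assay")
}

# log-likelihood of m given counts, censoring counts > k_max into the tail
# mass 1 - sum(p); returns the score (d loglik / dm) as attribute when
# gradient = TRUE
ld_loglik <- function(m, counts, k_max = 1e4, gradient = FALSE) {
  cens <- counts > k_max
  kk <- c(counts[!cens], if (any(cens)) k_max)
  K <- max(kk)
  if (m == 0) {
    ll <- if (all(counts == 0)) 0 else -Inf
    return(ll)
  }
  if (gradient) {
    pg <- .ld_pmf_grad_cpp(m, K)
    p <- pg$p; dp <- pg$dp
  } else {
    p <- .ld_pmf_cpp(m, K)
  }
  obs <- counts[!cens]
  ll <- sum(log(p[obs + 1]))
  if (any(cens)) {
    tail_p <- max(1 - sum(p), .Machine$double.xmin)
    ll <- ll + sum(cens) * log(tail_p)
  }
  if (gradient) {
    sc <- sum(dp[obs + 1] / p[obs + 1])
    if (any(cens)) {
      tail_p <- max(1 - sum(p), .Machine$double.xmin)
      sc <- sc + sum(cens) * (-sum(dp)) / tail_p
    }
    attr(ll, "score") <- sc
  }
  ll
}

#' Maximum-likelihood estimate of the fluctuation-assay mutation rate
#'
#' Maximises the Luria-Delbruck log-likelihood of the observed mutant counts
#' in m (expected mutational events per culture) by Newton-Raphson on the
#' score, with derivative recursions and a bisection safeguard, then converts
#' to a per-division rate `mu_hat = m_hat / Nt`. Counts above `k_max` are
#' right-censored into the tail mass `1 - sum(p)`.
#'
#' @param assay A [fluctuation_assay()].
#' @param k_max Censoring bound for the pmf recursion.
#' @param ci Compute a 95% profile-likelihood interval for m
#'   (`Delta loglik = 1.92`).
#' @return Object of class `ld_estimate`: `m_hat`, `mu_hat`, `loglik`,
#'   `ci_low`/`ci_high` (on m; `NA` unless `ci = TRUE`), `label`, `n_cultures`.
#' @export
ld_mle <- function(assay, k_max = 1e4, ci = FALSE) {
  stopifnot(inherits(assay, "fluctuation_assay"))
  counts <- assay$counts
  if (length(counts) < 2) stop("need >= 2 cultures")
  out <- list(label = assay$label, n_cultures = length(counts),
    ci_low = NA_real_, ci_high = NA_real_)
  if (all(counts == 0)) {
    warning("all mutant counts are zero: degenerate data, m_hat = 0")
    out <- c(list(m_hat = 0, mu_hat = 0, loglik = 0), out)
    class(out) <- "ld_estimate"
    return(out)
  }
  score <- function(m) {
    ll <- ld_loglik(m, counts, k_max, gradient = TRUE)
    attr(ll, "score")
  }
  # bracket the root of the score: score -> +Inf as m -> 0 when any count > 0
  lo <- 1e-8
  hi <- max(1, -log(max(mean(counts == 0), 1e-12)) * 2)
  while (score(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (score(hi) > 0) stop("ld_mle failed to bracket the MLE (m > 1e6?)")
  # Newton with bisection safeguard
  m <- min(max(-log(max(mean(counts == 0), exp(-hi))), lo * 2), hi / 2)
  if (m <= lo) m <- (lo + hi) / 2
  for (it in seq_len(100)) {
    pg <- ld_loglik(m, counts, k_max, gradient = TRUE)
    s <- attr(pg, "score")
    if (s > 0) lo <- m else hi <- m
    h <- 1e-4 * max(m, 1)
    s2 <- score(m + h)
    d <- (s2 - s) / h
    step_ok <- is.finite(d) && d < 0
    m_new <- if (step_ok) m - s / d else (lo + hi) / 2
    if (!is.finite(m_new) || m_new <= lo || m_new >= hi) m_new <- (lo + hi) / 2
    if (abs(m_new - m) < 1e-10 * max(1, m)) { m <- m_new; break }
    m <- m_new
  }
  ll <- ld_loglik(m, counts, k_max)
  out <- c(list(m_hat = m, mu_hat = m / assay$n_final, loglik = as.numeric(ll)), out)
  if (ci) {
    target <- as.numeric(ll) - 1.92
    f <- function(mm) ld_loglik(mm, counts, k_max) - target
    out$ci_low <- tryCatch(
      stats::uniroot(f, c(max(m * 1e-3, 1e-9), m))$root, error = function(e) 0)
    up <- m * 2
    while (f(up) > 0 && up < 1e7) up <- up * 2
    out$ci_high <- tryCatch(stats::uniroot(f, c(m, up))$root,
      error = function(e) NA_real_)
  }
  class(out) <- "ld_estimate"
  out
}

#' Fold change between two fluctuation-test rate estimates
#'
#' @param estimate_a,estimate_b `ld_estimate` objects (or lists with
#'   `mu_hat`).
#' @return `mu_a / mu_b`; `NA` when `mu_b` is zero.
#' @export
fold_change <- function(estimate_a, estimate_b) {
  if (estimate_b$mu_hat == 0) {
    warning("reference rate is zero; fold change undefined")
    return(NA_real_)
  }
  estimate_a$mu_hat / estimate_b$mu_hat
}

#' @export
print.ld_estimate <- function(x, ...) {
  cat(sprintf("LD estimate%s: m_hat = %.4g, mu_hat = %.4g (%d cultures)\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$m_hat, x$mu_hat, x$n_cultures))
  invisible(x)
}
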