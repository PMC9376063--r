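# run expr under an explicit seed without disturbing global random state
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a random reference genome
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`.
#'
#' @param length Genome length in bases (>= 3, so at least one interior
#'   position has a full trinucleotide context).
#' @param gc_fraction GC content in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @param name Sequence name.
#' @return Named character vector of length 1 (a reference genome).
#' @export
gen_genome <- function(length, gc_fraction = 0.5, seed = 1L, name = "chr") {
  stopifnot(length >= 3)
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0, 1)")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
    (1 - gc_fraction) / 2)
  with_seed(seed, {
    bases <- sample(BASES, length, replace = TRUE, prob = p)
    stats::setNames(paste(bases, collapse = ""), name)
  })
}

#' Ground-truth parameters for a simulated MA experiment
#'
#' Holds the true per-site per-generation SNM and SIM rates, the per-genome
#' per-generation SV rate, the 96-class context spectrum the SNMs are drawn
#' from, and the experiment dimensions, for later recovery tests.
#'
#' @param snm_rate,sim_rate Per-site per-generation rates (>= 0).
#' @param svm_rate Per-genome per-generation structural-variant rate.
#' @param spectrum_weights 96 non-negative weights in [spectrum_contexts()]
#'   order (normalised internally); default uniform.
#' @param n_lines Number of MA lines.
#' @param generations_per_line Total generations G elapsed per line.
#' @param genome_length Genome size used by convenience wrappers.
#' @param progenitor_id Label of the shared MA progenitor.
#' @return Object of class `ma_truth`.
#' @export
ma_truth <- function(snm_rate, sim_rate = 0, svm_rate = 0,
                     spectrum_weights = NULL, n_lines = 25L,
                     generations_per_line = 1500, genome_length = 1e5,
                     progenitor_id = "anc") {
  stopifnot(snm_rate >= 0, sim_rate >= 0, svm_rate >= 0, n_lines >= 1,
    generations_per_line > 0)
  if (is.null(spectrum_weights)) spectrum_weights <- rep(1 / 96, 96)
  stopifnot(length(spectrum_weights) == 96, all(spectrum_weights >= 0),
    sum(spectrum_weights) > 0)
  structure(list(
    snm_rate = snm_rate, sim_rate = sim_rate, svm_rate = svm_rate,
    spectrum_weights = spectrum_weights / sum(spectrum_weights),
    n_lines = as.integer(n_lines),
    generations_per_line = generations_per_line,
    genome_length = genome_length, progenitor_id = progenitor_id
  ), class = "ma_truth")
}

#' Plan of injected artifact calls for filter testing
#'
#' @param n_shared_snm Number of false SNM loci injected identically into
#'   `shared_in_lines` lines each (exercises the cross-line consensus rule).
#' @param shared_in_lines Lines each shared artifact appears in.
#' @param n_lowdepth Number of calls injected with read depth < 4.
#' @param n_outlier_lines Lines whose SNM counts are inflated by
#'   `outlier_factor` (exercises Z-score outlier exclusion).
#' @param outlier_factor Multiplier applied to the expected mutation count of
#'   inflated lines.
#' @return Object of class `artifact_plan`.
#' @export
artifact_plan <- function(n_shared_snm = 0L, shared_in_lines = 3L,
                          n_lowdepth = 0L, n_outlier_lines = 0L,
                          outlier_factor = 10) {
  stopifnot(n_shared_snm >= 0, shared_in_lines >= 1, n_lowdepth >= 0,
    n_outlier_lines >= 0, outlier_factor >= 1)
  structure(list(n_shared_snm = as.integer(n_shared_snm),
    shared_in_lines = as.integer(shared_in_lines),
    n_lowdepth = as.integer(n_lowdepth),
    n_outlier_lines = as.integer(n_outlier_lines),
    outlier_factor = outlier_factor), class = "artifact_plan")
}

# per-site pyrimidine-collapsed context index for one sequence.
# Returns list(ctx = integer vector over interior positions (NA where the
# trinucleotide has a non-ACGT base), id_of = function(p5, ref, p3) -> id).
# id encodes the pyrimidine-strand trinucleotide (X, R, Y), R in {C, T}:
#   id = (R==T)*16 + (X-1)*4 + Y, bases coded A=1 C=2 G=3 T=4.
context_index <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], BASES)
  L <- length(code)
  if (L < 3) return(list(ctx = integer(0), pos = integer(0)))
  ctr <- code[2:(L - 1)]
  lft <- code[1:(L - 2)]
  rgt <- code[3:L]
  pyr <- ctr %in% c(2L, 4L)
  x <- ifelse(pyr, lft, 5L - rgt)
  r <- ifelse(pyr, ctr, 5L - ctr)
  y <- ifelse(pyr, rgt, 5L - lft)
  ctx <- (r == 4L) * 16L + (x - 1L) * 4L + y
  ctx[is.na(lft) | is.na(ctr) | is.na(rgt)] <- NA_integer_
  list(ctx = as.integer(ctx), pos = 2:(L - 1))
}

# map each of the 96 context classes to its 32-level context id and alt base
class_meta <- function() {
  labels <- spectrum_contexts()
  p5 <- substr(labels, 1, 1)
  ref <- substr(labels, 3, 3)
  alt <- substr(labels, 5, 5)
  p3 <- substr(labels, 7, 7)
  id <- (match(ref, BASES) == 4L) * 16L +
    (match(p5, BASES) - 1L) * 4L + match(p3, BASES)
  data.frame(label = labels, ctx = as.integer(id), ref = ref, alt = alt,
    stringsAsFactors = FALSE)
}

#' Simulate a mutation-accumulation experiment
#'
#' Emulates daily single-colony bottlenecking, under which nearly all
#' mutations fix by drift: per line, SNM counts are Poisson with mean
#' `snm_rate * G * n` (n = interior sites with a full ACGT context), each SNM
#' placed at a site whose pyrimidine-strand trinucleotide matches a class
#' drawn from `truth$spectrum_weights` (restricted, with a warning and
#' renormalisation, to contexts present in the genome); sites are drawn
#' without replacement within a line. SIM counts are Poisson with mean
#' `sim_rate * G * n` with indel lengths uniform on 1-4; SV counts Poisson
#' with mean `svm_rate * G`. Clean calls get depth ~ Poisson(150) and
#' phred quality 60 so they pass the default quality filters. Artifact calls
#' from `plan` are appended with an `ARTIFACT` INFO tag.
#'
#' @param truth An [ma_truth()].
#' @param genome Named character vector (see [gen_genome()], [read_fasta()]).
#' @param plan An [artifact_plan()].
#' @param seed Integer seed.
#' @return List: `calls` (mutation-call data frame), `lines` (data frame
#'   line_id, progenitor_id, generations, covered_sites, inflated), `truth`.
#' @export
simulate_ma <- function(truth, genome, plan = artifact_plan(), seed = 1L) {
  stopifnot(inherits(truth, "ma_truth"), inherits(plan, "artifact_plan"))
  cm <- class_meta()
  idx <- lapply(genome, context_index)
  # flatten (chrom, pos, ctx) over all sequences
  chrom_v <- rep(names(genome), vapply(idx, function(i) length(i$pos), 0L))
  pos_v <- unlist(lapply(idx, function(i) i$pos), use.names = FALSE)
  ctx_v <- unlist(lapply(idx, function(i) i$ctx), use.names = FALSE)
  valid <- !is.na(ctx_v)
  n_sites <- sum(valid)
  if (n_sites < 1) stop("genome has no interior site with full ACGT context")
  sites_by_ctx <- split(which(valid), ctx_v[valid])
  w <- truth$spectrum_weights
  avail <- cm$ctx %in% as.integer(names(sites_by_ctx))
  if (any(w[!avail] > 0)) {
    warning("spectrum weight on context classes absent from the genome; ",
      "renormalising over available contexts")
    w[!avail] <- 0
    if (sum(w) == 0) stop("no spectrum weight on any available context")
    w <- w / sum(w)
  }
  G <- truth$generations_per_line
  with_seed(seed, {
    inflated <- sort(sample(truth$n_lines,
      min(plan$n_outlier_lines, truth$n_lines)))
    line_ids <- sprintf("%s-L%02d", truth$progenitor_id, seq_len(truth$n_lines))
    calls <- list()
    for (li in seq_len(truth$n_lines)) {
      fac <- if (li %in% inflated) plan$outlier_factor else 1
      # --- SNMs, placed by context ---
      n_snm <- stats::rpois(1, truth$snm_rate * fac * G * n_sites)
      if (n_snm > 0) {
        cls <- sample.int(96, n_snm, replace = TRUE, prob = w)
        used <- integer(0)
        for (ct in unique(cm$ctx[cls])) {
          members <- which(cm$ctx[cls] == ct)
          pool <- setdiff(sites_by_ctx[[as.character(ct)]], used)
          if (length(members) > length(pool))
            stop("context ", ct, " exhausted: genome too small for the requested rate")
          picked <- pool[sample.int(length(pool), length(members))]
          used <- c(used, picked)
          for (j in seq_along(members)) {
            k <- cls[members[j]]
            site <- picked[j]
            base <- substr(genome[[chrom_v[site]]], pos_v[site], pos_v[site])
            pyr <- base %in% c("C", "T")
            calls[[length(calls) + 1L]] <- data.frame(
              line_id = line_ids[li], chrom = chrom_v[site], pos = pos_v[site],
              ref = base,
              alt = if (pyr) cm$alt[k] else unname(COMPLEMENT[cm$alt[k]]),
              mclass = "SNM", depth = stats::rpois(1, 150), qual = 60,
              sv_type = NA_character_, sv_start = NA_integer_,
              sv_end = NA_integer_, source = "sim", info = ".",
              stringsAsFactors = FALSE)
          }
        }
      }
      # --- SIMs: indels of 1-4 bp at uniform interior positions ---
      n_sim <- stats::rpois(1, truth$sim_rate * G * n_sites)
      for (j in seq_len(n_sim)) {
        site <- sample.int(length(pos_v), 1)
        chrom <- chrom_v[site]
        len <- sample.int(4L, 1)
        pos <- min(pos_v[site], nchar(genome[[chrom]]) - len)
        if (stats::runif(1) < 0.5) {  # deletion
          ref <- substr(genome[[chrom]], pos, pos + len)
          alt <- substr(ref, 1, 1)
        } else {                      # insertion
          alt0 <- substr(genome[[chrom]], pos, pos)
          ref <- alt0
          alt <- paste0(alt0, paste(sample(BASES, len, replace = TRUE),
            collapse = ""))
        }
        calls[[length(calls) + 1L]] <- data.frame(
          line_id = line_ids[li], chrom = chrom, pos = pos, ref = ref,
          alt = alt, mclass = "SIM", depth = stats::rpois(1, 150), qual = 60,
          sv_type = NA_character_, sv_start = NA_integer_,
          sv_end = NA_integer_, source = "sim", info = ".",
          stringsAsFactors = FALSE)
      }
      # --- SVs: per-genome events ---
      n_sv <- stats::rpois(1, truth$svm_rate * G)
      for (j in seq_len(n_sv)) {
        chrom <- sample(names(genome), 1)
        L <- nchar(genome[[chrom]])
        len <- sample(100:min(10000, max(100, L %/% 2)), 1)
        start <- sample.int(max(1L, L - len), 1)
        calls[[length(calls) + 1L]] <- data.frame(
          line_id = line_ids[li], chrom = chrom, pos = start, ref = "N",
          alt = "<SV>", mclass = "SV", depth = stats::rpois(1, 150), qual = 60,
          sv_type = sample(c("DEL", "DUP", "INV", "INS"), 1),
          sv_start = start, sv_end = start + len - 1L, source = "sim",
          info = ".", stringsAsFactors = FALSE)
      }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else empty_calls()
    # --- injected artifacts ---
    if (plan$n_shared_snm > 0) {
      if (plan$shared_in_lines > truth$n_lines)
        stop("shared_in_lines exceeds n_lines")
      art_sites <- which(valid)[sample.int(n_sites, plan$n_shared_snm)]
      for (site in art_sites) {
        base <- substr(genome[[chrom_v[site]]], pos_v[site], pos_v[site])
        alt <- sample(setdiff(BASES, base), 1)
        in_lines <- sample(line_ids, plan$shared_in_lines)
        for (l in in_lines) {
          calls <- rbind(calls, data.frame(
            line_id = l, chrom = chrom_v[site], pos = pos_v[site], ref = base,
            alt = alt, mclass = "SNM", depth = stats::rpois(1, 150), qual = 60,
            sv_type = NA_character_, sv_start = NA_integer_,
            sv_end = NA_integer_, source = "sim", info = "ARTIFACT=shared",
            stringsAsFactors = FALSE))
        }
      }
    }
    if (plan$n_lowdepth > 0) {
      for (j in seq_len(plan$n_lowdepth)) {
        site <- which(valid)[sample.int(n_sites, 1)]
        base <- substr(genome[[chrom_v[site]]], pos_v[site], pos_v[site])
        calls <- rbind(calls, data.frame(
          line_id = sample(line_ids, 1), chrom = chrom_v[site],
          pos = pos_v[site], ref = base, alt = sample(setdiff(BASES, base), 1),
          mclass = "SNM", depth = sample(0:3, 1), qual = 60,
          sv_type = NA_character_, sv_start = NA_integer_,
          sv_end = NA_integer_, source = "sim", info = "ARTIFACT=lowdepth",
          stringsAsFactors = FALSE))
      }
    }
    lines <- data.frame(line_id = line_ids,
      progenitor_id = truth$progenitor_id, generations = G,
      covered_sites = n_sites,
      inflated = seq_len(truth$n_lines) %in% inflated,
      stringsAsFactors = FALSE)
    ma_log("simulate_ma", nrow(calls), " call(s) across ", truth$n_lines,
      " line(s), ", n_sites, " callable sites")
    list(calls = as_calls(calls), lines = lines, truth = truth)
  })
}

#' Simulate a Luria-Delbruck fluctuation assay
#'
#' Per culture, mutational events M ~ Poisson(m) with
#' `m = mu_per_division * n_final`; each event founds a clone whose size has
#' the Lea-Coulson tail `P(S >= s) = 1/s`, drawn as `ceiling(1/U) - 1` with U
#' uniform on (0, 1], zero-size draws discarded, sizes capped at `n_final`.
#' The observed mutant count is the sum of clone sizes.
#'
#' @param mu_per_division Mutation rate per cell division, in (0, 1); zero
#'   allowed (all counts zero).
#' @param n_final Final cells per culture (>= 2).
#' @param n_cultures Number of parallel cultures.
#' @param seed Integer seed.
#' @param label Tag carried on the assay.
#' @return A [fluctuation_assay()].
#' @export
simulate_fluctuation <- function(mu_per_division, n_final, n_cultures,
                                 seed = 1L, label = "") {
  stopifnot(mu_per_division >= 0, mu_per_division < 1, n_final >= 2,
    n_cultures >= 1)
  m <- mu_per_division * n_final
  with_seed(seed, {
    counts <- vapply(seq_len(n_cultures), function(i) {
      M <- stats::rpois(1, m)
      if (M == 0) return(0)
      sizes <- numeric(M)
      for (j in seq_len(M)) {
        s <- 0
        while (s < 1) s <- ceiling(1 / stats::runif(1)) - 1
        sizes[j] <- min(s, n_final)
      }
      sum(sizes)
    }, 0)
    fluctuation_assay(counts, n_final, label)
  })
}

#' Simulate a genomic-divergence time series
#'
#' `y_i = slope * x_i + Normal(0, noise_sd)`, truncated at zero.
#'
#' @param slope True divergence per generation (>= 0).
#' @param timepoints Increasing vector of generation counts.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame (`generations`, `divergence`).
#' @export
simulate_divergence <- function(slope, timepoints, noise_sd = 0, seed = 1L) {
  stopifnot(slope >= 0, noise_sd >= 0, !is.unsorted(timepoints))
  with_seed(seed, {
    y <- pmax(0, slope * timepoints + stats::rnorm(length(timepoints), 0, noise_sd))
    data.frame(generations = timepoints, divergence = y)
  })
}
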