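#' Generations per passage from CFU-derived generation counts
#'
#' Daily single-colony passaging slows as lines accumulate load; generations
#' per passage are interpolated from colony generation counts measured at day
#' 0, day 30 and the last day N of the experiment, with the two halves of the
#' run weighted as
#' `((G0 + G30) * a + (G30 + GN) * b) / N`, `a = 15`, `b = N/2 - 15`.
#'
#' @param G0,G30,GN Generations per passage estimated at days 0, 30, and the
#'   last day.
#' @param N Total days of the experiment (>= 30 so the weights are
#'   non-negative).
#' @return Mean generations per passage.
#' @export
passage_generations <- function(G0, G30, GN, N) {
  stopifnot(G0 > 0, G30 > 0, GN > 0)
  if (N < 30) stop("N must be >= 30: weighting is undefined for shorter runs")
  a <- 15
  b <- N / 2 - 15
  ((G0 + G30) * a + (G30 + GN) * b) / N
}

#' Per-site per-generation mutation rate
#'
#' `u = m / (G * n)` for m observed mutations over G generations and n
#' ancestral sites covered at high quality. Used for SNM and SIM rates.
#'
#' @param m Observed mutation count (>= 0).
#' @param G Total generations elapsed in the lineage (> 0).
#' @param n Number of covered ancestral sites (> 0).
#' @return Mutation rate per site per generation. Vectorised.
#' @export
site_rate <- function(m, G, n) {
  if (any(G <= 0)) stop("G must be > 0")
  if (any(n <= 0)) stop("n must be > 0")
  stopifnot(all(m >= 0))
  m / (G * n)
}

#' Per-genome per-generation mutation rate
#'
#' `u = m / G`; used for structural-variant rates, which are counted per
#' genome rather than per site.
#'
#' @inheritParams site_rate
#' @return Mutation rate per genome per generation. Vectorised.
#' @export
genome_rate <- function(m, G) {
  if (any(G <= 0)) stop("G must be > 0")
  stopifnot(all(m >= 0))
  m / G
}

#' Z-score exclusion of lines with odd mutation rates
#'
#' Within one MA progenitor, a line is excluded when `|u - U| / S` exceeds
#' `cutoff`, with U and S the mean and sample standard deviation of the rates
#' of ALL lines of that progenitor. Single pass: U and S are not recomputed
#' after exclusions. When S = 0 all Z are defined as 0 and nothing is
#' excluded.
#'
#' @param rates Named numeric vector of per-line rates (names = line ids) for
#'   one progenitor and one mutation class.
#' @param cutoff Absolute Z-score threshold (default 2.5).
#' @return List with `kept`, `excluded` (both named numeric vectors) and `z`
#'   (Z-score per line).
#' @export
zscore_exclude <- function(rates, cutoff = 2.5) {
  stopifnot(is.numeric(rates), length(rates) >= 2)
  U <- mean(rates)
  S <- stats::sd(rates)
  z <- if (S == 0) rep(0, length(rates)) else (rates - U) / S
  names(z) <- names(rates)
  out <- abs(z) > cutoff
  list(kept = rates[!out], excluded = rates[out], z = z)
}

#' Per-line and per-group mutation-rate table
#'
#' Counts mutations per (line, class) among filtered calls, converts them to
#' rates with [site_rate()] (SNM, SIM) or [genome_rate()] (SV), applies
#' [zscore_exclude()] within each progenitor and class, and summarises each
#' progenitor group by mean, SEM and line count.
#'
#' @param calls Filtered mutation-call data frame.
#' @param lines Data frame of MA lines with columns `line_id`,
#'   `progenitor_id`, `generations` (G) and `covered_sites` (n). Lines with no
#'   calls count as zero mutations.
#' @param cutoff Z-score cutoff passed to [zscore_exclude()]; `Inf` disables
#'   outlier exclusion.
#' @return List of data frames `per_line` (line_id, progenitor_id, mclass, m,
#'   u, excluded) and `per_group` (progenitor_id, mclass, mean, sem, n_lines).
#' @export
rate_table <- function(calls, lines, cutoff = 2.5) {
  calls <- as_calls(calls)
  stopifnot(all(c("line_id", "progenitor_id", "generations", "covered_sites")
    %in% names(lines)))
  stopifnot(all(lines$generations > 0), all(lines$covered_sites > 0))
  classes <- c("SNM", "SIM", "SV")
  per_line <- expand.grid(line_id = lines$line_id, mclass = classes,
    stringsAsFactors = FALSE)
  per_line <- merge(per_line,
    lines[, c("line_id", "progenitor_id", "generations", "covered_sites")],
    by = "line_id")
  cnt <- table(factor(calls$line_id, levels = lines$line_id),
    factor(calls$mclass, levels = classes))
  per_line$m <- mapply(function(l, cl) cnt[l, cl],
    per_line$line_id, per_line$mclass)
  per_line$u <- ifelse(per_line$mclass == "SV",
    genome_rate(per_line$m, per_line$generations),
    site_rate(per_line$m, per_line$generations, per_line$covered_sites))
  per_line$excluded <- FALSE
  for (prog in unique(per_line$progenitor_id)) {
    for (cl in classes) {
      idx <- which(per_line$progenitor_id == prog & per_line$mclass == cl)
      if (length(idx) < 2 || !is.finite(cutoff)) next
      ex <- zscore_exclude(stats::setNames(per_line$u[idx], per_line$line_id[idx]),
        cutoff)
      per_line$excluded[idx] <- names(ex$z) %in% names(ex$excluded)
    }
  }
  keep <- per_line[!per_line$excluded, , drop = FALSE]
  groups <- unique(per_line[, c("progenitor_id", "mclass")])
  per_group <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    u <- keep$u[keep$progenitor_id == groups$progenitor_id[i] &
                  keep$mclass == groups$mclass[i]]
    data.frame(progenitor_id = groups$progenitor_id[i], mclass = groups$mclass[i],
      mean = mean(u), sem = stats::sd(u) / sqrt(length(u)), n_lines = length(u),
      stringsAsFactors = FALSE)
  }))
  n_ex <- sum(per_line$excluded)
  ma_log("rates", nrow(per_line), " line-class rates, ", n_ex, " excluded as outliers")
  per_line$generations <- NULL
  per_line$covered_sites <- NULL
  list(per_line = per_line, per_group = per_group)
}

#' Compare mean mutation rates between two groups of MA lines
#'
#' Two-tailed unpaired t-test (Welch's unequal-variance test by default) with
#' the fold change of group means.
#'
#' @param rates_a,rates_b Numeric vectors of per-line rates (>= 2 each).
#' @param welch Use Welch's unequal-variance test (default); `FALSE` gives
#'   Student's pooled-variance test.
#' @return List: `fold_change` (mean_a / mean_b), `t_stat`, `p_value`, `df`,
#'   `mean_a`, `mean_b`, `sem_a`, `sem_b`, `direction`.
#' @export
compare_groups <- function(rates_a, rates_b, welch = TRUE) {
  stopifnot(length(rates_a) >= 2, length(rates_b) >= 2)
  ma <- mean(rates_a); mb <- mean(rates_b)
  va <- stats::var(rates_a); vb <- stats::var(rates_b)
  na <- length(rates_a); nb <- length(rates_b)
  if (va == 0 && vb == 0 && ma == mb) {
    t <- 0; df <- na + nb - 2; p <- 1
  } else if (welch) {
    se2 <- va / na + vb / nb
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(fold_change = if (mb > 0) ma / mb else NA_real_,
    t_stat = t, p_value = p, df = df,
    mean_a = ma, mean_b = mb,
    sem_a = sqrt(va / na), sem_b = sqrt(vb / nb),
    direction = if (ma >= mb) "increase" else "decrease")
}
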