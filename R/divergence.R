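#' Genomic divergence at one timepoint
#'
#' Divergence of a population sample from its ancestor is the sum of derived
#' allele frequencies over all detected single-nucleotide mutations.
#'
#' @param allele_frequencies Numeric vector of derived allele frequencies in
#'   `[0, 1]` (may be empty).
#' @return Sum of frequencies.
#' @export
divergence_at_timepoint <- function(allele_frequencies) {
  if (length(allele_frequencies) &&
      (any(allele_frequencies < 0) || any(allele_frequencies > 1)))
    stop("allele frequencies must lie in [0, 1]")
  sum(allele_frequencies)
}

#' Rate of genomic evolution by zero-intercept regression
#'
#' Fits divergence ~ generations + 0 by least squares: the slope is
#' sum(x*y) / sum(x^2), with residual degrees of freedom n - 1 for the
#' standard error (no intercept is estimated).
#'
#' @param generations Non-negative, strictly increasing regressor x.
#' @param divergence Non-negative response y, same length.
#' @return List: `slope` (divergence per generation), `se`, `n`.
#' @export
evolution_rate <- function(generations, divergence) {
  x <- generations; y <- divergence
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (is.unsorted(x, strictly = TRUE)) stop("generations must be strictly increasing")
  if (all(x == 0)) stop("all generations are zero; slope undefined")
  # closed-form zero-intercept least squares (equivalent to lm(y ~ x + 0))
  slope <- sum(x * y) / sum(x^2)
  rss <- sum((y - slope * x)^2)
  list(slope = slope,
    se = sqrt(rss / (length(x) - 1) / sum(x^2)),
    n = length(x))
}

#' Divergence series from a long allele-frequency table
#'
#' @param freqs Data frame with columns `generations`, `locus`, `frequency`;
#'   frequencies are summed within each timepoint.
#' @return Data frame (`generations`, `divergence`) sorted by generations.
#' @export
divergence_series <- function(freqs) {
  stopifnot(all(c("generations", "locus", "frequency") %in% names(freqs)))
  agg <- tapply(freqs$frequency, freqs$generations, divergence_at_timepoint)
  out <- data.frame(generations = as.numeric(names(agg)),
    divergence = as.numeric(agg))
  out[order(out$generations), , drop = FALSE]
}
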