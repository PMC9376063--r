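#' Serial-transfer scheme
#'
#' @param dilution Dilution factor D applied at each transfer, in (0, 1).
#' @param period_days Days between transfers.
#' @param capacity Carrying capacity K (cells per culture); defaults to the
#'   ~1e10 cells/tube typical of rich-media E. coli tubes.
#' @return Object of class `transfer_scheme`.
#' @export
transfer_scheme <- function(dilution, period_days = 1L, capacity = 1e10) {
  stopifnot(dilution > 0, dilution < 1, period_days >= 1, capacity >= 1 / dilution)
  structure(list(dilution = dilution, period_days = as.integer(period_days),
    capacity = capacity), class = "transfer_scheme")
}

#' Census trajectory through one growth cycle
#'
#' After a transfer the population starts at the bottleneck N0 = K * D and
#' doubles back to carrying capacity. The census snapshots are the integer
#' doublings N0 * 2^i strictly below K, followed by the final size K.
#'
#' @param scheme A [transfer_scheme()].
#' @return Numeric vector of census sizes.
#' @export
census_trajectory <- function(scheme) {
  stopifnot(inherits(scheme, "transfer_scheme"))
  n0 <- scheme$capacity * scheme$dilution
  sizes <- n0
  while (sizes[length(sizes)] * 2 < scheme$capacity)
    sizes <- c(sizes, sizes[length(sizes)] * 2)
  c(sizes, scheme$capacity)
}

#' Harmonic-mean effective population size
#'
#' For serial dilution the effective size is the harmonic mean of the
#' fluctuating census sizes through the growth cycle, k / sum(1/N_i).
#'
#' @param trajectory Numeric vector of census sizes (all >= 1).
#' @return Effective population size.
#' @export
harmonic_ne <- function(trajectory) {
  if (length(trajectory) == 0L) stop("empty census trajectory")
  stopifnot(all(trajectory >= 1))
  length(trajectory) / sum(1 / trajectory)
}

#' Generations per day under a transfer scheme
#'
#' Each cycle regrows the dilution, giving log2(1/D) doublings per
#' `period_days` days.
#'
#' @param scheme A [transfer_scheme()].
#' @return Generations per day.
#' @export
generations_per_day <- function(scheme) {
  stopifnot(inherits(scheme, "transfer_scheme"))
  log2(1 / scheme$dilution) / scheme$period_days
}

#' @export
print.transfer_scheme <- function(x, ...) {
  cat(sprintf("transfer scheme: D=%g every %d day(s), K=%g\n",
    x$dilution, x$period_days, x$capacity))
  invisible(x)
}
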