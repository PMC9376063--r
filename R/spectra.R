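BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(b)
    paste(rev(COMPLEMENT[b]), collapse = ""), "")
}

#' Canonical 96-class trinucleotide context labels
#'
#' Labels have the form `X[R>A]Y` with a pyrimidine focal base R (C or T),
#' mutant base A != R, and flanking bases X (5') and Y (3'). Ordering follows
#' the conventional six substitution blocks C>A, C>G, C>T, T>A, T>C, T>G with
#' the 16 flank combinations sorted alphabetically, 5' flank major.
#'
#' @return Character vector of the 96 labels.
#' @export
spectrum_contexts <- function() {
  out <- character(0)
  for (ref in c("C", "T")) for (alt in setdiff(BASES, ref))
    for (p5 in BASES) for (p3 in BASES)
      out <- c(out, sprintf("%s[%s>%s]%s", p5, ref, alt, p3))
  out
}

#' The six substitution classes
#'
#' @return Character vector `c("C>A", ..., "T>G")`.
#' @export
six_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Pyrimidine-centred context class of a single-nucleotide mutation
#'
#' When the reference base is a purine (A or G) the mutation and both flanks
#' are reverse-complemented before labelling, so every label carries a
#' pyrimidine focal base and the flanks swap roles under the flip.
#'
#' @param ref_base,alt_base Reference and mutant base at the focal site.
#' @param five_prime,three_prime Flanking reference bases (reference strand).
#' @return Class label, e.g. `"A[C>T]G"`. Vectorised.
#' @export
context_class <- function(ref_base, alt_base, five_prime, three_prime) {
  args <- cbind(ref_base, alt_base, five_prime, three_prime)
  if (any(!args %in% BASES)) stop("bases must be one of A, C, G, T")
  if (any(ref_base == alt_base)) stop("ref and alt must differ")
  flip <- ref_base %in% c("A", "G")
  r <- ifelse(flip, COMPLEMENT[ref_base], ref_base)
  a <- ifelse(flip, COMPLEMENT[alt_base], alt_base)
  p5 <- ifelse(flip, COMPLEMENT[three_prime], five_prime)
  p3 <- ifelse(flip, COMPLEMENT[five_prime], three_prime)
  sprintf("%s[%s>%s]%s", p5, r, a, p3)
}

#' Build a 96-class contextual mutation spectrum from SNM calls
#'
#' Counts each single-nucleotide mutation by the pyrimidine-centred class of
#' its reference trinucleotide. Calls at sequence ends, with a non-ACGT base
#' anywhere in the trinucleotide, or whose ref allele disagrees with the
#' genome are skipped and counted in `skipped`.
#'
#' @param snm_calls Mutation-call data frame; only rows with `mclass == "SNM"`
#'   are used.
#' @param genome Named character vector of uppercase sequences
#'   (see [read_fasta()]).
#' @return Object of class `context_spectrum`: list with `counts` (named
#'   integer vector over [spectrum_contexts()]), `six_class` (aggregate over
#'   flanks), `skipped`, and `errors` (per-call ref-mismatch records).
#' @export
build_spectrum <- function(snm_calls, genome) {
  snm_calls <- as_calls(snm_calls)
  snm <- snm_calls[snm_calls$mclass == "SNM", , drop = FALSE]
  labels <- spectrum_contexts()
  counts <- stats::setNames(integer(96), labels)
  skipped <- 0L
  errors <- empty_calls()
  if (nrow(snm)) {
    lens <- nchar(genome)
    keep <- logical(nrow(snm))
    lab <- character(nrow(snm))
    for (i in seq_len(nrow(snm))) {
      chrom <- snm$chrom[i]; pos <- snm$pos[i]
      if (!chrom %in% names(genome) || pos < 2L || pos > lens[[chrom]] - 1L) {
        skipped <- skipped + 1L
        next
      }
      tri <- strsplit(substr(genome[[chrom]], pos - 1L, pos + 1L), "")[[1]]
      if (tri[2] != snm$ref[i]) {
        errors <- rbind(errors, snm[i, , drop = FALSE])
        skipped <- skipped + 1L
        next
      }
      if (any(!tri %in% BASES) || !snm$alt[i] %in% BASES) {
        skipped <- skipped + 1L
        next
      }
      lab[i] <- context_class(tri[2], snm$alt[i], tri[1], tri[3])
      keep[i] <- TRUE
    }
    if (any(keep)) {
      tab <- table(factor(lab[keep], levels = labels))
      counts <- counts + as.integer(tab)
      names(counts) <- labels
    }
  }
  six <- stats::setNames(integer(6), six_classes())
  core <- sub("^.\\[", "", sub("\\].$", "", labels))
  for (cl in six_classes()) six[cl] <- sum(counts[core == cl])
  if (skipped) ma_log("build_spectrum", skipped, " call(s) skipped")
  structure(list(counts = counts, six_class = six, skipped = skipped,
    errors = errors), class = "context_spectrum")
}

#' Spectrum counts as frequencies
#'
#' @param spectrum A `context_spectrum`.
#' @return Named numeric vector summing to 1 (all-zero spectra return zeros).
#' @export
spectrum_frequencies <- function(spectrum) {
  n <- sum(spectrum$counts)
  if (n == 0) return(spectrum$counts * 0)
  spectrum$counts / n
}

#' Assemble per-sample spectra into a 96 x samples count matrix
#'
#' @param spectra Named list of `context_spectrum` objects.
#' @return Integer matrix, rows in [spectrum_contexts()] order.
#' @export
spectrum_matrix <- function(spectra) {
  stopifnot(length(spectra) > 0L, !is.null(names(spectra)))
  m <- vapply(spectra, function(s) s$counts, integer(96))
  rownames(m) <- spectrum_contexts()
  m
}

#' @export
print.context_spectrum <- function(x, ...) {
  cat("96-class context spectrum:", sum(x$counts), "mutations,",
    x$skipped, "skipped\n")
  print(x$six_class)
  invisible(x)
}
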