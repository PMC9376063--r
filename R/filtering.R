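#' Post-calling filter thresholds
#'
#' Defaults follow the standard MA pipeline: candidate variants with read
#' depth < 4 or phred score < 10 are discarded; SNM (SIM) calls present in
#' more than two (four) MA lines of one progenitor are consensus artifacts;
#' SVs matching within a 500-bp end window an ancestral SV, or found in at
#' least three parallel lines, are removed; indels above 4 bp are structural.
#'
#' @param min_depth Minimum read depth kept.
#' @param min_qual Minimum phred quality kept.
#' @param snm_consensus_limit SNM calls in more than this many lines are
#'   removed.
#' @param sim_consensus_limit Likewise for SIMs.
#' @param sv_parallel_limit SVs whose match-class spans at least this many
#'   lines are removed.
#' @param sv_window Maximum end-coordinate slack (bp) for SV matching.
#' @param max_sim_len Largest indel (bp) classified as SIM.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 4L, min_qual = 10, snm_consensus_limit = 2L,
                          sim_consensus_limit = 4L, sv_parallel_limit = 3L,
                          sv_window = 500L, max_sim_len = 4L) {
  cfg <- list(min_depth = as.integer(min_depth), min_qual = min_qual,
    snm_consensus_limit = as.integer(snm_consensus_limit),
    sim_consensus_limit = as.integer(sim_consensus_limit),
    sv_parallel_limit = as.integer(sv_parallel_limit),
    sv_window = as.integer(sv_window), max_sim_len = as.integer(max_sim_len))
  stopifnot(all(vapply(cfg, function(x) x >= 0, TRUE)))
  structure(cfg, class = "filter_config")
}

call_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

# attach a removal reason and bind kept/removed partitions
partition <- function(calls, keep, reason) {
  removed <- calls[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!keep] else removed$reason <- character(0)
  list(kept = calls[keep, , drop = FALSE], removed = removed)
}

#' Depth and quality filter
#'
#' Keeps a call iff `depth >= min_depth` and `qual >= min_qual` (the discard
#' rule is strict: depths below 4 or phreds below 10 go). Calls with missing
#' depth or quality are removed with reason `"missing-evidence"`.
#'
#' @param calls Mutation-call data frame.
#' @param config A [filter_config()].
#' @return List `kept` / `removed` (removed carries a `reason` column); the
#'   partition is exhaustive and no call is modified.
#' @export
quality_filter <- function(calls, config = filter_config()) {
  calls <- as_calls(calls)
  missing <- is.na(calls$depth) | is.na(calls$qual)
  ok <- !missing & calls$depth >= config$min_depth & calls$qual >= config$min_qual
  reason <- ifelse(missing, "missing-evidence", "low-depth-or-qual")
  out <- partition(calls, ok, reason)
  ma_log("quality_filter", nrow(calls), " in, ", nrow(out$kept), " kept")
  out
}

#' Subtract ancestral variants
#'
#' Removes, from every line, any call whose identity key
#' (chrom, pos, ref, alt) appears among the variants of the MA progenitor
#' (ancestral variants are differences between reference and progenitor, not
#' mutations that arose during the MA experiment).
#'
#' @param calls Mutation-call data frame.
#' @param ancestral_calls Calls identified in the progenitor.
#' @return List `kept` / `removed` (reason `"ancestral"`).
#' @export
subtract_ancestral <- function(calls, ancestral_calls) {
  calls <- as_calls(calls)
  anc <- if (nrow(ancestral_calls)) unique(call_key(as_calls(ancestral_calls)))
    else character(0)
  keep <- !(call_key(calls) %in% anc)
  out <- partition(calls, keep, rep("ancestral", nrow(calls)))
  ma_log("subtract_ancestral", nrow(calls), " in, ", nrow(out$kept), " kept")
  out
}

#' Cross-line consensus filter
#'
#' Within one MA progenitor, an SNM key present in more than
#' `snm_consensus_limit` distinct lines (a SIM key, more than
#' `sim_consensus_limit`) is a shared artifact or ancestral residue and is
#' removed from every line carrying it.
#'
#' @param calls Mutation-call data frame (all lines share one progenitor).
#' @param config A [filter_config()].
#' @return List `kept` / `removed` (reason `"consensus"`).
#' @export
consensus_filter <- function(calls, config = filter_config()) {
  calls <- as_calls(calls)
  keep <- rep(TRUE, nrow(calls))
  for (cl in c("SNM", "SIM")) {
    limit <- if (cl == "SNM") config$snm_consensus_limit else config$sim_consensus_limit
    sel <- calls$mclass == cl
    if (!any(sel)) next
    keys <- call_key(calls[sel, , drop = FALSE])
    nlines <- tapply(calls$line_id[sel], keys, function(x) length(unique(x)))
    bad_keys <- names(nlines)[nlines > limit]
    keep[which(sel)[keys %in% bad_keys]] <- FALSE
  }
  out <- partition(calls, keep, rep("consensus", nrow(calls)))
  ma_log("consensus_filter", nrow(calls), " in, ", nrow(out$kept), " kept")
  out
}

# TRUE when two SVs of the same type have both interval ends within `window`
sv_match <- function(a_type, a_start, a_end, b_type, b_start, b_end, window) {
  a_type == b_type & abs(a_start - b_start) <= window & abs(a_end - b_end) <= window
}

#' Deduplicate SV predictions across callers
#'
#' Callers are visited in `precedence` order (the supported convention:
#' Lumpy, then CNVnator, then BreakDancer). An SV from a later caller is
#' redundant, and dropped, iff some retained SV of the same type from an
#' earlier caller has both interval ends within `window` bases of it.
#'
#' @param sv_calls Mutation-call data frame of SVs with `source`, `sv_type`,
#'   `sv_start`, `sv_end` populated.
#' @param precedence Ordered character vector of source tags.
#' @param window End slack in bases.
#' @return List `kept` / `removed` (reason `"redundant"`).
#' @export
sv_dedup <- function(sv_calls, precedence = c("Lumpy", "CNVnator", "BreakDancer"),
                     window = 500L) {
  calls <- as_calls(sv_calls)
  unknown <- setdiff(unique(calls$source), precedence)
  if (length(unknown)) stop("unknown SV source tag(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(calls))
  retained <- integer(0)
  for (src in precedence) {
    idx <- which(calls$source == src)
    for (i in idx) {
      red <- FALSE
      for (j in retained) {
        if (calls$chrom[i] == calls$chrom[j] &&
            sv_match(calls$sv_type[i], calls$sv_start[i], calls$sv_end[i],
              calls$sv_type[j], calls$sv_start[j], calls$sv_end[j], window)) {
          red <- TRUE
          break
        }
      }
      if (red) keep[i] <- FALSE else retained <- c(retained, i)
    }
  }
  out <- partition(calls, keep, rep("redundant", nrow(calls)))
  ma_log("sv_dedup", nrow(calls), " in, ", nrow(out$kept), " kept")
  out
}

# single-linkage match classes over the both-ends-within-window relation
sv_match_classes <- function(calls, window) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (calls$chrom[i] == calls$chrom[j] &&
        sv_match(calls$sv_type[i], calls$sv_start[i], calls$sv_end[i],
          calls$sv_type[j], calls$sv_start[j], calls$sv_end[j], window)) {
      old <- comp[j]; new <- comp[i]
      comp[comp == old] <- new
    }
  }
  match(comp, unique(comp))
}

#' Remove ancestral and parallel structural variants
#'
#' An SV is removed iff it matches an ancestral SV (same type, both ends
#' within `sv_window`) or its match-class — built by single linkage over the
#' pairwise both-ends-within-window relation — spans at least
#' `sv_parallel_limit` distinct MA lines.
#'
#' @param sv_calls SV mutation-call data frame.
#' @param ancestral_svs SVs called in the MA ancestral clone.
#' @param config A [filter_config()].
#' @return List `kept` / `removed` (reason `"ancestral-sv"` or
#'   `"parallel-sv"`).
#' @export
sv_parallel_filter <- function(sv_calls, ancestral_svs = empty_calls(),
                               config = filter_config()) {
  calls <- as_calls(sv_calls)
  anc <- as_calls(ancestral_svs)
  w <- config$sv_window
  n <- nrow(calls)
  anc_hit <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(nrow(anc)), function(j)
      calls$chrom[i] == anc$chrom[j] &&
        sv_match(calls$sv_type[i], calls$sv_start[i], calls$sv_end[i],
          anc$sv_type[j], anc$sv_start[j], anc$sv_end[j], w), TRUE))
  }, TRUE)
  cls <- sv_match_classes(calls, w)
  par_hit <- rep(FALSE, n)
  if (n) {
    span <- tapply(calls$line_id, cls, function(x) length(unique(x)))
    par_hit <- span[as.character(cls)] >= config$sv_parallel_limit
  }
  keep <- !(anc_hit | par_hit)
  reason <- ifelse(anc_hit, "ancestral-sv", "parallel-sv")
  out <- partition(calls, keep, reason)
  ma_log("sv_parallel_filter", n, " in, ", nrow(out$kept), " kept")
  out
}

#' Full post-calling filter pipeline
#'
#' SNM/SIM route: quality filter, ancestral subtraction, cross-line consensus
#' removal. SV route: cross-caller dedup, then ancestral/parallel removal.
#' Composing the stages is idempotent; calls are only partitioned, never
#' modified.
#'
#' @param calls Mutation-call data frame (mixed classes).
#' @param ancestral_calls Progenitor variants (SNM/SIM and SV).
#' @param config A [filter_config()].
#' @param precedence SV caller precedence for [sv_dedup()].
#' @return List `kept` / `removed`; `removed` carries a `reason` column.
#' @export
filter_calls <- function(calls, ancestral_calls = empty_calls(),
                         config = filter_config(),
                         precedence = c("Lumpy", "CNVnator", "BreakDancer")) {
  calls <- as_calls(calls)
  anc <- as_calls(ancestral_calls)
  small <- calls[calls$mclass != "SV", , drop = FALSE]
  svs <- calls[calls$mclass == "SV", , drop = FALSE]
  removed <- list()
  q <- quality_filter(small, config)
  removed$q <- q$removed
  a <- subtract_ancestral(q$kept, anc[anc$mclass != "SV", , drop = FALSE])
  removed$a <- a$removed
  cns <- consensus_filter(a$kept, config)
  removed$c <- cns$removed
  kept <- cns$kept
  if (nrow(svs)) {
    dd <- if (all(svs$source %in% precedence))
      sv_dedup(svs, precedence, config$sv_window)
    else list(kept = svs, removed = cbind(svs[0, , drop = FALSE], reason = character(0)))
    removed$d <- dd$removed
    pp <- sv_parallel_filter(dd$kept, anc[anc$mclass == "SV", , drop = FALSE], config)
    removed$p <- pp$removed
    kept <- rbind(kept, pp$kept)
  }
  removed <- do.call(rbind, removed)
  rownames(removed) <- NULL
  ma_log("filter_calls", nrow(calls), " in, ", nrow(kept), " kept, ",
    nrow(removed), " removed")
  list(kept = kept, removed = removed)
}
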