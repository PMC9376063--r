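#' @useDynLib mamut, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cophenetic cor cutree dist hclust lm optimize pnorm
#'   pt qnorm rbinom rnorm rpois runif sd setNames uniroot var
#' @importFrom utils read.delim write.table modifyList
NULL

# one-line stage log with in/out counts, to stderr
ma_log <- function(stage, ...) {
  message(sprintf("[mamut:%s] %s", stage, paste0(...)))
}

#' Column schema shared by all mutation-call tables
#'
#' Calls are plain data frames; every reader, simulator and filter in the
#' package produces or consumes this schema. Coordinates are 1-based and
#' intervals are closed, VCF-style.
#'
#' @return Character vector of canonical column names.
#' @export
call_columns <- function() {
  c("line_id", "chrom", "pos", "ref", "alt", "mclass",
    "depth", "qual", "sv_type", "sv_start", "sv_end", "source", "info")
}

#' Create an empty mutation-call table
#'
#' @return Zero-row data frame with the [call_columns()] schema.
#' @export
empty_calls <- function() {
  data.frame(
    line_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), mclass = character(),
    depth = integer(), qual = double(), sv_type = character(),
    sv_start = integer(), sv_end = integer(), source = character(),
    info = character(), stringsAsFactors = FALSE
  )
}

# coerce a partial call table to full schema, with basic invariant checks
as_calls <- function(df) {
  stopifnot(is.data.frame(df))
  tmpl <- empty_calls()
  for (col in names(tmpl)) {
    if (is.null(df[[col]])) {
      df[[col]] <- rep(tmpl[[col]][NA_integer_][0], nrow(df))
      df[[col]] <- rep(NA, nrow(df))
      mode(df[[col]]) <- mode(tmpl[[col]])
    }
  }
  df <- df[, names(tmpl), drop = FALSE]
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  df$qual <- as.double(df$qual)
  df$sv_start <- as.integer(df$sv_start)
  df$sv_end <- as.integer(df$sv_end)
  if (nrow(df)) {
    if (any(df$pos < 1L, na.rm = TRUE)) stop("call pos must be >= 1")
    bad <- !df$mclass %in% c("SNM", "SIM", "SV")
    if (any(bad)) stop("unknown mclass: ", paste(unique(df$mclass[bad]), collapse = ", "))
    sv <- !is.na(df$sv_start) & !is.na(df$sv_end)
    if (any(df$sv_start[sv] > df$sv_end[sv])) stop("sv_start must be <= sv_end")
  }
  rownames(df) <- NULL
  df
}

# classify a ref/alt pair: single-base substitution, small indel (length
# difference 1-4 bp), or structural variant
classify_alleles <- function(ref, alt) {
  d <- abs(nchar(ref) - nchar(alt))
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L & ref != alt, "SNM",
    ifelse(d >= 1L & d <= 4L, "SIM", "SV"))
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased (soft-masked lowercase runs are unmasked).
#' Non-ACGT characters are tolerated on input but positions carrying them are
#' skipped by the context-spectrum builder downstream.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) stop("zero-length sequence in ", path)
  ma_log("read_fasta", length(seqs), " sequence(s), ",
    sum(nchar(seqs)), " bases from ", path)
  seqs
}

#' Write a reference genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(length(genome) > 0L, !is.null(names(genome)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# split a VCF INFO string into a named character vector; flag keys get ""
parse_info <- function(info) {
  if (is.na(info) || info == "." || info == "") return(character())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  has_eq <- grepl("=", parts, fixed = TRUE)
  keys <- ifelse(has_eq, sub("=.*$", "", parts), parts)
  vals <- ifelse(has_eq, sub("^[^=]*=", "", parts), "")
  stats::setNames(vals, keys)
}

info_get <- function(info, key) {
  kv <- parse_info(info)
  if (key %in% names(kv)) kv[[key]] else NA_character_
}

#' Read mutation calls from a minimal VCF
#'
#' Only the eight mandatory VCF columns are required (CHROM POS ID REF ALT
#' QUAL FILTER INFO). The MA line identifier is taken from a ninth column if
#' present, else from the INFO key `LINE`. Read depth comes from INFO `DP`.
#' Mutation class is inferred from allele lengths (single-base substitution;
#' indel with length difference 1-4 bp; anything else a structural variant)
#' unless INFO `SVTYPE` forces class SV. Unknown INFO keys are preserved
#' verbatim in the `info` column.
#'
#' @param path Path to a tab-separated minimal VCF.
#' @return Mutation-call data frame ([call_columns()] schema).
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  body <- lines[!startsWith(lines, "##")]
  header <- body[startsWith(body, "#")]
  body <- body[!startsWith(body, "#")]
  if (length(body) == 0L) return(empty_calls())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld < 8L)) {
    stop("minimal VCF needs 8 columns CHROM POS ID REF ALT QUAL FILTER INFO; row ",
      which(nfld < 8L)[1], " has ", nfld[which(nfld < 8L)[1]])
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:9][1:9]))
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) stop("non-integer POS at row ", which(is.na(pos))[1])
  info <- m[, 8]
  line_id <- ifelse(nfld >= 9L & !is.na(m[, 9]), m[, 9], NA_character_)
  info_line <- vapply(info, info_get, "", key = "LINE", USE.NAMES = FALSE)
  line_id <- ifelse(is.na(line_id) | line_id == "", info_line, line_id)
  dp <- suppressWarnings(as.integer(
    vapply(info, info_get, "", key = "DP", USE.NAMES = FALSE)))
  svtype <- vapply(info, info_get, "", key = "SVTYPE", USE.NAMES = FALSE)
  end <- suppressWarnings(as.integer(
    vapply(info, info_get, "", key = "END", USE.NAMES = FALSE)))
  src <- vapply(info, info_get, "", key = "SOURCE", USE.NAMES = FALSE)
  mclass <- classify_alleles(m[, 4], m[, 5])
  mclass[!is.na(svtype)] <- "SV"
  is_sv <- mclass == "SV"
  calls <- as_calls(data.frame(
    line_id = line_id, chrom = m[, 1], pos = pos, ref = m[, 4], alt = m[, 5],
    mclass = mclass, depth = dp,
    qual = suppressWarnings(as.double(ifelse(m[, 6] == ".", NA, m[, 6]))),
    sv_type = svtype,
    sv_start = ifelse(is_sv, pos, NA_integer_),
    sv_end = ifelse(is_sv, ifelse(is.na(end), pos + nchar(m[, 4]) - 1L, end),
      NA_integer_),
    source = src, info = info, stringsAsFactors = FALSE
  ))
  ma_log("read_calls", nrow(calls), " call(s) from ", path)
  calls
}

#' Write mutation calls as a minimal VCF
#'
#' Round-trips with [read_calls()]: line id is written as a ninth column and
#' DP/SVTYPE/END/SOURCE merged into INFO (existing verbatim INFO keys kept).
#'
#' @param calls Mutation-call data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  calls <- as_calls(calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
    "INFO", "LINE"), collapse = "\t"), con)
  if (nrow(calls)) {
    info <- vapply(seq_len(nrow(calls)), function(i) {
      kv <- parse_info(calls$info[i])
      kv <- kv[!names(kv) %in% c("DP", "SVTYPE", "END", "SOURCE", "LINE")]
      add <- character()
      if (!is.na(calls$depth[i])) add <- c(add, paste0("DP=", calls$depth[i]))
      if (!is.na(calls$sv_type[i])) add <- c(add, paste0("SVTYPE=", calls$sv_type[i]))
      if (!is.na(calls$sv_end[i])) add <- c(add, paste0("END=", calls$sv_end[i]))
      if (!is.na(calls$source[i]) && nzchar(calls$source[i]))
        add <- c(add, paste0("SOURCE=", calls$source[i]))
      rest <- if (length(kv)) paste0(names(kv), ifelse(nzchar(kv), "=", ""), kv) else character()
      out <- c(add, rest)
      if (length(out)) paste(out, collapse = ";") else "."
    }, "")
    writeLines(paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
      ifelse(is.na(calls$qual), ".", format(calls$qual, trim = TRUE)),
      "PASS", info, calls$line_id, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a tabular result as TSV
#'
#' Header row, tab separation, floats at full precision (>= 6 significant
#' digits) so that [read_table()] round-trips losslessly.
#'
#' @param records Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  rec <- records
  for (col in names(rec)) {
    if (is.double(rec[[col]])) {
      rec[[col]] <- vapply(rec[[col]], function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 15, trim = TRUE, scientific = NA)
      }, "")
    }
  }
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
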