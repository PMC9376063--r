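# shared fixture builders and independent oracles, all generated in code

# a single mutation call row with sensible defaults
mk_call <- function(line_id = "L1", chrom = "chr", pos = 10L, ref = "C",
                    alt = "T", mclass = NULL, depth = 100L, qual = 60,
                    sv_type = NA_character_, sv_start = NA_integer_,
                    sv_end = NA_integer_, source = NA_character_,
                    info = ".") {
  if (is.null(mclass)) {
    d <- abs(nchar(ref) - nchar(alt))
    mclass <- if (nchar(ref) == 1 && nchar(alt) == 1) "SNM"
      else if (d >= 1 && d <= 4) "SIM" else "SV"
  }
  data.frame(line_id = line_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, mclass = mclass, depth = as.integer(depth),
    qual = qual, sv_type = sv_type, sv_start = as.integer(sv_start),
    sv_end = as.integer(sv_end), source = source, info = info,
    stringsAsFactors = FALSE)
}

mk_sv <- function(line_id = "L1", sv_type = "DEL", sv_start = 1000L,
                  sv_end = 2000L, source = "Lumpy", chrom = "chr") {
  mk_call(line_id = line_id, chrom = chrom, pos = sv_start, ref = "N",
    alt = "<SV>", mclass = "SV", sv_type = sv_type, sv_start = sv_start,
    sv_end = sv_end, source = source)
}

# independent R oracle for the Luria-Delbruck pmf (plain recursion, no C++)
ld_pmf_oracle <- function(m, k_max) {
  p <- numeric(k_max + 1)
  p[1] <- exp(-m)
  for (k in seq_len(k_max)) {
    s <- 0
    for (i in 0:(k - 1)) s <- s + p[i + 1] / (k - i + 1)
    p[k + 1] <- (m / k) * s
  }
  p
}

# brute-force grid argmax of the LD log-likelihood built only from ld_pmf;
# coarse pass over [lo, hi] then a fine pass at the stated resolution
ld_grid_mle <- function(counts, lo, hi, resolution = 1e-4) {
  K <- max(counts)
  ll <- function(m) sum(log(ld_pmf(m, K)[counts + 1]))
  coarse <- seq(lo, hi, by = 0.01)
  m0 <- coarse[which.max(vapply(coarse, ll, 0))]
  fine <- seq(max(lo, m0 - 0.02), min(hi, m0 + 0.02), by = resolution)
  fine[which.max(vapply(fine, ll, 0))]
}

# three fixed ground-truth 96-class patterns and multinomial samples
truth_patterns <- function() {
  mk <- function(seed) {
    set.seed(seed)
    w <- stats::rexp(96)^2
    w / sum(w)
  }
  P <- cbind(mk(101), mk(202), mk(303))
  rownames(P) <- spectrum_contexts()
  colnames(P) <- paste0("true", 1:3)
  P
}

pattern_samples <- function(P, n_per = 8, n_mut = 1000, dominant = 0.8,
                            seed = 5) {
  set.seed(seed)
  k <- ncol(P)
  V <- sapply(seq_len(k * n_per), function(i) {
    dom <- (i - 1) %/% n_per + 1
    expo <- rep((1 - dominant) / (k - 1), k)
    expo[dom] <- dominant
    stats::rmultinom(1, n_mut, as.vector(P %*% expo))
  })
  rownames(V) <- rownames(P)
  colnames(V) <- paste0("s", seq_len(ncol(V)))
  V
}
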