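test_that("context classes enumerate exactly 96 labels, pyrimidine-centred", {
  labels <- spectrum_contexts()
  expect_length(labels, 96L)
  expect_length(unique(labels), 96L)
  expect_true(all(substr(labels, 3, 3) %in% c("C", "T")))
  # enumerating every (ref, alt, 5', 3') input yields exactly those 96
  all_labels <- character(0)
  for (r in c("A", "C", "G", "T")) for (a in setdiff(c("A", "C", "G", "T"), r))
    for (p5 in c("A", "C", "G", "T")) for (p3 in c("A", "C", "G", "T"))
      all_labels <- c(all_labels, context_class(r, a, p5, p3))
  expect_setequal(unique(all_labels), labels)
  expect_length(all_labels, 192L)  # two stranded inputs per class
})

test_that("purine-reference mutations are reverse-complemented before labelling", {
  expect_equal(context_class("C", "A", "A", "A"), "A[C>A]A")
  expect_equal(context_class("G", "T", "T", "T"), "A[C>A]A")
  expect_equal(context_class("A", "G", "C", "T"), "A[T>C]G")  # flanks swap
  expect_error(context_class("N", "A", "C", "C"), "A, C, G, T")
  expect_error(context_class("C", "C", "A", "A"), "differ")
})

test_that("build_spectrum counts contexts and conserves calls", {
  g <- c(s = "ACA")
  calls <- mk_call("l1", chrom = "s", pos = 2, ref = "C", alt = "T")
  sp <- build_spectrum(calls, g)
  expect_equal(unname(sp$counts["A[C>T]A"]), 1L)
  expect_equal(sum(sp$counts), 1L)
  expect_equal(sum(sp$six_class), 1L)
  expect_equal(unname(sp$six_class["C>T"]), 1L)
  # empty call list: all-zero spectrum
  sp0 <- build_spectrum(empty_calls(), g)
  expect_true(all(sp0$counts == 0L))
})

test_that("calls at sequence ends, bad contexts and ref mismatches are skipped", {
  g <- c(s = "ACGNA")
  calls <- rbind(
    mk_call("l1", chrom = "s", pos = 1, ref = "A", alt = "C"),  # end
    mk_call("l1", chrom = "s", pos = 3, ref = "G", alt = "A"),  # N in context
    mk_call("l1", chrom = "s", pos = 2, ref = "T", alt = "A"),  # ref mismatch
    mk_call("l1", chrom = "s", pos = 2, ref = "C", alt = "T"))  # good
  sp <- build_spectrum(calls, g)
  expect_equal(sum(sp$counts), 1L)
  expect_equal(sp$skipped, 3L)
  expect_equal(nrow(sp$errors), 1L)  # only the mismatch is an error record
  expect_equal(sp$errors$pos, 2L)
  expect_equal(sp$errors$ref, "T")
})

test_that("spectra are strand invariant under reverse complement", {
  g <- gen_genome(3000, 0.45, seed = 77)
  tr <- ma_truth(snm_rate = 5e-5, n_lines = 2, generations_per_line = 100)
  sim <- simulate_ma(tr, g, artifact_plan(), seed = 78)
  snm <- sim$calls[sim$calls$mclass == "SNM", ]
  sp <- build_spectrum(snm, g)
  # reverse-complement the genome and remap the calls
  L <- nchar(g[[1]])
  rc <- function(x) chartr("ACGT", "TGCA",
    paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  g_rc <- stats::setNames(rc(g[[1]]), names(g))
  snm_rc <- snm
  snm_rc$pos <- L - snm$pos + 1L
  snm_rc$ref <- chartr("ACGT", "TGCA", snm$ref)
  snm_rc$alt <- chartr("ACGT", "TGCA", snm$alt)
  sp_rc <- build_spectrum(snm_rc, g_rc)
  expect_identical(sp$counts, sp_rc$counts)
  expect_gt(sum(sp$counts), 10L)
})

test_that("six-class aggregation partitions the 96 classes", {
  set.seed(3)
  g <- gen_genome(5000, 0.5, seed = 31)
  tr <- ma_truth(snm_rate = 2e-5, n_lines = 3, generations_per_line = 100)
  sim <- simulate_ma(tr, g, artifact_plan(), seed = 32)
  sp <- build_spectrum(sim$calls, g)
  expect_equal(sum(sp$six_class), sum(sp$counts))
  core <- sub("^.\\[", "", sub("\\].$", "", names(sp$counts)))
  for (cl in six_classes())
    expect_equal(unname(sp$six_class[cl]), sum(sp$counts[core == cl]))
})

test_that("simulated spectra track the generating 96-class weights", {
  set.seed(4)
  w <- stats::rexp(96); w <- w / sum(w)
  g <- gen_genome(3e5, 0.5, seed = 41)
  tr <- ma_truth(snm_rate = 1e-6, spectrum_weights = w, n_lines = 5,
    generations_per_line = 2000)
  sim <- simulate_ma(tr, g, artifact_plan(), seed = 42)
  sp <- build_spectrum(sim$calls, g)
  expect_gt(sum(sp$counts), 2000)
  expect_gt(stats::cor(as.numeric(sp$counts), w), 0.9)
})

test_that("spectrum frequencies normalise and spectrum_matrix assembles", {
  g <- c(s = "ACAACA")
  calls <- rbind(mk_call("l1", chrom = "s", pos = 2, ref = "C", alt = "T"),
    mk_call("l1", chrom = "s", pos = 5, ref = "C", alt = "G"))
  sp <- build_spectrum(calls, g)
  f <- spectrum_frequencies(sp)
  expect_equal(sum(f), 1)
  m <- spectrum_matrix(list(a = sp, b = sp))
  expect_equal(dim(m), c(96L, 2L))
  expect_equal(rownames(m), spectrum_contexts())
  expect_equal(colSums(m), c(a = 2L, b = 2L))
})
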