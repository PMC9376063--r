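test_that("exact low-rank input is factorised to near-zero divergence", {
  set.seed(10)
  w <- stats::rexp(96); w <- w / sum(w)
  h <- stats::runif(6, 50, 500)
  V <- outer(w, h)  # exact rank 1
  colnames(V) <- paste0("s", 1:6)
  fit <- nmf(V, 1, restarts = 3, seed = 2)
  expect_lt(fit$objective, 1e-6)
  expect_equal(unname(colSums(fit$patterns)), 1)
  expect_gt(cosine_similarity(fit$patterns[, 1], w), 0.99999)
})

test_that("KL objective is non-increasing over iterations", {
  set.seed(12)
  V <- matrix(stats::rpois(96 * 8, 20), 96, 8)
  objs <- vapply(c(5, 20, 80, 320), function(it) {
    mamut:::with_seed(99, mamut:::nmf_single(V, 3, max_iter = it, tol = 0))$objective
  }, 0)
  expect_true(all(diff(objs) <= 1e-8))
})

test_that("nmf is reproducible bit-for-bit and validates input", {
  set.seed(13)
  V <- matrix(stats::rpois(96 * 6, 15), 96, 6,
    dimnames = list(spectrum_contexts(), paste0("s", 1:6)))
  f1 <- nmf(V, 2, restarts = 4, seed = 7)
  f2 <- nmf(V, 2, restarts = 4, seed = 7)
  expect_identical(f1$patterns, f2$patterns)
  expect_identical(f1$exposures, f2$exposures)
  expect_true(all(f1$patterns >= 0) && all(f1$exposures >= 0))
  expect_equal(unname(colSums(f1$patterns)), rep(1, 2))
  expect_error(nmf(V, 6), "k <")
  expect_error(nmf(V, 0), "k <")
  Vz <- V; Vz[, 3] <- 0
  expect_error(nmf(Vz, 2), "s3")
  expect_error(nmf(-V, 2), "non-negative")
})

test_that("best-of-restarts divergence does not increase with rank", {
  set.seed(14)
  P <- truth_patterns()
  V <- pattern_samples(P, n_per = 4, n_mut = 400, seed = 15)
  objs <- vapply(2:4, function(k) nmf(V, k, restarts = 5, seed = 3)$objective, 0)
  expect_true(all(diff(objs) <= 1e-6))
})

test_that("three planted patterns are recovered and rank 3 is selected", {
  P <- truth_patterns()
  V <- pattern_samples(P, n_per = 8, n_mut = 1000, seed = 5)
  sel <- select_rank(V, 2:5, restarts = 15, seed = 42)
  expect_equal(sel$chosen, 3L)
  model <- nmf(V, 3, restarts = 8, seed = 42)
  cs <- vapply(1:3, function(i)
    max(vapply(1:3, function(j)
      cosine_similarity(P[, i], model$patterns[, j]), 0)), 0)
  expect_true(all(cs >= 0.9))
})

test_that("one-pattern data yields an early decrease; degenerate data warns", {
  P <- truth_patterns()[, 1, drop = FALSE]
  set.seed(16)
  V <- sapply(1:12, function(i) stats::rmultinom(1, 800, P[, 1]))
  colnames(V) <- paste0("s", 1:12)
  sel <- select_rank(V, 2:4, restarts = 10, seed = 8)
  # no real structure beyond one pattern: selection cannot prefer a larger rank
  expect_lte(sel$chosen, 3L)
  # identical samples: no clustering structure at all, warning flag raised
  Vid <- matrix(rep(stats::rmultinom(1, 500, P[, 1]), 8), ncol = 8)
  colnames(Vid) <- paste0("s", 1:8)
  expect_warning(sel2 <- select_rank(Vid, 2:3, restarts = 5, seed = 9),
    "identical")
  expect_true(sel2$warning_flag)
  expect_error(select_rank(V, 3, restarts = 5), "at least 2")
})

test_that("signature correlation: identity, missingness, scale invariance", {
  P <- truth_patterns()
  model <- list(patterns = P)
  class(model) <- "pattern_model"
  out <- correlate_signatures(model, P)
  expect_equal(unname(diag(out$r)), rep(1, 3))
  expect_true(all(diag(out$display)))
  # rescaling a reference leaves r unchanged
  out2 <- correlate_signatures(model, P * 17)
  expect_equal(out$r, out2$r)
  # zero-variance reference: undefined, NA, masked
  flat <- matrix(1 / 96, 96, 1, dimnames = list(rownames(P), "flat"))
  out3 <- correlate_signatures(model, flat)
  expect_true(all(is.na(out3$r)))
  expect_false(any(out3$display))
})

test_that("cosine similarity behaves at the edges", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_true(is.na(cosine_similarity(c(0, 0), c(1, 1))))
})

test_that("shipped toy reference signatures load and correlate", {
  # synthetic stand-ins for user-supplied reference spectra (COSMIC-style
  # tables are inputs, never downloaded); 96 rows in canonical label order
  f <- system.file("extdata", "toy_signatures_synthetic.tsv", package = "mamut")
  refs <- read_table(f)
  expect_equal(refs$label, spectrum_contexts())
  R <- as.matrix(refs[, -1])
  expect_equal(unname(colSums(R)), rep(1, 3), tolerance = 1e-4)
  out <- correlate_signatures(R, R)
  expect_equal(unname(diag(out$r)), rep(1, 3))
})
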