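test_that("quality filter keeps depth >= 4 and qual >= 10, boundary inclusive", {
  calls <- rbind(
    mk_call("l1", pos = 1, depth = 3, qual = 30),    # low depth
    mk_call("l1", pos = 2, depth = 4, qual = 10),    # boundary: kept
    mk_call("l1", pos = 3, depth = 150, qual = 9.9), # low qual
    mk_call("l1", pos = 4, depth = 150, qual = 60))
  out <- quality_filter(calls)
  expect_equal(out$kept$pos, c(2L, 4L))
  expect_equal(out$removed$pos, c(1L, 3L))
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(calls))
  # empty input
  out0 <- quality_filter(empty_calls())
  expect_equal(nrow(out0$kept), 0L)
  expect_equal(nrow(out0$removed), 0L)
})

test_that("missing depth or quality routes a call to removed with reason", {
  calls <- mk_call("l1", depth = NA, qual = 60)
  out <- quality_filter(calls)
  expect_equal(nrow(out$kept), 0L)
  expect_equal(out$removed$reason, "missing-evidence")
})

test_that("ancestral subtraction removes exact key matches across all lines", {
  anc <- mk_call("anc", pos = 100, ref = "C", alt = "T")
  calls <- rbind(
    mk_call("l1", pos = 100, ref = "C", alt = "T"),
    mk_call("l2", pos = 100, ref = "C", alt = "T"),
    mk_call("l3", pos = 100, ref = "C", alt = "G"),  # different alt: kept
    mk_call("l1", pos = 200, ref = "C", alt = "T"))
  out <- subtract_ancestral(calls, anc)
  expect_equal(nrow(out$removed), 2L)
  expect_setequal(out$kept$pos, c(100L, 200L))
  expect_setequal(out$kept$line_id, c("l3", "l1"))
  # empty ancestral set leaves input unchanged
  out2 <- subtract_ancestral(calls, empty_calls())
  expect_equal(out2$kept, as.data.frame(calls))
})

test_that("consensus filter: more-than-two (SNM) / more-than-four (SIM) lines", {
  snm_at <- function(lines, pos) do.call(rbind,
    lapply(lines, function(l) mk_call(l, pos = pos, ref = "C", alt = "T")))
  sim_at <- function(lines, pos) do.call(rbind,
    lapply(lines, function(l) mk_call(l, pos = pos, ref = "CAA", alt = "C")))
  calls <- rbind(
    snm_at(c("l1", "l2", "l3"), 100),              # 3 lines > 2: all removed
    snm_at(c("l1", "l2"), 200),                    # 2 lines: kept
    sim_at(c("l1", "l2", "l3", "l4"), 300),        # 4 lines: kept
    sim_at(c("l1", "l2", "l3", "l4", "l5"), 400))  # 5 lines > 4: removed
  out <- consensus_filter(calls)
  expect_setequal(unique(out$removed$pos), c(100L, 400L))
  expect_equal(sum(out$removed$pos == 100), 3L)
  expect_setequal(unique(out$kept$pos), c(200L, 300L))
})

test_that("SV dedup drops later-caller predictions within the end window", {
  a <- mk_sv("l1", "DEL", 1000L, 2000L, "Lumpy")
  b <- mk_sv("l1", "DEL", 1400L, 2300L, "CNVnator")   # ends 400/300 off: dropped
  c_ <- mk_sv("l1", "DEL", 1600L, 2700L, "CNVnator")  # ends 600/700 off: kept
  d <- mk_sv("l1", "DUP", 1000L, 2000L, "CNVnator")   # type mismatch: kept
  out <- sv_dedup(rbind(a, b, c_, d), window = 500L)
  expect_equal(nrow(out$removed), 1L)
  expect_equal(out$removed$source, "CNVnator")
  expect_equal(out$removed$sv_start, 1400L)
  expect_equal(nrow(out$kept), 3L)
  expect_error(sv_dedup(mk_sv(source = "novel")), "unknown")
})

test_that("precedence order decides which duplicate survives", {
  b <- mk_sv("l1", "DEL", 1000L, 2000L, "BreakDancer")
  l <- mk_sv("l1", "DEL", 1100L, 2100L, "Lumpy")
  out <- sv_dedup(rbind(b, l), window = 500L)
  expect_equal(out$kept$source, "Lumpy")
  expect_equal(out$removed$source, "BreakDancer")
})

test_that("SV parallel filter removes ancestral matches and >= 3-line classes", {
  anc <- mk_sv("anc", "DEL", 5000L, 6000L)
  calls <- rbind(
    mk_sv("l1", "DEL", 5400L, 6300L),   # matches ancestral: removed
    mk_sv("l1", "INV", 10000L, 12000L), # class spans 3 lines: removed
    mk_sv("l2", "INV", 10200L, 12100L),
    mk_sv("l3", "INV", 10400L, 12200L),
    mk_sv("l4", "DUP", 30000L, 31000L), # class spans 2 lines: kept
    mk_sv("l5", "DUP", 30100L, 31100L))
  out <- sv_parallel_filter(calls, anc)
  expect_equal(sort(out$removed$reason),
    c("ancestral-sv", rep("parallel-sv", 3)))
  expect_equal(out$kept$sv_type, c("DUP", "DUP"))
})

test_that("single-linkage chains SV match classes", {
  # l1-l2 and l2-l3 match pairwise; l1-l3 do not (ends 800 apart), yet
  # single linkage puts all three in one class spanning 3 lines
  calls <- rbind(
    mk_sv("l1", "DEL", 1000L, 2000L),
    mk_sv("l2", "DEL", 1400L, 2400L),
    mk_sv("l3", "DEL", 1800L, 2800L))
  out <- sv_parallel_filter(calls, empty_calls())
  expect_equal(nrow(out$kept), 0L)
  expect_equal(unique(out$removed$reason), "parallel-sv")
})

test_that("filter pipeline is idempotent and only partitions", {
  set.seed(8)
  g <- gen_genome(5e4, 0.5, seed = 18)
  tr <- ma_truth(snm_rate = 2e-7, sim_rate = 4e-8, svm_rate = 2e-3,
    n_lines = 8, generations_per_line = 1000)
  plan <- artifact_plan(n_shared_snm = 3, shared_in_lines = 4, n_lowdepth = 6)
  sim <- simulate_ma(tr, g, plan, seed = 19)
  out1 <- filter_calls(sim$calls)
  out2 <- filter_calls(out1$kept)
  expect_equal(nrow(out2$removed), 0L)
  ord <- function(df) df[do.call(order, df[c("chrom", "pos", "line_id", "ref", "alt")]),
    call_columns()]
  expect_equal(ord(out2$kept), ord(out1$kept), ignore_attr = TRUE)
  # no call fields were modified: every kept row appears verbatim in input
  key_in <- do.call(paste, sim$calls[call_columns()])
  key_kept <- do.call(paste, out1$kept[call_columns()])
  expect_true(all(key_kept %in% key_in))
})

test_that("injected artifacts are all removed and clean calls all kept", {
  g <- gen_genome(2e5, 0.5, seed = 28)
  tr <- ma_truth(snm_rate = 5e-8, sim_rate = 1e-8, n_lines = 12,
    generations_per_line = 1500)
  plan <- artifact_plan(n_shared_snm = 4, shared_in_lines = 5, n_lowdepth = 10)
  sim <- simulate_ma(tr, g, plan, seed = 29)
  out <- filter_calls(sim$calls)
  expect_false(any(grepl("ARTIFACT", out$kept$info)))
  expect_true(all(grepl("ARTIFACT", out$removed$info)))
  expect_equal(nrow(out$removed), 4L * 5L + 10L)
})
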