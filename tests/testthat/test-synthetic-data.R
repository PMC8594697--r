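test_that("simulation is a pure function of its seed", {
  spec <- sim_spec(n_chroms = 1L, chrom_length = 30000L, seed = 2L,
                   injections = data.frame(chrom = "chr1", start = 1000,
                                           end = 1500, context = "CHH",
                                           delta = 30))
  a <- simulate_methylomes(spec)
  b <- simulate_methylomes(spec)
  expect_identical(a, b)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(spec, d1)
  write_simulation(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the draw
  other <- simulate_methylomes(sim_spec(n_chroms = 1L, chrom_length = 30000L,
                                        seed = 3L))
  expect_false(identical(a$reference$n_meth, other$reference$n_meth))
})

test_that("the spec rejects overlapping injections and missing seeds", {
  inj <- data.frame(chrom = "chr1", start = c(100, 300), end = c(400, 600),
                    context = "CHH", delta = 10)
  expect_error(sim_spec(n_chroms = 1L, chrom_length = 1000L,
                        injections = inj, seed = 1L), "overlap")
  expect_error(sim_spec(n_chroms = 1L, chrom_length = 1000L), "seed")
})

test_that("a saturating injection fully methylates covered sites in the test group", {
  spec <- sim_spec(n_chroms = 1L, chrom_length = 20000L, seed = 4L,
                   baseline = c(CG = 60, CHG = 40, CHH = 0),
                   injections = data.frame(chrom = "chr1", start = 5000,
                                           end = 6000, context = "CHH",
                                           delta = 100))
  sim <- simulate_methylomes(spec)
  inside <- sim$test[sim$test$context == "CHH" &
                       sim$test$pos - 1L >= 5000 & sim$test$pos - 1L < 6000, ]
  expect_gt(nrow(inside), 0L)
  expect_true(all(inside$n_meth == inside$n_total))
  outside <- sim$test[sim$test$context == "CHH" &
                        (sim$test$pos - 1L < 5000 | sim$test$pos - 1L >= 6000), ]
  expect_true(all(outside$n_meth == 0L))
  # reference untouched by the injection
  ref_in <- sim$reference[sim$reference$context == "CHH" &
                            sim$reference$pos - 1L >= 5000, ]
  expect_true(all(ref_in$n_meth == 0L))
})

test_that("empirical site levels converge to the specified law", {
  # 200 pseudo-replicates of one condition: per-context mean within 2 pp
  spec <- sim_spec(n_chroms = 1L, chrom_length = 5000L, seed = 6L,
                   n_replicates = 200L)
  sim <- simulate_methylomes(spec)
  ref <- sim$reference
  for (cx in c("CG", "CHG", "CHH")) {
    sub <- ref[ref$context == cx, ]
    expect_lt(abs(mean(sub$n_meth / sub$n_total) * 100 - spec$baseline[[cx]]), 2)
  }
  # coverage is zero-truncated with the right mean
  expect_true(all(ref$n_total >= 1L))
  expect_lt(abs(mean(ref$n_total) - 14), 0.5)
})

test_that("random injections are non-overlapping, in-bounds and seeded", {
  spec <- sim_spec(n_chroms = 2L, chrom_length = 100000L, seed = 8L)
  inj <- random_injections(spec, n = 40, width = 500L, delta = -30)
  expect_equal(nrow(inj), 40L)
  expect_true(all(inj$end - inj$start == 500L))
  expect_true(all(inj$start >= 0 & inj$end <= 100000L))
  by_chrom <- split(inj, inj$chrom)
  for (g in by_chrom) {
    if (nrow(g) > 1L) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_identical(inj, random_injections(spec, n = 40, width = 500L, delta = -30))
})

test_that("expression coupling follows the promoter CHH delta closed form", {
  inj <- data.frame(chrom = "chr1", start = 10000, end = 10500,
                    context = "CHH", delta = -50)
  spec <- sim_spec(n_chroms = 1L, chrom_length = 50000L, seed = 10L,
                   injections = inj, n_genes = 10L, n_tes = 5L,
                   effect = 4, noise_sd = 0)
  feats <- simulate_features(spec)
  expr <- simulate_expression(spec, feats)
  coupled <- expr$truth[expr$truth$coupled, ]
  expect_gt(nrow(coupled), 0L)
  r <- expr$det[match(coupled$transcript_id, expr$det$transcript_id), ]$ratio
  expect_equal(r, rep(2.0, nrow(coupled)))   # -4 * (-50/100)
  # uncoupled genes are pure noise (zero here)
  un <- expr$det[expr$det$kind == "gene" &
                   !(expr$det$transcript_id %in% coupled$transcript_id), ]
  expect_true(all(un$ratio == 0))
})

test_that("under no coupling roughly alpha of transcripts pass the DET filter", {
  spec <- sim_spec(n_chroms = 1L, chrom_length = 50000L, seed = 12L,
                   n_genes = 1500L, n_tes = 500L, effect = 0, noise_sd = 0.3)
  feats <- simulate_features(spec)
  expr <- simulate_expression(spec, feats)
  frac <- mean(expr$det$p_value <= 0.05)
  expect_gt(frac, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 2000))
})

test_that("call evaluation matches brute-force interval matching", {
  calls <- data.table(chrom = "chr1", start = c(100L, 500L, 900L),
                      end = c(300L, 700L, 1100L), context = "CHH",
                      direction = c("hypo", "hypo", "hyper"))
  truth <- data.table(chrom = "chr1", start = c(250L, 2000L),
                      end = c(550L, 2400L), context = "CHH", delta = -30)
  ev <- evaluate_calls(calls, truth)
  # calls 1 and 2 overlap injection 1 with matching direction; call 3 is hyper
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$fdp, 1 / 3)
  # exact equality: calls identical to injections
  exact <- data.table(chrom = "chr1", start = truth$start, end = truth$end,
                      context = "CHH", direction = "hypo")
  ev2 <- evaluate_calls(exact, truth)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$precision, 1)
  # no calls: sensitivity 0, precision undefined
  ev3 <- evaluate_calls(calls[0], truth)
  expect_equal(ev3$sensitivity, 0)
  expect_true(is.na(ev3$precision))
  # random calls vs random truth equal a brute-force matcher
  set.seed(86)
  rc <- data.table(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                   start = sample.int(5000L, 60),
                   context = sample(c("CG", "CHH"), 60, TRUE),
                   direction = sample(c("hypo", "hyper"), 60, TRUE))
  rc[, end := start + 200L]
  rt <- data.table(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                   start = sample.int(5000L, 20),
                   context = sample(c("CG", "CHH"), 20, TRUE),
                   delta = sample(c(-30, 30), 20, TRUE))
  rt[, end := start + 400L]
  ev4 <- evaluate_calls(rc, rt)
  dirs <- ifelse(rt$delta < 0, "hypo", "hyper")
  hit_t <- vapply(seq_len(nrow(rt)), function(j) {
    any(rc$chrom == rt$chrom[j] & rc$context == rt$context[j] &
          rc$direction == dirs[j] & rc$start < rt$end[j] & rc$end > rt$start[j])
  }, logical(1))
  hit_c <- vapply(seq_len(nrow(rc)), function(i) {
    any(rt$chrom == rc$chrom[i] & rt$context == rc$context[i] &
          dirs == rc$direction[i] & rt$start < rc$end[i] & rt$end > rc$start[i])
  }, logical(1))
  expect_equal(ev4$sensitivity, mean(hit_t))
  expect_equal(ev4$precision, mean(hit_c))
})
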