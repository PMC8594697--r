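p4 <- dmr_params(min_sites_per_window = 4L)

test_that("window enumeration matches the sliding-window arithmetic", {
  w <- enumerate_windows(c(chr1 = 450), dmr_params())
  expect_equal(w$start, c(0L, 100L, 200L, 300L, 400L))
  expect_equal(w$end, c(200L, 300L, 400L, 450L, 450L))
  w2 <- enumerate_windows(c(chr1 = 200), dmr_params())
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$end, c(200L, 200L))
})

test_that("every interior base is covered by exactly window/step windows", {
  params <- dmr_params()
  for (len in c(1L, 99L, 100L, 101L, 250L, 449L, 450L, 777L, 1000L)) {
    w <- enumerate_windows(c(c1 = len), params)
    cover <- integer(len)
    for (i in seq_len(nrow(w))) {
      idx <- (w$start[i] + 1L):w$end[i]
      cover[idx] <- cover[idx] + 1L
    }
    interior <- seq_len(len) > params$step
    expect_true(all(cover[interior] == params$window_size / params$step))
    expect_true(all(cover[!interior] == 1L))
  }
})

test_that("window replicate level averages per-site ratios over covered sites", {
  calls <- make_calls(pos = c(10, 20, 30, 40), n_meth = c(2, 8, 5, 5),
                      n_total = 10)
  lv <- window_replicate_level(calls, "chr1", 0L, 200L, "CHH", p4)
  expect_equal(lv$level, 50)
  expect_equal(lv$n_sites, 4L)

  # a site under the coverage floor is excluded from the mean
  calls2 <- rbind(calls, make_calls(50, 2, 2))
  lv2 <- window_replicate_level(calls2, "chr1", 0L, 200L, "CHH", p4)
  expect_equal(lv2$level, 50)
  expect_equal(lv2$n_sites, 4L)

  # fully methylated sites give 100%
  lv3 <- window_replicate_level(make_calls(1:4, 10, 10), "chr1", 0L, 200L, "CHH", p4)
  expect_equal(lv3$level, 100)

  # below the site minimum the level is undefined, not zero
  lv4 <- window_replicate_level(calls[1:2], "chr1", 0L, 200L, "CHH", p4)
  expect_true(is.na(lv4$level))
  expect_equal(lv4$n_sites, 2L)
})

test_that("the window test reproduces textbook two-sample t results", {
  r <- test_window(c(10, 12, 11), c(10, 12, 11))
  expect_equal(r$delta_mC, 0)
  expect_equal(r$sda_a, 1)
  expect_equal(r$sda_b, 1)
  expect_equal(r$p_value, 1)

  a <- c(10, 12, 11); b <- c(30, 32, 31)
  rs <- test_window(a, b, "student")
  expect_equal(rs$delta_mC, 20)
  expect_equal(rs$p_value, t.test(a, b, var.equal = TRUE)$p.value)
  rw <- test_window(a, b, "welch")
  expect_equal(rw$p_value, t.test(a, b)$p.value)

  rc <- test_window(c(5, 5, 5), c(5, 5, 5))
  expect_equal(rc$sda_a, 0)
  expect_equal(rc$sda_b, 0)
  expect_equal(rc$p_value, 1)

  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(4, 50, 5); b <- rnorm(3, 55, 5)
    expect_equal(test_window(a, b, "student")$p_value,
                 t.test(a, b, var.equal = TRUE)$p.value)
    expect_equal(test_window(a, b, "welch")$p_value, t.test(a, b)$p.value)
  }
  expect_error(test_window(c(1, 2), 5), ">= 2")
})

test_that("global methylation levels average sites then replicates", {
  zero <- make_calls(1:10, 0, 10)
  g <- global_methylation_levels(zero, 3L)
  expect_equal(g$conditions[g$conditions$context == "CHH", ]$level, 0)
  one <- make_calls(1, 5, 10)
  g1 <- global_methylation_levels(one, 3L)
  expect_equal(g1$conditions[g1$conditions$context == "CHH", ]$level, 50)
  # contexts with no qualifying site are flagged undefined, not 0
  expect_true(is.na(g1$conditions[g1$conditions$context == "CG", ]$level))
  expect_false(g1$conditions[g1$conditions$context == "CG", ]$defined)
})

test_that("global levels recover the simulated methylation rate", {
  set.seed(5)
  n <- 500L
  cov <- rpois(n, 14) + 1L
  calls <- make_calls(seq_len(n) * 10L, rbinom(n, cov, 0.10), cov)
  g <- global_methylation_levels(calls, 3L)
  lv <- g$conditions[g$conditions$context == "CHH", ]$level
  expect_lt(abs(lv - 10), 3)
})

test_that("identical groups give no DMRs at any p threshold below 1", {
  spec <- sim_spec(n_chroms = 1L, chrom_length = 50000L, seed = 9L)
  sim <- simulate_methylomes(spec)
  copy_as_test <- data.table::copy(sim$reference)
  copy_as_test[, sample_id := paste0("t_", sample_id)]
  copy_as_test[, condition := "B"]
  dmrs <- call_dmrs(sim$reference, copy_as_test,
                    dmr_params(p_threshold = 0.99, min_abs_delta = 0),
                    sim$chrom_lengths)
  expect_equal(nrow(dmrs), 0L)
  expect_gt(attr(dmrs, "n_tested"), 0L)
})

test_that("bulk window levels equal brute-force per-site recomputation", {
  spec <- sim_spec(n_chroms = 1L, chrom_length = 10000L, seed = 13L,
                   injections = data.frame(chrom = "chr1", start = 4000,
                                           end = 4600, context = "CHH",
                                           delta = 40))
  sim <- simulate_methylomes(spec)
  ws <- window_stats(sim$reference, sim$test, p4, sim$chrom_lengths)
  expect_gt(nrow(ws), 10L)
  reps_ref <- split(sim$reference, sim$reference$sample_id)
  reps_test <- split(sim$test, sim$test$sample_id)
  idx <- seq(1L, nrow(ws), by = max(1L, nrow(ws) %/% 25L))
  for (i in idx) {
    lev_r <- vapply(reps_ref, function(cc)
      window_replicate_level(cc, ws$chrom[i], ws$start[i], ws$end[i],
                             ws$context[i], p4)$level, numeric(1))
    lev_t <- vapply(reps_test, function(cc)
      window_replicate_level(cc, ws$chrom[i], ws$start[i], ws$end[i],
                             ws$context[i], p4)$level, numeric(1))
    expect_equal(ws$mean_ref[i], mean(lev_r), tolerance = 1e-12)
    expect_equal(ws$mean_test[i], mean(lev_t), tolerance = 1e-12)
    o <- test_window(lev_r, lev_t, "student")
    expect_equal(ws$p_value[i], o$p_value, tolerance = 1e-12)
    expect_equal(ws$delta_mC[i], o$delta_mC, tolerance = 1e-12)
    expect_equal(ws$sda_ref[i], o$sda_a, tolerance = 1e-12)
  }
})

test_that("swapping reference and test negates delta, keeps p, swaps labels", {
  spec <- sim_spec(n_chroms = 1L, chrom_length = 60000L, seed = 21L,
                   injections = data.frame(chrom = "chr1", start = 20000,
                                           end = 20500, context = "CHH",
                                           delta = 60))
  sim <- simulate_methylomes(spec)
  fwd <- call_dmrs(sim$reference, sim$test, p4, sim$chrom_lengths)
  rev <- call_dmrs(sim$test, sim$reference, p4, sim$chrom_lengths)
  expect_gt(nrow(fwd), 0L)
  expect_equal(nrow(fwd), nrow(rev))
  key <- function(d) paste(d$chrom, d$start, d$context)
  expect_equal(key(fwd), key(rev))
  expect_equal(fwd$delta_mC, -rev$delta_mC)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  expect_equal(fwd$direction, ifelse(rev$direction == "hypo", "hyper", "hypo"))
  # direction/sign coherence
  expect_true(all((fwd$direction == "hypo") == (fwd$delta_mC < 0)))
})

test_that("tightening thresholds never increases the number of DMRs", {
  spec <- sim_spec(n_chroms = 1L, chrom_length = 100000L, seed = 33L)
  sim <- simulate_methylomes(spec)
  ws <- window_stats(sim$reference, sim$test, p4, sim$chrom_lengths)
  n_at <- function(p, sda, d = 0) nrow(filter_windows(
    ws, dmr_params(p_threshold = p, min_abs_delta = d,
                   sda_threshold = c(CG = sda, CHG = sda, CHH = sda))))
  for (i in 1:5) {
    p_hi <- runif(1, 0.05, 0.5); p_lo <- p_hi / 10
    expect_lte(n_at(p_lo, 100), n_at(p_hi, 100))
    expect_lte(n_at(p_hi, 1), n_at(p_hi, 5))
    expect_lte(n_at(p_hi, 5, d = 3), n_at(p_hi, 5, d = 0))
  }
})

test_that("DMR summaries reproduce printed-style share arithmetic", {
  counts <- data.frame(
    context = rep(c("CHH", "CHG", "CG"), each = 2),
    direction = rep(c("hypo", "hyper"), 3),
    n = c(93784L, 4998L, 22L, 157L, 78L, 398L))
  s <- summarize_dmrs(counts)
  expect_equal(s$total, 99437L)
  expect_equal(round_half_out(s$pct_direction_of_total[["hypo"]], 1), 94.4)
  expect_equal(round_half_out(s$pct_direction_of_total[["hypo"]]), 94)
  expect_equal(round_half_out(s$pct_direction_within_context["CHH", "hypo"], 1), 94.9)
  expect_equal(round_half_out(s$pct_context_of_total[["CHH"]], 1), 99.3)
  expect_equal(round_half_out(direction_share(s, c("CG", "CHG"))[["hyper"]]), 85)
  # counts conserve the total
  expect_equal(sum(s$counts[, c("hypo", "hyper")]), s$total)
})

test_that("empty DMR sets summarize to zero counts with undefined percentages", {
  s <- summarize_dmrs(data.frame(context = character(), direction = character()))
  expect_equal(s$total, 0)
  expect_true(all(is.na(s$pct_direction_within_context)))
  expect_true(all(is.na(s$pct_context_of_total)))
})

test_that("round_half_out rounds halves away from zero", {
  expect_equal(round_half_out(0.5), 1)
  expect_equal(round_half_out(-0.5), -1)
  expect_equal(round_half_out(2.45, 1), 2.5)
  expect_equal(round_half_out(94.415, 1), 94.4)
})

test_that("density tracks conserve per-context DMR counts", {
  lens <- c(chr1 = 200000L, chr2 = 150000L)
  empty <- dmr_density(data.table(), lens)
  expect_true(all(empty$n == 0L))
  expect_false(any(empty$hotspot))

  five <- data.table(chrom = "chr1", start = c(10L, 100L, 20000L, 49999L, 30000L),
                     end = 200L, context = "CHH", direction = "hypo")
  d5 <- dmr_density(five, lens)
  expect_equal(d5[d5$chrom == "chr1" & d5$bin_start == 0L & d5$context == "CHH", ]$n, 5L)

  set.seed(17)
  rnd <- data.table(chrom = sample(names(lens), 200, TRUE),
                    start = sample.int(140000L, 200, TRUE),
                    context = sample(c("CG", "CHG", "CHH"), 200, TRUE))
  rnd[, end := start + 200L]
  dd <- dmr_density(rnd, lens)
  tot <- tapply(dd$n, dd$context, sum)
  expect_equal(as.integer(tot[c("CG", "CHG", "CHH")]),
               as.integer(table(rnd$context)[c("CG", "CHG", "CHH")]))
})
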