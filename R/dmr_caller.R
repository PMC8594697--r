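#' DMR-calling parameters
#'
#' Bundles every tunable of the sliding-window caller. Defaults follow the
#' windowing scheme of 200-bp windows advanced in 100-bp steps with a
#' minimum per-site coverage of 3 reads and a per-window p-value cutoff of
#' 0.01. The SDA (standard deviation of per-replicate window averages)
#' thresholds are reproducibility filters keyed by context; they must be
#' fitted to the data set at hand and the defaults make no claim beyond
#' being reasonable starting points for a plant methylome.
#'
#' @param window_size window width in bp.
#' @param step window step in bp (`step <= window_size`).
#' @param min_site_coverage minimum reads at a cytosine for it to count.
#' @param min_sites_per_window minimum qualifying cytosines for a window
#'   level to be defined. At 14x coverage a single cytosine's methylation
#'   ratio carries binomial noise of up to ~13 pp (sd, at 50% methylation);
#'   averaging at least 10 sites brings the window level's noise near the
#'   smallest methylation difference worth reporting, so windows too sparse
#'   to measure are never tested.
#' @param p_threshold per-window p-value cutoff.
#' @param sda_threshold named vector of per-context SDA caps in percentage
#'   points, applied to both groups.
#' @param min_abs_delta minimum |delta_mC| (pp) for a window to be reported.
#' @param test per-window test: pooled-variance Student t ("student"),
#'   unequal-variance Welch t ("welch"), or Fisher's exact test on pooled
#'   methylated/unmethylated counts ("fisher").
#' @param merge_windows merge overlapping same-direction significant
#'   windows into runs (off by default: each window is one DMR).
#' @param p_adjust multiple-testing correction applied to window p-values
#'   before thresholding ("none" mirrors raw-p reporting; "BH" available).
#' @return a list of class `dmr_params`.
#' @export
dmr_params <- function(window_size = 200L, step = 100L, min_site_coverage = 3L,
                       min_sites_per_window = 10L, p_threshold = 0.01,
                       sda_threshold = c(CG = 10, CHG = 10, CHH = 5),
                       min_abs_delta = 5,
                       test = c("student", "welch", "fisher"),
                       merge_windows = FALSE,
                       p_adjust = c("none", "BH")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  stopifnot(window_size >= 1, step >= 1, step <= window_size,
            min_site_coverage >= 0, min_sites_per_window >= 1,
            p_threshold >= 0, p_threshold <= 1, min_abs_delta >= 0,
            all(sda_threshold >= 0))
  if (!all(.CONTEXTS %in% names(sda_threshold))) {
    stop("sda_threshold must name all of ", paste(.CONTEXTS, collapse = ", "))
  }
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 min_site_coverage = as.integer(min_site_coverage),
                 min_sites_per_window = as.integer(min_sites_per_window),
                 p_threshold = p_threshold, sda_threshold = sda_threshold,
                 min_abs_delta = min_abs_delta, test = test,
                 merge_windows = merge_windows, p_adjust = p_adjust),
            class = "dmr_params")
}

#' Genome-wide methylation levels per condition and context
#'
#' The per-replicate level is the unweighted mean of per-site methylation
#' ratios (n_meth/n_total, in %) over sites with coverage at least
#' `min_site_coverage`; the condition level averages its replicates.
#' Condition pairs are compared per context with a two-sample Student
#' t-test on replicate levels. A context with no qualifying site in some
#' replicate is flagged undefined (NA), never reported as 0.
#'
#' @param calls combined call table over all conditions and replicates
#'   (e.g. `rbind` of [methylome_set()] results).
#' @param min_site_coverage minimum reads per site.
#' @return list with `replicates` (per sample_id x context level),
#'   `conditions` (mean over replicates, `defined` flag), and `tests`
#'   (pairwise per-context t-test p-values; NA where fewer than 2
#'   replicates per side).
#' @export
global_methylation_levels <- function(calls, min_site_coverage = 3L) {
  calls <- as.data.table(calls)
  grid <- CJ(sample_id = unique(calls$sample_id), context = .CONTEXTS)
  grid <- merge(grid, unique(calls[, .(sample_id, condition)]), by = "sample_id")
  lev <- calls[n_total >= min_site_coverage,
               .(level = mean(n_meth / n_total) * 100, n_sites = .N),
               by = .(condition, sample_id, context)]
  reps <- merge(grid, lev, by = c("condition", "sample_id", "context"), all.x = TRUE)
  conds <- reps[, .(level = if (anyNA(level)) NA_real_ else mean(level),
                    defined = !anyNA(level), n_replicates = .N),
                by = .(condition, context)]
  cond_names <- sort(unique(reps$condition))
  tests <- NULL
  if (length(cond_names) >= 2L) {
    pairs <- utils::combn(cond_names, 2L)
    tests <- rbindlist(lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      rbindlist(lapply(.CONTEXTS, function(cx) {
        xa <- reps[condition == a & context == cx & !is.na(level), level]
        xb <- reps[condition == b & context == cx & !is.na(level), level]
        p <- if (length(xa) >= 2L && length(xb) >= 2L &&
                 (sd(xa) > 0 || sd(xb) > 0)) {
          stats::t.test(xa, xb, var.equal = TRUE)$p.value
        } else NA_real_
        data.table(condition_a = a, condition_b = b, context = cx, p_value = p)
      }))
    }))
  }
  list(replicates = reps[], conditions = conds[], tests = tests)
}

#' Enumerate sliding windows over chromosomes
#'
#' Windows start at 0, step, 2*step, ... while the start lies inside the
#' chromosome; each window ends at `min(start + window_size, length)`, so
#' trailing windows are truncated, never dropped.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param params a [dmr_params()] object.
#' @return `data.table` chrom/start/end in genomic order, 0-based half-open.
#' @export
enumerate_windows <- function(chrom_lengths, params = dmr_params()) {
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, len - 1L, by = params$step)
    data.table(chrom = ch, start = starts,
               end = pmin(starts + params$window_size, len))
  }))
}

#' Methylation level of one replicate in one window
#'
#' The window level is the unweighted mean of per-site methylation ratios
#' (in %) over cytosines of the requested context inside the 0-based
#' half-open window with coverage at least `min_site_coverage`. With fewer
#' than `min_sites_per_window` qualifying sites the level is undefined
#' (NA), a represented state rather than an error.
#'
#' @param calls call table for a single replicate.
#' @param chrom,start,end window coordinates (0-based half-open).
#' @param context cytosine context.
#' @param params a [dmr_params()] object.
#' @return list(level = % or NA, n_sites = qualifying sites).
#' @export
window_replicate_level <- function(calls, chrom, start, end, context,
                                   params = dmr_params()) {
  calls <- as.data.table(calls)
  ch <- chrom; ctx <- context; s0 <- start; e0 <- end
  cov_min <- params$min_site_coverage
  sub <- calls[calls$chrom == ch & calls$context == ctx &
                 calls$pos - 1L >= s0 & calls$pos - 1L < e0 &
                 calls$n_total >= cov_min, ]
  n <- nrow(sub)
  level <- if (n >= params$min_sites_per_window) mean(sub$n_meth / sub$n_total) * 100 else NA_real_
  list(level = level, n_sites = n)
}

#' Two-group test on replicate window levels
#'
#' Given the per-replicate window methylation averages of two groups,
#' returns the test p-value, delta_mC = mean(B) - mean(A) in percentage
#' points (A is the reference), and each group's SDA (sample standard
#' deviation of replicate averages). With both groups constant the
#' p-value is 1 when the means agree and 0 when they differ (a limiting
#' convention; such windows carry no within-group noise).
#'
#' @param levels_a,levels_b numeric vectors of replicate levels (%), at
#'   least 2 defined values each.
#' @param test "student" (pooled variance) or "welch".
#' @return list(p_value, delta_mC, sda_a, sda_b).
#' @export
test_window <- function(levels_a, levels_b, test = c("student", "welch")) {
  test <- match.arg(test)
  levels_a <- levels_a[!is.na(levels_a)]
  levels_b <- levels_b[!is.na(levels_b)]
  if (length(levels_a) < 2L || length(levels_b) < 2L) {
    stop("test_window needs >= 2 defined replicate levels per group")
  }
  na <- length(levels_a); nb <- length(levels_b)
  ma <- mean(levels_a); mb <- mean(levels_b)
  va <- var(levels_a); vb <- var(levels_b)
  delta <- mb - ma
  if (test == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- if (se == 0) { if (delta == 0) 1 else 0 } else 2 * pt(-abs(delta / se), df)
  list(p_value = p, delta_mC = delta, sda_a = sqrt(va), sda_b = sqrt(vb))
}

# Map each site to the step-grid indices of every window containing it.
# A site at 0-based position p lies in windows starting at multiples of
# `step` in (p - window_size, p]; starts are clipped to [0, chrom length).
.site_window_index <- function(pos0, window_size, step) {
  hi <- pos0 %/% step
  lo <- pmax(0L, (pos0 - window_size) %/% step + 1L)
  k <- hi - lo + 1L
  list(lo = lo, k = k)
}

# Per-(chrom, context, window, sample) levels for all replicates at once.
.window_levels_bulk <- function(calls, params) {
  calls <- as.data.table(calls)
  ok <- calls[n_total >= params$min_site_coverage,
              .(chrom, pos0 = pos - 1L, context, ratio = n_meth / n_total, sample_id)]
  if (!nrow(ok)) return(data.table())
  idx <- .site_window_index(ok$pos0, params$window_size, params$step)
  rep_i <- rep.int(seq_len(nrow(ok)), idx$k)
  win <- ok[rep_i]
  win[, wstart := (sequence(idx$k) - 1L + rep.int(idx$lo, idx$k)) * params$step]
  win[, .(level = mean(ratio) * 100, n_sites = .N),
      by = .(chrom, context, wstart, sample_id)]
}

#' Per-window two-group statistics across the genome
#'
#' Computes, for every window of every context in which *all* replicates
#' of both groups have a defined level, the group means, delta_mC, SDA per
#' group, and the test p-value. No significance filtering is applied here;
#' [call_dmrs()] layers the filters on top. This is also the entry point
#' for calibration studies (e.g. the null distribution of window p-values).
#'
#' @param ref_calls,test_calls call tables for the reference and test
#'   condition ([methylome_set()] output).
#' @param params a [dmr_params()] object.
#' @param chrom_lengths optional named lengths; windows extending past a
#'   length are truncated. Defaults to the max observed position per chrom.
#' @return `data.table` of WindowStats: chrom, start, end, context,
#'   n_sites (total over replicates), mean_ref, mean_test, delta_mC,
#'   sda_ref, sda_test, p_value.
#' @export
window_stats <- function(ref_calls, test_calls, params = dmr_params(),
                         chrom_lengths = NULL) {
  ref_calls <- as.data.table(ref_calls)
  test_calls <- as.data.table(test_calls)
  if (!nrow(ref_calls) || !nrow(test_calls)) {
    warning("empty methylome; no windows tested")
    return(.empty_window_stats())
  }
  n_ref <- length(unique(ref_calls$sample_id))
  n_test <- length(unique(test_calls$sample_id))
  if (n_ref < 2L || n_test < 2L) stop("need >= 2 replicates per condition")
  if (is.null(chrom_lengths)) {
    mx <- rbind(ref_calls[, .(chrom, pos)], test_calls[, .(chrom, pos)])
    mx <- mx[, .(len = max(pos)), by = chrom]
    chrom_lengths <- setNames(mx$len, mx$chrom)
  }
  lev_r <- .window_levels_bulk(ref_calls, params)
  lev_t <- .window_levels_bulk(test_calls, params)
  if (!nrow(lev_r) || !nrow(lev_t)) return(.empty_window_stats())
  min_n <- params$min_sites_per_window
  agg <- function(lev, n_reps, suff) {
    lev <- lev[n_sites >= min_n]
    out <- lev[, .(nrep = .N, m = mean(level), v = if (.N > 1L) var(level) else NA_real_,
                   ns = sum(n_sites)),
               by = .(chrom, context, wstart)]
    out <- out[nrep == n_reps]
    setnames(out, c("m", "v", "ns"), paste0(c("mean_", "var_", "nsites_"), suff))
    out[, nrep := NULL]
    out
  }
  a <- agg(lev_r, n_ref, "ref")
  b <- agg(lev_t, n_test, "test")
  w <- merge(a, b, by = c("chrom", "context", "wstart"))
  if (!nrow(w)) return(.empty_window_stats())
  w[, delta_mC := mean_test - mean_ref]
  w[, sda_ref := sqrt(var_ref)]
  w[, sda_test := sqrt(var_test)]
  if (params$test == "fisher") {
    set(w, j = "p_value", value = .fisher_window_p(ref_calls, test_calls, w, params))
  } else if (params$test == "student") {
    sp2 <- ((n_ref - 1) * w$var_ref + (n_test - 1) * w$var_test) / (n_ref + n_test - 2)
    se <- sqrt(sp2 * (1 / n_ref + 1 / n_test))
    df <- n_ref + n_test - 2
    w[, p_value := .t_p(delta_mC, se, df)]
  } else {
    se <- sqrt(w$var_ref / n_ref + w$var_test / n_test)
    df <- (w$var_ref / n_ref + w$var_test / n_test)^2 /
      ((w$var_ref / n_ref)^2 / (n_ref - 1) + (w$var_test / n_test)^2 / (n_test - 1))
    w[, p_value := .t_p(delta_mC, se, df)]
  }
  len <- chrom_lengths[w$chrom]
  w[, start := wstart]
  w[, end := pmin(wstart + params$window_size, as.integer(len))]
  w[, n_sites := nsites_ref + nsites_test]
  out <- w[, .(chrom, start, end, context, n_sites, mean_ref, mean_test,
               delta_mC, sda_ref, sda_test, p_value)]
  setorder(out, chrom, start, context)
  out[]
}

.t_p <- function(delta, se, df) {
  p <- 2 * pt(-abs(delta / se), df)
  deg <- !is.finite(p) | se == 0
  p[deg] <- ifelse(delta[deg] == 0, 1, 0)
  p
}

# Fisher's exact test on pooled methylated/unmethylated read counts per window.
.fisher_window_p <- function(ref_calls, test_calls, w, params) {
  pool <- function(calls) {
    ok <- calls[n_total >= params$min_site_coverage,
                .(chrom, pos0 = pos - 1L, context, n_meth, n_total)]
    idx <- .site_window_index(ok$pos0, params$window_size, params$step)
    rep_i <- rep.int(seq_len(nrow(ok)), idx$k)
    x <- ok[rep_i]
    x[, wstart := (sequence(idx$k) - 1L + rep.int(idx$lo, idx$k)) * params$step]
    x[, .(meth = sum(n_meth), unmeth = sum(n_total - n_meth)),
      by = .(chrom, context, wstart)]
  }
  pr <- pool(as.data.table(ref_calls)); pt_ <- pool(as.data.table(test_calls))
  key <- w[, .(chrom, context, wstart)]
  key[, row_i := .I]
  key <- merge(key, pr, by = c("chrom", "context", "wstart"), all.x = TRUE)
  setnames(key, c("meth", "unmeth"), c("mr", "ur"))
  key <- merge(key, pt_, by = c("chrom", "context", "wstart"), all.x = TRUE)
  setorder(key, row_i)
  mapply(function(mr, ur, mt, ut) {
    if (anyNA(c(mr, ur, mt, ut))) return(NA_real_)
    stats::fisher.test(matrix(c(mr, ur, mt, ut), 2L))$p.value
  }, key$mr, key$ur, key$meth, key$unmeth)
}

.empty_window_stats <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             context = character(), n_sites = integer(), mean_ref = numeric(),
             mean_test = numeric(), delta_mC = numeric(), sda_ref = numeric(),
             sda_test = numeric(), p_value = numeric())
}

#' Call differentially methylated regions
#'
#' Filters the [window_stats()] table: a window becomes a DMR when its
#' p-value (optionally BH-adjusted) is at most `p_threshold`, both groups'
#' SDA are within the per-context cap, and |delta_mC| reaches
#' `min_abs_delta`. The direction is "hypo" when the test condition is
#' less methylated than the reference (delta_mC < 0) and "hyper"
#' otherwise. Overlapping significant windows are not merged by default:
#' each window is one DMR. `attr(, "n_tested")` records how many windows
#' were eligible for testing.
#'
#' @inheritParams window_stats
#' @return DMR `data.table` (WindowStats columns plus `direction`).
#' @export
call_dmrs <- function(ref_calls, test_calls, params = dmr_params(),
                      chrom_lengths = NULL) {
  ws <- window_stats(ref_calls, test_calls, params, chrom_lengths)
  dmrs <- filter_windows(ws, params)
  setattr(dmrs, "n_tested", nrow(ws))
  dmrs
}

#' Apply DMR filters to a window-statistics table
#'
#' Split out from [call_dmrs()] so the same windows can be re-thresholded
#' without recomputation.
#' @param ws a [window_stats()] table.
#' @param params a [dmr_params()] object.
#' @return filtered DMR `data.table` with `direction`.
#' @export
filter_windows <- function(ws, params = dmr_params()) {
  ws <- as.data.table(ws)
  if (!nrow(ws)) {
    out <- .empty_window_stats()
    out[, direction := character()]
    return(out[])
  }
  p <- if (params$p_adjust == "BH") p.adjust(ws$p_value, "BH") else ws$p_value
  cap <- params$sda_threshold[ws$context]
  keep <- p <= params$p_threshold & ws$sda_ref <= cap & ws$sda_test <= cap &
    abs(ws$delta_mC) >= params$min_abs_delta & ws$delta_mC != 0
  dmrs <- ws[keep]
  dmrs[, direction := ifelse(delta_mC < 0, "hypo", "hyper")]
  if (isTRUE(params$merge_windows) && nrow(dmrs)) {
    dmrs <- .merge_dmr_runs(dmrs)
  }
  setorder(dmrs, chrom, start, context)
  dmrs[]
}

# Optional post-hoc merge of overlapping same-direction windows into runs;
# merged delta/sda/p are the extreme-|delta| window's values.
.merge_dmr_runs <- function(dmrs) {
  setorder(dmrs, context, direction, chrom, start)
  grp <- dmrs[, {
    new_run <- c(TRUE, start[-1L] >= cummax(head(end, -1L)))
    run <- cumsum(new_run)
    best <- function(v) v[which.max(abs(delta_mC))]
    .SD[, .(start = min(start), end = max(end), n_sites = sum(n_sites),
            mean_ref = best(mean_ref), mean_test = best(mean_test),
            delta_mC = best(delta_mC), sda_ref = best(sda_ref),
            sda_test = best(sda_test), p_value = min(p_value)),
        by = .(run_id = run)]
  }, by = .(chrom, context, direction)]
  grp[, run_id := NULL]
  grp
}

#' Tabulate DMRs by context and direction
#'
#' Produces counts per context x direction with row/column totals and the
#' three derived share tables: direction share within each context,
#' context share of all DMRs, and direction share of all DMRs. Accepts
#' either one row per DMR (columns context, direction) or a pre-tabulated
#' count table (columns context, direction, n) so printed counts can be
#' fed straight in. Percentages are exact; [round_half_out()] reproduces
#' printed-style rounding. An empty input yields zero counts and
#' NA-flagged percentages.
#'
#' @param dmrs DMR table or count table.
#' @return list of class `dmr_summary`: `counts` (context x direction
#'   matrix incl. totals), `pct_direction_within_context`,
#'   `pct_context_of_total`, `pct_direction_of_total`, `total`.
#' @export
summarize_dmrs <- function(dmrs) {
  dmrs <- as.data.table(dmrs)
  if (!nrow(dmrs)) {
    cnt <- data.table(context = character(), direction = character(), n = integer())
  } else if ("n" %in% names(dmrs)) {
    cnt <- dmrs[, .(n = sum(n)), by = .(context, direction)]
  } else {
    cnt <- dmrs[, .(n = .N), by = .(context, direction)]
  }
  dirs <- c("hypo", "hyper")
  m <- matrix(0, nrow = length(.CONTEXTS), ncol = 2L,
              dimnames = list(.CONTEXTS, dirs))
  for (i in seq_len(nrow(cnt))) m[cnt$context[i], cnt$direction[i]] <- cnt$n[i]
  total <- sum(m)
  ctx_tot <- rowSums(m)
  dir_tot <- colSums(m)
  pct_dir_within <- if (total) sweep(m, 1L, ctx_tot, "/") * 100 else m * NA_real_
  pct_dir_within[ctx_tot == 0, ] <- NA_real_
  pct_ctx <- if (total) ctx_tot / total * 100 else ctx_tot * NA_real_
  pct_dir <- if (total) dir_tot / total * 100 else dir_tot * NA_real_
  structure(list(counts = cbind(m, total = ctx_tot),
                 direction_totals = dir_tot,
                 pct_direction_within_context = pct_dir_within,
                 pct_context_of_total = pct_ctx,
                 pct_direction_of_total = pct_dir,
                 total = total),
            class = "dmr_summary")
}

#' @export
print.dmr_summary <- function(x, ...) {
  cat("DMR summary:", x$total, "DMRs\n")
  print(cbind(x$counts, pct_of_total = round_half_out(x$pct_context_of_total, 1)))
  cat("direction share of total (%):",
      paste(names(x$pct_direction_of_total),
            round_half_out(x$pct_direction_of_total, 1), collapse = "  "), "\n")
  invisible(x)
}

#' Direction share within a subset of contexts
#'
#' Share (%) of each direction among DMRs of the given contexts pooled,
#' e.g. the hypermethylated share of CG+CHG DMRs.
#' @param x a `dmr_summary`.
#' @param contexts contexts to pool.
#' @return named vector (hypo/hyper) of percentages (NA when empty).
#' @export
direction_share <- function(x, contexts = .CONTEXTS) {
  stopifnot(inherits(x, "dmr_summary"), all(contexts %in% .CONTEXTS))
  sub <- x$counts[contexts, c("hypo", "hyper"), drop = FALSE]
  tot <- sum(sub)
  if (tot == 0) return(c(hypo = NA_real_, hyper = NA_real_))
  colSums(sub) / tot * 100
}

#' Round half away from zero
#'
#' Commercial-style rounding (0.5 goes away from zero), matching how the
#' printed summary percentages in this field are usually typeset, unlike
#' base R's round-half-even.
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_out <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' DMR density along the genome
#'
#' Counts DMR start positions per context in fixed-size genomic bins
#' (50 kb by default) over the full chromosome grid, and flags hotspot
#' bins: bins whose count reaches the given quantile of the *nonzero* bin
#' counts of their context.
#'
#' @param dmrs DMR table.
#' @param chrom_lengths named chromosome lengths.
#' @param bin_size bin width in bp.
#' @param hotspot_quantile quantile of nonzero per-context bin counts at or
#'   above which a bin is a hotspot.
#' @return `data.table` chrom, bin_start, bin_end, context, n, hotspot.
#' @export
dmr_density <- function(dmrs, chrom_lengths, bin_size = 50000L,
                        hotspot_quantile = 0.99) {
  stopifnot(bin_size > 0, !is.null(names(chrom_lengths)))
  dmrs <- as.data.table(dmrs)
  grid <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    starts <- seq.int(0L, as.integer(chrom_lengths[[ch]]) - 1L, by = bin_size)
    CJ(chrom = ch, bin_start = starts, context = .CONTEXTS)
  }))
  grid[, bin_end := pmin(bin_start + as.integer(bin_size),
                         as.integer(chrom_lengths[chrom]))]
  if (nrow(dmrs)) {
    cnt <- dmrs[, .(n = .N),
                by = .(chrom, bin_start = (start %/% as.integer(bin_size)) * as.integer(bin_size),
                       context)]
    out <- merge(grid, cnt, by = c("chrom", "bin_start", "context"), all.x = TRUE)
    out[is.na(n), n := 0L]
  } else {
    out <- copy(grid)
    out[, n := 0L]
  }
  out[, hotspot := FALSE]
  for (cx in .CONTEXTS) {
    nz <- out[context == cx & n > 0L, n]
    if (length(nz)) {
      thr <- as.numeric(quantile(nz, hotspot_quantile))
      out[context == cx & n > 0L & n >= thr, hotspot := TRUE]
    }
  }
  setorder(out, chrom, bin_start, context)
  out[, .(chrom, bin_start, bin_end, context, n, hotspot)][]
}
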