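#' Specification of a synthetic two-condition methylome experiment
#'
#' Describes a replicated bisulfite experiment: a genome of `n_chroms`
#' chromosomes, per-position cytosine context densities, per-context
#' baseline methylation, read coverage, and a set of injected
#' differentially methylated regions applied to the test condition only.
#' Defaults emulate a plant methylome: CHH-dominant cytosine composition
#' (~71% of cytosines), baselines CG 60 / CHG 40 / CHH 10%, mean coverage
#' 14 reads, 3 replicates per condition.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param densities named per-context probability that a position is a
#'   cytosine of that context (single-strand site model).
#' @param baseline named per-context methylation level (%).
#' @param coverage_mean mean of the (zero-truncated) Poisson read depth.
#' @param n_replicates replicates per condition.
#' @param injections `data.frame` with chrom, start, end (0-based
#'   half-open), context, delta (pp, applied to the test condition and
#'   clipped to [0, 100]); NULL for a null experiment. Must not overlap.
#' @param n_genes,n_tes features for the matching annotation.
#' @param effect expression coupling: log2 ratio contribution is
#'   `-effect * (promoter CHH delta / 100)`.
#' @param noise_sd standard deviation of the gene-level log2-ratio noise.
#' @param expr_rep_sd replicate-level expression noise (drives p-values).
#' @param conditions labels of (reference, test).
#' @param seed mandatory integer seed; every output is a pure function of
#'   the spec.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_chroms = 2L, chrom_length = 1e6,
                     densities = c(CG = 0.02, CHG = 0.02, CHH = 0.10),
                     baseline = c(CG = 60, CHG = 40, CHH = 10),
                     coverage_mean = 14, n_replicates = 3L,
                     injections = NULL, n_genes = 200L, n_tes = 300L,
                     effect = 4, noise_sd = 0.5, expr_rep_sd = 0.5,
                     conditions = c("A", "B"), seed) {
  if (missing(seed) || is.null(seed)) stop("sim_spec requires a seed")
  stopifnot(n_chroms >= 1, chrom_length >= 1,
            all(densities > 0), all(densities <= 1), sum(densities) <= 1,
            all(.CONTEXTS %in% names(densities)),
            all(.CONTEXTS %in% names(baseline)),
            all(baseline >= 0), all(baseline <= 100),
            coverage_mean > 0, n_replicates >= 1,
            length(conditions) == 2L)
  if (!is.null(injections)) {
    injections <- as.data.table(injections)
    stopifnot(all(c("chrom", "start", "end", "context", "delta") %in% names(injections)),
              all(injections$start < injections$end),
              all(injections$start >= 0),
              all(injections$end <= chrom_length),
              all(injections$context %in% .CONTEXTS))
    setorder(injections, chrom, start)
    ov <- injections[, any(start[-1L] < head(end, -1L)), by = chrom]$V1
    if (any(ov)) stop("injections overlap")
  }
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 densities = densities, baseline = baseline,
                 coverage_mean = coverage_mean,
                 n_replicates = as.integer(n_replicates),
                 injections = injections, n_genes = as.integer(n_genes),
                 n_tes = as.integer(n_tes), effect = effect,
                 noise_sd = noise_sd, expr_rep_sd = expr_rep_sd,
                 conditions = conditions, seed = as.integer(seed)),
            class = "sim_spec")
}

.chrom_names <- function(spec) sprintf("chr%d", seq_len(spec$n_chroms))

#' Chromosome lengths of a simulation spec
#' @param spec a [sim_spec()].
#' @return named integer vector.
#' @export
sim_chrom_lengths <- function(spec) {
  setNames(rep(spec$chrom_length, spec$n_chroms), .chrom_names(spec))
}

#' Draw non-overlapping injection regions
#'
#' Places `n` regions of width `width` and the given context/delta on a
#' spacing grid (guaranteeing non-overlap and at least `width` separation)
#' uniformly over the chromosomes of `spec`. Driven by `seed` (default:
#' the spec seed), independent of the methylome stream.
#'
#' @param spec a [sim_spec()].
#' @param n number of regions.
#' @param width region width (bp).
#' @param context cytosine context of the injection.
#' @param delta methylation shift (pp) in the test condition.
#' @param seed RNG seed.
#' @return injection `data.table` suitable for [sim_spec()].
#' @export
random_injections <- function(spec, n, width = 500L, context = "CHH",
                              delta = -30, seed = spec$seed) {
  slot <- 2L * width
  per_chrom <- spec$chrom_length %/% slot
  cand <- CJ(chrom = .chrom_names(spec), slot_i = seq_len(per_chrom) - 1L)
  if (n > nrow(cand)) stop("genome too small for ", n, " injections")
  set.seed(seed)
  pick <- sort(sample.int(nrow(cand), n))
  out <- cand[pick]
  out[, start := slot_i * slot + (slot - width) %/% 2L]
  out[, end := start + as.integer(width)]
  out[, context := context]
  out[, delta := delta]
  setorder(out, chrom, start)
  out[, .(chrom, start, end, context, delta)][]
}

# Site scaffold: one row per cytosine with context, strand and the two
# condition-specific true levels (baseline; injected delta on the test side).
.sim_sites <- function(spec) {
  d <- spec$densities
  th <- cumsum(c(d[["CG"]], d[["CHG"]], d[["CHH"]]))
  sites <- rbindlist(lapply(.chrom_names(spec), function(ch) {
    u <- runif(spec$chrom_length)
    idx <- findInterval(u, th) + 1L          # 1=CG 2=CHG 3=CHH 4=none
    keep <- which(idx <= 3L)
    data.table(chrom = ch, pos = keep, context = .CONTEXTS[idx[keep]])
  }))
  sites[, strand := ifelse(runif(.N) < 0.5, "+", "-")]
  sites[, level_ref := spec$baseline[context]]
  sites[, level_test := level_ref]
  inj <- spec$injections
  if (!is.null(inj) && nrow(inj)) {
    for (i in seq_len(nrow(inj))) {
      sites[chrom == inj$chrom[i] & context == inj$context[i] &
              pos - 1L >= inj$start[i] & pos - 1L < inj$end[i],
            level_test := pmin(pmax(level_ref + inj$delta[i], 0), 100)]
    }
  }
  sites
}

.truncated_poisson <- function(n, lambda) {
  qpois(runif(n, ppois(0, lambda), 1), lambda)
}

#' Simulate replicated two-condition methylomes
#'
#' Cytosine positions are drawn per context density; for every site,
#' replicate and condition, read depth is zero-truncated
#' Poisson(`coverage_mean`) and the methylated count is
#' Binomial(depth, level/100), where the level is the context baseline
#' plus, inside an injected region of matching context in the test
#' condition only, the injected delta (clipped to [0, 100]). Everything
#' is a pure function of the spec seed.
#'
#' @param spec a [sim_spec()].
#' @return list: `reference` and `test` call tables ([methylome_set()]
#'   layout), `truth` (injections with direction), `chrom_lengths`.
#' @export
simulate_methylomes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  sites <- .sim_sites(spec)
  n <- nrow(sites)
  draw_condition <- function(condition, level_col) {
    rbindlist(lapply(seq_len(spec$n_replicates), function(r) {
      cov <- .truncated_poisson(n, spec$coverage_mean)
      meth <- rbinom(n, cov, sites[[level_col]] / 100)
      data.table(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
                 context = sites$context, n_meth = meth, n_total = cov,
                 sample_id = paste0(condition, "_rep", r),
                 condition = condition)
    }))
  }
  ref <- draw_condition(spec$conditions[1L], "level_ref")
  test <- draw_condition(spec$conditions[2L], "level_test")
  truth <- if (is.null(spec$injections)) {
    data.table(chrom = character(), start = integer(), end = integer(),
               context = character(), delta = numeric(), direction = character())
  } else {
    t <- copy(spec$injections)
    t[, direction := ifelse(delta < 0, "hypo", "hyper")]
    t[]
  }
  list(reference = ref, test = test, truth = truth,
       chrom_lengths = sim_chrom_lengths(spec))
}

#' Simulate a matching gene/TE annotation
#'
#' Places `n_genes` genes (2-kb spans) and `n_tes` TEs (500-bp spans) on
#' the spec's genome. Half of the injected regions (rounded down, capped
#' by `n_genes`) get a gene planted immediately downstream on the plus
#' strand so that the injection falls in the gene's promoter flank; the
#' remaining features are placed uniformly at random. Driven by
#' `spec$seed + 1` so the annotation stream is independent of the
#' methylome stream.
#'
#' @param spec a [sim_spec()].
#' @return feature `data.table` ([read_features()] layout).
#' @export
simulate_features <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  gene_w <- 2000L; te_w <- 500L
  inj <- spec$injections
  planted <- data.table(chrom = character(), start = integer())
  if (!is.null(inj) && nrow(inj)) {
    n_plant <- min((nrow(inj) + 1L) %/% 2L, spec$n_genes)
    if (n_plant > 0L) {
      sel <- inj[seq_len(n_plant)]
      planted <- sel[, .(chrom, start = pmin(end + 200L,
                                             spec$chrom_length - gene_w))]
    }
  }
  n_rand <- spec$n_genes - nrow(planted)
  rand <- data.table(
    chrom = sample(.chrom_names(spec), n_rand, replace = TRUE),
    start = sample.int(spec$chrom_length - gene_w, n_rand))
  genes <- rbind(planted, rand)
  genes[, `:=`(end = start + gene_w,
               strand = sample(c("+", "-"), .N, replace = TRUE),
               kind = "gene", class_label = NA_character_)]
  # planted genes stay plus-strand so the injection is 5' of the start
  if (nrow(planted)) genes[seq_len(nrow(planted)), strand := "+"]
  genes[, feature_id := sprintf("gene_%05d", seq_len(.N))]
  tes <- data.table(
    chrom = sample(.chrom_names(spec), spec$n_tes, replace = TRUE),
    start = sample.int(spec$chrom_length - te_w, spec$n_tes))
  tes[, `:=`(end = start + te_w,
             strand = sample(c("+", "-"), .N, replace = TRUE),
             kind = "TE",
             class_label = sample(c("ClassI", "ClassII"), .N, replace = TRUE),
             feature_id = sprintf("te_%05d", seq_len(.N)))]
  out <- rbind(genes, tes)[, .(feature_id, chrom, start, end, strand, kind, class_label)]
  setorder(out, chrom, start, feature_id)
  out[]
}

#' Simulate a differential-transcription table coupled to promoter CHH
#'
#' Each gene's reported log2 ratio is the coupling signal
#' `-effect * (promoter CHH delta / 100)` plus Gaussian(0, `noise_sd`)
#' measurement noise. Replicate expression values are drawn around 0
#' (reference) and around the coupling signal (test) with `expr_rep_sd`
#' noise and compared by a pooled two-sample t-test, giving the reported
#' p-value; uncoupled genes are therefore exact nulls and the p-values
#' stay calibrated when `effect = 0`.
#' TEs are uncoupled (promoter delta 0). The promoter is the 2000-bp
#' strand-aware flank 5' of the feature start. Driven by `spec$seed + 2`.
#'
#' @param spec a [sim_spec()].
#' @param features table from [simulate_features()].
#' @return list: `det` (transcript_id, kind, ratio, p_value), `truth`
#'   (transcript_id, promoter_delta, coupled).
#' @export
simulate_expression <- function(spec, features) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 2L)
  features <- as.data.table(features)
  flank <- 2000L
  inj <- spec$injections
  prom_delta <- numeric(nrow(features))
  if (!is.null(inj) && nrow(inj)) {
    chh <- inj[context == "CHH"]
    for (i in seq_len(nrow(features))) {
      plus <- features$strand[i] != "-"
      ps <- if (plus) features$start[i] - flank else features$end[i]
      pe <- if (plus) features$start[i] else features$end[i] + flank
      hit <- chh[chrom == features$chrom[i] & start < pe & end > ps]
      if (nrow(hit)) prom_delta[i] <- hit$delta[1L]
    }
  }
  n <- nrow(features)
  signal <- -spec$effect * (prom_delta / 100)
  true_ratio <- signal + rnorm(n, 0, spec$noise_sd)
  nr <- spec$n_replicates
  ref_m <- matrix(rnorm(n * nr, 0, spec$expr_rep_sd), nrow = n)
  test_m <- matrix(rnorm(n * nr, signal, spec$expr_rep_sd), nrow = n)
  va <- apply(ref_m, 1L, var); vb <- apply(test_m, 1L, var)
  d <- rowMeans(test_m) - rowMeans(ref_m)
  sp2 <- ((nr - 1) * va + (nr - 1) * vb) / (2 * nr - 2)
  se <- sqrt(sp2 * 2 / nr)
  p <- .t_p(d, se, 2 * nr - 2)
  det <- data.table(transcript_id = features$feature_id,
                    kind = features$kind, ratio = true_ratio, p_value = p)
  truth <- data.table(transcript_id = features$feature_id,
                      promoter_delta = prom_delta, coupled = prom_delta != 0)
  list(det = det[], truth = truth[])
}

#' Evaluate DMR calls against injected truth
#'
#' A call matches an injection when they overlap by at least one base on
#' the same chromosome with the same context and direction. Sensitivity
#' is the fraction of injections matched by at least one call; precision
#' the fraction of calls matching at least one injection (undefined, NA,
#' with zero calls); the false-discovery proportion is 1 - precision.
#'
#' @param calls DMR table from [call_dmrs()].
#' @param truth injection truth table (chrom, start, end, context, delta
#'   and/or direction).
#' @return list: sensitivity, precision, fdp, n_calls, n_truth,
#'   n_matched_calls, n_matched_truth, per_context breakdown.
#' @export
evaluate_calls <- function(calls, truth) {
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  if (!"direction" %in% names(truth)) {
    truth[, direction := ifelse(delta < 0, "hypo", "hyper")]
  }
  match_flags <- function(a, b) {
    # for each row of a: does any row of b overlap it (same chrom/context/direction)?
    if (!nrow(a)) return(logical(0))
    if (!nrow(b)) return(rep(FALSE, nrow(a)))
    vapply(seq_len(nrow(a)), function(i) {
      nrow(b[chrom == a$chrom[i] & context == a$context[i] &
               direction == a$direction[i] &
               start < a$end[i] & end > a$start[i]]) > 0L
    }, logical(1L))
  }
  call_hit <- match_flags(calls, truth)
  truth_hit <- match_flags(truth, calls)
  sens <- if (nrow(truth)) mean(truth_hit) else NA_real_
  prec <- if (nrow(calls)) mean(call_hit) else NA_real_
  per_ctx <- rbindlist(lapply(.CONTEXTS, function(cx) {
    tc <- truth$context == cx; cc <- calls$context == cx
    data.table(context = cx,
               n_truth = sum(tc), n_calls = sum(cc),
               sensitivity = if (any(tc)) mean(truth_hit[tc]) else NA_real_,
               precision = if (any(cc)) mean(call_hit[cc]) else NA_real_)
  }))
  list(sensitivity = sens, precision = prec,
       fdp = if (is.na(prec)) NA_real_ else 1 - prec,
       n_calls = nrow(calls), n_truth = nrow(truth),
       n_matched_calls = sum(call_hit), n_matched_truth = sum(truth_hit),
       per_context = per_ctx[])
}

#' Write a simulated experiment to disk
#'
#' Emits per-replicate methylation-call TSVs, a features GFF3, the DET
#' table and the truth tables into `dir`, byte-deterministically. File
#' names: `<condition>_<replicate>.calls.tsv`, `features.gff3`,
#' `det.tsv`, `truth_dmrs.tsv`, `truth_expression.tsv`.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
write_simulation <- function(spec, dir) {
  sim <- simulate_methylomes(spec)
  features <- simulate_features(spec)
  expr <- simulate_expression(spec, features)
  .write_sim_files(sim, features, expr, dir)
}

.write_sim_files <- function(sim, features, expr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cond in list(sim$reference, sim$test)) {
    for (sid in unique(cond$sample_id)) {
      p <- file.path(dir, paste0(sid, ".calls.tsv"))
      write_methylation_calls(cond[sample_id == sid], p)
      paths <- c(paths, p)
    }
  }
  p_gff <- file.path(dir, "features.gff3")
  .write_gff3(features, p_gff)
  p_det <- file.path(dir, "det.tsv")
  fwrite(expr$det[, .(transcript_id, kind,
                      ratio = format(ratio, digits = 15, trim = TRUE),
                      p_value = format(p_value, digits = 15, trim = TRUE))],
         p_det, sep = "\t")
  p_truth <- file.path(dir, "truth_dmrs.tsv")
  fwrite(sim$truth, p_truth, sep = "\t")
  p_expr <- file.path(dir, "truth_expression.tsv")
  fwrite(expr$truth, p_expr, sep = "\t")
  invisible(c(paths, p_gff, p_det, p_truth, p_expr))
}

.write_gff3 <- function(features, path) {
  features <- as.data.table(features)
  attr_col <- ifelse(is.na(features$class_label),
                     paste0("ID=", features$feature_id),
                     paste0("ID=", features$feature_id, ";class_label=",
                            features$class_label))
  type <- ifelse(features$kind == "TE", "transposable_element", "gene")
  lines <- paste(features$chrom, "methylgraft", type,
                 features$start + 1L, features$end, ".", features$strand, ".",
                 attr_col, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
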