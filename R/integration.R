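#' Methylation-transcription integration parameters
#'
#' @param contexts DMR contexts retained (CHH only by default: the
#'   context in which nearly all DMRs of a juvenile-vs-adult plant
#'   methylome comparison fall, and the one maintained by de novo RdDM).
#' @param min_abs_ratio minimum |log2 expression ratio| for a gene to be
#'   integrated.
#' @export
integration_params <- function(contexts = "CHH", min_abs_ratio = 1.5) {
  stopifnot(all(contexts %in% .CONTEXTS), min_abs_ratio >= 0)
  structure(list(contexts = contexts, min_abs_ratio = min_abs_ratio),
            class = "integration_params")
}

#' Join differential transcription with feature-linked DMRs
#'
#' Inner join of DTGs (or DTTEs) with deduplicated DMR-feature links on
#' the gene identifier, keeping records whose DMR context is in the
#' context filter and whose |ratio| reaches `min_abs_ratio`. The link
#' table must already hold at most one DMR per feature
#' ([dedupe_per_feature()]); duplicated feature ids are a contract
#' violation and raise an error.
#'
#' @param dets DET table (transcript_id, ratio, p_value, ...).
#' @param links deduplicated link table from [dedupe_per_feature()].
#' @param params an [integration_params()] object.
#' @param bin_map optional bin assignment (transcript_id, bincode,
#'   class_name) merged in for pathway flags.
#' @return `data.table`: gene_id, ratio, delta_mC, context,
#'   position_class, distance (+ bin columns when a map is given).
#' @export
join_dtg_dmr <- function(dets, links, params = integration_params(),
                         bin_map = NULL) {
  dets <- as.data.table(dets)
  links <- as.data.table(links)
  if (anyDuplicated(links$feature_id)) {
    stop("links contain several DMRs for one feature; run dedupe_per_feature() first")
  }
  l <- links[context %in% params$contexts,
             .(gene_id = feature_id, delta_mC, context, position_class, distance)]
  d <- dets[abs(ratio) >= params$min_abs_ratio,
            .(gene_id = transcript_id, ratio, expr_p = p_value)]
  out <- merge(d, l, by = "gene_id")
  if (!is.null(bin_map)) {
    bm <- as.data.table(bin_map)[, .(gene_id = transcript_id, bincode, class_name)]
    out <- merge(out, bm, by = "gene_id", all.x = TRUE)
  }
  setorder(out, gene_id)
  out[]
}

#' Quadrant shares of methylation change vs expression change
#'
#' Percentages of records in each (sign of delta_mC x sign of ratio)
#' quadrant, per position class and pooled. Quadrants are labelled
#' hypo_up, hypo_down, hyper_up, hyper_down. A class with no records is
#' flagged undefined (NA percentages), never 0/0.
#'
#' @param records table from [join_dtg_dmr()].
#' @param by stratifying column, "position_class" by default.
#' @return `data.table`: one row per (stratum, quadrant) with n and pct;
#'   stratum "all" pools everything.
#' @export
quadrant_summary <- function(records, by = "position_class") {
  records <- as.data.table(records)
  quadrants <- c("hypo_up", "hypo_down", "hyper_up", "hyper_down")
  strata <- c("all", if (nrow(records)) sort(unique(records[[by]])))
  rbindlist(lapply(strata, function(s) {
    sub <- if (s == "all") records else records[records[[by]] == s]
    grid <- data.table(stratum = s, quadrant = quadrants)
    if (!nrow(sub)) {
      grid[, `:=`(n = 0L, pct = NA_real_)]
      return(grid)
    }
    q <- paste0(ifelse(sub$delta_mC < 0, "hypo", "hyper"),
                ifelse(sub$ratio > 0, "_up", "_down"))
    cnt <- data.table(quadrant = q)[, .(n = .N), by = quadrant]
    grid <- merge(grid, cnt, by = "quadrant", all.x = TRUE, sort = FALSE)
    grid[is.na(n), n := 0L]
    grid[, pct := n / sum(n) * 100]
    grid[, .(stratum, quadrant, n, pct)]
  }))
}

#' Correlation between methylation change and expression ratio
#'
#' Least-squares regression of ratio on delta_mC; reports R^2, the signed
#' correlation r = sign(slope) * sqrt(R^2) (identical to Pearson's r),
#' the Student statistic t = r * sqrt((n - 2) / (1 - R^2)) and its
#' two-sided p-value on n - 2 degrees of freedom. With n < 50 an F-ratio
#' comparing the variances of the two plotted variables is reported
#' alongside as a small-sample homogeneity annotation; it never gates the
#' correlation test. Zero variance in either variable leaves the
#' correlation undefined (flagged NA).
#'
#' @param delta_mC,ratio paired numeric vectors (n >= 3), or a records
#'   table via [correlation_by_class()].
#' @return list: n, r_squared, r, t, p_value, variance_test_p (NA when
#'   n >= 50), defined.
#' @export
correlation_test <- function(delta_mC, ratio) {
  ok <- is.finite(delta_mC) & is.finite(ratio)
  x <- delta_mC[ok]; y <- ratio[ok]
  n <- length(x)
  if (n < 3L) stop("correlation_test needs n >= 3 paired values")
  if (var(x) == 0 || var(y) == 0) {
    return(list(n = n, r_squared = NA_real_, r = NA_real_, t = NA_real_,
                p_value = NA_real_, variance_test_p = NA_real_, defined = FALSE))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2L]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  r2 <- min(max(r2, 0), 1)
  r <- sign(slope) * sqrt(r2)
  t <- if (r2 >= 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r2))
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), n - 2)
  vp <- NA_real_
  if (n < 50L) {
    f <- var(x) / var(y)
    vp <- 2 * min(pf(f, n - 1, n - 1), pf(f, n - 1, n - 1, lower.tail = FALSE))
    vp <- min(vp, 1)
  }
  list(n = n, r_squared = unname(r2), r = unname(r), t = unname(t),
       p_value = unname(p), variance_test_p = vp, defined = TRUE)
}

#' Correlation test per position class
#'
#' Applies [correlation_test()] within each position class and pooled.
#' Classes with fewer than 3 records are flagged undefined.
#'
#' @param records table from [join_dtg_dmr()].
#' @return `data.table`: stratum, n, r_squared, r, t, p_value,
#'   variance_test_p, defined.
#' @export
correlation_by_class <- function(records) {
  records <- as.data.table(records)
  strata <- c("all", if (nrow(records)) sort(unique(records$position_class)))
  rbindlist(lapply(strata, function(s) {
    sub <- if (s == "all") records else records[position_class == s]
    if (nrow(sub) < 3L) {
      return(data.table(stratum = s, n = nrow(sub), r_squared = NA_real_,
                        r = NA_real_, t = NA_real_, p_value = NA_real_,
                        variance_test_p = NA_real_, defined = FALSE))
    }
    ct <- correlation_test(sub$delta_mC, sub$ratio)
    data.table(stratum = s, n = ct$n, r_squared = ct$r_squared, r = ct$r,
               t = ct$t, p_value = ct$p_value,
               variance_test_p = ct$variance_test_p, defined = ct$defined)
  }))
}
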