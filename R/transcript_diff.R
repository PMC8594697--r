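#' Read a differential-transcription table
#'
#' TSV with columns transcript_id, kind (gene/TE/other), ratio (signed
#' log2 expression ratio, test over reference) and p_value, as produced
#' upstream by a normalized two-condition differential analysis.
#'
#' @param path TSV path (header line required).
#' @return `data.table` with those four columns.
#' @export
read_det_table <- function(path) {
  if (!file.exists(path)) stop("DET table not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("transcript_id", "kind", "ratio", "p_value")
  if (!all(need %in% names(dt))) {
    stop("DET table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(dt$p_value < 0 | dt$p_value > 1, na.rm = TRUE)) {
    stop("p_value outside [0, 1] in ", path)
  }
  dt[, .(transcript_id, kind, ratio, p_value)][]
}

#' Select differential transcripts
#'
#' Retains records with p-value at most `alpha` (1% by default) and
#' splits them by annotation kind into differentially transcribed genes
#' (DTGs) and transposable elements (DTTEs). Counts are reported per kind
#' and per sign of the ratio.
#'
#' @param det_table table as from [read_det_table()].
#' @param alpha p-value cutoff.
#' @return list: `dets` (all retained), `dtg`, `dtte`, `counts`
#'   (kind x up/down table).
#' @export
select_dets <- function(det_table, alpha = 0.01) {
  det_table <- as.data.table(det_table)
  keep <- det_table[p_value <= alpha]
  counts <- keep[, .(n = .N), by = .(kind, sign = ifelse(ratio >= 0, "up", "down"))]
  list(dets = keep[],
       dtg = keep[kind == "gene"][],
       dtte = keep[kind == "TE"][],
       counts = counts[])
}

#' Read a Mercator-style BIN map
#'
#' Three tab-separated columns: bincode (dotted hierarchy, e.g. "1.1.2"),
#' name, identifier (transcript/gene id). Single quotes around fields, as
#' Mercator emits them, are stripped. When an identifier maps to several
#' bins only the most specific (deepest, then first listed) assignment is
#' retained; downstream analyses use at most one bin per transcript.
#'
#' @param path TSV path.
#' @return `data.table` transcript_id, bincode, class_name (one row per
#'   transcript).
#' @export
read_bin_map <- function(path) {
  if (!file.exists(path)) stop("bin map not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  names(dt) <- tolower(gsub("'", "", names(dt), fixed = TRUE))
  need <- c("bincode", "name", "identifier")
  if (!all(need %in% names(dt))) {
    stop("bin map must have columns: ", paste(need, collapse = ", "))
  }
  strip <- function(x) gsub("^'|'$", "", x)
  dt <- dt[, .(transcript_id = strip(identifier), bincode = strip(bincode),
               class_name = strip(name))]
  dt <- dt[!is.na(transcript_id) & nzchar(transcript_id)]
  dt[, depth := lengths(strsplit(bincode, ".", fixed = TRUE))]
  setorder(dt, transcript_id, -depth)
  out <- dt[, .SD[1L], by = transcript_id]
  out[, depth := NULL]
  out[]
}

#' Tabulate DETs by functional bin
#'
#' Joins DETs to their bin assignment; unassigned transcripts are
#' excluded (their number is kept as an attribute) and percentages are of
#' all assigned DETs, summing to 100. [collapse_minor_bins()] produces the
#' reporting view in which bins under a share threshold are pooled.
#'
#' @param dets DET table (e.g. `select_dets(...)$dtg`).
#' @param bin_map map from [read_bin_map()].
#' @return `data.table` bincode, class_name, n, pct;
#'   `attr(, "n_unassigned")` holds the excluded count.
#' @export
classify_bins <- function(dets, bin_map) {
  dets <- as.data.table(dets)
  bin_map <- as.data.table(bin_map)
  joined <- merge(dets, bin_map, by = "transcript_id")
  n_unassigned <- nrow(dets) - nrow(joined)
  out <- joined[, .(n = .N), by = .(bincode, class_name)]
  out[, pct := n / sum(n) * 100]
  setorder(out, -n, bincode)
  setattr(out, "n_unassigned", n_unassigned)
  out[]
}

#' Pool minor bins into an "Other class" row
#'
#' @param bin_table output of [classify_bins()].
#' @param threshold share (%) below which a bin is pooled.
#' @return table with minor bins replaced by one "Other class" row.
#' @export
collapse_minor_bins <- function(bin_table, threshold = 5) {
  bin_table <- as.data.table(bin_table)
  minor <- bin_table$pct < threshold
  if (!any(minor)) return(bin_table[])
  other <- data.table(bincode = "other", class_name = "Other class",
                      n = sum(bin_table$n[minor]), pct = sum(bin_table$pct[minor]))
  out <- rbind(bin_table[!minor], other)
  setorder(out, -n, bincode)
  out[]
}

#' Hypergeometric bin over-representation with BH correction
#'
#' For every bin present in the DET set, tests over-representation of the
#' bin among DETs against the platform background with the one-sided
#' hypergeometric law: p = P(X >= k) for X ~ Hypergeom(K in-bin
#' background, N - K out-of-bin, n draws). Benjamini-Hochberg adjustment
#' is applied over all tested bins; bins with q <= `q_threshold` are
#' flagged enriched.
#'
#' @param det_bins per-transcript bin assignments of the DETs
#'   (`data.table` with transcript_id, bincode).
#' @param background_bins same for all bin-assigned transcripts on the
#'   platform (must cover every DET bin).
#' @param q_threshold enrichment flag cutoff on q.
#' @return `data.table` bincode, k, n, K, N, p_value, q_value, enriched.
#' @export
bin_enrichment <- function(det_bins, background_bins, q_threshold = 0.05) {
  det_bins <- as.data.table(det_bins)
  background_bins <- as.data.table(background_bins)
  n <- nrow(det_bins)
  N <- nrow(background_bins)
  k_tab <- det_bins[, .(k = .N), by = bincode]
  K_tab <- background_bins[, .(K = .N), by = bincode]
  out <- merge(k_tab, K_tab, by = "bincode", all.x = TRUE)
  if (anyNA(out$K)) {
    stop("bin(s) absent from background (inconsistent map): ",
         paste(out$bincode[is.na(out$K)], collapse = ", "))
  }
  out[, n := n]
  out[, N := N]
  out[, p_value := phyper(k - 1L, K, N - K, n, lower.tail = FALSE)]
  out[, q_value := p.adjust(p_value, "BH")]
  out[, enriched := q_value <= q_threshold]
  setorder(out, p_value, bincode)
  out[, .(bincode, k, n, K, N, p_value, q_value, enriched)][]
}

#' Compare two DET contrasts
#'
#' Intersects the transcript-id sets of two contrasts and, within the
#' common set, counts concordant (same ratio sign) and opposite
#' regulation. `common + specific` partitions each contrast's set;
#' `concordant_up + concordant_down + opposite = common`.
#'
#' @param dets_1,dets_2 DET tables sharing an id namespace.
#' @return list with id vectors `common`, `specific_1`, `specific_2` and
#'   counts `n_concordant_up`, `n_concordant_down`, `n_opposite`.
#' @export
compare_contrasts <- function(dets_1, dets_2) {
  dets_1 <- as.data.table(dets_1)
  dets_2 <- as.data.table(dets_2)
  common <- intersect(dets_1$transcript_id, dets_2$transcript_id)
  s1 <- setdiff(dets_1$transcript_id, common)
  s2 <- setdiff(dets_2$transcript_id, common)
  r1 <- dets_1[match(common, transcript_id), ratio]
  r2 <- dets_2[match(common, transcript_id), ratio]
  conc <- sign(r1) == sign(r2)
  list(common = common, specific_1 = s1, specific_2 = s2,
       n_common = length(common),
       n_concordant_up = sum(conc & r1 > 0),
       n_concordant_down = sum(conc & r1 < 0),
       n_opposite = sum(!conc))
}

#' Relative expression by the 2^-ddCt method
#'
#' For each sample, the quantity of every gene relative to the calibrator
#' sample is efficiency^(Ct_calibrator - Ct_sample); the normalization
#' factor is the geometric mean of the reference-gene quantities
#' (multi-reference-gene correction); normalized expression is the target
#' quantity divided by that factor. The calibrator's normalized
#' expression is 1 by construction, and a constant Ct shift applied to a
#' whole sample cancels through the normalization factor.
#'
#' @param measurements long `data.table`/data.frame with columns
#'   sample_id, gene, ct.
#' @param target target gene name.
#' @param references character vector of reference gene names (>= 1).
#' @param calibrator sample_id of the calibrator.
#' @param efficiency amplification efficiency in (1, 2]; 2 corresponds to
#'   perfect doubling per cycle.
#' @return `data.table` sample_id, norm_factor, expression.
#' @export
ddct_quantify <- function(measurements, target, references, calibrator,
                          efficiency = 2) {
  stopifnot(efficiency > 1, efficiency <= 2, length(references) >= 1)
  m <- as.data.table(measurements)
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(m))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  }
  if (any(m$ct <= 0)) stop("Ct values must be positive")
  genes <- c(target, references)
  samples <- unique(m$sample_id)
  if (!calibrator %in% samples) stop("calibrator sample not found: ", calibrator)
  wide <- dcast(m[gene %in% genes], sample_id ~ gene, value.var = "ct",
                fun.aggregate = mean)
  miss <- setdiff(genes, names(wide))
  if (length(miss)) stop("missing Ct for gene(s): ", paste(miss, collapse = ", "))
  if (anyNA(wide[, ..genes])) {
    bad <- wide$sample_id[!complete.cases(wide[, ..genes])]
    stop("missing Ct in sample(s): ", paste(bad, collapse = ", "))
  }
  cal <- wide[sample_id == calibrator]
  qty <- function(g) efficiency^(cal[[g]] - wide[[g]])
  ref_q <- vapply(references, qty, numeric(nrow(wide)))
  if (is.null(dim(ref_q))) ref_q <- matrix(ref_q, nrow = nrow(wide))
  nf <- exp(rowMeans(log(ref_q)))
  data.table(sample_id = wide$sample_id, norm_factor = nf,
             expression = qty(target) / nf)[]
}
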