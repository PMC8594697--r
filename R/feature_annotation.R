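#' DMR-feature association parameters
#'
#' @param flank distance in bp within which a DMR is linked to a feature
#'   and width of the promoter/terminator regions.
#' @param position_priority tie-break order when a DMR touches several
#'   region classes of one gene.
#' @export
assoc_params <- function(flank = 2000L,
                         position_priority = c("promoter", "body", "terminator")) {
  stopifnot(flank >= 0,
            setequal(position_priority, c("promoter", "body", "terminator")))
  structure(list(flank = as.integer(flank), position_priority = position_priority),
            class = "assoc_params")
}

.as_granges <- function(dt) {
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(start = dt$start + 1L, end = dt$end),
                         strand = if ("strand" %in% names(dt)) dt$strand else "*")
}

#' Link DMRs to nearby genes and TEs
#'
#' Emits one link per (DMR, feature) pair whose intervals overlap or lie
#' within `flank` bp of each other (closest-edge distance; 0 when
#' overlapping). A DMR may link to several features and a feature to
#' several DMRs at this stage; [dedupe_per_feature()] reduces to one DMR
#' per feature. Gene links carry a promoter/body/terminator position
#' class; TE links the analogous flank5/body/flank3.
#'
#' @param dmrs DMR table (chrom/start/end/context/delta_mC/... as from
#'   [call_dmrs()]).
#' @param features feature table from [read_features()].
#' @param params an [assoc_params()] object.
#' @return `data.table` with the DMR coordinates and statistics plus
#'   feature_id, kind, position_class, distance.
#' @export
associate_dmrs <- function(dmrs, features, params = assoc_params()) {
  dmrs <- as.data.table(dmrs)
  features <- as.data.table(features)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), delta_mC = numeric(),
                      p_value = numeric(), direction = character(),
                      feature_id = character(), kind = character(),
                      position_class = character(), distance = integer())
  if (!nrow(dmrs) || !nrow(features)) return(empty)
  qd <- copy(dmrs)
  if ("strand" %in% names(qd)) qd[, strand := NULL]
  gq <- .as_granges(qd)
  gs <- .as_granges(features)
  hits <- GenomicRanges::findOverlaps(gq, gs, maxgap = params$flank,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(gq[qi], gs[si], ignore.strand = TRUE)
  keep <- dist <= params$flank
  qi <- qi[keep]; si <- si[keep]; dist <- dist[keep]
  if (!length(qi)) return(empty)
  out <- dmrs[qi, .(chrom, start, end, context, delta_mC,
                    p_value = if ("p_value" %in% names(dmrs)) p_value else NA_real_,
                    direction = if ("direction" %in% names(dmrs)) direction else
                      ifelse(delta_mC < 0, "hypo", "hyper"))]
  out[, feature_id := features$feature_id[si]]
  out[, kind := features$kind[si]]
  out[, distance := as.integer(dist)]
  out[, position_class := classify_position(
    start, end, features$start[si], features$end[si], features$strand[si],
    kind, params)]
  setorder(out, chrom, start, context, feature_id)
  out[]
}

#' Classify a DMR's position relative to a feature
#'
#' Strand-aware geometry on 0-based half-open intervals: the promoter is
#' the `flank`-bp region 5' of the gene start, the terminator the
#' `flank`-bp region 3' of the gene end (so on the minus strand the
#' promoter lies at higher coordinates). A DMR touching several regions is
#' resolved by `position_priority` (promoter > body > terminator by
#' default). A linked DMR whose closest-edge distance equals `flank`
#' exactly touches no region interior and is assigned the flank class of
#' its side. TE features use the labels flank5/body/flank3.
#'
#' Vectorized over all arguments.
#'
#' @param dmr_start,dmr_end DMR interval.
#' @param f_start,f_end feature interval.
#' @param f_strand "+" or "-".
#' @param kind "gene" or "TE".
#' @param params an [assoc_params()] object.
#' @return character vector of position classes.
#' @export
classify_position <- function(dmr_start, dmr_end, f_start, f_end, f_strand,
                              kind = "gene", params = assoc_params()) {
  n <- max(length(dmr_start), length(f_start))
  dmr_start <- rep_len(dmr_start, n); dmr_end <- rep_len(dmr_end, n)
  f_start <- rep_len(f_start, n); f_end <- rep_len(f_end, n)
  f_strand <- rep_len(f_strand, n); kind <- rep_len(kind, n)
  fl <- params$flank
  plus <- f_strand != "-"
  # 5'-side region (promoter on genes)
  p_start <- ifelse(plus, f_start - fl, f_end)
  p_end <- ifelse(plus, f_start, f_end + fl)
  # 3'-side region (terminator on genes)
  t_start <- ifelse(plus, f_end, f_start - fl)
  t_end <- ifelse(plus, f_end + fl, f_start)
  hit <- function(s, e) dmr_start < e & dmr_end > s
  in_p <- hit(p_start, p_end)
  in_b <- hit(f_start, f_end)
  in_t <- hit(t_start, t_end)
  # boundary case: linked at exactly `flank` distance, touching no interior
  none <- !(in_p | in_b | in_t)
  upstream_side <- ifelse(plus, dmr_end <= f_start, dmr_start >= f_end)
  in_p <- in_p | (none & upstream_side)
  in_t <- in_t | (none & !upstream_side)
  cls <- character(n)
  for (pc in rev(params$position_priority)) {
    m <- switch(pc, promoter = in_p, body = in_b, terminator = in_t)
    cls[m] <- pc
  }
  te <- kind == "TE"
  cls[te & cls == "promoter"] <- "flank5"
  cls[te & cls == "terminator"] <- "flank3"
  cls
}

#' Keep one DMR per feature
#'
#' For each feature, retains the link whose DMR has the largest
#' |delta_mC| (the strongest methylation variation); ties go to the
#' smaller genomic start, then to the lexicographically first context.
#'
#' @param links link table from [associate_dmrs()].
#' @return link table with unique feature_id, each row present in the input.
#' @export
dedupe_per_feature <- function(links) {
  links <- as.data.table(links)
  if (!nrow(links)) return(links[])
  setorderv(links, c("feature_id", "start", "context"))
  links[, abs_delta := abs(delta_mC)]
  setorderv(links, c("feature_id", "abs_delta", "start", "context"),
            order = c(1L, -1L, 1L, 1L))
  out <- links[, .SD[1L], by = feature_id]
  out[, abs_delta := NULL]
  links[, abs_delta := NULL]
  setcolorder(out, names(links))
  setorder(out, chrom, start, context, feature_id)
  out[]
}
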