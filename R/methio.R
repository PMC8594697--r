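#' @import data.table
#' @importFrom stats pt pf phyper p.adjust sd var setNames rbinom rnorm rpois runif qpois ppois quantile complete.cases
#' @importFrom utils head
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")
.STRANDS <- c("+", "-")

#' Read a methylation-call table
#'
#' Reads a per-cytosine methylation-call TSV (Bsmap-methratio-like dialect
#' reduced to its authoritative columns): `chrom`, `pos` (1-based),
#' `strand` (+/-), `context` (CG/CHG/CHH), `n_meth`, `n_total`. The first
#' line is a `#`-prefixed header. Rows with `n_total == 0` carry no
#' information and are dropped; any other malformed row is a hard error
#' naming its line number.
#'
#' @param path path to the TSV file.
#' @param sample_id replicate label attached to every call.
#' @param condition group label (e.g. "OG", "SD", "YG").
#' @return a `data.table` with columns chrom, pos, strand, context, n_meth,
#'   n_total, sample_id, condition. Counts are kept exactly as read;
#'   methylation level is always recomputed from them downstream.
#' @export
read_methylation_calls <- function(path, sample_id, condition) {
  if (!file.exists(path)) stop("methylation-call file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty methylation-call file: ", path)
  start <- if (startsWith(lines[1L], "#")) 2L else 1L
  if (length(lines) < start) {
    dt <- data.table(chrom = character(), pos = integer(), strand = character(),
                     context = character(), n_meth = integer(), n_total = integer())
  } else {
    body <- lines[start:length(lines)]
    keep <- nzchar(body)
    body <- body[keep]
    lineno <- (start:length(lines))[keep]
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 6L)) {
      bad <- which(nf != 6L)[1L]
      stop(sprintf("malformed row at line %d of %s: expected 6 tab-separated fields, got %d",
                   lineno[bad], path, nf[bad]))
    }
    m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
    dt <- data.table(chrom = m[, 1L], pos = suppressWarnings(as.integer(m[, 2L])),
                     strand = m[, 3L], context = m[, 4L],
                     n_meth = suppressWarnings(as.integer(m[, 5L])),
                     n_total = suppressWarnings(as.integer(m[, 6L])))
    .check_call_rows(dt, lineno, path)
  }
  dt <- dt[n_total > 0L]
  set(dt, j = "sample_id", value = sample_id)
  set(dt, j = "condition", value = condition)
  dt[]
}

.check_call_rows <- function(dt, lineno, path) {
  fail <- function(i, why) {
    stop(sprintf("malformed row at line %d of %s: %s", lineno[i], path, why))
  }
  i <- which(is.na(dt$pos) | is.na(dt$n_meth) | is.na(dt$n_total))
  if (length(i)) fail(i[1L], "non-integer pos or counts")
  i <- which(dt$pos < 1L)
  if (length(i)) fail(i[1L], "pos must be >= 1")
  i <- which(!(dt$context %in% .CONTEXTS))
  if (length(i)) fail(i[1L], paste0("unknown context '", dt$context[i[1L]], "'"))
  i <- which(!(dt$strand %in% .STRANDS))
  if (length(i)) fail(i[1L], paste0("unknown strand '", dt$strand[i[1L]], "'"))
  i <- which(dt$n_meth < 0L | dt$n_total < 0L)
  if (length(i)) fail(i[1L], "negative count")
  i <- which(dt$n_meth > dt$n_total)
  if (length(i)) fail(i[1L], sprintf("n_meth (%d) > n_total (%d)", dt$n_meth[i[1L]], dt$n_total[i[1L]]))
  invisible(TRUE)
}

#' Write a methylation-call table
#'
#' Inverse of [read_methylation_calls()]: the read/write round trip is the
#' identity on all six call columns.
#'
#' @param calls data.table of calls.
#' @param path output path.
#' @export
write_methylation_calls <- function(calls, path) {
  calls <- as.data.table(calls)
  out <- calls[, .(chrom, pos, strand, context, n_meth, n_total)]
  writeLines("#chrom\tpos\tstrand\tcontext\tn_meth\tn_total", path)
  if (nrow(out)) {
    fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Combine replicate call tables into one methylome set
#'
#' Binds per-replicate call tables for one condition and checks the
#' replicate structure: at least one replicate, and all replicates on the
#' same chromosome namespace.
#'
#' @param ... call tables from [read_methylation_calls()] (or one list of them).
#' @return a single `data.table` of calls; `attr(, "replicates")` holds the
#'   ordered replicate labels.
#' @export
methylome_set <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is.data.frame(parts[[1L]])) {
    parts <- parts[[1L]]
  }
  if (!length(parts)) stop("a methylome set needs at least one replicate")
  dt <- rbindlist(lapply(parts, as.data.table), use.names = TRUE)
  if (length(unique(dt$condition)) > 1L) {
    stop("a methylome set holds one condition; got: ",
         paste(unique(dt$condition), collapse = ", "))
  }
  reps <- unique(dt$sample_id)
  chroms <- dt[, .(chroms = list(sort(unique(chrom)))), by = sample_id]
  if (nrow(chroms) > 1L) {
    ref <- chroms$chroms[[1L]]
    same <- vapply(chroms$chroms, identical, logical(1L), y = ref)
    if (!all(same)) stop("replicates do not share the same chromosome namespace")
  }
  setattr(dt, "replicates", reps)
  dt[]
}

#' Read gene and transposable-element features from GFF3
#'
#' Imports a GFF3 annotation and keeps `gene` and transposable-element
#' records (`transposable_element`, `transposon_fragment`, or any type
#' containing "transposable"). GFF3 1-based inclusive coordinates are
#' converted to the package-internal 0-based half-open convention at this
#' boundary and nowhere else. Records of other types are skipped and their
#' count reported in a message.
#'
#' @param path GFF3 file path.
#' @return `data.table` with feature_id, chrom, start (0-based), end
#'   (half-open), strand, kind ("gene"/"TE"), class_label.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  kind <- rep(NA_character_, length(gr))
  kind[type == "gene"] <- "gene"
  kind[type %in% c("transposable_element", "transposon_fragment", "TE") |
         grepl("transposable", type, ignore.case = TRUE)] <- "TE"
  skipped <- sum(is.na(kind))
  if (skipped > 0L) message(skipped, " GFF3 record(s) of other types skipped")
  gr <- gr[!is.na(kind)]
  kind <- kind[!is.na(kind)]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  miss <- is.na(ids) | !nzchar(ids)
  if (any(miss)) ids[miss] <- sprintf("feature_%06d", which(miss))
  cls <- if (!is.null(gr$class_label)) as.character(gr$class_label) else rep(NA_character_, length(gr))
  dt <- data.table(
    feature_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind,
    class_label = cls
  )
  dt[strand == "*", strand := "+"]
  if (any(dt$start >= dt$end)) stop("feature with end < start in ", path)
  dt[]
}

.DMR_COLS <- c("chrom", "start", "end", "context", "delta_mC", "p_value",
               "sda_ref", "sda_test", "direction")

#' Write DMRs to a BED-like TSV
#'
#' Nine columns: chrom, start (0-based), end (half-open), context, delta_mC
#' (percentage points, test minus reference), p_value, sda_ref, sda_test
#' (standard deviation of per-replicate window averages, in %), direction
#' (hypo/hyper). Rows are sorted by (chrom, start, context) so output is
#' byte-deterministic.
#'
#' @param dmrs DMR table (possibly empty).
#' @param path output path.
#' @export
write_dmrs <- function(dmrs, path) {
  dmrs <- as.data.table(dmrs)
  if (!nrow(dmrs)) {
    dmrs <- data.table(chrom = character(), start = integer(), end = integer(),
                       context = character(), delta_mC = numeric(),
                       p_value = numeric(), sda_ref = numeric(),
                       sda_test = numeric(), direction = character())
  }
  out <- dmrs[, .SD, .SDcols = .DMR_COLS]
  setorder(out, chrom, start, context)
  writeLines(paste0("#", paste(.DMR_COLS, collapse = "\t")), path)
  if (nrow(out)) {
    out[, delta_mC := format(delta_mC, digits = 15, trim = TRUE, scientific = FALSE)]
    out[, p_value := format(p_value, digits = 15, trim = TRUE)]
    out[, sda_ref := format(sda_ref, digits = 15, trim = TRUE, scientific = FALSE)]
    out[, sda_test := format(sda_test, digits = 15, trim = TRUE, scientific = FALSE)]
    fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Read a DMR table written by [write_dmrs()]
#' @param path DMR TSV path.
#' @return DMR `data.table`; round trip through write/read preserves fields.
#' @export
read_dmrs <- function(path) {
  if (!file.exists(path)) stop("DMR file not found: ", path)
  dt <- fread(path, sep = "\t", header = FALSE, skip = 1L,
              col.names = .DMR_COLS,
              colClasses = list(character = c(1L, 4L, 9L), integer = c(2L, 3L),
                                numeric = 5:8))
  dt[]
}
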