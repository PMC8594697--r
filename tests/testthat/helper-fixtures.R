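library(data.table)

# build a call table from vectors (defaults make single-site edits terse)
make_calls <- function(pos, n_meth, n_total, chrom = "chr1", strand = "+",
                       context = "CHH", sample_id = "s1", condition = "A") {
  data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, n_meth = as.integer(n_meth),
             n_total = as.integer(n_total), sample_id = sample_id,
             condition = condition)
}

# replicated calls at shared positions: meth is a list of per-replicate
# n_meth vectors, one list element per replicate
make_replicates <- function(pos, meth, n_total, condition, context = "CHH",
                            chrom = "chr1") {
  rbindlist(lapply(seq_along(meth), function(r) {
    make_calls(pos, meth[[r]], n_total, chrom = chrom, context = context,
               sample_id = paste0(condition, "_rep", r), condition = condition)
  }))
}

write_call_file <- function(calls, path = tempfile(fileext = ".tsv")) {
  write_methylation_calls(calls, path)
  path
}

write_gff3_lines <- function(rows, path = tempfile(fileext = ".gff3")) {
  # rows: data.frame chrom, type, start1, end1, strand, id
  lines <- paste(rows$chrom, "test", rows$type, rows$start1, rows$end1,
                 ".", rows$strand, ".", paste0("ID=", rows$id), sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  path
}

# naive line-by-line GFF3 parse, independent of rtracklayer
naive_gff3_spans <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.table(chrom = vapply(f, `[`, "", 1L),
             type = vapply(f, `[`, "", 3L),
             start1 = as.integer(vapply(f, `[`, "", 4L)),
             end1 = as.integer(vapply(f, `[`, "", 5L)))
}

# brute-force Benjamini-Hochberg
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  q[o] <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[o[i]] <- min(q[o[i]], q[o[i + 1]])
  pmin(q, 1)
}

# exhaustive hypergeometric upper tail: P(X >= k), X ~ Hyper(K, N-K, n)
hyper_tail_brute <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# brute-force nested-loop interval association within a flank
brute_associate <- function(dmrs, features, flank) {
  out <- list()
  for (i in seq_len(nrow(dmrs))) for (j in seq_len(nrow(features))) {
    if (dmrs$chrom[i] != features$chrom[j]) next
    gap <- max(features$start[j] - dmrs$end[i], dmrs$start[i] - features$end[j], 0)
    if (gap <= flank) out[[length(out) + 1L]] <- data.table(
      dmr_i = i, feature_id = features$feature_id[j], distance = gap)
  }
  rbindlist(out)
}

tiny_features <- function() {
  data.table(feature_id = c("g1", "g2", "te1"),
             chrom = "chr1",
             start = c(9000L, 30000L, 15000L),
             end = c(12000L, 32000L, 15500L),
             strand = c("+", "-", "+"),
             kind = c("gene", "gene", "TE"),
             class_label = c(NA, NA, "ClassI"))
}
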