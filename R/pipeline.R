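#' Read and validate a pipeline configuration
#'
#' YAML with blocks: `simulate` (enabled + [sim_spec()] fields and
#' injection layout) or `inputs` (paths: ref_calls, test_calls, features,
#' det_table, optional bin_map), plus optional parameter blocks `dmr`
#' ([dmr_params()] fields), `association` (flank), `integration`
#' (contexts, min_abs_ratio), `density` (bin_size), `det_alpha` and
#' `conditions`. Referenced files must exist at validation time;
#' validation failures abort before any stage runs.
#'
#' @param path YAML config path.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config list (already parsed).
#' @export
validate_pipeline_config <- function(cfg) {
  simulate <- isTRUE(cfg$simulate$enabled)
  if (!simulate) {
    ins <- cfg$inputs
    if (is.null(ins)) stop("config error: neither simulate.enabled nor inputs given")
    for (key in c("ref_calls", "test_calls", "features", "det_table")) {
      if (is.null(ins[[key]])) stop("config error: inputs.", key, " missing")
      for (f in unlist(ins[[key]])) {
        if (!file.exists(f)) stop("config error: input file not found: ", f)
      }
    }
    if (!is.null(ins$bin_map) && !file.exists(ins$bin_map)) {
      stop("config error: bin map not found: ", ins$bin_map)
    }
    if (length(unlist(ins$ref_calls)) < 2L || length(unlist(ins$test_calls)) < 2L) {
      stop("config error: need >= 2 replicate call files per condition")
    }
  } else if (is.null(cfg$simulate$seed)) {
    stop("config error: simulate.seed is mandatory")
  }
  dp <- do.call(dmr_params, .take(cfg$dmr, names(formals(dmr_params))))
  ap <- do.call(assoc_params, .take(cfg$association, names(formals(assoc_params))))
  ip <- do.call(integration_params, .take(cfg$integration, names(formals(integration_params))))
  structure(list(raw = cfg, simulate = simulate,
                 dmr = dp, association = ap, integration = ip,
                 det_alpha = cfg$det_alpha %||% 0.01,
                 density_bin = as.integer(cfg$density$bin_size %||% 50000L),
                 conditions = unlist(cfg$conditions %||% c("A", "B"))),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.take <- function(lst, allowed) {
  if (is.null(lst)) return(list())
  got <- lst[intersect(names(lst), allowed)]
  if ("sda_threshold" %in% names(got)) got$sda_threshold <- unlist(got$sda_threshold)
  if ("contexts" %in% names(got)) got$contexts <- unlist(got$contexts)
  if ("position_priority" %in% names(got)) got$position_priority <- unlist(got$position_priority)
  got
}

.sim_spec_from_config <- function(cfg) {
  s <- cfg$raw$simulate
  spec_args <- .take(s, setdiff(names(formals(sim_spec)), "injections"))
  if (!is.null(spec_args$densities)) spec_args$densities <- unlist(spec_args$densities)
  if (!is.null(spec_args$baseline)) spec_args$baseline <- unlist(spec_args$baseline)
  spec_args$conditions <- cfg$conditions
  spec <- do.call(sim_spec, spec_args)
  n_inj <- s$n_injections %||% 0L
  if (n_inj > 0L) {
    inj <- random_injections(spec, n = n_inj,
                             width = s$injection_width %||% 500L,
                             context = s$injection_context %||% "CHH",
                             delta = s$injection_delta %||% -30)
    spec_args$injections <- inj
    spec <- do.call(sim_spec, spec_args)
  }
  spec
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the whole analysis pipeline
#'
#' Executes, in order: global methylation levels, window testing and DMR
#' calling, context/direction summary, 50-kb density track, DMR-feature
#' association with per-feature deduplication, differential-transcript
#' selection, optional bin enrichment, and methylation-transcription
#' integration. All outputs land in `out_dir` together with
#' `manifest.json` recording parameters and input/output checksums; a
#' rerun with identical inputs reproduces identical bytes. Any stage
#' error aborts with a stage-named message.
#'
#' @param config path to a YAML config or a `pipeline_config`.
#' @param out_dir output directory.
#' @return invisibly, named vector of output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character(0)

  if (cfg$simulate) {
    spec <- .stage("simulate", .sim_spec_from_config(cfg))
    sim <- .stage("simulate", simulate_methylomes(spec))
    features <- .stage("simulate", simulate_features(spec))
    expr <- .stage("simulate", simulate_expression(spec, features))
    .stage("simulate", .write_sim_files(sim, features, expr, file.path(out_dir, "sim")))
    ref <- sim$reference; test <- sim$test
    chrom_lengths <- sim$chrom_lengths
    det_table <- expr$det
    bin_map <- NULL
  } else {
    ins <- cfg$raw$inputs
    load_group <- function(paths, cond) {
      methylome_set(lapply(seq_along(paths), function(i) {
        read_methylation_calls(paths[i], sample_id = paste0(cond, "_rep", i),
                               condition = cond)
      }))
    }
    ref <- .stage("read_calls", load_group(unlist(ins$ref_calls), cfg$conditions[1L]))
    test <- .stage("read_calls", load_group(unlist(ins$test_calls), cfg$conditions[2L]))
    chrom_lengths <- NULL
    features <- .stage("read_features", read_features(ins$features))
    det_table <- .stage("read_det", read_det_table(ins$det_table))
    bin_map <- if (!is.null(ins$bin_map)) .stage("read_bin_map", read_bin_map(ins$bin_map)) else NULL
    inputs <- unlist(ins[c("ref_calls", "test_calls", "features", "det_table", "bin_map")])
  }

  out <- c()
  glev <- .stage("global_levels",
                 global_methylation_levels(rbind(ref, test),
                                           cfg$dmr$min_site_coverage))
  out["global_levels"] <- file.path(out_dir, "global_levels.tsv")
  fwrite(glev$replicates, out["global_levels"], sep = "\t")

  dmrs <- .stage("call_dmrs", call_dmrs(ref, test, cfg$dmr, chrom_lengths))
  out["dmrs"] <- file.path(out_dir, "dmrs.tsv")
  write_dmrs(dmrs, out["dmrs"])

  summ <- .stage("summarize", summarize_dmrs(dmrs))
  out["dmr_summary"] <- file.path(out_dir, "dmr_summary.tsv")
  st <- as.data.table(summ$counts, keep.rownames = "context")
  fwrite(st, out["dmr_summary"], sep = "\t")

  if (is.null(chrom_lengths)) {
    mx <- rbind(ref[, .(chrom, pos)], test[, .(chrom, pos)])[, .(len = max(pos)), by = chrom]
    chrom_lengths <- setNames(mx$len, mx$chrom)
  }
  dens <- .stage("density", dmr_density(dmrs, chrom_lengths, cfg$density_bin))
  out["dmr_density"] <- file.path(out_dir, "dmr_density.tsv")
  fwrite(dens, out["dmr_density"], sep = "\t")

  links <- .stage("annotate", associate_dmrs(dmrs, features, cfg$association))
  links <- .stage("annotate", dedupe_per_feature(links))
  out["links"] <- file.path(out_dir, "links.tsv")
  fwrite(links, out["links"], sep = "\t")

  sel <- .stage("dets", select_dets(det_table, cfg$det_alpha))
  out["dets"] <- file.path(out_dir, "dets.tsv")
  fwrite(sel$dets, out["dets"], sep = "\t")

  if (!is.null(bin_map)) {
    enr <- .stage("enrich", bin_enrichment(
      merge(sel$dtg[, .(transcript_id)], bin_map, by = "transcript_id")[, .(transcript_id, bincode)],
      bin_map[, .(transcript_id, bincode)]))
    out["enrichment"] <- file.path(out_dir, "enrichment.tsv")
    fwrite(enr, out["enrichment"], sep = "\t")
  }

  rec <- .stage("integrate", join_dtg_dmr(sel$dtg, links[kind == "gene"],
                                          cfg$integration, bin_map))
  out["dtg_dmr"] <- file.path(out_dir, "dtg_dmr.tsv")
  fwrite(rec, out["dtg_dmr"], sep = "\t")

  quad <- .stage("integrate", quadrant_summary(rec))
  corr <- .stage("integrate", correlation_by_class(rec))
  out["integration_summary"] <- file.path(out_dir, "integration_summary.json")
  jsonlite::write_json(list(quadrants = quad, correlation = corr),
                       out["integration_summary"], digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")

  manifest <- list(
    package = "methylgraft",
    version = as.character(utils::packageVersion("methylgraft")),
    parameters = list(dmr = unclass(cfg$dmr),
                      association = unclass(cfg$association),
                      integration = unclass(cfg$integration),
                      det_alpha = cfg$det_alpha,
                      density_bin = cfg$density_bin,
                      conditions = cfg$conditions,
                      simulate = if (cfg$simulate) cfg$raw$simulate else NULL),
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
    output_md5 = as.list(tools::md5sum(unname(out)))
  )
  out["manifest"] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, out["manifest"], digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(out)
}
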