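#' Default run configuration
#'
#' All tunables default to the pipeline's standard values: LRR SD cutoff
#' 0.30, maximum CNV length 8 Mb, Bayes-factor threshold 15, 1000
#' permutations, frequency classes 1/2/5%.
#'
#' @param out_dir output directory for stage TSVs.
#' @param seed master RNG seed.
#' @param ... overrides for any config field (`lrr_sd_max`, `max_cnv_len`,
#'   `bf_min`, `n_perm`, `freq_thresholds`, `min_probes`, `spec`, `noise`,
#'   `sd_enrichment`, `n_sd`, `n_genes`, `sweep_thresholds`).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("cnvrun"), seed = 1L, ...) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              lrr_sd_max = 0.30, max_cnv_len = 8e6, bf_min = 15,
              n_perm = 1000L, freq_thresholds = c(0.01, 0.02, 0.05),
              min_probes = 3L, sweep_thresholds = c(10, 15, 20, 30),
              spec = NULL, noise = NULL, sd_enrichment = 1,
              n_sd = 60L, n_genes = 400L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$bf_min < 0) stop("bf_min must be non-negative")
  if (cfg$lrr_sd_max <= 0) stop("lrr_sd_max must be positive")
  if (cfg$max_cnv_len <= 0) stop("max_cnv_len must be positive")
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' @param path YAML file of scalar config fields.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full pipeline end to end
#'
#' Fixed stage order: simulate -> qc -> call (presets A and B) ->
#' consensus -> cnvr -> sd-test -> annotate -> summarize -> validate.
#' Every stage writes its TSV under the configured output directory and
#' logs a record count into the run manifest; a stage failure aborts with
#' the stage named. Re-running with the same config and seed is
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return run manifest: seed, per-stage record counts, output file
#'   checksums, and the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  spec <- config$spec %||% cohort_spec(seed = config$seed)
  noise <- config$noise %||% noise_spec()
  cohort <- stage("simulate",
                  simulate_cohort(spec, noise,
                                  sd_enrichment = config$sd_enrichment,
                                  n_sd = config$n_sd,
                                  n_genes = config$n_genes))
  counts$simulate <- c(probes = nrow(cohort$map),
                       samples = length(cohort$signals),
                       truth_calls = nrow(cohort$truth))

  qc <- stage("qc", {
    rep <- assess_cohort(cohort$signals, cohort$map, config$lrr_sd_max)
    utils::write.table(rep, file.path(config$out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })
  keep <- qc$passed
  signals <- lapply(which(keep), function(i)
    gc_correct(cohort$signals[[i]], cohort$map))
  counts$qc <- c(passed = sum(keep), failed = sum(!keep))

  callsA <- stage("call_A", call_cohort(signals, cohort$map,
                                        hmm_params("A"),
                                        config$min_probes))
  callsB <- stage("call_B", call_cohort(signals, cohort$map,
                                        hmm_params("B"),
                                        config$min_probes))
  counts$call <- c(A = nrow(callsA), B = nrow(callsB))

  consensus <- stage("consensus", {
    merged <- merge_dual_calls(callsA, callsB)
    merged <- filter_long_calls(merged, config$max_cnv_len)$kept
    apply_bf_threshold(merged, config$bf_min)
  })
  write_cnv_table(consensus, file.path(config$out_dir, "cnv_calls.tsv"))
  dedup <- deduplicate(consensus)
  counts$consensus <- c(calls = nrow(consensus),
                        unique = nrow(dedup$unique_calls))

  regions <- stage("cnvr", build_cnvrs(consensus, sum(keep)))
  write_cnvr_table(regions, file.path(config$out_dir, "cnvr.tsv"))
  counts$cnvr <- c(regions = nrow(regions))

  sd_res <- NULL
  if (!is.null(cohort$sd_track) && nrow(cohort$sd_track) &&
        nrow(consensus)) {
    sd_res <- stage("sd_test",
                    sd_association(consensus, cohort$sd_track,
                                   spec$chrom_lengths_bp,
                                   n_perm = config$n_perm,
                                   seed = config$seed))
  } else {
    message("run_pipeline: sd-test stage skipped (no SD track or no calls)")
  }

  annotation <- stage("annotate",
                      annotate_intervals(regions, cohort$gene_track))
  counts$annotate <- c(
    genes = length(unique(unlist(annotation))))

  summaries <- stage("summarize", list(
    class_table = genotype_class_table(consensus),
    region_ratio = region_class_ratio(regions),
    freq_classes = frequency_classes(regions, config$freq_thresholds),
    coverage = genome_coverage(regions, spec$chrom_lengths_bp),
    breeds = breed_summaries(consensus, cohort$samples,
                             chroms = seq_along(spec$chrom_lengths_bp))))

  outputs <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(seed = config$seed, counts = counts,
                   checksums = tools::md5sum(outputs),
                   consensus = consensus, regions = regions,
                   sd_result = sd_res, annotation = annotation,
                   summaries = summaries, cohort = cohort, qc = qc)
  invisible(manifest)
}
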