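# End-to-end orchestration: simulate -> qc -> cells -> ewas -> compare ->
# power -> report, with deterministic seeding and a checksummed manifest.

.default_model_registry <- function() {
  list(
    alcohol = model_spec("alcohol", "methylation_outcome",
                         covariates = c("age", "bmi", "cell_counts")),
    smoking = model_spec("smoking", "methylation_outcome",
                         covariates = c("age", "cell_counts"),
                         exposure_coding = "current_vs_never"),
    bmi = model_spec("bmi", "trait_outcome",
                     covariates = c("age", "smoking", "alcohol",
                                    "physical_activity", "cell_counts")),
    wc = model_spec("wc", "methylation_outcome",
                    covariates = c("age", "alcohol", "smoking",
                                   "physical_activity", "education",
                                   "cell_counts")),
    crp = model_spec("crp", "methylation_outcome",
                     covariates = c("age", "smoking", "bmi", "cell_counts"),
                     transform = "log"),
    tc = model_spec("tc", "methylation_outcome",
                    covariates = c("age", "cell_counts")),
    ldl = model_spec("ldl", "methylation_outcome",
                     covariates = c("age", "cell_counts")),
    hdl = model_spec("hdl", "methylation_outcome",
                     covariates = c("age", "cell_counts")),
    tg = model_spec("tg", "methylation_outcome",
                    covariates = c("age", "cell_counts")),
    age = model_spec("age", "methylation_outcome",
                     covariates = c("smoking", "cell_counts"))
  )
}

#' Build and validate a pipeline run configuration
#'
#' @param synthetic a [synthetic_config()] for the simulate stage, or `NULL`
#'   when `meth_path`/`pheno_path` or `local_summary_path` supply the data.
#' @param traits traits to analyse (keys of the model registry).
#' @param models named list of [model_spec()] overriding registry defaults.
#' @param seed master seed; stage seeds are derived from it.
#' @param level confidence level used throughout.
#' @param gw_threshold genome-wide significance threshold.
#' @param n_perm surrogate-selection permutations.
#' @param stages character vector of enabled stages, in order, among
#'   `simulate`, `qc`, `cells`, `ewas`, `compare`, `power`, `report`.
#' @param local_summary_path,reference_summary_path optional TSV paths for a
#'   concordance-only run with user-supplied statistics.
#' @param planted_bad_samples,planted_bad_probes QC failures planted in the
#'   simulated detection matrix.
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       traits = "alcohol",
                       models = list(),
                       seed = 1L,
                       level = 0.95,
                       gw_threshold = 9.4e-8,
                       n_perm = 50L,
                       stages = c("simulate", "qc", "cells", "ewas",
                                  "compare", "power", "report"),
                       local_summary_path = NULL,
                       reference_summary_path = NULL,
                       planted_bad_samples = 0L,
                       planted_bad_probes = 0L) {
  valid_stages <- c("simulate", "qc", "cells", "ewas", "compare", "power",
                    "report")
  problems <- character()
  bad <- setdiff(stages, valid_stages)
  if (length(bad)) problems <- c(problems,
    sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  if (level <= 0 || level >= 1) problems <- c(problems,
    "level must lie in (0, 1)")
  if (gw_threshold <= 0 || gw_threshold > 1) problems <- c(problems,
    "gw_threshold must lie in (0, 1]")
  registry <- modifyList(.default_model_registry(), models)
  missing_models <- setdiff(traits, names(registry))
  if (length(missing_models)) problems <- c(problems,
    sprintf("no model registered for trait(s): %s",
            paste(missing_models, collapse = ", ")))
  needs_data <- any(c("qc", "cells", "ewas") %in% stages)
  if (needs_data && !"simulate" %in% stages && is.null(local_summary_path)) {
    problems <- c(problems,
      "stages needing cohort data are enabled but simulate is off and no summary paths are supplied")
  }
  for (p in c(local_summary_path, reference_summary_path)) {
    if (!is.null(p) && !file.exists(p)) problems <- c(problems,
      sprintf("path does not exist: %s", p))
  }
  if (length(problems)) {
    stop(paste0("invalid run config:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  structure(list(synthetic = synthetic, traits = traits, models = registry,
                 seed = as.integer(seed), level = level,
                 gw_threshold = gw_threshold, n_perm = as.integer(n_perm),
                 stages = stages,
                 local_summary_path = local_summary_path,
                 reference_summary_path = reference_summary_path,
                 planted_bad_samples = as.integer(planted_bad_samples),
                 planted_bad_probes = as.integer(planted_bad_probes)),
            class = "run_config")
}

.config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(.serializable_config(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

.serializable_config <- function(config) {
  x <- unclass(config)
  x$models <- lapply(x$models, unclass)
  x$synthetic <- if (!is.null(x$synthetic)) unclass(x$synthetic)
  x
}

#' Run the replication pipeline end-to-end
#'
#' Executes the enabled stages in order and writes every stage output plus a
#' manifest (config hash, seeds, per-file md5 checksums, stage log) into
#' `out_dir`. Re-running with an identical config reproduces byte-identical
#' numeric outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  results <- list()
  stage_on <- function(s) s %in% config$stages

  cohort <- NULL
  meth <- NULL

  if (stage_on("simulate")) {
    syn <- config$synthetic
    syn$seed <- .derived_seed(config$seed, syn$seed)
    cohort <- generate_cohort(syn)
    meth <- cohort$meth
    write_table_tsv(cohort$pheno, file.path(out_dir, "phenotypes.tsv"))
    write_table_tsv(cohort$truth, file.path(out_dir, "truth.tsv"))
    write_matrix_tsv(cohort$meth, file.path(out_dir, "methylation.tsv"))
    write_json_file(.serializable_config(syn),
                    file.path(out_dir, "synthetic_config.json"))
    log$simulate <- list(n_probes = nrow(meth), n_samples = ncol(meth))
    results$cohort <- cohort
  }

  if (stage_on("qc") && !is.null(meth)) {
    det <- generate_detection_matrix(
      cohort$config, config$planted_bad_samples, config$planted_bad_probes)
    dimnames(det) <- dimnames(meth)[c(1, 2)]
    report <- qc_filter(det)
    meth <- apply_qc(meth, report)
    write_json_file(list(excluded_samples = report$excluded_samples,
                         excluded_probes = report$excluded_probes,
                         p_threshold = report$p_threshold,
                         max_fail_fraction = report$max_fail_fraction),
                    file.path(out_dir, "qc_report.json"))
    log$qc <- list(probes_out = nrow(meth), samples_out = ncol(meth),
                   excluded_probes = length(report$excluded_probes),
                   excluded_samples = length(report$excluded_samples))
    results$qc <- report
  }

  if (stage_on("cells") && !is.null(meth)) {
    ref <- synthetic_cell_reference()
    if (length(intersect(rownames(meth), rownames(ref)))) {
      cf <- estimate_cell_fractions(meth, ref)
      write_table_tsv(data.frame(sample_id = rownames(cf),
                                 as.data.frame(unclass(cf))),
                      file.path(out_dir, "cell_fractions.tsv"))
      log$cells <- list(n_shared_probes = attr(cf, "n_shared_probes"))
      results$cell_fractions <- cf
    } else {
      log$cells <- list(skipped = "no reference probes in matrix")
    }
  }

  summaries <- list()
  if (stage_on("ewas") && !is.null(meth)) {
    pheno <- cohort$pheno[match(colnames(meth), cohort$pheno$sample_id), ]
    for (tr in config$traits) {
      spec <- config$models[[tr]]
      sv <- estimate_surrogates(meth, pheno, spec, n_perm = config$n_perm,
                                seed = .derived_seed(config$seed, 77))
      st <- fit_ewas(meth, pheno, spec, surrogates = sv,
                     level = config$level, cohort = "local")
      summaries[[tr]] <- st
      write_table_tsv(st, file.path(out_dir, sprintf("ewas_%s.tsv", tr)))
      hits <- genomewide_hits(st, config$gw_threshold)
      write_table_tsv(hits, file.path(out_dir, sprintf("hits_%s.tsv", tr)))
      log[[paste0("ewas_", tr)]] <- list(n_probes = nrow(st),
                                         n_surrogates = sv$k,
                                         n_hits = nrow(hits))
    }
    results$summaries <- summaries
  } else if (!is.null(config$local_summary_path)) {
    st <- read_summary_tsv(config$local_summary_path, config$level)
    summaries[[st$trait[1]]] <- st
    results$summaries <- summaries
  }

  trait_summaries <- list()
  if (stage_on("compare") && length(summaries)) {
    for (tr in names(summaries)) {
      reference <- if (!is.null(config$reference_summary_path)) {
        read_summary_tsv(config$reference_summary_path, config$level)
      } else if (!is.null(cohort)) {
        syn <- cohort$config
        generate_reference_summary(cohort$truth, syn, level = config$level)
      } else NULL
      if (is.null(reference)) next
      rec <- compare_associations(summaries[[tr]], reference,
                                  level = config$level)
      write_table_tsv(rec, file.path(out_dir,
                                     sprintf("comparison_%s.tsv", tr)))
      # plot-data table: x = local, y = reference, class color key
      plot_df <- data.frame(
        probe_id = rec$probe_id, x_local = rec$local_effect,
        y_reference = rec$ref_effect, class = rec$direction_class,
        color = c(overlap = "green", consistent_nonoverlap = "yellow",
                  opposite = "red")[rec$direction_class],
        stringsAsFactors = FALSE)
      write_table_tsv(plot_df, file.path(out_dir,
                                         sprintf("plotdata_%s.tsv", tr)))
      ts <- summarize_trait(rec)
      trait_summaries[[tr]] <- ts
      log[[paste0("compare_", tr)]] <- list(
        n_tests = ts$n_tests, n_overlap = ts$n_overlap,
        n_consistent = ts$n_consistent, n_opposite = ts$n_opposite)
    }
    results$trait_summaries <- trait_summaries
  }

  if (stage_on("power")) {
    thr <- bonferroni_threshold(0.05, 530639L)
    probe_sd <- if (!is.null(meth)) apply(meth, 1, sd) else 0.05
    ps <- power_spec(n = if (!is.null(meth)) ncol(meth) else 120L,
                     probe_sd = probe_sd)
    pw <- probe_power(ps, per_test_alpha = thr)
    write_json_file(list(per_test_alpha = thr,
                         per_test_alpha_2sf = format_threshold(thr),
                         fraction_power_ge_80 = pw$fraction_at_target),
                    file.path(out_dir, "power.json"))
    log$power <- list(per_test_alpha = thr,
                      fraction_power_ge_80 = pw$fraction_at_target)
    results$power <- pw
  }

  if (stage_on("report") && length(trait_summaries)) {
    rep <- replication_report(trait_summaries)
    write_json_file(rep, file.path(out_dir, "replication_report.json"))
    results$report <- rep
  }

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("ewasrep")),
    config_hash = .config_digest(config),
    seed = config$seed,
    stages = config$stages,
    log = log,
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 basename(files)))
  )
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

#' Pool per-trait concordance summaries into one replication report
#'
#' @param summaries list of [summarize_trait()] results.
#' @return list with pooled counts/fractions over the
#'   overlap / consistent / opposite partition and the per-trait table.
#' @export
replication_report <- function(summaries) {
  if (length(summaries) == 0L) stop("need at least one trait summary",
                                    call. = FALSE)
  per_trait <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(trait = s$trait, ancestry = s$ancestry, n_tests = s$n_tests,
               n_overlap = s$n_overlap, n_consistent = s$n_consistent,
               n_opposite = s$n_opposite, stringsAsFactors = FALSE)
  }))
  totals <- colSums(per_trait[, c("n_tests", "n_overlap", "n_consistent",
                                  "n_opposite")])
  fractions <- totals[c("n_overlap", "n_consistent", "n_opposite")] /
    totals[["n_tests"]]
  names(fractions) <- c("overlap", "consistent", "opposite")
  list(n_tests = totals[["n_tests"]],
       n_overlap = totals[["n_overlap"]],
       n_consistent = totals[["n_consistent"]],
       n_opposite = totals[["n_opposite"]],
       fractions = as.list(fractions),
       percent = as.list(round(100 * fractions)),
       per_trait = per_trait)
}
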