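# Synthetic methylation cohorts with known ground truth.
#
# The generator emulates the structure the downstream analysis assumes:
# beta-valued methylation with probe-specific baselines, planted linear trait
# effects, leukocyte cell-mixture structure, slide-batch offsets, a hidden
# confounder, and a paired "reference study" summary table with scaled
# effects, sampling noise and a configurable fraction of sign-discordant CpGs.

.cell_types <- c("B", "CD4T", "CD8T", "Gran", "Mono", "NK")
.cell_cols <- paste0("cf_", .cell_types)

# marginal SDs used when emulating reference-study standard errors;
# shapes follow the descriptive table of a 120-man cohort aged 45-88
.trait_sd_table <- c(
  age = 9.5, bmi = 4.9, wc = 12.8, alcohol = 36.6, physical_activity = 0.94,
  crp = 27.2, tc = 41.6, ldl = 35.7, hdl = 22.7, tg = 30.5, smoking = 0.5
)

#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates every knob of the generator. Defaults describe a
#' small methylation cohort: 120 men aged 45-88 years with zero-inflated
#' alcohol intake, six leukocyte fractions, slide batches, and a paired
#' reference study with much larger sample size and effects scaled by
#' `reference_effect_multiplier`.
#'
#' @param n_samples number of samples in the local cohort.
#' @param n_probes number of CpG probes.
#' @param n_causal number of probes carrying a true trait effect.
#' @param effect_scale typical beta-value change per unit trait at causal
#'   probes; individual effects are drawn uniformly in
#'   `[0.5, 1.5] * effect_scale` with random sign.
#' @param se_profile list describing reference-study standard errors. One of
#'   `list(type = "scaled", n_ref, noise_scale)` (local-like SE shrunk by
#'   `sqrt(n_ref / n_samples)`), `list(type = "lognormal", meanlog, sdlog,
#'   noise_scale)`, or `list(type = "fixed", se, noise_scale)`.
#'   `noise_scale` multiplies the sampling noise added to reference effects
#'   (0 gives noise-free effects with positive SEs).
#' @param discordant_fraction proportion of causal probes whose reference
#'   effect sign is flipped (genetically driven discordance), in `[0, 1]`.
#' @param reference_effect_multiplier scaling of reference vs local effects.
#' @param confounder_strength scale of hidden-confounder loadings (0 = none).
#' @param confounder_fraction fraction of probes loading on the confounder.
#' @param n_slides number of array slides (batch levels).
#' @param noise_sd residual beta-scale noise SD (> 0).
#' @param slide_sd SD of per-probe, per-slide batch offsets.
#' @param cell_effect_sd scale of per-probe cell-composition loadings.
#' @param trait name of the phenotype column that drives planted effects.
#' @param include_cell_reference embed the probes of
#'   [synthetic_cell_reference()] so cell deconvolution is exercised
#'   end-to-end (requires `n_probes >=` the reference probe count).
#' @param logit_scale assemble signal on the logit scale before squashing
#'   back to `(0, 1)`; the default linear-beta scale keeps planted effects
#'   exactly recoverable by ordinary least squares.
#' @param seed integer seed; identical config + seed reproduces bit-identical
#'   output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 120, n_probes = 5000, n_causal = 100,
                             effect_scale = 5e-4,
                             se_profile = list(type = "scaled", n_ref = 5000,
                                               noise_scale = 1),
                             discordant_fraction = 0.01,
                             reference_effect_multiplier = 0.5,
                             confounder_strength = 1,
                             confounder_fraction = 0.5,
                             n_slides = 15,
                             noise_sd = 0.02,
                             slide_sd = 0.003,
                             cell_effect_sd = 0.1,
                             trait = "alcohol",
                             include_cell_reference = TRUE,
                             logit_scale = FALSE,
                             seed = 1L) {
  for (f in c("n_samples", "n_probes", "n_causal", "effect_scale",
              "discordant_fraction", "reference_effect_multiplier",
              "confounder_strength", "confounder_fraction", "n_slides",
              "noise_sd", "slide_sd", "cell_effect_sd", "seed")) {
    .check_finite(get(f), f)
  }
  if (discordant_fraction < 0 || discordant_fraction > 1) {
    stop("config field `discordant_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (n_causal > n_probes) {
    stop("config field `n_causal` must not exceed `n_probes`", call. = FALSE)
  }
  if (noise_sd <= 0) {
    stop("config field `noise_sd` must be > 0", call. = FALSE)
  }
  if (!is.list(se_profile) || is.null(se_profile$type)) {
    stop("config field `se_profile` must be a list with a `type` entry",
         call. = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
    n_causal = as.integer(n_causal), effect_scale = effect_scale,
    se_profile = se_profile, discordant_fraction = discordant_fraction,
    reference_effect_multiplier = reference_effect_multiplier,
    confounder_strength = confounder_strength,
    confounder_fraction = confounder_fraction,
    n_slides = as.integer(n_slides), noise_sd = noise_sd,
    slide_sd = slide_sd, cell_effect_sd = cell_effect_sd, trait = trait,
    include_cell_reference = isTRUE(include_cell_reference),
    logit_scale = isTRUE(logit_scale), seed = as.integer(seed)
  ), class = "synthetic_config")
}

# phenotype marginals follow the descriptive table of the emulated cohort:
# age uniform 45-88 y, BMI 22.5 +/- 4.9, alcohol zero-inflated gamma with
# 47% never-users, cell fractions Dirichlet around whole-blood means
.simulate_phenotypes <- function(config) {
  n <- config$n_samples
  sample_id <- sprintf("S%04d", seq_len(n))
  age <- runif(n, 45, 88)
  bmi <- pmax(rnorm(n, 22.5, 4.9), 14)
  wc <- pmax(rnorm(n, 83.8, 12.8), 55)
  drinker <- runif(n) >= 0.47
  alcohol <- ifelse(drinker, rgamma(n, shape = 0.8, scale = 31.5 / 0.8), 0)
  smoking <- sample(c("never", "current", "former"), n, replace = TRUE,
                    prob = c(0.47, 0.51, 0.02))
  physical_activity <- pmax(rnorm(n, 2.41, 0.94), 0)
  education <- sample(c("none", "1-7y", "8-12y"), n, replace = TRUE,
                      prob = c(0.22, 0.55, 0.23))
  crp <- rlnorm(n, meanlog = 1.18, sdlog = 1.48)
  tc <- pmax(rnorm(n, 171, 41.6), 60)
  ldl <- pmax(rnorm(n, 96.5, 35.7), 20)
  hdl <- pmax(rnorm(n, 54.1, 22.7), 10)
  tg <- pmax(rnorm(n, 48.5, 30.5), 10)
  cell_means <- c(B = 0.04, CD4T = 0.11, CD8T = 0.11, Gran = 0.47,
                  Mono = 0.09, NK = 0.11)
  cell_means <- cell_means / sum(cell_means)
  fr <- .rdirichlet(n, cell_means * 20)
  colnames(fr) <- .cell_cols
  slide <- rep_len(seq_len(config$n_slides), n)[sample.int(n)]
  pheno <- data.frame(sample_id = sample_id, age = age, bmi = bmi, wc = wc,
                      alcohol = alcohol, smoking = smoking,
                      physical_activity = physical_activity,
                      education = education, crp = crp, tc = tc, ldl = ldl,
                      hdl = hdl, tg = tg, slide = slide,
                      stringsAsFactors = FALSE)
  cbind(pheno, as.data.frame(fr))
}

#' Generate a synthetic methylation cohort
#'
#' Draws a phenotype table, a probe truth table and a probes-by-samples beta
#' matrix assembled as baseline + planted trait effect + cell-composition
#' contribution + slide offset + hidden-confounder contribution + Gaussian
#' noise, clipped to `[0, 1]`. The hidden factor and slide offsets are kept
#' on the returned object so tests can use them as oracles.
#'
#' Baselines at causal probes are drawn at intermediate methylation
#' (uniform 0.3-0.6) so planted effects are not truncated by clipping;
#' remaining baselines follow the bimodal shape typical of array data.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `ewas_cohort`: a list with elements `meth`
#'   (matrix, probes x samples), `pheno` (data.frame), `truth` (data.frame
#'   with `probe_id`, `true_effect`, `confounder_loading`, `discordant`,
#'   `baseline`), `hidden_factor`, `slide_offsets` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_probes
  pheno <- .simulate_phenotypes(config)
  if (!config$trait %in% names(pheno)) {
    stop(sprintf("config field `trait` names an unknown phenotype: %s",
                 config$trait), call. = FALSE)
  }
  probe_id <- sprintf("cg%08d", seq_len(m))

  ref <- NULL
  ref_idx <- integer(0)
  if (config$include_cell_reference) {
    ref <- synthetic_cell_reference()
    if (m >= nrow(ref)) {
      ref_idx <- seq_len(nrow(ref))
      probe_id[ref_idx] <- rownames(ref)
    } else {
      ref <- NULL
    }
  }

  baseline <- 0.02 + 0.96 * rbeta(m, 0.4, 0.4)
  causal_pool <- setdiff(seq_len(m), ref_idx)
  causal <- sort(sample(causal_pool, config$n_causal))
  baseline[causal] <- runif(config$n_causal, 0.3, 0.6)

  true_effect <- numeric(m)
  true_effect[causal] <- config$effect_scale *
    sample(c(-1, 1), config$n_causal, replace = TRUE) *
    runif(config$n_causal, 0.5, 1.5)

  loading <- numeric(m)
  n_aff <- round(config$confounder_fraction * m)
  if (n_aff > 0 && config$confounder_strength != 0) {
    aff <- sample(seq_len(m), n_aff)
    loading[aff] <- config$confounder_strength * rnorm(n_aff, 0, 0.02)
  }

  discordant <- logical(m)
  if (config$n_causal > 0) {
    discordant[causal] <- runif(config$n_causal) < config$discordant_fraction
  }

  hidden <- rnorm(n)
  trait <- pheno[[config$trait]]
  if (is.character(trait)) trait <- as.numeric(factor(trait))

  fr <- as.matrix(pheno[, .cell_cols])
  fr_centred <- sweep(fr, 2, colMeans(fr))
  cell_load <- matrix(0, m, length(.cell_types))
  if (config$cell_effect_sd > 0) {
    pool <- setdiff(seq_len(m), c(ref_idx, causal))
    n_cell <- round(0.3 * length(pool))
    if (n_cell > 0) {
      idx <- sample(pool, n_cell)
      cell_load[idx, ] <- rnorm(n_cell * length(.cell_types), 0,
                                config$cell_effect_sd)
    }
  }

  slide_off <- matrix(rnorm(m * config$n_slides, 0, config$slide_sd),
                      m, config$n_slides)
  noise <- matrix(rnorm(m * n, 0, config$noise_sd), m, n)

  signal <- outer(true_effect, trait) + cell_load %*% t(fr_centred) +
    outer(loading, hidden) + slide_off[, pheno$slide, drop = FALSE]
  if (config$logit_scale) {
    base_clamped <- pmin(pmax(baseline, 1e-4), 1 - 1e-4)
    beta <- stats::plogis(stats::qlogis(base_clamped) + signal + noise)
  } else {
    beta <- baseline + signal + noise
  }
  if (length(ref_idx)) {
    beta[ref_idx, ] <- ref %*% t(fr) + noise[ref_idx, , drop = FALSE]
  }
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(probe_id, pheno$sample_id)

  truth <- data.frame(probe_id = probe_id, true_effect = true_effect,
                      confounder_loading = loading, discordant = discordant,
                      baseline = baseline, stringsAsFactors = FALSE)
  structure(list(meth = beta, pheno = pheno, truth = truth,
                 hidden_factor = hidden, slide_offsets = slide_off,
                 config = config),
            class = "ewas_cohort")
}

#' @export
print.ewas_cohort <- function(x, ...) {
  cat(sprintf("<ewas_cohort> %d probes x %d samples, %d causal, trait '%s'\n",
              nrow(x$meth), ncol(x$meth), sum(x$truth$true_effect != 0),
              x$config$trait))
  invisible(x)
}

#' Construct a per-CpG association summary table
#'
#' The common container for local and reference association statistics:
#' one row per probe with effect, SE, two-sided normal p and a symmetric
#' confidence interval. Also the ingestion shape for external
#' reference-study statistics.
#'
#' @param probe_id character vector of probe identifiers.
#' @param effect,se numeric vectors (se > 0 unless the fit is degenerate).
#' @param trait,cohort,ancestry,model_id metadata labels recycled per row.
#' @param n sample size(s) used.
#' @param level confidence level for the interval bounds.
#' @param p optional p-values; computed from `effect / se` when omitted.
#' @param df optional residual degrees of freedom: when supplied, p comes
#'   from the t distribution rather than the normal.
#' @return a `data.frame` of class `ewas_summary` with columns `probe_id`,
#'   `trait`, `cohort`, `ancestry`, `n`, `effect`, `se`, `p`, `ci_low`,
#'   `ci_high`, `model_id`.
#' @export
summary_table <- function(probe_id, effect, se, trait, cohort,
                          ancestry = "NA", n = NA_integer_, level = 0.95,
                          p = NULL, df = NULL, model_id = "unspecified") {
  if (any(se < 0, na.rm = TRUE)) stop("standard errors must be >= 0",
                                      call. = FALSE)
  z <- ci_multiplier(level)
  if (is.null(p)) {
    stat <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, Inf))
    p <- if (is.null(df)) 2 * pnorm(-abs(stat)) else 2 * pt(-abs(stat), df)
  }
  out <- data.frame(
    probe_id = as.character(probe_id), trait = trait, cohort = cohort,
    ancestry = ancestry, n = n, effect = effect, se = se,
    p = .p_floor(p), ci_low = effect - z * se, ci_high = effect + z * se,
    model_id = model_id, stringsAsFactors = FALSE
  )
  attr(out, "level") <- level
  class(out) <- c("ewas_summary", "data.frame")
  out
}

# draw reference-study standard errors under the configured profile
.reference_se <- function(truth, config) {
  prof <- config$se_profile
  m <- nrow(truth)
  se <- switch(prof$type,
    fixed = rep(prof$se, m),
    lognormal = rlnorm(m, meanlog = prof$meanlog, sdlog = prof$sdlog),
    scaled = {
      trait_sd <- .trait_sd_table[[config$trait]] %||% 1
      se_local <- config$noise_sd / (trait_sd * sqrt(config$n_samples))
      rep(se_local / sqrt((prof$n_ref %||% 5000) / config$n_samples), m)
    },
    stop(sprintf("unknown se_profile type: %s", prof$type), call. = FALSE)
  )
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("se_profile yields non-positive or non-finite standard errors",
         call. = FALSE)
  }
  se
}

#' Generate a reference-study summary table from synthetic ground truth
#'
#' Emulates the published summary statistics a replication analysis is
#' compared against: reference effects equal
#' `reference_effect_multiplier * true_effect`, sign-flipped at probes marked
#' discordant, plus sampling noise with the SE drawn from the configured
#' profile. p and CI fields follow the two-sided normal statistic.
#'
#' @param truth a `TruthTable` data.frame as produced by [generate_cohort()].
#' @param config the matching [synthetic_config()].
#' @param ancestry label recorded on the output rows.
#' @param level confidence level of the interval bounds.
#' @return an `ewas_summary` table over the same probe universe as `truth`.
#' @export
generate_reference_summary <- function(truth, config, ancestry = "EUR",
                                       level = 0.95) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(c("probe_id", "true_effect", "discordant") %in% names(truth))) {
    stop("`truth` must have columns probe_id, true_effect, discordant",
         call. = FALSE)
  }
  set.seed(.derived_seed(config$seed, 1000003))
  se <- .reference_se(truth, config)
  noise_scale <- config$se_profile$noise_scale %||% 1
  base_effect <- config$reference_effect_multiplier * truth$true_effect *
    ifelse(truth$discordant, -1, 1)
  effect <- base_effect + rnorm(nrow(truth), 0, se * noise_scale)
  n_ref <- config$se_profile$n_ref %||% NA_integer_
  summary_table(truth$probe_id, effect, se, trait = config$trait,
                cohort = "reference", ancestry = ancestry, n = n_ref,
                level = level, model_id = "reference_synthetic")
}

#' Generate a detection p-value matrix with planted QC failures
#'
#' Background detection p-values are far below the usual 0.01 threshold;
#' planted bad samples (columns) and bad probes (rows) have more than 5% of
#' their entries failing, so the QC module should exclude exactly those.
#'
#' @param config a [synthetic_config()] (dimensions and seed).
#' @param planted_bad_samples,planted_bad_probes counts of planted failures.
#' @param fail_rate fraction of entries pushed above the threshold within a
#'   planted row/column (must exceed the QC `max_fail_fraction`).
#' @return matrix of detection p-values (probes x samples) with attributes
#'   `bad_samples` and `bad_probes` holding the planted identifiers.
#' @export
generate_detection_matrix <- function(config, planted_bad_samples = 0,
                                      planted_bad_probes = 0,
                                      fail_rate = 0.10) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  m <- config$n_probes
  if (planted_bad_samples > n || planted_bad_probes > m) {
    stop("planted counts exceed matrix dimensions", call. = FALSE)
  }
  set.seed(.derived_seed(config$seed, 2000003))
  det <- matrix(runif(m * n, 0, 0.005), m, n,
                dimnames = list(sprintf("cg%08d", seq_len(m)),
                                sprintf("S%04d", seq_len(n))))
  bad_s <- sort(sample.int(n, planted_bad_samples))
  bad_p <- sort(sample.int(m, planted_bad_probes))
  k_rows <- max(ceiling(fail_rate * m), floor(0.05 * m) + 1)
  for (j in bad_s) {
    det[sample.int(m, k_rows), j] <- runif(k_rows, 0.02, 0.8)
  }
  k_cols <- max(ceiling(fail_rate * n), floor(0.05 * n) + 1)
  for (i in bad_p) {
    det[i, sample.int(n, k_cols)] <- runif(k_cols, 0.02, 0.8)
  }
  attr(det, "bad_samples") <- colnames(det)[bad_s]
  attr(det, "bad_probes") <- rownames(det)[bad_p]
  det
}
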