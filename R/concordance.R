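# Cross-cohort replication classification: CI overlap, directional
# consistency, effect-size regression and genetic-context annotation.

.flag_cols <- c("polymorphic_probe", "cross_reactive", "has_cis_mqtl",
                "has_trans_mqtl", "maf_discordant")

#' Classify per-CpG associations by confidence-interval overlap
#'
#' Joins two summary tables on `probe_id` (inner join) and classifies each
#' shared probe: `overlap` when the confidence intervals intersect
#' (`max(lows) <= min(highs)`), otherwise `consistent_nonoverlap` when the
#' effect signs agree (a zero effect is treated as consistent with either
#' sign) and `opposite` when they disagree. The three classes partition all
#' records. Probes present in only one table are not dropped silently: they
#' are listed in the `unmatched` attribute.
#'
#' Intervals are recomputed from effect and SE at the requested level so both
#' cohorts use the same multiplier.
#'
#' @param local,reference `ewas_summary` tables in the same effect units and
#'   orientation (the caller asserts this; mismatched `trait` metadata
#'   errors).
#' @param level confidence level for the overlap rule.
#' @return a data.frame of class `comparison_records`, one row per shared
#'   probe, with local/reference statistics, `overlap`, `direction_class`,
#'   and all genetic-context flags initialised to `FALSE`.
#' @export
compare_associations <- function(local, reference, level = 0.95) {
  for (tab in list(local, reference)) {
    if (!all(c("probe_id", "effect", "se") %in% names(tab))) {
      stop("summary tables need columns probe_id, effect, se", call. = FALSE)
    }
  }
  lt <- unique(local$trait)
  rt <- unique(reference$trait)
  if (length(lt) == 1L && length(rt) == 1L && !identical(lt, rt)) {
    stop(sprintf("trait metadata mismatch: local '%s' vs reference '%s'",
                 lt, rt), call. = FALSE)
  }
  z <- ci_multiplier(level)
  shared <- intersect(local$probe_id, reference$probe_id)
  li <- match(shared, local$probe_id)
  ri <- match(shared, reference$probe_id)
  le <- local$effect[li]; lse <- local$se[li]
  re <- reference$effect[ri]; rse <- reference$se[ri]
  l_lo <- le - z * lse; l_hi <- le + z * lse
  r_lo <- re - z * rse; r_hi <- re + z * rse
  overlap <- pmax(l_lo, r_lo) <= pmin(l_hi, r_hi)
  sign_consistent <- sign(le) == sign(re) | le == 0 | re == 0
  direction_class <- ifelse(overlap, "overlap",
                            ifelse(sign_consistent, "consistent_nonoverlap",
                                   "opposite"))
  rec <- data.frame(
    probe_id = shared,
    trait = if (length(lt)) lt[1] else NA_character_,
    ancestry = if ("ancestry" %in% names(reference))
      reference$ancestry[ri] else NA_character_,
    local_effect = le, local_se = lse, local_ci_low = l_lo,
    local_ci_high = l_hi,
    ref_effect = re, ref_se = rse, ref_ci_low = r_lo, ref_ci_high = r_hi,
    overlap = overlap, direction_class = direction_class,
    stringsAsFactors = FALSE
  )
  for (fc in .flag_cols) rec[[fc]] <- FALSE
  attr(rec, "level") <- level
  attr(rec, "unmatched") <- list(
    local_only = setdiff(local$probe_id, shared),
    reference_only = setdiff(reference$probe_id, shared)
  )
  class(rec) <- c("comparison_records", "data.frame")
  rec
}

#' Summarize replication classes for one trait comparison
#'
#' Counts and fractions over the overlap / consistent-nonoverlap / opposite
#' partition, plus (when at least three records are available) the
#' cross-cohort effect-size regression. Displayed percentages are rounded to
#' integers, mirroring conventional reporting; the exact fractions are
#' retained.
#'
#' @param records a [compare_associations()] result sharing one
#'   trait/ancestry.
#' @param y_axis axis convention forwarded to [effect_size_regression()].
#' @return object of class `trait_concordance`: counts, exact fractions,
#'   rounded percentages, and the slope statistics.
#' @export
summarize_trait <- function(records, y_axis = c("reference", "local")) {
  if (nrow(records) == 0L) stop("no comparison records to summarize",
                                call. = FALSE)
  y_axis <- match.arg(y_axis)
  n <- nrow(records)
  n_overlap <- sum(records$direction_class == "overlap")
  n_consistent <- sum(records$direction_class == "consistent_nonoverlap")
  n_opposite <- sum(records$direction_class == "opposite")
  stopifnot(n_overlap + n_consistent + n_opposite == n)
  fr <- c(overlap = n_overlap, consistent = n_consistent,
          opposite = n_opposite) / n
  slope <- list(slope = NA_real_, se = NA_real_, p = NA_real_,
                r_squared = NA_real_, n = n)
  if (n >= 3) {
    x <- records$local_effect
    y <- records$ref_effect
    if (y_axis == "local") { tmp <- x; x <- y; y <- tmp }
    slope <- .ols_slope(x, y)
  }
  structure(list(
    trait = records$trait[1], ancestry = records$ancestry[1],
    n_tests = n, n_overlap = n_overlap, n_consistent = n_consistent,
    n_opposite = n_opposite, fractions = fr,
    percent = round(100 * fr),
    slope = slope$slope, slope_se = slope$se, slope_p = slope$p,
    r_squared = slope$r_squared, y_axis = y_axis
  ), class = "trait_concordance")
}

#' @export
print.trait_concordance <- function(x, ...) {
  cat(sprintf(
    "<trait_concordance> %s (%s): %d tests; %d%% overlap, %d%% consistent, %d%% opposite; slope %.3g\n",
    x$trait, x$ancestry, x$n_tests, x$percent[["overlap"]],
    x$percent[["consistent"]], x$percent[["opposite"]], x$slope))
  invisible(x)
}

.ols_slope <- function(x, y, null_slope = 0) {
  if (length(x) < 3L || var(x) == 0) {
    return(list(slope = NA_real_, se = NA_real_, p = NA_real_,
                r_squared = NA_real_, n = length(x)))
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact lines are legitimate input
  est <- coef(sm)["x", ]
  tval <- (est[["Estimate"]] - null_slope) / est[["Std. Error"]]
  list(slope = est[["Estimate"]], se = est[["Std. Error"]],
       p = 2 * pt(-abs(tval), fit$df.residual),
       r_squared = sm$r.squared, n = length(x))
}

#' Regress one cohort's effect sizes on the other's
#'
#' Ordinary least squares with intercept. The default places the reference
#' effects on the y axis and the local effects on the x axis, so a slope
#' below one reads "local effects larger than reference effects".
#'
#' @param local,reference `ewas_summary` tables joined on `probe_id`.
#' @param y_axis which cohort supplies the y values.
#' @param null_slope the slope hypothesis tested by the reported p
#'   (default 0; set 1 to test departure from the line of equality).
#' @return list with `slope`, `se`, `p`, `r_squared`, `n`, `y_axis`,
#'   `null_slope`.
#' @export
effect_size_regression <- function(local, reference,
                                   y_axis = c("reference", "local"),
                                   null_slope = 0) {
  y_axis <- match.arg(y_axis)
  shared <- intersect(local$probe_id, reference$probe_id)
  if (length(shared) < 3L) {
    stop("need at least 3 shared probes for effect-size regression",
         call. = FALSE)
  }
  le <- local$effect[match(shared, local$probe_id)]
  re <- reference$effect[match(shared, reference$probe_id)]
  x <- if (y_axis == "reference") le else re
  y <- if (y_axis == "reference") re else le
  out <- .ols_slope(x, y, null_slope)
  out$y_axis <- y_axis
  out$null_slope <- null_slope
  out
}

#' Assemble a genetic-context annotation set
#'
#' @param mqtl data.frame with columns `probe_id`, `snp_id`, `type`
#'   (`"cis"`/`"trans"`), `z`.
#' @param maf data.frame with columns `snp_id`, `population`, `maf` in
#'   `[0, 0.5]`.
#' @param flags data.frame with columns `probe_id`, `flag` (values among
#'   `"polymorphic"`, `"cross_reactive"`).
#' @return object of class `genetic_annotation`.
#' @export
genetic_annotation <- function(mqtl = NULL, maf = NULL, flags = NULL) {
  empty <- function(...) {
    d <- list(...)
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  mqtl <- mqtl %||% empty(probe_id = character(), snp_id = character(),
                          type = character(), z = numeric())
  maf <- maf %||% empty(snp_id = character(), population = character(),
                        maf = numeric())
  flags <- flags %||% empty(probe_id = character(), flag = character())
  if (nrow(maf) && (any(maf$maf < 0) || any(maf$maf > 0.5))) {
    stop("minor allele frequencies must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(mqtl = mqtl, maf = maf, flags = flags),
            class = "genetic_annotation")
}

#' Annotate comparison records with genetic context
#'
#' Sets `has_cis_mqtl` / `has_trans_mqtl` from the mQTL table,
#' `maf_discordant` when any linked SNP's minor allele frequency differs by
#' at least `maf_gap_threshold` between the two named populations, and the
#' polymorphic-site / cross-reactive probe flags from the flag list. A
#' summary of flagged-among-opposite counts is attached as an attribute.
#'
#' @param records a [compare_associations()] result.
#' @param annotation a [genetic_annotation()].
#' @param maf_gap_threshold minimum absolute MAF difference.
#' @param populations character pair naming the populations compared.
#' @return `records` with flags filled in; attribute `flag_summary` holds
#'   counts among `opposite`-class records.
#' @export
annotate_genetic_context <- function(records, annotation,
                                     maf_gap_threshold = 0.10,
                                     populations = c("AFR", "EUR")) {
  stopifnot(inherits(annotation, "genetic_annotation"),
            length(populations) == 2L)
  maf <- annotation$maf
  if (nrow(maf)) {
    missing_pop <- setdiff(populations, unique(maf$population))
    if (length(missing_pop)) {
      stop(sprintf("population(s) absent from MAF table: %s",
                   paste(missing_pop, collapse = ", ")), call. = FALSE)
    }
  } else if (nrow(annotation$mqtl)) {
    # mQTLs without MAF rows simply cannot be MAF-discordant
    maf <- annotation$maf
  }

  mq <- annotation$mqtl
  records$has_cis_mqtl <- records$probe_id %in%
    mq$probe_id[mq$type == "cis"]
  records$has_trans_mqtl <- records$probe_id %in%
    mq$probe_id[mq$type == "trans"]

  # per-SNP MAF gap between the two populations
  if (nrow(maf)) {
    m1 <- maf[maf$population == populations[1], ]
    m2 <- maf[maf$population == populations[2], ]
    gap <- abs(m1$maf[match(mq$snp_id, m1$snp_id)] -
               m2$maf[match(mq$snp_id, m2$snp_id)])
    discordant_snps <- mq$snp_id[!is.na(gap) & gap >= maf_gap_threshold]
    records$maf_discordant <- records$probe_id %in%
      mq$probe_id[mq$snp_id %in% discordant_snps]
  } else {
    records$maf_discordant <- FALSE
  }

  fl <- annotation$flags
  records$polymorphic_probe <- records$probe_id %in%
    fl$probe_id[fl$flag == "polymorphic"]
  records$cross_reactive <- records$probe_id %in%
    fl$probe_id[fl$flag == "cross_reactive"]

  opp <- records[records$direction_class == "opposite", , drop = FALSE]
  attr(records, "flag_summary") <- c(
    n_opposite = nrow(opp),
    vapply(.flag_cols, function(fc) sum(opp[[fc]]), integer(1))
  )
  records
}

#' Per-probe variance explained by the exposure
#'
#' For each requested probe, fits the full methylation-outcome model and
#' reports (i) the exposure's LMG relative-importance share of methylation
#' variance (x100), (ii) the full-model R-squared (x100), and (iii) the
#' chi-square p comparing nested models with and without the exposure.
#' Covariate blocks (cell fractions, surrogate variables) are grouped as
#' single predictors for the LMG enumeration.
#'
#' @param meth methylation beta matrix.
#' @param pheno phenotype table.
#' @param spec a [model_spec()] (methylation-outcome orientation).
#' @param probe_set character vector of probes to decompose.
#' @param surrogates optional [estimate_surrogates()] result.
#' @return data.frame with `probe_id`, `pct_var_exposure`, `pct_var_total`,
#'   `chi2_p`.
#' @export
variance_explained_column <- function(meth, pheno, spec, probe_set,
                                      surrogates = NULL) {
  stopifnot(inherits(spec, "model_spec"),
            spec$orientation == "methylation_outcome")
  missing <- setdiff(probe_set, rownames(meth))
  if (length(missing)) {
    stop(sprintf("probe(s) absent from matrix: %s", missing[1L]),
         call. = FALSE)
  }
  exp_info <- .code_exposure(pheno, spec)
  C <- .covariate_matrix(pheno, spec)
  SV <- if (!is.null(surrogates)) surrogates$sv else NULL
  keep <- exp_info$keep & complete.cases(cbind(exp_info$x, C, SV))
  x <- exp_info$x[keep]

  blocks <- list(exposure = matrix(x, dimnames = list(NULL, spec$trait)))
  for (nm in spec$covariates) {
    cm <- .covariate_matrix(pheno, structure(list(covariates = nm,
                                                  trait = spec$trait),
                                             class = "model_spec"))
    blocks[[nm]] <- cm[keep, , drop = FALSE]
  }
  if (!is.null(SV) && ncol(SV) > 0) {
    blocks[["surrogates"]] <- SV[keep, , drop = FALSE]
  }
  design <- do.call(cbind, blocks)
  groups <- list()
  start <- 1L
  for (nm in names(blocks)) {
    k <- ncol(blocks[[nm]])
    groups[[nm]] <- seq(start, length.out = k)
    start <- start + k
  }
  reduced <- design[, -groups$exposure, drop = FALSE]

  out <- lapply(probe_set, function(pid) {
    y <- meth[pid, keep]
    dec <- lmg_shares(y, design, groups = groups)
    lrt <- nested_lrt(y, cbind(1, design), cbind(1, reduced))
    data.frame(probe_id = pid,
               pct_var_exposure = 100 * dec$shares[["exposure"]],
               pct_var_total = 100 * dec$total_r2,
               chi2_p = lrt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
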