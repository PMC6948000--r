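# Per-CpG linear association models on beta values, in either orientation,
# with covariates and surrogate variables as fixed effects.

#' Specify an EWAS model
#'
#' @param trait phenotype of interest (a `PhenotypeTable` column).
#' @param orientation `"methylation_outcome"` (methylation ~ trait + ...) or
#'   `"trait_outcome"` (trait ~ methylation + ...). The latter requires a
#'   continuous trait.
#' @param covariates ordered character vector of covariate names. The
#'   pseudo-covariate `"cell_counts"` expands to all but one of the six cell
#'   fraction columns (the last is dropped because fractions sum to one);
#'   `"smoking"` as a covariate is coded ever vs never; `"education"` expands
#'   to factor dummies.
#' @param exposure_coding `"continuous"`, `"current_vs_never"` or
#'   `"ever_vs_never"`; the contrast codings subset/dichotomise a categorical
#'   exposure such as smoking status.
#' @param n_surrogates `"auto"` (permutation-selected), a fixed count, or 0.
#' @param transform trait transform: `"identity"` or `"log"` (e.g. log-CRP).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(trait,
                       orientation = c("methylation_outcome", "trait_outcome"),
                       covariates = character(),
                       exposure_coding = c("continuous", "current_vs_never",
                                           "ever_vs_never"),
                       n_surrogates = "auto",
                       transform = c("identity", "log")) {
  orientation <- match.arg(orientation)
  exposure_coding <- match.arg(exposure_coding)
  transform <- match.arg(transform)
  if (orientation == "trait_outcome" && exposure_coding != "continuous") {
    stop("trait_outcome orientation requires a continuous trait", call. = FALSE)
  }
  structure(list(trait = trait, orientation = orientation,
                 covariates = covariates, exposure_coding = exposure_coding,
                 n_surrogates = n_surrogates, transform = transform),
            class = "model_spec")
}

# exposure vector under the configured coding; returns values + kept rows
.code_exposure <- function(pheno, spec) {
  raw <- pheno[[spec$trait]]
  if (is.null(raw)) {
    stop(sprintf("trait `%s` not found in phenotype table", spec$trait),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(pheno))
  if (spec$exposure_coding == "continuous") {
    if (!is.numeric(raw)) {
      stop(sprintf("continuous coding requires numeric trait `%s`",
                   spec$trait), call. = FALSE)
    }
    x <- if (spec$transform == "log") log(raw) else raw
  } else if (spec$exposure_coding == "current_vs_never") {
    keep <- raw %in% c("current", "never")
    x <- as.numeric(raw == "current")
  } else {
    x <- as.numeric(raw != "never")
  }
  list(x = x, keep = keep)
}

# covariate design matrix (no intercept column)
.covariate_matrix <- function(pheno, spec) {
  cols <- list()
  for (nm in spec$covariates) {
    if (nm == "cell_counts") {
      cf <- as.matrix(pheno[, .cell_cols[-length(.cell_cols)], drop = FALSE])
      cols[[nm]] <- cf
    } else if (nm == "smoking") {
      cols[[nm]] <- matrix(as.numeric(pheno$smoking != "never"),
                           dimnames = list(NULL, "smoking_ever"))
    } else if (nm == "education") {
      mm <- model.matrix(~ education, data = pheno)[, -1, drop = FALSE]
      cols[[nm]] <- mm
    } else {
      v <- pheno[[nm]]
      if (is.null(v)) stop(sprintf("covariate `%s` not found", nm),
                           call. = FALSE)
      if (all(is.na(v))) stop(sprintf("covariate `%s` is all missing", nm),
                              call. = FALSE)
      cols[[nm]] <- matrix(as.numeric(v), dimnames = list(NULL, nm))
    }
  }
  if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow(pheno), 0)
}

#' Estimate surrogate variables from methylation residuals
#'
#' Two-step procedure: each probe is regressed on the exposure and
#' covariates, the row-centred residual matrix is decomposed by SVD, and the
#' number of surrogates k is chosen by comparing each leading singular
#' value's variance share against a permutation null in which every probe's
#' residuals are independently permuted (Buja-Eyuboglu style), stopping at
#' the first non-significant component. The first k right-singular vectors
#' (orthonormal by construction) are returned.
#'
#' @param meth methylation beta matrix (probes x samples).
#' @param pheno phenotype table aligned with `meth` columns.
#' @param spec a [model_spec()]; a fixed `n_surrogates` skips the
#'   permutation test.
#' @param n_perm permutations for the null (when `n_surrogates = "auto"`).
#' @param seed permutation seed (mandatory for reproducibility).
#' @param alpha per-component significance level for retention.
#' @param max_k cap on the number of components tested.
#' @return object of class `surrogate_set`: `sv` (samples x k orthonormal
#'   matrix), `k`, `method`, `n_perm`, `seed`.
#' @export
estimate_surrogates <- function(meth, pheno, spec, n_perm = 100, seed = 1L,
                                alpha = 0.05, max_k = 10L) {
  stopifnot(is.matrix(meth), inherits(spec, "model_spec"))
  exp_info <- .code_exposure(pheno, spec)
  C <- .covariate_matrix(pheno, spec)
  keep <- exp_info$keep & complete.cases(cbind(exp_info$x, C))
  Xk <- cbind(`(Intercept)` = 1, exposure = exp_info$x[keep],
              C[keep, , drop = FALSE])
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    bad <- colnames(Xk)[qrX$pivot[seq(qrX$rank + 1, ncol(Xk))]]
    stop(sprintf("design matrix is collinear in column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n <- sum(keep)
  if (n <= ncol(Xk) + 2) stop("too few samples for the design", call. = FALSE)

  M <- meth[, keep, drop = FALSE]
  # residualize each probe on the design, then row-centre
  R <- t(qr.resid(qrX, t(M)))
  R <- R - rowMeans(R)

  fixed_k <- !identical(spec$n_surrogates, "auto")
  k_cap <- as.integer(min(max_k, n - ncol(Xk) - 1L, nrow(R)))
  sv <- svd(R, nu = 0, nv = k_cap)
  shares <- sv$d^2 / sum(sv$d^2)

  if (fixed_k) {
    k <- as.integer(spec$n_surrogates)
    if (k > k_cap) stop("requested more surrogates than available",
                        call. = FALSE)
  } else {
    set.seed(seed)
    exceed <- integer(k_cap)
    for (b in seq_len(n_perm)) {
      Rp <- R
      for (i in seq_len(nrow(Rp))) Rp[i, ] <- Rp[i, sample.int(ncol(Rp))]
      Rp <- Rp - rowMeans(Rp)
      dp <- svd(Rp, nu = 0, nv = 0)$d
      sp <- dp^2 / sum(dp^2)
      exceed <- exceed + (sp[seq_len(k_cap)] >= shares[seq_len(k_cap)])
    }
    pvals <- (exceed + 1) / (n_perm + 1)
    k <- 0L
    for (i in seq_len(k_cap)) {
      if (pvals[i] <= alpha) k <- i else break
    }
  }

  svs <- if (k > 0) sv$v[, seq_len(k), drop = FALSE] else
    matrix(numeric(0), n, 0)
  if (k > 0) svs <- qr.Q(qr(svs))  # re-orthonormalize defensively
  rownames(svs) <- colnames(M)
  structure(list(sv = svs, k = k,
                 method = if (fixed_k) "fixed" else "be-permutation",
                 n_perm = if (fixed_k) NA_integer_ else n_perm, seed = seed,
                 variance_shares = shares[seq_len(k_cap)]),
            class = "surrogate_set")
}

#' @export
print.surrogate_set <- function(x, ...) {
  cat(sprintf("<surrogate_set> k = %d (%s)\n", x$k, x$method))
  invisible(x)
}

#' Fit per-CpG linear association models
#'
#' Ordinary least squares per probe with the exposure, covariates and
#' surrogate variables as fixed effects. In `methylation_outcome`
#' orientation each probe's beta values are the outcome; in `trait_outcome`
#' the (transformed) trait is the outcome and the probe enters as a
#' predictor. Two-sided p-values come from the t statistic on residual
#' degrees of freedom; confidence bounds use the normal multiplier by
#' default (a `t` switch is provided) for consistency with
#' normal-approximation reference intervals.
#'
#' @param meth methylation beta matrix (probes x samples).
#' @param pheno phenotype table; rows aligned with `meth` columns.
#' @param spec a [model_spec()].
#' @param surrogates optional [estimate_surrogates()] result.
#' @param level confidence level for the interval bounds.
#' @param ci_method `"normal"` (default) or `"t"` quantile for the CI.
#' @param cohort,ancestry metadata labels stamped on the output.
#' @return an `ewas_summary` table (one row per retained probe). Probes with
#'   zero variance are dropped with a warning; degenerate (perfect) fits get
#'   `se = 0`, p at the smallest representable double, and are listed in the
#'   `degenerate_probes` attribute.
#' @export
fit_ewas <- function(meth, pheno, spec, surrogates = NULL, level = 0.95,
                     ci_method = c("normal", "t"), cohort = "local",
                     ancestry = "NA") {
  stopifnot(is.matrix(meth), inherits(spec, "model_spec"))
  ci_method <- match.arg(ci_method)
  exp_info <- .code_exposure(pheno, spec)
  C <- .covariate_matrix(pheno, spec)
  SV <- if (!is.null(surrogates)) surrogates$sv else
    matrix(numeric(0), nrow(pheno), 0)
  if (ncol(SV) > 0 && nrow(SV) != nrow(pheno)) {
    # surrogate rows were estimated on a sample subset; align by name
    SV <- SV[match(pheno$sample_id, rownames(SV)), , drop = FALSE]
  }
  keep <- exp_info$keep & complete.cases(cbind(exp_info$x, C, SV))
  x <- exp_info$x[keep]
  Cov <- cbind(C[keep, , drop = FALSE],
               if (ncol(SV)) SV[keep, , drop = FALSE])
  if (!is.null(Cov) && ncol(SV)) {
    colnames(Cov)[(ncol(Cov) - ncol(SV) + 1):ncol(Cov)] <-
      paste0("sv", seq_len(ncol(SV)))
  }
  M <- meth[, keep, drop = FALSE]
  n <- sum(keep)

  zero_var <- apply(M, 1, function(r) var(r) == 0)
  if (any(zero_var)) {
    warning(sprintf("dropping %d zero-variance probe(s)", sum(zero_var)))
    M <- M[!zero_var, , drop = FALSE]
  }
  if (nrow(M) == 0L) stop("no probes left to fit", call. = FALSE)

  model_id <- paste0(
    if (spec$orientation == "methylation_outcome") "meth~" else
      paste0(spec$trait, "~meth+"),
    spec$trait, if (length(spec$covariates))
      paste0("+", paste(spec$covariates, collapse = "+")) else "",
    if (ncol(SV)) sprintf("+%dsv", ncol(SV)) else "")

  if (spec$orientation == "methylation_outcome") {
    X <- cbind(`(Intercept)` = 1, exposure = x, Cov)
    p_par <- ncol(X)
    if (n < p_par + 2) stop("too few complete cases for the design",
                            call. = FALSE)
    qrX <- qr(X)
    if (qrX$rank < p_par) {
      bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p_par)]]
      stop(sprintf("design matrix is collinear in column(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    Y <- t(M)
    cf <- qr.coef(qrX, Y)
    res <- qr.resid(qrX, Y)
    df <- n - p_par
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(chol(crossprod(X)))
    eff <- cf["exposure", ]
    se <- sqrt(pmax(sigma2, 0) * xtx_inv[2, 2])
  } else {
    y <- if (spec$transform == "log") log(pheno[[spec$trait]][keep]) else
      pheno[[spec$trait]][keep]
    p_par <- 2L + if (is.null(Cov)) 0L else ncol(Cov)
    if (n < p_par + 2) stop("too few complete cases for the design",
                            call. = FALSE)
    df <- n - p_par
    fit_one <- function(mrow) {
      X <- cbind(1, mrow, Cov)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) return(c(NA_real_, NA_real_))
      cf <- qr.coef(qrX, y)
      rss <- sum(qr.resid(qrX, y)^2)
      xtx_inv <- chol2inv(chol(crossprod(X)))
      c(cf[2], sqrt((rss / df) * xtx_inv[2, 2]))
    }
    est <- apply(M, 1, fit_one)
    eff <- est[1, ]
    se <- est[2, ]
  }

  degenerate <- is.finite(se) & se < sqrt(.Machine$double.eps) * (abs(eff) + 1)
  se[degenerate] <- 0
  tstat <- ifelse(se > 0, eff / se, ifelse(eff == 0, 0, Inf))
  p <- 2 * pt(-abs(tstat), df)
  p[degenerate] <- .Machine$double.xmin
  mult <- if (ci_method == "normal") ci_multiplier(level) else
    qt(1 - (1 - level) / 2, df)
  out <- summary_table(rownames(M), eff, se, trait = spec$trait,
                       cohort = cohort, ancestry = ancestry, n = n,
                       level = level, p = .p_floor(p), model_id = model_id)
  out$ci_low <- eff - mult * se
  out$ci_high <- eff + mult * se
  attr(out, "degenerate_probes") <- rownames(M)[which(degenerate)]
  attr(out, "df") <- df
  out
}

#' Genome-wide significant subset of a summary table
#'
#' @param table an `ewas_summary` table.
#' @param threshold per-test significance threshold; the conventional
#'   EPIC-array genome-wide value is `9.4e-8` (0.05 / 530,639 independent
#'   tests, see [bonferroni_threshold()]).
#' @return rows with `p < threshold`, sorted by ascending p with ties broken
#'   lexicographically by `probe_id`.
#' @export
genomewide_hits <- function(table, threshold = 9.4e-8) {
  if (nrow(table) == 0L) stop("summary table is empty", call. = FALSE)
  hits <- table[table$p < threshold, , drop = FALSE]
  hits[order(hits$p, hits$probe_id), , drop = FALSE]
}
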