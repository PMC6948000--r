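# Variance decomposition (LMG relative importance), nested-model tests,
# incremental adjusted R-squared, Bonferroni thresholds and two-group power.

.r2_of <- function(y, X) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  fit <- lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / tss
}

#' LMG relative-importance shares
#'
#' Decomposes the R-squared of a linear model over its predictors (or
#' predictor groups): a predictor's share is its average incremental
#' R-squared over all orderings of model entry, computed by exact
#' enumeration via the subset-weighting identity. Shares are nonnegative
#' for any design and sum exactly to the full-model R-squared.
#'
#' @param outcome numeric outcome vector.
#' @param predictors numeric matrix or data.frame of predictor columns
#'   (no intercept; one is added internally).
#' @param groups optional named list mapping group names to column indices;
#'   each group enters the orderings as one unit (useful to keep cell
#'   fractions or surrogate variables together). Defaults to one group per
#'   column. At most 12 groups (factorial enumeration bound).
#' @return object of class `variance_decomposition`: named `shares`,
#'   `total_r2`, `n`, `groups`.
#' @export
lmg_shares <- function(outcome, predictors, groups = NULL) {
  X <- as.matrix(predictors)
  storage.mode(X) <- "double"
  y <- as.numeric(outcome)
  if (length(y) != nrow(X)) stop("outcome/predictor length mismatch",
                                 call. = FALSE)
  if (is.null(groups)) {
    nms <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
    groups <- setNames(as.list(seq_len(ncol(X))), nms)
  }
  p <- length(groups)
  if (p < 1L) stop("need at least one predictor", call. = FALSE)
  if (p > 12L) {
    stop("more than 12 predictor groups: group related columns to keep the factorial enumeration tractable",
         call. = FALSE)
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("design matrix is rank deficient", call. = FALSE)
  }

  # R-squared for every subset of groups, indexed by bitmask
  n_masks <- bitwShiftL(1L, p)
  r2 <- numeric(n_masks)
  for (mask in seq_len(n_masks - 1L)) {
    cols <- unlist(groups[which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)])
    r2[mask + 1L] <- .r2_of(y, X[, cols, drop = FALSE])
  }

  popcount <- vapply(seq_len(n_masks) - 1L, function(m) {
    s <- 0L
    while (m > 0L) { s <- s + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }
    s
  }, integer(1))
  w <- factorial(seq_len(p) - 1L) * factorial(p - seq_len(p)) / factorial(p)

  shares <- numeric(p)
  for (g in seq_len(p)) {
    gbit <- bitwShiftL(1L, g - 1L)
    without_g <- which(bitwAnd(seq_len(n_masks) - 1L, gbit) == 0L)
    masks <- without_g - 1L
    shares[g] <- sum(w[popcount[without_g] + 1L] *
                     (r2[masks + gbit + 1L] - r2[masks + 1L]))
  }
  names(shares) <- names(groups)
  structure(list(shares = shares, total_r2 = r2[n_masks], n = length(y),
                 groups = groups),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("<variance_decomposition> total R2 = %.4f\n", x$total_r2))
  print(round(x$shares, 4))
  invisible(x)
}

#' Nested-model chi-square (likelihood ratio) test
#'
#' Compares two nested ordinary-least-squares models via Gaussian
#' log-likelihoods derived from residual sums of squares:
#' `chi2 = n * log(RSS_reduced / RSS_full)` on `df` = column-count
#' difference.
#'
#' @param outcome numeric outcome.
#' @param full_design,reduced_design design matrices (including any
#'   intercept column); every reduced column must appear in the full design.
#' @return list with `chi2`, `df`, `p`.
#' @export
nested_lrt <- function(outcome, full_design, reduced_design) {
  Xf <- as.matrix(full_design)
  Xr <- as.matrix(reduced_design)
  y <- as.numeric(outcome)
  n <- length(y)
  # nesting check: each reduced column must equal some full column
  for (j in seq_len(ncol(Xr))) {
    if (!any(apply(Xf, 2, function(cf) isTRUE(all.equal(cf, Xr[, j],
                                                        check.attributes = FALSE))))) {
      stop("designs are not nested: a reduced column is absent from the full design",
           call. = FALSE)
    }
  }
  rss_f <- sum(lm.fit(Xf, y)$residuals^2)
  rss_r <- sum(lm.fit(Xr, y)$residuals^2)
  df <- ncol(Xf) - ncol(Xr)
  if (df == 0L) return(list(chi2 = 0, df = 0L, p = 1))
  tss <- sum((y - mean(y))^2)
  if (rss_r <= 1e-12 * max(tss, .Machine$double.xmin)) {
    # reduced model already fits to numerical precision
    return(list(chi2 = 0, df = df, p = 1))
  }
  eps <- .Machine$double.xmin
  chi2 <- max(n * (log(max(rss_r, eps)) - log(max(rss_f, eps))), 0)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Incremental adjusted R-squared of a predictor block
#'
#' Adjusted R-squared (`1 - (1 - R2) (n - 1) / (n - k - 1)`) before and
#' after adding a block of predictors, with the block's nested-model
#' chi-square p.
#'
#' @param outcome numeric outcome.
#' @param base_design matrix of baseline predictors (no intercept column).
#' @param added_block matrix of predictors to add (may have zero columns).
#' @return list with `adj_r2_before`, `adj_r2_after`, `delta`, `p`.
#' @export
incremental_adj_r2 <- function(outcome, base_design, added_block) {
  y <- as.numeric(outcome)
  Xb <- as.matrix(base_design)
  Xa <- as.matrix(added_block)
  n <- length(y)
  k_total <- ncol(Xb) + ncol(Xa)
  if (n <= k_total + 1L) stop("too few observations for the combined design",
                              call. = FALSE)
  full <- cbind(Xb, Xa)
  if (qr(cbind(1, full))$rank < k_total + 1L) {
    stop("combined design is rank deficient", call. = FALSE)
  }
  adj <- function(r2, k) 1 - (1 - r2) * (n - 1) / (n - k - 1)
  before <- adj(.r2_of(y, Xb), ncol(Xb))
  after <- adj(.r2_of(y, full), k_total)
  p <- if (ncol(Xa) == 0L) 1 else
    nested_lrt(y, cbind(1, full), cbind(1, Xb))$p
  list(adj_r2_before = before, adj_r2_after = after, delta = after - before,
       p = p)
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha_family family-wise alpha.
#' @param m_tests number of independent tests.
#' @return the per-test threshold `alpha_family / m_tests`.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, m_tests = 1L) {
  if (m_tests < 1) stop("m_tests must be >= 1", call. = FALSE)
  alpha_family / m_tests
}

#' Display helper: threshold at two significant figures
#' @param threshold a per-test threshold.
#' @return the value rounded to two significant figures.
#' @export
format_threshold <- function(threshold) signif(threshold, 2)

#' Power specification for a two-group methylation difference
#'
#' @param alpha_family family-wise alpha.
#' @param m_tests number of independent tests.
#' @param delta detectable beta-value difference between groups.
#' @param n total sample size.
#' @param group_split proportion of samples in group 1, in (0, 1).
#' @param probe_sd beta-scale SD, scalar or per-probe vector.
#' @return object of class `power_spec`.
#' @export
power_spec <- function(alpha_family = 0.05, m_tests = 530639L, delta = 0.05,
                       n = 120L, group_split = 0.5, probe_sd = 0.05) {
  for (f in c("alpha_family", "delta", "group_split")) .check_finite(get(f), f)
  if (group_split <= 0 || group_split >= 1) {
    stop("group_split must lie in (0, 1)", call. = FALSE)
  }
  if (any(probe_sd < 0)) stop("probe_sd must be nonnegative", call. = FALSE)
  structure(list(alpha_family = alpha_family, m_tests = as.integer(m_tests),
                 delta = delta, n = n, group_split = group_split,
                 probe_sd = probe_sd),
            class = "power_spec")
}

#' Two-group normal-approximation power per probe
#'
#' Power to detect a mean beta difference `delta` between two groups of
#' sizes `n * split` and `n * (1 - split)` at the per-test alpha:
#' `power = Phi(-z + delta/se) + Phi(-z - delta/se)` with
#' `se = sd * sqrt(1/n1 + 1/n2)` and `z` the two-sided normal quantile.
#'
#' @param spec a [power_spec()].
#' @param per_test_alpha per-test alpha; defaults to the Bonferroni
#'   threshold implied by the spec.
#' @param target power level for the reported fraction of probes.
#' @return list with per-probe `power`, `fraction_at_target`, a `degenerate`
#'   logical vector flagging zero-SD probes (power reported as 1), and the
#'   `per_test_alpha` used.
#' @export
probe_power <- function(spec, per_test_alpha = NULL, target = 0.80) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(per_test_alpha)) {
    per_test_alpha <- bonferroni_threshold(spec$alpha_family, spec$m_tests)
  }
  n1 <- spec$n * spec$group_split
  n2 <- spec$n * (1 - spec$group_split)
  z <- qnorm(1 - per_test_alpha / 2)
  degenerate <- spec$probe_sd == 0
  se_diff <- spec$probe_sd * sqrt(1 / n1 + 1 / n2)
  ncp <- ifelse(degenerate, Inf, spec$delta / se_diff)
  pow <- pnorm(-z + ncp) + pnorm(-z - ncp)
  pow[degenerate] <- 1
  list(power = pow, fraction_at_target = mean(pow >= target),
       degenerate = degenerate, per_test_alpha = per_test_alpha,
       target = target)
}
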