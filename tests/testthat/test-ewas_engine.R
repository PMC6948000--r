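toy_pheno <- function(x, ...) {
  data.frame(sample_id = sprintf("S%03d", seq_along(x)), x = x, ...)
}

test_that("a perfect linear fit is handled as degenerate", {
  meth <- matrix(c(1, 2, 3, 4, 5) / 10, 1,
                 dimnames = list("cg1", sprintf("S%03d", 1:5)))
  pheno <- toy_pheno(0:4)
  st <- fit_ewas(meth, pheno, model_spec("x"))
  expect_equal(st$effect, 0.1, tolerance = 1e-12)
  expect_lt(st$se, 1e-10)
  expect_identical(attr(st, "degenerate_probes"), "cg1")
  expect_lte(st$p, 1e-300)
  expect_gt(st$p, 0)
})

test_that("rescaling the trait rescales effects but not p-values", {
  set.seed(21)
  n <- 40
  meth <- matrix(runif(3 * n, 0.2, 0.8), 3,
                 dimnames = list(paste0("cg", 1:3), sprintf("S%03d", 1:n)))
  ph1 <- toy_pheno(rnorm(n), age = rnorm(n, 60, 8))
  ph2 <- ph1
  ph2$x <- ph2$x * 10
  s1 <- fit_ewas(meth, ph1, model_spec("x", covariates = "age"))
  s2 <- fit_ewas(meth, ph2, model_spec("x", covariates = "age"))
  expect_equal(s2$effect, s1$effect / 10, tolerance = 1e-12)
  expect_equal(s2$p, s1$p, tolerance = 1e-10)
})

test_that("effects and SEs match the normal-equations oracle to 10 decimals", {
  set.seed(31)
  n <- 20
  C <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("c1", "c2", "c3")))
  x <- rnorm(n)
  meth <- matrix(runif(5 * n, 0.1, 0.9), 5,
                 dimnames = list(paste0("cg", 1:5), sprintf("S%03d", 1:n)))
  pheno <- data.frame(sample_id = sprintf("S%03d", 1:n), x = x, C)
  st <- fit_ewas(meth, pheno,
                 model_spec("x", covariates = c("c1", "c2", "c3")))
  X <- cbind(1, x, C)
  for (i in 1:5) {
    or <- ols_oracle(meth[i, ], X, which = 2L)
    expect_equal(st$effect[i], unname(or["effect"]), tolerance = 1e-10)
    expect_equal(st$se[i], unname(or["se"]), tolerance = 1e-10)
  }
  # trait_outcome orientation against the same oracle, probe as predictor
  st2 <- fit_ewas(meth, pheno,
                  model_spec("x", orientation = "trait_outcome",
                             covariates = c("c1", "c2")))
  for (i in 1:5) {
    Xi <- cbind(1, meth[i, ], C[, 1:2])
    or <- ols_oracle(x, Xi, which = 2L)
    expect_equal(st2$effect[i], unname(or["effect"]), tolerance = 1e-10)
    expect_equal(st2$se[i], unname(or["se"]), tolerance = 1e-10)
  }
})

test_that("type-I error is nominal on a 2000-probe null simulation", {
  set.seed(41)
  n <- 100
  m <- 2000
  meth <- matrix(pmin(pmax(0.5 + rnorm(m * n, 0, 0.05), 0), 1), m,
                 dimnames = list(sprintf("cg%04d", 1:m),
                                 sprintf("S%03d", 1:n)))
  pheno <- toy_pheno(rnorm(n))
  st <- fit_ewas(meth, pheno, model_spec("x"))
  frac <- mean(st$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("95% CIs cover planted effects at the nominal rate", {
  set.seed(43)
  n <- 120
  m <- 1000
  x <- rnorm(n, 0, 2)
  b <- rnorm(m, 0, 0.002)
  meth <- 0.5 + outer(b, x) + matrix(rnorm(m * n, 0, 0.03), m)
  dimnames(meth) <- list(sprintf("cg%04d", 1:m), sprintf("S%03d", 1:n))
  st <- fit_ewas(meth, toy_pheno(x), model_spec("x"))
  covered <- mean(st$ci_low <= b & b <= st$ci_high)
  expect_lt(abs(covered - 0.95), 3 * sqrt(0.95 * 0.05 / m))
})

test_that("fixed surrogate counts return orthonormal columns", {
  cfg <- test_config(seed = 3L)
  ch <- generate_cohort(cfg)
  spec <- model_spec("alcohol", covariates = c("age", "bmi"),
                     n_surrogates = 3)
  sv <- estimate_surrogates(ch$meth, ch$pheno, spec, seed = 1L)
  expect_equal(sv$k, 3L)
  expect_equal(crossprod(sv$sv), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("permutation selection finds k = 0 under the null in >= 90% of runs", {
  ks <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 50
    m <- 200
    meth <- matrix(pmin(pmax(0.5 + rnorm(m * n, 0, 0.03), 0), 1), m,
                   dimnames = list(sprintf("cg%03d", 1:m),
                                   sprintf("S%03d", 1:n)))
    pheno <- data.frame(sample_id = colnames(meth), x = rnorm(n))
    estimate_surrogates(meth, pheno, model_spec("x"), n_perm = 50,
                        seed = s + 1000L)$k
  }, integer(1))
  expect_gte(mean(ks == 0L), 0.9)
})

test_that("a planted confounder is recovered by at least one surrogate", {
  cfg <- test_config(n_probes = 400, confounder_strength = 1.5,
                     include_cell_reference = FALSE, seed = 19L)
  ch <- generate_cohort(cfg)
  spec <- model_spec("alcohol", covariates = c("age", "bmi"))
  sv <- estimate_surrogates(ch$meth, ch$pheno, spec, n_perm = 50, seed = 2L)
  expect_gte(sv$k, 1L)
  expect_gt(stats::cancor(sv$sv, ch$hidden_factor)$cor[1], 0.9)
})

test_that("surrogates orthogonal to the exposure leave estimates unchanged", {
  set.seed(53)
  n <- 30
  x <- rnorm(n)
  b <- 0.004
  meth <- matrix(0.4 + b * x, 1, dimnames = list("cg1",
                                                 sprintf("S%03d", 1:n)))
  pheno <- toy_pheno(x)
  base <- fit_ewas(meth, pheno, model_spec("x"))
  raw <- rnorm(n)
  orth <- residuals(lm(raw ~ x))
  svs <- structure(list(sv = matrix(orth / sqrt(sum(orth^2)),
                                    dimnames = list(pheno$sample_id, "sv1")),
                        k = 1L, method = "fixed", seed = 1L),
                   class = "surrogate_set")
  with_sv <- fit_ewas(meth, pheno, model_spec("x"), surrogates = svs)
  expect_equal(with_sv$effect, base$effect, tolerance = 1e-8)
})

test_that("genomewide_hits filters and sorts as specified", {
  st <- summary_table(c("cgB", "cgA", "cgC"), c(1, 2, 3) * 1e-4,
                      rep(1e-5, 3), trait = "x", cohort = "local",
                      p = c(1e-7, 1e-9, 0.5))
  expect_equal(nrow(genomewide_hits(st, 1.0)), 3L)
  expect_equal(nrow(genomewide_hits(st, .Machine$double.xmin)), 0L)
  hits <- genomewide_hits(st, 9.4e-8)
  expect_identical(hits$probe_id, "cgA")
  tied <- summary_table(c("cgZ", "cgA"), c(1, 1) * 1e-4, rep(1e-5, 2),
                        trait = "x", cohort = "local", p = c(1e-9, 1e-9))
  expect_identical(genomewide_hits(tied, 1e-4)$probe_id, c("cgA", "cgZ"))
})

test_that("degenerate designs and codings are rejected informatively", {
  n <- 30
  pheno <- toy_pheno(rnorm(n), dup = NA)
  pheno$dup <- pheno$x
  meth <- matrix(runif(2 * n), 2, dimnames = list(c("cg1", "cg2"),
                                                  pheno$sample_id))
  expect_error(fit_ewas(meth, pheno, model_spec("x", covariates = "dup")),
               "collinear")
  expect_error(model_spec("smoking", orientation = "trait_outcome",
                          exposure_coding = "current_vs_never"),
               "continuous")
  meth0 <- meth
  meth0[1, ] <- 0.5
  expect_warning(fit_ewas(meth0, pheno, model_spec("x")), "zero-variance")
})

test_that("smoking contrast codings subset and dichotomise correctly", {
  cfg <- test_config(n_samples = 120, seed = 29L)
  ch <- generate_cohort(cfg)
  spec_cur <- model_spec("smoking", exposure_coding = "current_vs_never",
                         covariates = "age")
  st <- fit_ewas(ch$meth, ch$pheno, spec_cur)
  n_expected <- sum(ch$pheno$smoking %in% c("current", "never"))
  expect_true(all(st$n == n_expected))
  spec_ever <- model_spec("smoking", exposure_coding = "ever_vs_never",
                          covariates = "age")
  st2 <- fit_ewas(ch$meth, ch$pheno, spec_ever)
  expect_true(all(st2$n == nrow(ch$pheno)))
})
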