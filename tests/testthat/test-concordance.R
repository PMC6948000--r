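mk_summary <- function(ids, effect, se, trait = "alcohol",
                       cohort = "local", ancestry = "NA") {
  summary_table(ids, effect, se, trait = trait, cohort = cohort,
                ancestry = ancestry)
}

test_that("identical tables give 100% overlap", {
  st <- mk_summary(paste0("cg", 1:10), seq(-5, 4) * 1e-4, rep(1e-4, 10))
  rec <- compare_associations(st, st)
  expect_true(all(rec$overlap))
  expect_true(all(rec$direction_class == "overlap"))
})

test_that("hand-computed CI bounds drive the overlap decision", {
  local <- mk_summary("cg1", 1.0, 0.1)
  ref <- mk_summary("cg1", 2.0, 0.1, cohort = "reference")
  rec <- compare_associations(local, ref, level = 0.95)
  # beta +/- 1.959964 * se
  expect_equal(rec$local_ci_low, 0.804, tolerance = 1e-3)
  expect_equal(rec$local_ci_high, 1.196, tolerance = 1e-3)
  expect_equal(rec$ref_ci_low, 1.804, tolerance = 1e-3)
  expect_false(rec$overlap)
  expect_identical(rec$direction_class, "consistent_nonoverlap")

  opp <- compare_associations(mk_summary("cg1", 0.5, 0.01),
                              mk_summary("cg1", -0.5, 0.01,
                                         cohort = "reference"))
  expect_identical(opp$direction_class, "opposite")

  # zero effects count as consistent with either sign
  z <- compare_associations(mk_summary("cg1", 0, 1e-6),
                            mk_summary("cg1", -0.5, 0.01,
                                       cohort = "reference"))
  expect_identical(z$direction_class, "consistent_nonoverlap")
})

test_that("overlap is symmetric and unmatched probes are reported", {
  set.seed(61)
  a <- mk_summary(paste0("cg", 1:30), rnorm(30), runif(30, 0.05, 0.2))
  b <- mk_summary(paste0("cg", 11:40), rnorm(30), runif(30, 0.05, 0.2),
                  cohort = "reference")
  r1 <- compare_associations(a, b)
  r2 <- compare_associations(b, a)
  expect_equal(nrow(r1), 20L)
  expect_identical(r1$overlap, r2$overlap[match(r1$probe_id, r2$probe_id)])
  un <- attr(r1, "unmatched")
  expect_setequal(un$local_only, paste0("cg", 1:10))
  expect_setequal(un$reference_only, paste0("cg", 31:40))
})

test_that("widening a CI never breaks an existing overlap", {
  set.seed(67)
  ids <- paste0("cg", 1:50)
  a <- mk_summary(ids, rnorm(50), runif(50, 0.05, 0.3))
  b <- mk_summary(ids, rnorm(50), runif(50, 0.05, 0.3), cohort = "reference")
  r1 <- compare_associations(a, b)
  b_wide <- b
  b_wide$se <- b_wide$se * 3
  r2 <- compare_associations(a, b_wide)
  expect_true(all(r2$overlap[r1$overlap]))
})

test_that("the three direction classes always partition the records", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    ids <- paste0("cg", seq_len(n))
    a <- mk_summary(ids, rnorm(n), runif(n, 0.01, 0.5))
    b <- mk_summary(ids, rnorm(n), runif(n, 0.01, 0.5), cohort = "reference")
    rec <- compare_associations(a, b)
    s <- summarize_trait(rec)
    expect_equal(s$n_overlap + s$n_consistent + s$n_opposite, s$n_tests)
    expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
  }
})

test_that("trait summaries count and round like the classifier says", {
  ids <- paste0("cg", 1:10)
  eff <- rep(1, 10)
  local <- mk_summary(ids, eff, rep(0.5, 10))
  ref_eff <- eff
  ref_eff[10] <- 5  # far away: non-overlap but same sign
  ref <- mk_summary(ids, ref_eff, c(rep(0.5, 9), 0.01), cohort = "reference")
  rec <- compare_associations(local, ref)
  s <- summarize_trait(rec)
  expect_equal(s$n_tests, 10L)
  expect_equal(unname(s$fractions), c(0.9, 0.1, 0.0))
  expect_equal(unname(s$percent), c(90, 10, 0))
  expect_equal(s$n_opposite, 0L)
  expect_error(summarize_trait(rec[0, ]), "no comparison records")
})

test_that("effect-size regression recovers exact lines", {
  set.seed(73)
  ids <- paste0("cg", 1:25)
  eff <- rnorm(25)
  local <- mk_summary(ids, eff, rep(0.1, 25))
  half <- mk_summary(ids, 0.5 * eff, rep(0.1, 25), cohort = "reference")
  fit <- effect_size_regression(local, half)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  same <- effect_size_regression(local, local)
  expect_equal(same$slope, 1, tolerance = 1e-12)
  # axis swap inverts the slope on exact lines
  fit_local_y <- effect_size_regression(local, half, y_axis = "local")
  expect_equal(fit_local_y$slope, 2, tolerance = 1e-10)
  expect_error(effect_size_regression(local[1:2, ], half[1:2, ]),
               "at least 3")
})

test_that("genetic context flags follow the mQTL and MAF tables", {
  ids <- c("cg21227253", "cg_equal", "cg_nomqtl")
  local <- mk_summary(ids, c(0.5, 0.5, 0.5), rep(0.01, 3))
  ref <- mk_summary(ids, c(-0.5, -0.5, -0.5), rep(0.01, 3),
                    cohort = "reference")
  rec <- compare_associations(local, ref)
  ann <- genetic_annotation(
    mqtl = data.frame(probe_id = c("cg21227253", "cg_equal"),
                      snp_id = c("rs7153432", "rs_same"),
                      type = c("cis", "trans"), z = c(12.9, 5.0),
                      stringsAsFactors = FALSE),
    maf = data.frame(snp_id = c("rs7153432", "rs7153432", "rs_same",
                                "rs_same"),
                     population = c("AFR", "EUR", "AFR", "EUR"),
                     maf = c(0.18, 0.40, 0.25, 0.25),
                     stringsAsFactors = FALSE),
    flags = data.frame(probe_id = "cg21227253", flag = "polymorphic",
                       stringsAsFactors = FALSE))
  out <- annotate_genetic_context(rec, ann, maf_gap_threshold = 0.10,
                                  populations = c("AFR", "EUR"))
  r1 <- out[out$probe_id == "cg21227253", ]
  expect_true(r1$has_cis_mqtl)
  expect_true(r1$maf_discordant)   # |0.18 - 0.40| >= 0.10
  expect_true(r1$polymorphic_probe)
  r2 <- out[out$probe_id == "cg_equal", ]
  expect_true(r2$has_trans_mqtl)
  expect_false(r2$maf_discordant)  # equal MAFs
  r3 <- out[out$probe_id == "cg_nomqtl", ]
  expect_false(any(unlist(r3[c("has_cis_mqtl", "has_trans_mqtl",
                               "maf_discordant", "polymorphic_probe",
                               "cross_reactive")])))
  fs <- attr(out, "flag_summary")
  expect_equal(unname(fs["n_opposite"]), 3L)
  expect_equal(unname(fs["maf_discordant"]), 1L)
  expect_error(annotate_genetic_context(rec, ann,
                                        populations = c("AFR", "EAS")),
               "EAS")
})

test_that("variance-explained column matches its brute-force oracle", {
  # sole noise-free predictor: exposure share equals total R2 equals 100%
  n <- 40
  x <- rnorm(n, 10, 4)
  meth <- matrix(0.2 + 0.003 * x, 1,
                 dimnames = list("cg1", sprintf("S%03d", 1:n)))
  pheno <- data.frame(sample_id = colnames(meth), x = x)
  v <- variance_explained_column(meth, pheno, model_spec("x"), "cg1")
  expect_equal(v$pct_var_exposure, 100, tolerance = 1e-6)
  expect_equal(v$pct_var_total, 100, tolerance = 1e-6)
  expect_lt(v$chi2_p, 1e-10)

  # exposure orthogonal to the covariate: share equals incremental R2
  set.seed(79)
  n <- 60
  c1 <- rnorm(n)
  x <- residuals(lm(rnorm(n) ~ c1))
  y <- 0.3 + 0.1 * x + 0.2 * c1 + rnorm(n, 0, 0.05)
  meth2 <- matrix(y, 1, dimnames = list("cgA", sprintf("S%03d", 1:n)))
  ph2 <- data.frame(sample_id = colnames(meth2), x = x, c1 = c1)
  v2 <- variance_explained_column(meth2, ph2,
                                  model_spec("x", covariates = "c1"), "cgA")
  r2_full <- summary(lm(y ~ x + c1))$r.squared
  r2_cov <- summary(lm(y ~ c1))$r.squared
  expect_equal(v2$pct_var_exposure, 100 * (r2_full - r2_cov),
               tolerance = 1e-8)

  # random correlated design vs the all-orderings oracle
  set.seed(83)
  n <- 50
  Z <- matrix(rnorm(n * 3), n)
  Z[, 2] <- Z[, 2] + 0.7 * Z[, 1]
  x <- rnorm(n) + 0.5 * Z[, 3]
  y <- 0.5 + 0.002 * x + Z %*% c(0.001, 0.002, -0.001) + rnorm(n, 0, 0.01)
  meth3 <- matrix(drop(y), 1, dimnames = list("cgB", sprintf("S%03d", 1:n)))
  ph3 <- data.frame(sample_id = colnames(meth3), x = x, z1 = Z[, 1],
                    z2 = Z[, 2], z3 = Z[, 3])
  v3 <- variance_explained_column(meth3, ph3,
                                  model_spec("x", covariates = c("z1", "z2",
                                                                 "z3")),
                                  "cgB")
  oracle <- lmg_bruteforce(drop(y), cbind(x, Z))
  expect_equal(v3$pct_var_exposure, 100 * oracle[1], tolerance = 1e-8)
  expect_error(variance_explained_column(meth3, ph3, model_spec("x"),
                                         "cg_missing"), "cg_missing")
})
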