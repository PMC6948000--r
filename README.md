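# ewasrep

Cross-ancestry **replication analysis for epigenome-wide association studies
(EWAS)** of DNA methylation.

When a small cohort from an understudied population re-measures CpGs with
published trait associations, significance-based replication is hopeless —
the interesting question is whether the *effect sizes* are compatible.
`ewasrep` implements that workflow for methylation beta values
(per-probe methylated/total signal ratios in [0, 1]):

* **Synthetic cohorts with ground truth** — beta matrices with probe-specific
  baselines, planted linear trait effects, leukocyte cell-mixture structure,
  slide-batch offsets, a hidden confounder, plus paired "reference study"
  summary tables with scaled effects and a configurable fraction of
  genetically driven sign-discordant CpGs. Every downstream stage is
  testable offline against known truth.
* **Detection p-value QC** — exclude any sample or probe with detection
  p > 0.01 in more than 5% of its measures.
* **Cell deconvolution** — Houseman-style nonnegative least squares against
  a (synthetic or user-supplied) cell-type reference, normalized to
  proportions.
* **EWAS engine** — per-CpG ordinary least squares in either orientation
  (methylation ~ trait + covariates, or trait ~ methylation + covariates)
  with surrogate variables selected by a seeded permutation test on the
  residual SVD; effects, SEs, two-sided p, and normal-approximation CIs.
* **Concordance** — the replication classifier: for each shared CpG, the two
  cohorts **overlap** when their 95% CIs intersect
  (`max(lows) <= min(highs)`), are **directionally consistent** when
  disjoint CIs share an effect sign, and **opposite** otherwise;
  cross-cohort effect-size regression (reference on the y axis, so slope <
  1 means larger local effects); mQTL / minor-allele-frequency annotation of
  discordant CpGs.
* **Variance & power** — exact LMG relative-importance decomposition
  (average incremental R² over all predictor orderings), nested-model
  chi-square tests, incremental adjusted R², Bonferroni thresholds
  (0.05 / 530,639 tests → p < 9.4 × 10⁻⁸ on the EPIC array) and two-group
  power for a beta-value difference δ:
  `power = Φ(−z + δ/se) + Φ(−z − δ/se)`, `se = σ·√(1/n₁ + 1/n₂)`.
* **Pipeline** — `run_pipeline()` chains simulate → qc → cells → ewas →
  compare → power → report deterministically, writing TSV/JSON outputs and
  a checksummed manifest; `inst/cli/ewasrep` exposes it as a command line.

## Worked example

```r
library(ewasrep)

cfg    <- synthetic_config(n_samples = 120, n_probes = 2000,
                           n_causal = 100, seed = 1)
cohort <- generate_cohort(cfg)

spec  <- model_spec("alcohol", covariates = c("age", "bmi", "cell_counts"))
sv    <- estimate_surrogates(cohort$meth, cohort$pheno, spec,
                             n_perm = 50, seed = 1)
local <- fit_ewas(cohort$meth, cohort$pheno, spec, surrogates = sv)

reference <- generate_reference_summary(cohort$truth, cfg)
records   <- compare_associations(local, reference)
summarize_trait(records)
#> <trait_concordance> alcohol (EUR): 2000 tests; 92% overlap, 6% consistent, 2% opposite; slope 0.356

fit <- effect_size_regression(local, reference)
sprintf("slope %.3f (se %.3f)", fit$slope, fit$se)
#> "slope 0.356 (se 0.005)"

format_threshold(bonferroni_threshold(0.05, 530639))
#> 9.4e-08
nrow(genomewide_hits(local))
#> 70
```

Reading the output: the surrogate step recovered the planted hidden
confounder (`k = 1`); 92% of the 2000 CpG comparisons have overlapping 95%
CIs, a further 6% are directionally consistent, and ~2% flip sign — the
sign-discordant fraction plus null probes whose tight reference intervals
miss noisy local estimates. The cross-cohort slope of 0.36 (reference on y)
reflects the configured reference-vs-local effect scaling of 0.5 attenuated
by sampling noise in the local estimates: local effects are systematically
larger than the reference's, exactly the regime the classifier is built
for. Per-hit variance decomposition
(`variance_explained_column()`) reports, e.g., alcohol explaining 27.2% of
one hit probe's methylation variance within a model explaining 79.1% in
total (nested-model χ² p = 3.6 × 10⁻²³).

## Repository layout

* `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  suites (all fixtures generated in code);
* `vignettes/ewas-replication-methods.Rmd` — the methods account: model
  assumptions, generator defaults and what they emulate, numerical choices,
  limitations;
* `inst/cli/ewasrep` — command-line front end (`run`, `simulate`, `qc`,
  `cells`, `ewas`, `compare`, `power`, `report`);
* `scripts/acceptance.R` — acceptance report generator.
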