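---
title: "Methods: cross-ancestry EWAS replication analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-ancestry EWAS replication analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewasrep)
```

## The problem

Most epigenome-wide association studies (EWAS) of DNA methylation have been
run in European or admixed American cohorts. When a small cohort from an
understudied ancestry measures the same CpGs, the question is not whether
each association reaches genome-wide significance again — a cohort of ~120
people cannot be powered for that — but whether the *effect sizes* are
compatible with the published ones. `ewasrep` implements that replication
logic end to end: per-CpG linear models on methylation beta values,
surrogate-variable adjustment for unmeasured structure, a
confidence-interval-overlap replication classifier, cross-cohort effect-size
regression, and annotation of sign-discordant CpGs with genetic context
(mQTLs and population minor-allele-frequency differences), plus the variance
decomposition and power arithmetic such analyses report.

## Models and procedures

### Per-CpG association model

For each probe $j$, methylation is a beta value $\beta_{ij} \in [0,1]$
(ratio of methylated to total signal in sample $i$). The default model is

$$\beta_{ij} = \alpha_j + b_j\, x_i + \gamma_j^\top c_i + \delta_j^\top s_i + \varepsilon_{ij},$$

with $x_i$ the trait (exposure), $c_i$ measured covariates (age, BMI,
smoking, leukocyte fractions, ...), and $s_i$ surrogate variables. The
orientation can be reversed (`trait_outcome`) so that the trait is regressed
on methylation plus covariates, as is conventional for BMI. Fits are
ordinary least squares; $p$-values are two-sided from the $t$ statistic on
residual degrees of freedom.

Confidence bounds default to the *normal* multiplier
($z_{0.975} = 1.959964$) rather than the $t$ quantile: published reference
intervals are normal-approximation intervals from large samples, and the
overlap classifier should treat both cohorts symmetrically. A `ci_method =
"t"` switch exists for small-sample exactness.

Exposure codings: continuous (optionally log-transformed, e.g. C-reactive
protein), current-vs-never, and ever-vs-never. When smoking enters as a
*covariate* it is always coded ever/never. The six cell fractions enter as
five columns (they sum to one, so all six plus an intercept would be
collinear).

### Surrogate variables

`estimate_surrogates()` regresses each probe on the exposure and covariates,
row-centres the residual matrix, and takes its SVD. The number of components
$k$ is chosen by a permutation test: each probe's residuals are permuted
independently (destroying across-sample structure while preserving per-probe
distributions), the singular-value variance shares are recomputed, and a
leading component is retained while its observed share exceeds the
permutation null at level 0.05 (100 permutations, mandatory seed; retention
stops at the first non-significant component). This is the
Buja–Eyuboglu-style parallel analysis applied directly to the residual
matrix; iteratively reweighted surrogate estimation is deliberately out of
scope. Returned surrogates are orthonormal right-singular vectors.

### The replication classifier

Two cohorts' association for a probe is classified as

* **overlap** — the 95% CIs intersect: $\max(l_a, l_b) \le \min(u_a, u_b)$;
* **consistent_nonoverlap** — CIs disjoint but effect signs agree
  (a zero effect is consistent with either sign);
* **opposite** — CIs disjoint and signs disagree.

The three classes partition every comparison set, an invariant asserted on
every run. Intervals are recomputed from effect and SE with a common
multiplier so the rule is symmetric in the two cohorts; widening either SE
can only create overlap, never destroy it.

`effect_size_regression()` places the *reference* effects on the y axis by
default. With the local cohort's effects on x, a slope below one reads
"local effects larger than reference effects", which is the only convention
under which a slope can be below one for traits where local effects are
amplified and far above one for a trait (age) where the local association is
much weaker. The axis choice and the slope null hypothesis (0 by default; 1
available to test departure from the equality line) are both recorded in the
output because conventions differ across the literature.

`annotate_genetic_context()` flags each comparison with cis/trans mQTL
presence, polymorphic-site and cross-reactive probe membership, and
`maf_discordant` when a linked SNP's minor allele frequency differs by at
least 0.10 (default) between the two named populations. This encodes the
standard interpretation that sign-discordant CpGs across ancestries are
often driven by population-specific genetic variation.

### Variance decomposition and power

`lmg_shares()` implements the LMG relative-importance metric: a predictor's
share of the outcome variance is its average incremental $R^2$ over all
orderings of model entry. It is computed exactly via the subset-weighting
identity (all $2^p$ subset $R^2$s with factorial weights), capped at 12
predictor groups; correlated blocks (cell fractions, surrogate variables)
can be grouped so they enter the orderings as one unit. Shares sum exactly
to the full-model $R^2$, and tests compare them to a literal
all-orderings `lm()` oracle.

`nested_lrt()` compares nested OLS models via Gaussian likelihoods,
$\chi^2 = n \log(\mathrm{RSS}_r / \mathrm{RSS}_f)$ on the column-count
difference — the "model with and without the exposure" chi-square. When the
reduced model already fits to numerical precision the statistic is defined
as 0 (both residual sums are rounding noise and their ratio is
meaningless).

`bonferroni_threshold(0.05, 530639)` gives the conventional EPIC-array
genome-wide threshold, printed as $9.4\times10^{-8}$ at two significant
figures. `probe_power()` uses a two-group normal approximation for a mean
beta difference $\delta$:
$\mathrm{power} = \Phi(-z_{\alpha/2} + \delta/\mathrm{se}) +
\Phi(-z_{\alpha/2} - \delta/\mathrm{se})$,
$\mathrm{se} = \sigma\sqrt{1/n_1 + 1/n_2}$. The group-contrast power model
is an assumption (the "difference in methylation" phrasing of such power
statements implies a two-group contrast); the fraction of probes reaching a
power target depends entirely on the supplied per-probe SD vector, so the
package makes no claim about reproducing any particular printed fraction.

## The synthetic-data generator: a stated world

`generate_cohort()` emits a cohort whose structure matches what the analysis
assumes, with every piece of ground truth retained for oracle testing:

$$\beta_{ij} = \mathrm{clip}_{[0,1]}\big(b_{0j} + b_j x_i + L_j^\top (f_i - \bar f) + u_{j,\mathrm{slide}(i)} + \lambda_j h_i + \varepsilon_{ij}\big)$$

* **Phenotypes** follow the descriptive shape of a small all-male cohort
  aged 45–88: age uniform on 45–88 y, BMI $\mathcal N(22.5, 4.9^2)$ kg/m²,
  waist $\mathcal N(83.8, 12.8^2)$ cm, alcohol zero-inflated gamma with 47%
  never-users and mean ~16.7 g/day, smoking never/current/former =
  47/51/2%, C-reactive protein log-normal (mean 9.7, SD 27 mg/L), lipids
  normal at their table means. Cell fractions are Dirichlet with whole-blood
  means (granulocytes 0.47, CD4/CD8/NK 0.11, monocytes 0.09, B 0.04) and
  concentration 20, which reproduces the observed SDs (~0.11 for
  granulocytes). Smoking gets a small "former" category (rather than a pure
  Bernoulli) so the ever/never covariate coding is meaningful.
* **Effects**: `n_causal` probes carry effects of magnitude
  $[0.5, 1.5]\times$`effect_scale` (default $5\times10^{-4}$ beta per unit
  trait, the order of magnitude of genome-wide-significant alcohol effects)
  with random sign. Baselines at causal probes are drawn at intermediate
  methylation (0.3–0.6) so planted effects cannot be truncated by clipping;
  other baselines are bimodal as on real arrays.
* **Structure**: per-probe/per-slide batch offsets (SD 0.003), a single
  standard-normal hidden factor loading on half the probes (loading SD
  0.02 × `confounder_strength`), cell-composition loadings on 30% of
  non-causal probes, and i.i.d. Gaussian noise (SD 0.02) on the linear beta
  scale, then clipping. Noise on the linear scale keeps every planted effect
  exactly recoverable by OLS, which is what makes closed-form tests
  possible; a logit-scale switch exists for realism but is not the default.
* **Reference summaries**: reference effects are
  `reference_effect_multiplier` (default 0.5) times the true effects,
  sign-flipped for a `discordant_fraction` (default 1%) of causal probes —
  the injected "population-specific genetics" mechanism — plus sampling
  noise at the configured SE. Reference SEs default to a scaled-down local
  SE (divided by $\sqrt{n_\mathrm{ref}/n_\mathrm{local}}$), emulating
  much larger reference studies; since the generator works from the truth
  table, the local SE is approximated analytically as
  $\sigma_\varepsilon / (\mathrm{sd}(x)\sqrt{n})$. Reference SE magnitude
  is genuinely unspecified by the emulated setting and is fully exposed in
  `se_profile`.
* **Detection matrices**: background detection p-values are uniform on
  (0, 0.005), far below the 0.01 threshold; planted bad samples/probes get
  >5% of entries pushed above it, so QC must find exactly the planted set.

What the generator does **not** emulate: probe-type chemistry differences,
spatial slide artefacts, genotype-driven methylation (discordance is
injected at the summary level), missingness, or heavy-tailed residuals. A
green test suite therefore establishes that the statistical machinery is
correct under the stated model, not that any particular biological finding
replicates.

## QC and deconvolution choices

The detection-p rule uses *strict* inequalities on both sides ("p > 0.01"
in "more than 5%" of measures), matching the conventional wording. Sample
and probe failing fractions are computed on the full matrix simultaneously
and removed in one pass, which is deterministic and order-independent; an
iterative re-evaluation mode is available but off by default.

Cell fractions are estimated per sample by Lawson–Hanson nonnegative least
squares against a reference profile, then normalized to sum to one
(Houseman-style constrained projection). The shipped reference is
*synthetic* — 10 well-separated probes per cell type, generated
deterministically in code — because published L-DMR libraries are not
redistributable; a real library in the same probes × cell-types layout can
be supplied instead. Granulocytes and neutrophils are treated as a single
column whose label is just the reference's column name.

## Numerical choices and degenerate inputs

* Perfect per-probe fits (zero residual variance) are flagged: SE is
  reported as 0 and p as the smallest positive double, keeping
  $p \in (0,1]$.
* Zero-variance probes are dropped from fitting with a warning, not an
  error.
* Genome-wide hit lists sort by p with lexicographic probe-id tie-breaks,
  so output order is bit-stable.
* A zero effect's sign is treated as consistent with either sign in the
  direction classifier.
* All TSV writers serialize doubles at 17 significant digits so
  writer/reader pairs round-trip losslessly; pipeline reruns under an
  identical config are byte-identical (asserted by md5 in the manifest).
* Seeds: every stochastic operation takes or derives an explicit seed;
  derived stream seeds stay below $2^{31}$.

## Known limitations

* Surrogate selection permutes residuals directly rather than
  re-residualizing permuted raw data; with very few samples the retained
  $k$ can be conservative.
* The LMG enumeration is exact but exponential; more than 12 groups is
  refused rather than approximated by sampling.
* Mixed/random-effects models (slide as a random effect, as some reference
  pipelines use) are out of scope; slide structure must be absorbed by
  surrogates or covariates.
* The pipeline config is JSON only (no YAML parser among the declared
  dependencies).
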