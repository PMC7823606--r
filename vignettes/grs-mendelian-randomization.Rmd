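---
title: "One-sample Mendelian randomization with genetic risk scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-sample Mendelian randomization with genetic risk scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsmr)
```

## The scientific problem

Observational associations between circulating adiponectin (APN) and
diabetic retinopathy (DR) in type-2-diabetes patients are inconsistent:
both protective and adverse associations have been reported, plausibly
because adiponectin is entangled with adiposity, glycaemia, lipids,
medication and renal function, and because retinal disease may itself
shift adiponectin levels (reverse causation). Mendelian randomization
(MR) sidesteps these problems by using genetic variants as instruments:
alleles are fixed at conception and allocated independently of the
confounders of later-life exposures, so the variant-predicted component
of the exposure is a quasi-randomized dose.

`grsmr` implements the full one-sample analysis: variant quality
control, per-variant association estimation on both legs, instrument
strength diagnostics, linkage-disequilibrium (LD) pruning, genetic risk
score (GRS) construction, causal estimation with sensitivity analyses,
confounder scans and power — together with a synthetic-cohort generator
so that every stage is testable with known ground truth.

## The model

For subject $i$ with variant dosages $G_{ij} \in [0,2]$, standardized
log exposure $x_i$ (SD units of $\ln$ APN) and binary outcome $y_i$,
the two association legs are

$$x_i = \beta_{Xj} G_{ij} + \epsilon_{ij} \qquad
  \operatorname{logit} \Pr(y_i = 1) = \alpha_j + \beta_{Yj} G_{ij},$$

estimated per variant by least squares and maximum-likelihood logistic
regression respectively. The single-instrument (Wald) causal estimate
is $\hat\beta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$, the log-odds ratio
of the outcome per SD of genetically determined log exposure.

**Orientation note.** The ratio is implemented in the standard
orientation — outcome association divided by exposure association.
Some published descriptions print the reciprocal; the reciprocal does
not have log-OR-per-SD units, so the standard orientation is used
throughout and stated here deliberately.

Estimators over a set of $k$ instruments:

* **IVW** (`mr_ivw()`): fixed-effect inverse-variance average of the
  Wald ratios, $w_j = 1/\mathrm{se}_j^2$; algebraically the
  zero-intercept weighted least-squares slope of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ with weights $1/\mathrm{se}^2_{Yj}$. Multiplicative
  random effects (SE inflated by $\max(1, \sqrt{Q/(k-1)})$) are
  optional; the default is fixed-effect because a single CI per
  estimate, with no heterogeneity statistic, is the convention this
  analysis follows.
* **GRS two-stage** (`grs_two_stage()`): the weighted allele score
  $s_i = \sum_j w_j G_{ij}$ (standardized) as a single instrument;
  the causal estimate is the score-outcome log-OR divided by the
  score-exposure effect.
* **MR-Egger** (`mr_egger()`): weighted regression of outcome on
  exposure associations with a free intercept, variants oriented so the
  exposure effect is positive. The intercept estimates average
  directional pleiotropy; inference uses $t_{k-2}$ with multiplicative
  random-effects scaling $\max(1,\hat\sigma)$ of the standard errors.
* **Weighted median** (`mr_weighted_median()`): the interpolated 50%
  point of the weight-ordered ratios, consistent while valid
  instruments carry more than half the weight; its SE is a parametric
  bootstrap (both legs resampled from their normal sampling
  distributions under a required, fixed seed; default 1000 replicates).

Every emitted estimate satisfies the same interval contracts:
95% CI $=\beta \pm 1.959964\,\mathrm{se}$, 90% CI
$=\beta \pm 1.644854\,\mathrm{se}$, $\mathrm{OR}=e^\beta$. p-values are
two-sided normal for ratio-based estimates, $t$ for the least-squares
legs and for Egger.

## Instrument processing

* **Quality control** (`variant_qc()`): exclude variants with minor
  allele frequency strictly below 0.5% or imputation INFO strictly
  below 0.4; variants without an INFO score (directly typed) pass the
  INFO test, a variant at a threshold exactly is kept, and a variant
  failing both filters is counted once as a frequency failure.
* **Strength** (`instrument_strength()`): $F = (\beta/\mathrm{se})^2$,
  $R^2 = F/(F+n-2)$, "strong" means strictly $F > 10$.
* **LD pruning** (`ld_prune()`): greedy, ranked by exposure variance
  explained (descending, ties by variant id), accepting a variant iff
  its squared dosage correlation with all kept variants is below 0.05.
  Squared Pearson correlation on dosages (composite LD) is used because
  only genotype-level data are assumed. On small instances the greedy
  set matches exhaustive search, and pruned sets are maximal (verified
  property).
* **Harmonization** (`harmonize_weights()`): if an external weight's
  effect allele matches the genotype's other allele, the dosage is
  flipped ($2-d$); if neither allele matches, the variant is dropped
  with a warning. Missing genotypes are mean-imputed per variant
  (twice the effect-allele frequency) at read time, keeping the sample
  size constant across score definitions.
* **Score definitions** (`grs_definitions()`): `all` pruned variants;
  `gwas_significant` (external source p below $5\times10^{-8}$);
  `internally_significant` (in-sample exposure p below 0.05). External
  weights are the default ("two-sample-style" weighting); in-sample
  re-estimated weights are available but overfit in the same cohort —
  the score and its exposure association then share noise, which
  inflates the apparent instrument strength.

## The synthetic-cohort generator

`simulate_cohort()` realizes the structure the analysis assumes:

$$\ln \mathrm{APN}^* = \textstyle\sum_j a_j (G_j - 2p_j) + \gamma U + \epsilon,
\qquad
y \sim \mathrm{Bernoulli}\bigl(\operatorname{logit}^{-1}(\alpha_0 +
\beta_c\, x + \delta U + \textstyle\sum_j d_j G_j)\bigr)$$

with $U$ a standard-normal latent confounder, $\epsilon$ sized so the
log exposure has unit variance, $x$ the standardized log exposure, and
$\alpha_0$ solved by bisection (bracket $[-20, 20]$, tolerance
$10^{-4}$ on the expected prevalence over the realized linear
predictors). Genotypes are drawn by Gaussian-copula thresholding: two
latent haplotype draws per subject, equicorrelated within an LD block,
thresholded at $\Phi^{-1}(1-p)$ and summed — Hardy–Weinberg holds
marginally while block correlation is controlled directly. Covariates
load on $U$ with stated means and SDs; sex is an independent Bernoulli
draw.

Default parameter choices, and why:

* `maf_range = (0.05, 0.45)`: common variants, the regime of the
  emulated candidate panel.
* Exposure effects: positive per-allele effects (the effect allele is
  reported as the exposure-increasing allele, the usual orientation in
  discovery summaries), with heterogeneous variance contributions drawn
  once from a flat exponential spectrum and rescaled so the joint
  explained variance hits `target_r2` (default 0.05, the upper end of
  the 3–5% range a well-powered adiponectin score explains).
* `causal_beta = 0.61` log-OR per SD (OR 1.84): the moderate-effect
  regime of interest.
* `confounder_exposure = confounder_outcome = 0.3`: moderate latent
  confounding. Calibration and parameter-recovery validation runs set
  both to zero, since those runs measure the estimators' intrinsic
  behaviour, not confounding robustness.
* `baseline_prevalence = 0.35`: the emulated case fraction (438/1251).
* Pleiotropy presets: `none` ($d_j = 0$), `balanced`
  ($d_j \sim N(0, 0.05)$), `directional` ($d_j \sim N(0.25, 0.05)$
  log-OR per allele), drawn independently of the exposure effects
  (InSIDE). The directional magnitude was set by a design analysis
  (below).
* `table1_preset()`: 1251 subjects, 47 variants, one strong instrument
  (1.8% of exposure variance alone, the $F \approx 24$ regime), joint
  explained variance 5.2%, covariate means/SDs from the emulated
  population's control arm. A plausible emulation of the published data
  structure — not a calibration to its unavailable individual-level
  data.
* The raw exposure scale (`exp(2.8 + 0.9 z)`, pg/mL-like) only matters
  for IO round-trips; all analysis uses the standardized log value.

What the generator does *not* emulate: genotyping/imputation error and
batch structure, fine-scale LD (blocks are equicorrelated), missing
data patterns, selection into the cohort, misclassified self-reported
outcome status, and medication effects on the exposure. Passing tests
therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to those real-data features.

## Design analyses and numerical choices

**Directional-pleiotropy preset magnitude.** The Egger intercept's
precision is governed by the spread of exposure associations relative
to their estimation noise. At the emulated scale (n = 1251, 16
variants, 5% joint explained variance) per-variant instruments are
weak ($F \approx 4$), so occasionally a variant's estimated exposure
effect flips sign; the orientation step then mirrors its outcome
association, producing an outlier whose random-effects inflation grows
with the pleiotropy magnitude itself. A design analysis at the
summary-statistic level showed detection power plateaus near 50% under
strongly heterogeneous instrument strength, while a panel of comparably
informative instruments (equal variance contributions) keeps flips rare
and reaches ~60% power at $\mu_d = 0.25$. The preset therefore uses
$\mu_d = 0.25$, and the package's pleiotropy-detection validation runs
use equal-contribution panels; both choices are fixed design, stated
here.

**Degenerate inputs.** Monomorphic variants yield absent estimates with
a recorded reason rather than errors; logistic separation
($|\beta| > 20$ during iteration) likewise. Outcome models require both
classes with at least 5 subjects each. A zero-variance exposure or
score is an error. Egger requires $k \ge 3$ and excludes exposure
effects exactly at zero before orientation. Ties in the LD-pruning
ranking break deterministically (variance explained descending, then
variant id ascending), making the pipeline byte-reproducible under a
fixed seed.

**Logistic fitting.** Iteratively reweighted least squares with
convergence tolerance $10^{-12}$ and at most 50 iterations; Wald
standard errors come from the Fisher information at the MLE. The test
suite cross-checks against an independently coded Newton–Raphson
oracle.

## Known limitations

* **Non-collapsibility.** With a logistic outcome model, ratio-based
  estimators target the *marginal* log-OR, which is attenuated relative
  to the conditional coefficient $\beta_c$ by roughly
  $1/\sqrt{1 + 0.346\,\beta_c^2(1 - R^2_j)}$ (about 6% at
  $\beta_c = 0.61$). Simulation at the emulated scale shows the IVW
  mean estimate about 0.05 below a conditional $\beta_c = 0.61$ while
  coverage and type-I error remain nominal. This is a property of
  odds-ratio estimands, not an estimator defect.
* **Power formula.** `mr_power()` implements the standard asymptotic
  approximation
  $\Phi\bigl(\sqrt{n R^2_{xz}\, cf(1-cf)}\,|\ln \mathrm{OR}| -
  z_{1-\alpha/2}\bigr)$. It ignores non-collapsibility, so empirical
  rejection rates run a few points below it; published power figures
  computed with other conventions (e.g. 75% where this formula gives
  65% at the same inputs) need not match it.
* **One-sample caveats.** Exposure and outcome legs share subjects, so
  weak-instrument bias points toward the observational association,
  and in-sample score weighting overfits. External weights and strong
  composite scores mitigate but do not remove this.
* **Egger under weak instruments.** See the design analysis above; a
  non-significant intercept in this regime is weak evidence of absence.

## Validation scale

The shipped test-suite and acceptance runs use cohorts of n = 1251
(matching the emulated study) with 500 replicate cohorts for
recovery/calibration checks in the suite (400 in the acceptance
script), 150–200 replicates for pleiotropy detection, and smaller
replicate counts where a closed-form oracle fixes the expectation;
Monte-Carlo tolerances are stated next to each assertion. These sizes
were chosen so each property is measured well inside its tolerance.
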