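---
title: "Assessing genomic prediction quality with partial/whole cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing genomic prediction quality with partial/whole cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gebvqc)
```

## The problem

Genomic selection ranks animals by genomic estimated breeding values
(GEBV) predicted from SNP genotypes. Before acting on those rankings, a
breeding program needs to know how *good* they are: how accurate, and
whether they are biased (systematically shifted) or badly dispersed
(over- or under-spread relative to what will be realised). `gebvqc`
implements a complete quality-assessment workflow for GBLUP predictions
built around a cohort-based cross-validation: a *whole*-data fit serves
as calibration, *partial* fits with one validation cohort's phenotypes
masked serve as the predictions one would actually have had at decision
time, and the two are compared through four metrics plus a
quartile-difference statistic that translates accuracy into phenotypic
units. A synthetic-data generator with known simulation truth makes the
whole pipeline testable end to end.

## The model

All fits use the linear mixed model

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{u} + \mathbf{e},
\qquad
\mathbf{u} \sim N(\mathbf{0}, \mathbf{G} \otimes \mathbf{V_G}),
\qquad
\mathbf{e} \sim N(\mathbf{0}, \mathbf{I} \otimes \mathbf{V_R}),$$

where $\mathbf{G}$ is the VanRaden method-1 genomic relationship matrix
$\mathbf{G} = \mathbf{Z}\mathbf{Z}^\top / (2\sum_j p_j(1-p_j))$ with
$\mathbf{Z}$ the dosage matrix column-centred at $2p_j$, and
$\mathbf{V_G}$, $\mathbf{V_R}$ are the genetic and residual trait
covariance matrices. Fixed effects are a contemporary group (CG,
herd x cohort x measurement batch; separate factors for feedlot and
carcase traits because measurement dates differ), age of dam as a
categorical class in whole years, and age at measurement as a linear
covariate (age at feedlot entry for feedlot traits, age at carcase
assessment for carcase traits). Allele frequencies for $\mathbf{G}$ are
the observed ones; note this makes $\mathbf{G}$ exactly singular (the
centred dosage columns sum to zero), which is why a diagonal ridge
repair (`ridge_repair()`, default $10^{-6}$) is available and engaged
automatically wherever a factorization of $\mathbf{G}$ itself is
required, such as sampling breeding values in the generator. REML never
needs it because the phenotypic covariance adds a positive-definite
residual term.

### The solver

Variance components are estimated by average-information (AI) REML with
expectation-maximization fallback. A single trait is fitted on the
eigenbasis of the observed-animal submatrix of $\mathbf{G}$, where the
phenotypic covariance $\sigma^2_g \mathbf{D} + \sigma^2_e \mathbf{I}$ is
diagonal and each iteration costs $O(np^2)$; this is what makes the 49
partial fits and the replicate studies cheap. The multi-trait fit builds
the dense phenotypic covariance over all records, handling trait
missingness record-wise: the residual covariance for an animal is the
$\mathbf{V_R}$ submatrix of its observed traits. An AI update is
accepted only if it keeps $\mathbf{V_R}$ positive definite,
$\mathbf{V_G}$ positive semi-definite, and does not decrease the
restricted likelihood; otherwise the step is halved (up to 12 times)
and, failing that, a matrix-form EM-like update with projection onto the
PSD cone is taken. The log-likelihood trace is therefore monotone, a
property the tests assert. Convergence requires the log-likelihood
change below `tol_logl` ($10^{-6}$) *and* the largest relative parameter
change below `tol_par` ($10^{-5}$), within `max_iter` (200) iterations;
components are floored at $10^{-8}$ of the phenotypic variance and
boundary heritabilities are flagged rather than hidden.

## The cross-validation and the four metrics

`run_crossval()` performs one whole-data fit (multivariate when several
traits are analysed) and then, for every cohort x trait cell of the
plan, masks the focal trait for the focal cohort
(`mask_cell()`), refits univariately, and evaluates on the validation
animals (cohort members with an observed phenotype for that trait):

* **ACC_T** `acc_traditional()`: $r(\hat u_p, y^*) / \sqrt{h^2}$, the
  Pearson correlation between partial GEBV and adjusted phenotypes
  divided by the square root of heritability. Adjusted phenotypes
  $y^* = y - \mathbf{X}\hat\beta$ always use the *whole*-data
  fixed-effect estimates (`adjust_phenotypes()`); they are never
  re-estimated in partial runs.
* **Bias_LR** `bias_lr()`: $\overline{\hat u_p} - \overline{\hat u_w}$,
  in trait units; 0 expected in the absence of bias.
* **Disp_LR** `dispersion_lr()`:
  $\mathrm{cov}(\hat u_w, \hat u_p)/\mathrm{var}(\hat u_p)$, the slope
  of the regression of whole on partial GEBV; 1 expected.
* **ACC_LR** `acc_lr()`:
  $\sqrt{\mathrm{cov}(\hat u_w, \hat u_p) /
  ((1 + \bar F - 2\bar f)\,\sigma^2_{g})}$, where $\bar F$ and
  $2\bar f$ are the mean inbreeding and mean pairwise relationship of
  the validation animals (`relationship_summary()` on the validation
  subset) and $\sigma^2_g$ is the additive variance estimated from the
  partial dataset (the validation animals are not under selection in
  the designs this package targets). A negative radicand — possible in
  genuinely uninformative cells — returns `NA` with a warning; it is
  never clamped silently.

All variances and covariances use the unbiased $n-1$ convention
throughout; the ratio forms make most such choices cancel, but
consistency is enforced.

Several of these choices were genuinely open and are configurable:

* *Which cohorts "missing" masks.* The default masks the focal cohort
  only, giving cohorts x traits cells and matching the count of a
  7 x 7 design (49 univariate partial runs); a forward-truncation
  variant (mask the focal and all later cohorts) is available via
  `masking = "forward"` for sensitivity analysis.
* *Which $h^2$ enters ACC_T.* Default: the whole-data multivariate
  estimate (`h2_source = "whole"`); the partial estimate is available.
* *Which SD scales Q1Q4.* Default: the SD of adjusted phenotypes over
  all animals (`sd_ref_scope = "all"`); validation-only is available.

## Q1Q4: accuracy in phenotypic units

`q1q4_difference()` ranks validation animals by GEBV (descending, ties
broken stably on animal ID), takes the top and bottom $\lfloor n/4
\rfloor$, and reports the difference in mean adjusted phenotype between
the two quartiles, raw and in SD units. With an uninformative ranking
its expectation is zero; with a perfect ranking of a normal trait it
approaches $2\varphi(z_{0.75})/0.25 \approx 2.54$ SD. `regress_q1q4()`
fits `q1q4_sd ~ trait + cohort + accuracy` by OLS and reports the slope
per 0.1 accuracy, the intercept t-test (an intercept at zero means a
zero-accuracy ranking yields no quartile separation), and marginal
(type-III-style) F-tests per term, obtained via `drop1()` — with no
interactions in the model these marginal tests coincide with the
type-III convention of the GLM procedures traditionally used for this
analysis.

`anova_metrics()` applies the same machinery to the metrics themselves
(`metric ~ h2 + cohort + trait`). The $h^2$ covariate is each cell's
partial-run estimate: the whole-fit estimate is constant within trait
and the model would not be estimable with it.

## The synthetic-data generator

`sim_config()` + `simulate_dataset()` emulate a multi-herd paternal
half-sib beef cattle design. Defaults reproduce the Angus steer study
conditions: 294 sires, seven year-of-birth cohorts of 361, 514, 579,
274, 569, 575 and 536 steers (3408 in total, mean 11.6 progeny per
sire), 12 herds each spanning about three cohorts, 45,152 SNPs, and
seven traits (two feedlot, five carcase) whose genetic and residual
covariance matrices are assembled from published heritabilities,
correlations and phenotypic SDs (`angus_trait_defaults()`). Each sire's
progeny sit in a single cohort, so sire linkage across cohorts is
negligible by construction and each cohort is a genuinely independent
validation set — `linkage_report()` verifies this.

Genotypes: per-SNP allele frequencies are uniform on `maf_range`
((0.05, 0.5] by default), sires are drawn in Hardy-Weinberg
proportions, and each progeny receives one Mendelian gamete from its
sire plus one population gamete. Dams are not tracked: in the emulated
design dams have at most four progeny (mean 1.2), so maternal family
structure is negligible, and the analysis never uses dam identity.
Breeding values are drawn from $N(\mathbf{0}, \mathbf{G} \otimes
\mathbf{V_G})$ via factorizations of the (ridge-repaired) realised
$\mathbf{G}$ and of $\mathbf{V_G}$, so the simulation truth is exactly
the quantity GBLUP estimates.

Where the emulated study does not state a value, the generator fixes
one realistic default, documented here and not revisited:

* CG effect SD: 0.5 phenotypic SD per trait (contemporary groups
  commonly absorb a large share of raw variance in field data); the
  number of CG levels follows from herd x cohort x a 2-level
  measurement batch, giving many small groups.
* Age slope: 0.2 phenotypic SD per 70 days of age.
* Age-of-dam effects: a young-dam penalty of 0.25 phenotypic SD at
  2 years decaying geometrically to nil by about 6 years, fitted (and
  simulated) as a categorical class in whole years — the conservative
  reading of an "age of dam in years" effect.
* Missingness: 2% of records uniformly at random (per-trait record
  counts of 3261-3327 out of 3408 imply roughly 2-4%).

What the generator does **not** emulate: linkage disequilibrium with
realistic decay (SNPs are independent, so accuracy comes from
relationship capture rather than LD), selection over generations (the
LR method's $\sigma^2_{g,\infty}$ then equals the current additive
variance, which is exactly the assumption the package's ACC_LR makes),
genotyping error, and full-sib or maternal structure. Passing
calibration tests on these simulations therefore demonstrates that the
estimators are implemented correctly and are calibrated when the model
is true; it does not by itself certify behaviour on real data with LD,
selection and pedigree error.

## Problem sizes used by the tests

The package's replicate studies run at sizes chosen to give stable
Monte-Carlo error while keeping the suite quick: the calibration design
is 800 animals (80 sires, 4 cohorts of 200, 8 herds) with 4000 SNPs,
used for 20-replicate LR calibration and 30-replicate heritability
recovery; the accuracy-gradient study for Q1Q4 uses 10 designs of 400
animals with 2000 SNPs and heritabilities from 0.05 to 0.65; oracle
equivalence checks use 5-20 animals. The full 3408-animal, 45k-SNP
default configuration runs the same code paths and is practical on a
workstation, but the multivariate whole fit at that scale is dense and
takes correspondingly longer.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_sires = 40, cohort_sizes = rep(150, 4), n_herds = 4,
                  n_snps = 2000, V_G = 0.4, V_R = 0.6, seed = 1)
dat <- simulate_dataset(cfg)
metrics <- run_crossval(dat$pheno, dat$grm, truth = dat$truth)
summarize_metrics(metrics)
regress_q1q4(metrics, "acc_lr")
anova_metrics(metrics, "disp_lr")
```

For a complete run that writes every study table to disk, see
`run_full_study()`; `scripts/acceptance.R` in the source repository
reruns the calibration studies from scratch.

## Known limitations

* The dense multivariate solver scales as the cube of the total record
  count; beyond a few thousand records per fit it becomes the
  bottleneck. The univariate eigendecomposition path has no such limit
  in practice.
* `V_G` estimates are projected to the PSD cone when an update leaves
  it; near-singular genetic covariances can slow convergence and are
  reported through the `converged` flag and iteration trace rather
  than masked.
* The ACC_LR denominator uses relationship summaries of the validation
  subset; for very small cohorts these are noisy and occasionally
  produce a negative radicand (reported as `NA`).
* Fixed-effect designs are made full-rank by pivoted QR; levels
  confounded after masking are dropped silently from the design (the
  fit remains correct, but individual coefficients are reported in the
  reduced basis).
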