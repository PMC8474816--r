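# gebvqc — quality assessment of genomic breeding value predictions

`gebvqc` is an R package for asking, and answering quantitatively, the
question every genomic selection program faces: *how good are my GEBV?*
It targets the setting of multi-herd livestock designs — e.g. beef
steers from many sires across several year-of-birth (YOB) cohorts — and
implements the full workflow:

* **GRM**: VanRaden method-1 genomic relationship matrix
  `G = ZZ' / (2 Σ pⱼ(1−pⱼ))` from 0/1/2 SNP dosages, with observed
  allele frequencies, mean imputation of missing dosages, monomorphic
  SNP exclusion, and relationship summaries (mean inbreeding `F̄`, mean
  pairwise relationship `2f̄`).
* **REML/GBLUP**: own-written average-information REML with EM fallback
  for `y = Xβ + u + e`, `u ~ N(0, G ⊗ V_G)`, `e ~ N(0, I ⊗ V_R)` —
  univariate via an eigendecomposition of `G` (fast), multivariate with
  record-wise trait missingness; fixed effects are contemporary group,
  age-of-dam class and an age covariate. GEBV are returned for all
  genotyped animals, including unphenotyped ones.
* **Cohort cross-validation (the LR method)**: a whole-data fit is the
  calibration; per cohort × trait cell the focal phenotypes are masked
  and refitted univariately. Four metrics per cell:
  `ACC_T = r(û_p, y*)/√h²` (traditional accuracy against adjusted
  phenotypes), `Bias_LR = mean(û_p) − mean(û_w)`,
  `Disp_LR = cov(û_w, û_p)/var(û_p)` (1 = correctly dispersed), and
  `ACC_LR = sqrt(cov(û_w, û_p) / ((1 + F̄ − 2f̄) σ²_g))`.
* **Q1Q4**: the difference in mean adjusted phenotype between the top
  and bottom GEBV quartiles of the validation animals, in trait units
  and SD units — accuracy translated into phenotype, plus OLS
  regressions of Q1Q4 on each accuracy metric.
* **Meta-analysis**: ANOVA of each quality metric on heritability,
  cohort and trait; accuracy variability (SD, CV%) per trait; sire/herd
  linkage reports.
* **Synthetic data**: a generator for paternal half-sib, multi-cohort,
  multi-herd designs with known breeding values and fixed effects, so
  every estimator can be tested against simulation truth. Defaults
  emulate a 3408-steer, 294-sire, 7-cohort, 12-herd, 45k-SNP Angus
  design with seven feedlot/carcase traits.

## Worked example

```r
library(gebvqc)

cfg <- sim_config(n_sires = 40, cohort_sizes = rep(150, 4), n_herds = 4,
                  n_snps = 2000, traits = c("gain", "fatdepth"),
                  trait_groups = c(1, 2),
                  V_G = matrix(c(0.40, 0.12, 0.12, 0.30), 2),
                  V_R = matrix(c(0.60, 0.15, 0.15, 0.70), 2),
                  missing_rate = 0.02, seed = 1)
dat <- simulate_dataset(cfg)          # genotypes, GRM, phenotypes, truth
metrics <- run_crossval(dat$pheno, dat$grm, truth = dat$truth)
attr(metrics, "whole_fit")
#> gp_fit: 2 trait(s), converged after 5 iterations (logL -625.0836)
#>   h2: gain=0.386, fatdepth=0.423
summarize_metrics(metrics)$per_trait
#>      trait  metric    mean      sd      min    max
#> 1     gain   acc_t 0.27488 0.11793  0.14897 0.4182
#> 2     gain  acc_lr 0.29605 0.01981  0.28042 0.3243
#> 3     gain bias_lr 0.01383 0.00755  0.00754 0.0228
#> 4     gain disp_lr 0.96375 0.25679  0.75496 1.2930
#> 5 fatdepth   acc_t 0.35701 0.10245  0.25273 0.4739
#> 6 fatdepth  acc_lr 0.31885 0.03182  0.29235 0.3624
#> 7 fatdepth bias_lr 0.00472 0.02456 -0.01582 0.0395
#> 8 fatdepth disp_lr 1.12282 0.34036  0.79938 1.5709
regress_q1q4(metrics, "acc_lr")
#> Q1Q4 ~ trait + cohort + acc_lr  (n = 8 cells, R2 = 0.926)
#>   slope: 0.618 SD units per 0.1 accuracy
#>   intercept: -1.595 (p = 0.0844)
```

Reading this: with 600 animals and 2000 SNPs, both true heritabilities
(0.40, 0.30) are recovered within sampling error; per-cohort `Bias_LR`
is near 0 and `Disp_LR` scatters around 1, as they should for an
unbiased predictor; the LR accuracy is far less variable across cohorts
than the traditional accuracy (SD 0.02–0.03 vs 0.10–0.12); and cells
with higher accuracy show a larger phenotypic gap between extreme GEBV
quartiles. `run_full_study(cfg, "out/")` runs the same pipeline and
writes every table (descriptives, heritabilities/correlations, metric
summaries, ANOVA, Q1Q4, linkage, manifest) as CSV.

A thin command-line wrapper with `simulate` and `run-all` subcommands
over a YAML config is installed at `inst/cli/gebvqc.R`.

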