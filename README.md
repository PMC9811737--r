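# prognokin

Prognostic gene-signature modelling and radiotracer uptake kinetics for
primary prostate cancer, on fully synthetic, calibrated data.

`prognokin` is aimed at biostatisticians and translational researchers who
want a tested, reproducible implementation of a two-part procedure:

1. **Survival signature pipeline.** From a patients × genes table of
   z-scored mRNA expression with progression-free survival (PFS), derive a
   *genetic score*: repeated event-rate-preserving 67/33 random splits; per
   split, gene rankings by a Random Forest (impurity importance) and by a
   hybrid Lasso — L1-penalized logistic regression whose binary target is
   defined by an unsupervised fuzzy C-means threshold on follow-up time;
   rank averaging and intersection of the two top-10 lists; a multivariable
   Cox model on the consensus genes stabilized by a 500-replication
   bootstrap (coefficient = bootstrap mean, SE = bootstrap SD,
   HR = e^β, 95% CI = e^(β ± 1.96·SE)); a linear score from the significant
   coefficients, dichotomized at the cohort median; Kaplan–Meier curves,
   log-rank test, and Harrell's c-index with bootstrap optimism correction.

2. **Tracer kinetics.** Per-minute time–activity curves (fraction of the
   administered dose over 120 min, 3% detector efficiency) analyzed by
   closed-system **Patlak** graphical analysis for irreversible FDG-like
   uptake — slope `a` is the accumulation rate, `a × [glucose]` the glucose
   consumption — and by **one-phase association**
   `A(t) = Amax·(1 − e^(−kt))` for saturable PSMA-like binding, where
   `Amax` reflects accessible binding sites and `k` the association
   constant.

Simulators for both data types (`simulate_cohort()`, `simulate_fdg_curve()`,
`simulate_psma_curve()`) are first-class, tested components: the cohort
generator plants four prognostic genes (PARP2 +0.254, SLC2A4 −0.733,
CTH −0.372, ALDOB +0.140 log-hazard per z-unit) among 122 genes in 493
patients with a censoring window calibrated by bisection to an 18.9%
expected event rate; the curve presets encode low- vs high-passage LNCaP
cultures (FDG rates 1.4e-7 vs 2.7e-7 min⁻¹; PSMA Amax ratio 15, k ratio 5).

## Worked example

End-to-end pipeline on the default synthetic cohort:

```r
library(prognokin)
cfg <- pipeline_config(
  cohort = cohort_sim_config(seed = 42),  # 493 patients x 122 genes
  n_splits = 10, n_trees = 250, B = 200, seed = 42
)
res <- run_pipeline(cfg)
#> cohort: 493 patients, 122 genes, 107 events (21.7%)
#> FCM event threshold: 77.0 months; 84 adverse labels
#> consensus top-10 intersection: SLC2A4
#> genetic score: -0.666*SLC2A4 (cutoff 0.0016)
#> log-rank chi2 = 14.0 (p = 0.00018); c-index 0.659 (0.661 corrected)
```

The strongest planted gene (SLC2A4, true β = −0.733) is recovered into the
consensus and its bootstrap-stabilized coefficient (−0.666 ± 0.128) covers
the truth; the median-split score separates PFS (log-rank p = 1.8e-4).
Weaker planted genes (|β| ≤ 0.25) are recovered only intermittently at this
cohort size with independent genes — see the methods vignette
(`vignettes/prognokin-methods.Rmd`) for the power analysis.

Kinetics on simulated replicate groups:

```r
rep_kin <- run_kinetics(list(
  `LNCaP-30` = list(preset = "PSMA-LNCaP30", n_replicates = 6),
  `LNCaP-80` = list(preset = "PSMA-LNCaP80", n_replicates = 6)
), seed = 1)
print(rep_kin)
#> kinetics report (PSMA): groups LNCaP-30 vs LNCaP-80
#> amax: 0.04497 ± 5.897e-05 vs 0.002984 ± 3.402e-05 (fold change 15.1, p = 4.21e-23)
#> k: 0.04004 ± 0.0001511 vs 0.00806 ± 0.0001269 (fold change 4.97, p = 9.05e-22)
```

The 15-fold difference in accessible binding sites (`Amax`) and ~5-fold
difference in the association constant `k` between the low- and
high-passage models are recovered from the noisy curves, with every
replicate fit at R² > 0.95.

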