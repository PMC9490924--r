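# tmescan

Spatial tumor-microenvironment (TME) features from patch-level tissue
classification maps of lung-cancer H&E slides, and the outcome models
built on them.

## The problem

Modern digital-pathology pipelines classify every 87 µm patch of an H&E
slide into one of nine tissue classes (tumor, stroma, mixed, immune,
vessel, bronchi, necrosis, lung, background), producing a *label grid* — a
2D segmentation map of the slide. The scientific question is what the
spatial composition of that map says about the patient: survival, and the
mutation status of clinically relevant genes (*EGFR*, *STK11*, *TP53*,
*KRAS*, ...). `tmescan` implements that post-segmentation analysis as a
reusable, tested R package for computational pathology groups: from label
grids (or raw per-patch class probabilities, or raw slide rasters) to
interpretable features to fitted models.

## The features and models at its core

For a slide with $n_i$ patches of tissue class $i$ and $N$ non-background
patches in total:

- **Tissue prevalence (TIP):** $t_i = n_i / N$ for the eight tissue
  classes.
- **TME composition (TMEC):** $m_j = b_j / B$, where $b_j$ counts class-$j$
  patches among the 8-connected neighbors of tumor patches (each tumor
  patch counted separately, so adjacency multiplicity counts) and
  $B = \sum_j b_j$ over the seven non-tumor tissue classes.
- **ITLR:** $b_{\mathrm{IMMUNE}} / n_{\mathrm{TUMOR}}$ (patch-wise).
- **Shannon index:** $-\sum_i t_i \log t_i$; **Simpson index:**
  $\sum_i t_i^2$.

Downstream, the package provides: cutpoint stratification by maximally
selected rank statistics with seeded permutation inference; Kaplan–Meier /
log-rank comparison with Benjamini–Hochberg FDR control; multivariate Cox
proportional-hazards models (Efron ties, basal-level hazard ratios fixed
at 1) with 10-fold cross-validated Harrell c-index; and per-gene mutation
classifiers (ridge logistic regression and random forest) under
oversampling-balanced repeated cross-validation with feature importances.
A fully seeded synthetic-data module generates label grids, probability
tables, H&E-like patches and whole cohorts (clinical covariates, Cox-model
survival times, logistic-model mutations) with known ground truth. The
upstream image stage — tiling, Rec. 601 luma relevance filtering, Reinhard
color normalization — is included for users starting from raw rasters.

## Worked example

Simulate a 300-patient cohort in which the prevalence of necrosis drives
the death hazard (log-hazard 1.5), then screen features, compare model
variants and fit the final Cox model:

```r
library(tmescan)

cfg <- sim_config(seed = 7, n_patients = 300, prevalence_dispersion = 0.5,
                  cox_betas = c(t_necrosis = 1.5), censor_frac = 0.25)
cohort <- gen_cohort(cfg)

survival_feature_screen(cohort,
                        features = c("t_necrosis", "t_immune", "m_vessel"),
                        n_perm = 199, seed = 11)
#>      feature  cutoff statistic logrank_p perm_p bh_critical significant
#> 1 t_necrosis 0.67125     7.004  2.49e-12  0.005      0.0333        TRUE
#> 2   t_immune 0.00375     2.543  1.10e-02  0.100      0.0667        TRUE
#> 3   m_vessel 0.23867     0.732  4.64e-01  0.955      0.1000       FALSE

cv0 <- cv_cindex(cohort, "clinical",     k = 10, seed = 2)
cv1 <- cv_cindex(cohort, "clinical+TIP", k = 10, seed = 2)
c(clinical = cv0$median_cindex, clinical_TIP = cv1$median_cindex)
#>     clinical clinical_TIP
#>        0.436        0.582

cox_fit(cohort[c("age_group", "sex", "smoking", "stage", "t_necrosis")],
        cohort$time, cohort$event)
#> Cox proportional hazards fit (Efron ties)
#> n = 300, events = 221, c-index = 0.582
#>                    term   coef   hr    se     z  p_value
#> 1             age_group 0.1007 1.11 0.138 0.732 4.64e-01
#> 2                   sex 0.0284 1.03 0.137 0.208 8.35e-01
#> 3          smokinglight 0.2742 1.32 0.204 1.344 1.79e-01
#> 4          smokingheavy 0.2870 1.33 0.206 1.396 1.63e-01
#> 5 stagelocally_advanced 0.1091 1.12 0.153 0.713 4.76e-01
#> 6         stageadvanced 0.0389 1.04 0.192 0.203 8.39e-01
#> 7            t_necrosis 1.6750 5.34 0.245 6.835 8.19e-12
```

Reading the output: the screen finds the necrosis cutpoint 0.67 with a
selection-adjusted permutation p of 0.005 (the naive log-rank p of a
learned cutpoint is optimistic by construction); adding TIP features lifts
the cross-validated median c-index of the clinical-only model from 0.44 to
0.58; and the multivariate fit recovers the simulated necrosis effect
(true log-hazard 1.5, estimated 1.68 ± 0.25, hazard ratio 5.3) while the
null clinical covariates stay non-significant.

Mutation classification works the same way from the other end:

```r
run_mutation_cv(cohort, "EGFR", "clinical+TMEC", "logistic_regression",
                repeats = 10, k = 10, seed = 3)
```

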