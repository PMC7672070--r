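# bagpipe

**B**rain-**A**ge **G**ap **pipe**line: a tested, desk-scale R
implementation of the full analysis chain behind "brain-age difference"
studies — from 3D image to causal inference.

Structural brain MRI carries an imprint of ageing. A regression model
trained on images of *healthy* people predicts a "healthy brain age";
the difference between that prediction and a person's chronological
age,

    delta = corrected_predicted_age - chronological_age,

is a compact index of how much older (or younger) a brain looks than
its owner. `bagpipe` implements each stage of that analysis as tested R
functions:

| stage | functions |
|---|---|
| synthetic cohorts with planted ground truth | `generate_atlas()`, `generate_volumes()`, `generate_traits()`, `generate_mr_summary()` |
| residual 3D CNN age regression (im2col + BLAS, Adam, MSE) | `model_config()`, `build_age_model()`, `train_age_model()`, `predict()` |
| study-design split and age-bias correction | `make_split()`, `fit_bias_correction()`, `apply_bias_correction()`, `evaluate_predictions()` |
| region permutation importance | `permute_region()`, `region_importance_scan()`, `rank_regions()` |
| phenome-wide association scan | `association_scan()`, `bonferroni_threshold()`, `bh_fdr()`, `scan_report()` |
| two-sample Mendelian randomisation | `harmonise()`, `ld_clump()`, `mr_ivw()`, `mr_egger()`, `mr_weighted_median()`, `mr_suite()` |

The statistical core in brief: the CNN is trained by Adam on mean
squared error; raw predictions are re-calibrated by inverting the
training-split regression `raw = alpha + beta * age` (removing
regression-to-the-mean); a region's importance is the MAE increase
after exchanging its voxels between subjects; traits are regressed on
`delta` in SD units (linear / logistic / cumulative-logit) with age,
sex and centre adjustment and Bonferroni + Benjamini–Hochberg control;
and causal effects are estimated from harmonised GWAS summary
statistics by inverse-variance weighting with MR-Egger and
weighted-median sensitivity analyses and Cochran's Q heterogeneity
tests. The methods vignette (`vignettes/brain-age-pipeline.Rmd`)
documents every formula and design choice.

Real biobank imaging is access-controlled, so the package's synthetic
cohort module is a first-class citizen: it plants age signal in known
atlas regions, trait links with known effect sizes, and causal effects
with known pleiotropy, and the test suite verifies each stage by
parameter recovery.

## Worked example

```r
library(bagpipe)

atlas <- generate_atlas(c(16, 16, 16), n_regions = 20, seed = 1)
sim <- generate_volumes(atlas, n_subjects = 220,
                        signal_regions = c(3, 11), seed = 101)

cfg <- model_config(c(16, 16, 16), channels = c(4, 8, 16),
                    n_residual_blocks = c(0, 1, 1), batch_size = 16,
                    n_epochs = 12, learning_rate = 2e-3, seed = 1)
fit <- train_age_model(build_age_model(cfg), sim$volumes[1:150],
                       val_volumes = sim$volumes[151:180])

test <- sim$volumes[181:220]
ages <- vapply(test, `[[`, numeric(1), "age")
bc <- fit_bias_correction(predict(fit$model, sim$volumes[1:150]),
                          vapply(sim$volumes[1:150], `[[`, numeric(1), "age"))
rec <- apply_bias_correction(bc, predict(fit$model, test), ages)
evaluate_predictions(rec)
#> $mae
#> [1] 2.969848
#> $r
#> [1] 0.9280712

imp <- region_importance_scan(fit$model, test, atlas = atlas,
                              n_repeats = 3, seed = 5)
head(rank_regions(imp, threshold = 0.10), 3)
#>   region_id  delta_mae sd_repeats n_repeats informative
#> 1         3 5.70673682 0.37095013         3        TRUE
#> 2        11 0.83383658 0.17936127         3        TRUE
#> 3         9 0.07021453 0.06833795         3       FALSE
```

The held-out MAE of about 3 years sits just above the irreducible
floor set by the planted subject-level gap (`delta_true`, SD 3.72
years), and the two regions flagged as informative (MAE increase above
0.10 years when their voxels are exchanged between subjects) are
exactly the two regions the simulator endowed with age signal. The
correlation of 0.93 between corrected prediction and age says the model
has learned the planted signal, not that any particular accuracy would
transfer to real MRI.

Downstream, `association_scan()` takes the `delta` column of `rec`
against a typed trait table, and `mr_suite()` takes two GWAS-style
summary tables; both are demonstrated end to end in
`scripts/acceptance.R`.

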