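# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small atlas + cohort for cheap structural tests
tiny_atlas <- function() memo("tiny_atlas", function() {
  generate_atlas(c(8, 8, 8), n_regions = 4, seed = 11)
})

tiny_cohort <- function() memo("tiny_cohort", function() {
  generate_volumes(tiny_atlas(), n_subjects = 6,
                   signal_regions = 2L, effect_size = 0.5,
                   noise_sd = 0.5, delta_sd = 0, seed = 12)
})

# scan-scale cohort (16^3, 20 regions, 2 planted signal regions) with a
# trained CNN; reused by the model and importance tests
scan_fixture <- function() memo("scan_fixture", function() {
  atlas <- generate_atlas(c(16, 16, 16), n_regions = 20, seed = 1)
  sizes <- table(atlas$labels[atlas$labels > 0])
  signal <- as.integer(names(sort(sizes, decreasing = TRUE)[1:2]))
  sim <- generate_volumes(atlas, n_subjects = 220,
                          signal_regions = signal, seed = 101)
  cfg <- model_config(c(16, 16, 16), channels = c(4, 8, 16),
                      n_residual_blocks = c(0, 1, 1), batch_size = 16,
                      n_epochs = 12, learning_rate = 2e-3, seed = 1)
  fit <- train_age_model(build_age_model(cfg), sim$volumes[1:150],
                         val_volumes = sim$volumes[151:180])
  list(atlas = atlas, sim = sim, model = fit$model, history = fit$history,
       train_idx = 1:150, val_idx = 151:180, test_idx = 181:220)
})

# an oracle predictor that reads only one region's mean intensity and
# maps it affinely to age (for exact-zero importance checks)
oracle_region_model <- function(atlas, region_id, slope, intercept) {
  idx <- which(atlas$labels == region_id)
  function(volumes) {
    vapply(volumes, function(v) intercept + slope * mean(v$voxels[idx]),
           numeric(1L))
  }
}

expect_same_volumes <- function(a, b) {
  expect_equal(lapply(a, `[[`, "voxels"), lapply(b, `[[`, "voxels"))
}
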