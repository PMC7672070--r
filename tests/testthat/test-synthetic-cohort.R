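# Parameter-recovery and determinism checks for the cohort simulator.

test_that("atlas generation partitions the mask as requested", {
  # single region: all foreground voxels carry label 1
  a1 <- generate_atlas(c(8, 8, 8), n_regions = 1, seed = 3)
  expect_setequal(unique(as.integer(a1$labels)), c(0L, 1L))
  expect_identical(a1$region_ids, 1L)

  # full enumeration: 20 nonempty pairwise-disjoint regions
  a <- generate_atlas(c(32, 32, 32), n_regions = 20, seed = 5)
  counts <- table(a$labels[a$labels > 0])
  expect_identical(sort(as.integer(names(counts))), 1:20)
  expect_true(all(counts > 0))
  # disjoint by construction: each voxel has exactly one label, so the
  # region voxel sets cannot overlap; verify by exhaustive scan
  tot <- sum(vapply(1:20, function(r) sum(a$labels == r), integer(1L)))
  expect_identical(tot, sum(a$labels > 0L))

  # determinism and error cases
  expect_identical(generate_atlas(c(8, 8, 8), 5, seed = 9)$labels,
                   generate_atlas(c(8, 8, 8), 5, seed = 9)$labels)
  expect_error(generate_atlas(c(2, 8, 8), 3), "shape")
  expect_error(generate_atlas(c(4, 4, 4), 10000), "too small")
})

test_that("volume simulation plants a recoverable linear age signal", {
  atlas <- generate_atlas(c(12, 12, 12), 6, seed = 2)

  # null signal: per-voxel correlation with age is noise-level
  null_sim <- generate_volumes(atlas, 60, signal_regions = integer(),
                               noise_sd = 1, delta_sd = 0, seed = 4)
  expect_true(null_sim$truth$pure_noise)
  X <- bagpipe:::volumes_to_matrix(null_sim$volumes)
  ages <- bagpipe:::cohort_ages(null_sim$volumes)
  some_vox <- which(atlas$labels > 0)[c(1, 10, 25, 40)]
  rs <- apply(X[some_vox, , drop = FALSE], 1L, cor, y = ages)
  expect_true(all(abs(rs) < 3 / sqrt(60)))

  # noiseless limit: region mean is an exact affine function of age
  exact <- generate_volumes(atlas, 10, signal_regions = 2L,
                            effect_size = 0.3, noise_sd = 0,
                            delta_sd = 0, seed = 5)
  idx <- which(atlas$labels == 2L)
  m <- vapply(exact$volumes, function(v) mean(v$voxels[idx]), numeric(1L))
  a <- bagpipe:::cohort_ages(exact$volumes)
  fit <- lm(m ~ a)
  expect_equal(unname(coef(fit)[2L]), 0.3, tolerance = 1e-10)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-10)

  # noisy case: OLS of region mean on age recovers the slope within 2 SE
  noisy <- generate_volumes(atlas, 200, signal_regions = 2L,
                            effect_size = 1, noise_sd = 1,
                            delta_sd = 0, seed = 6)
  m <- vapply(noisy$volumes, function(v) mean(v$voxels[idx]), numeric(1L))
  a <- bagpipe:::cohort_ages(noisy$volumes)
  # independent closed-form OLS oracle (normal equations)
  slope <- cov(m, a) / var(a)
  resid <- m - mean(m) - slope * (a - mean(a))
  se <- sqrt(sum(resid^2) / (198) / sum((a - mean(a))^2))
  expect_lt(abs(slope - 1), 2 * se)

  # determinism and conservation
  again <- generate_volumes(atlas, 200, signal_regions = 2L,
                            effect_size = 1, noise_sd = 1,
                            delta_sd = 0, seed = 6)
  expect_same_volumes(noisy$volumes, again$volumes)
  expect_length(noisy$volumes, 200L)
  expect_error(generate_volumes(atlas, 5, signal_regions = 99L), "subset")
})

test_that("planted gap enters volumes as apparent extra age", {
  atlas <- tiny_atlas()
  sim <- generate_volumes(atlas, 100, signal_regions = 2L,
                          effect_size = 0.5, noise_sd = 0,
                          delta_sd = 4, seed = 7)
  idx <- which(atlas$labels == 2L)
  m <- vapply(sim$volumes, function(v) mean(v$voxels[idx]), numeric(1L))
  apparent <- bagpipe:::cohort_ages(sim$volumes) + sim$truth$delta_true
  fit <- lm(m ~ apparent)
  expect_equal(unname(coef(fit)[2L]), 0.5, tolerance = 1e-10)
})

test_that("trait generation honours the declared links", {
  set.seed(20)
  delta <- rnorm(500, 0, 3.72)

  # deterministic continuous link: trait equals standardized delta
  tt <- generate_traits(delta,
                        trait_spec("pure", "continuous", link_effect = 1,
                                   noise_sd = 0),
                        seed = 1)
  expect_equal(tt$pure, delta / sd(delta), tolerance = 1e-12)

  # missingness completely at random at the requested rate
  tm <- generate_traits(delta,
                        trait_spec("gappy", "continuous",
                                   missing_rate = 0.25),
                        seed = 2)
  miss <- mean(is.na(tm$gappy))
  expect_lt(abs(miss - 0.25), 3 * sqrt(0.25 * 0.75 / 500))

  # determinism
  t2 <- generate_traits(delta,
                        trait_spec("gappy", "continuous",
                                   missing_rate = 0.25),
                        seed = 2)
  expect_identical(tm$gappy, t2$gappy)

  # degenerate binary draw is rejected, not silently returned
  expect_error(
    generate_traits(rnorm(20),
                    trait_spec("rare", "binary", baseline = 0.001),
                    seed = 3),
    "degenerate")
})

test_that("planted binary log-odds are recovered by a logistic fit", {
  # Monte-Carlo recovery of an odds ratio of 1.42 per SD of the gap,
  # using glm as the independent fitter
  true_or <- 1.42
  reps <- 30
  cover <- 0
  for (r in seq_len(reps)) {
    set.seed(300 + r)
    delta <- rnorm(4000, 0, 3.72)
    tt <- generate_traits(delta,
                          trait_spec("dz", "binary",
                                     link_effect = log(true_or),
                                     baseline = 0.3),
                          seed = 300 + r)
    fit <- glm(dz ~ I(delta / sd(delta)), data = cbind(tt, delta = delta),
               family = binomial())
    ci <- coef(summary(fit))[2L, 1:2] %*% rbind(c(1, 1), 1.96 * c(-1, 1))
    cover <- cover + (log(true_or) >= ci[1L] && log(true_or) <= ci[2L])
  }
  expect_gte(cover / reps, 0.8)
})

test_that("MR summary simulation obeys its generative model", {
  # noiseless, no pleiotropy: outcome beta is exactly theta * gamma and
  # harmonisation recovers proportionality despite emitted flips
  cfg0 <- mr_sim_config(n_variants = 12, theta = 0.5, se_x = 0,
                        se_y = 0, flip_fraction = 0.5, seed = 21)
  g0 <- generate_mr_summary(cfg0)
  h <- harmonise(g0$exposure, g0$outcome)
  expect_equal(h$variants$beta_y, 0.5 * g0$truth$gamma, tolerance = 1e-12)

  # determinism
  g1 <- generate_mr_summary(cfg0)
  expect_identical(g0$exposure, g1$exposure)
  expect_identical(g0$outcome, g1$outcome)

  # null causal effect: IVW centred on zero over 200 replicates
  ests <- vapply(1:200, function(r) {
    g <- generate_mr_summary(mr_sim_config(n_variants = 30, theta = 0,
                                           flip_fraction = 0, seed = r))
    mr_ivw(g$exposure |> transform(beta_x = beta, se_x = se) |>
             cbind(beta_y = g$outcome$beta, se_y = g$outcome$se))$estimate
  }, numeric(1L))
  expect_lt(abs(mean(ests)), 2 * sd(ests) / sqrt(200))

  # config validation
  expect_error(mr_sim_config(invalid_fraction = 1.5), "invalid_fraction")
})
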