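# Two-sample MR: harmonisation, clumping, and the three estimators.

mk_variants <- function(n, seed, bx_sd = 0.05, sy = 0.02) {
  set.seed(seed)
  data.frame(variant_id = sprintf("rs%03d", 1:n),
             beta_x = rnorm(n, 0.15, bx_sd), se_x = 0.01,
             beta_y = rnorm(n, 0.03, 0.02), se_y = runif(n, 0.01, sy + 0.01),
             p_x = runif(n), stringsAsFactors = FALSE)
}

test_that("harmonisation aligns, flips and drops as documented", {
  ex <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "A", "A", "A"),
                   other_allele = c("G", "G", "T", "G"),
                   beta = c(0.1, 0.2, 0.3, 0.4), se = 0.05,
                   pval = c(0.01, 0.02, 0.03, 0.04),
                   eaf = c(0.3, 0.3, 0.3, 0.3),
                   stringsAsFactors = FALSE)
  oc <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "G", "A", "A"),
                   other_allele = c("G", "A", "T", "C"),
                   beta = c(0.5, 0.6, 0.7, 0.8), se = 0.05,
                   pval = rep(0.5, 4), eaf = c(0.3, 0.7, 0.3, 0.3),
                   stringsAsFactors = FALSE)
  h <- harmonise(ex, oc)
  # v1 aligned, v2 flipped, v3 palindromic dropped, v4 incompatible
  expect_identical(h$variants$variant_id, c("v1", "v2"))
  expect_equal(h$variants$beta_y, c(0.5, -0.6))
  expect_equal(h$variants$eaf_y, c(0.3, 0.3))
  expect_identical(h$audit$action, c("flip", "drop", "drop"))
  expect_match(h$audit$reason[h$audit$variant_id == "v3"], "palindromic")
  expect_match(h$audit$reason[h$audit$variant_id == "v4"], "incompatible")

  # aligned-only input: no flips logged
  h1 <- harmonise(ex[1:2, ], oc[1, , drop = FALSE])
  expect_identical(nrow(h1$audit), 0L)

  # palindromic inference from allele frequency
  h2 <- harmonise(ex, oc, palindromic = "infer")
  expect_true("v3" %in% h2$variants$variant_id)
})

test_that("orientation flips never change the estimates", {
  cfg <- mr_sim_config(n_variants = 15, theta = 0.1, seed = 33,
                       flip_fraction = 0)
  g <- generate_mr_summary(cfg)
  base <- mr_suite(g$exposure, g$outcome, n_bootstrap = 50, seed = 1)
  # flip the emitted orientation of a few outcome rows by hand
  oc <- g$outcome
  for (i in c(2, 5, 11)) {
    tmp <- oc$effect_allele[i]
    oc$effect_allele[i] <- oc$other_allele[i]
    oc$other_allele[i] <- tmp
    oc$beta[i] <- -oc$beta[i]
    oc$eaf[i] <- 1 - oc$eaf[i]
  }
  flipped <- mr_suite(g$exposure, oc, n_bootstrap = 50, seed = 1)
  expect_equal(base$results$estimate, flipped$results$estimate,
               tolerance = 1e-10)
})

test_that("LD clumping keeps the most significant variant per clump", {
  v <- mk_variants(4, seed = 1)
  v$p_x <- c(0.5, 0.01, 0.2, 0.04)

  # no LD: everything kept
  expect_identical(ld_clump(v, diag(4), 0.1)$variant_id, v$variant_id)

  # perfect LD: only the smallest exposure p survives
  allone <- matrix(1, 4, 4)
  expect_identical(ld_clump(v, allone, 0.1)$variant_id, "rs002")

  # 5-variant toy matrix against an independent greedy oracle
  v5 <- mk_variants(5, seed = 2)
  v5$p_x <- c(0.03, 0.01, 0.5, 0.02, 0.2)
  r2 <- diag(5)
  r2[1, 2] <- r2[2, 1] <- 0.5   # 1 clumps with 2
  r2[3, 4] <- r2[4, 3] <- 0.09  # just below threshold
  r2[2, 5] <- r2[5, 2] <- 0.8   # 5 clumps with 2
  oracle <- function(v, r2, thr) {
    left <- seq_len(nrow(v)); keep <- integer()
    while (length(left)) {
      i <- left[order(v$p_x[left], v$variant_id[left])][1L]
      keep <- c(keep, i)
      left <- setdiff(left, which(r2[i, ] >= thr))
    }
    sort(keep)
  }
  expect_identical(ld_clump(v5, r2, 0.1)$variant_id,
                   v5$variant_id[oracle(v5, r2, 0.1)])

  expect_error(ld_clump(v5, diag(4), 0.1), "square")
})

test_that("IVW equals the weighted-through-origin regression", {
  # single instrument: the ratio estimate
  v1 <- data.frame(variant_id = "v", beta_x = 0.5, se_x = 0.01,
                   beta_y = 0.1, se_y = 0.02, p_x = 0.01)
  r1 <- mr_ivw(v1)
  expect_equal(r1$estimate, 0.2, tolerance = 1e-12)
  expect_equal(r1$se, 0.02 / 0.5, tolerance = 1e-12)

  # duplicating a variant halves the variance (fixed-effect pooling)
  v2 <- rbind(v1, v1)
  r2 <- mr_ivw(v2)
  expect_equal(r2$estimate, r1$estimate)
  expect_equal(r2$se, r1$se / sqrt(2), tolerance = 1e-12)

  # 20 random variants against the normal-equations oracle
  v <- mk_variants(20, seed = 3)
  r <- mr_ivw(v)
  w <- 1 / v$se_y^2
  est_oracle <- sum(w * v$beta_x * v$beta_y) / sum(w * v$beta_x^2)
  se_oracle <- sqrt(1 / sum(w * v$beta_x^2))
  expect_equal(r$estimate, est_oracle, tolerance = 1e-8)
  expect_equal(r$se, se_oracle, tolerance = 1e-8)
  q_oracle <- sum((v$beta_x / v$se_y)^2 *
                    (v$beta_y / v$beta_x - est_oracle)^2)
  expect_equal(r$q_statistic, q_oracle, tolerance = 1e-8)
  expect_identical(r$q_df, 19L)
})

test_that("MR-Egger matches weighted least squares with intercept", {
  # exact affine data: intercept and slope recovered exactly
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  ve <- data.frame(variant_id = paste0("v", 1:5), beta_x = bx,
                   se_x = 0.01, beta_y = 0.03 + 0.5 * bx, se_y = 0.02,
                   p_x = 0.01)
  re <- mr_egger(ve)
  expect_equal(re$estimate, 0.5, tolerance = 1e-10)
  expect_equal(re$intercept, 0.03, tolerance = 1e-10)
  expect_equal(re$q_statistic, 0, tolerance = 1e-10)

  # data on a ray through the origin: zero intercept, slope equals IVW
  vr <- ve; vr$beta_y <- 0.4 * vr$beta_x
  rr <- mr_egger(vr)
  expect_equal(rr$intercept, 0, tolerance = 1e-10)
  expect_equal(rr$estimate, mr_ivw(vr)$estimate, tolerance = 1e-10)

  # random weighted data: coefficients and SEs match lm(weights=)
  v <- mk_variants(20, seed = 4)
  v$beta_x <- abs(v$beta_x)
  r <- mr_egger(v)
  fit <- lm(beta_y ~ beta_x, data = v, weights = 1 / v$se_y^2)
  sm <- coef(summary(fit))
  expect_equal(r$estimate, sm["beta_x", 1L], tolerance = 1e-8)
  expect_equal(r$se, sm["beta_x", 2L], tolerance = 1e-8)
  expect_equal(r$intercept, sm["(Intercept)", 1L], tolerance = 1e-8)
  expect_equal(r$intercept_se, sm["(Intercept)", 2L], tolerance = 1e-8)
  expect_equal(r$p_value, sm["beta_x", 4L], tolerance = 1e-8)

  expect_error(mr_egger(v[1:2, ]), ">= 3")
})

test_that("the weighted median interpolates the cumulative weights", {
  # single variant: the ratio itself
  v1 <- data.frame(variant_id = "v", beta_x = 0.4, se_x = 0,
                   beta_y = 0.1, se_y = 0.02, p_x = 0.01)
  expect_equal(mr_weighted_median(v1, n_bootstrap = 10)$estimate, 0.25)

  # three equal-weight ratios: the middle one
  v3 <- data.frame(variant_id = paste0("v", 1:3),
                   beta_x = c(1, 1, 1), se_x = 0,
                   beta_y = c(0.1, 0.2, 0.9), se_y = 1, p_x = 0.01)
  expect_equal(mr_weighted_median(v3, n_bootstrap = 10)$estimate, 0.2)

  # random weighted set against an exhaustive cumulative-weight scan
  v <- mk_variants(15, seed = 5)
  est <- mr_weighted_median(v, n_bootstrap = 10, seed = 1)$estimate
  ratio <- v$beta_y / v$beta_x
  w <- (v$beta_x / v$se_y)^2
  o <- order(ratio); rs <- ratio[o]; ws <- w[o] / sum(w)
  cw <- cumsum(ws) - ws / 2
  k <- max(which(cw < 0.5))
  oracle <- rs[k] + (rs[k + 1] - rs[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
  expect_equal(est, oracle, tolerance = 1e-10)

  # bootstrap se is seeded
  a <- mr_weighted_median(v, n_bootstrap = 100, seed = 7)
  b <- mr_weighted_median(v, n_bootstrap = 100, seed = 7)
  expect_identical(a$se, b$se)
})

test_that("the full suite recovers a planted causal effect", {
  theta <- 0.06
  ests <- t(vapply(1:50, function(r) {
    g <- generate_mr_summary(mr_sim_config(n_variants = 30, theta = theta,
                                           seed = 5000 + r))
    s <- mr_suite(g$exposure, g$outcome, n_bootstrap = 100, seed = r)
    out <- setNames(s$results$estimate, s$results$method)
    out[c("ivw", "egger", "weighted_median")]
  }, numeric(3L)))
  for (j in 1:3) {
    mc_se <- sd(ests[, j]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, j]) - theta), 2 * mc_se,
              label = paste("bias of", colnames(ests)[j]))
  }
})

test_that("the weighted median resists 40% invalid instruments", {
  bias <- t(vapply(1:60, function(r) {
    g <- generate_mr_summary(mr_sim_config(
      n_variants = 30, theta = 0.06, invalid_fraction = 0.4,
      pleiotropy_mean = 0.05, pleiotropy_sd = 0.01, seed = 7000 + r))
    s <- mr_suite(g$exposure, g$outcome, n_bootstrap = 50, seed = r)
    est <- setNames(s$results$estimate, s$results$method)
    abs(est[c("ivw", "weighted_median")] - 0.06)
  }, numeric(2L)))
  expect_lt(mean(bias[, "weighted_median"]), mean(bias[, "ivw"]))
})

test_that("homogeneous noiseless ratios give Q exactly zero", {
  g <- generate_mr_summary(mr_sim_config(n_variants = 10, theta = 0.3,
                                         se_x = 0, se_y = 0,
                                         flip_fraction = 0, seed = 2))
  v <- harmonise(g$exposure, g$outcome)$variants
  v$se_y <- 0.01  # weights must exist; ratios are still exact
  r <- mr_ivw(v)
  expect_equal(r$q_statistic, 0, tolerance = 1e-18)
  expect_equal(mr_egger(v)$q_statistic, 0, tolerance = 1e-18)
})

test_that("Q is chi-square calibrated under homogeneity", {
  qs <- vapply(1:100, function(r) {
    g <- generate_mr_summary(mr_sim_config(n_variants = 20, theta = 0.1,
                                           se_x = 0, seed = 9000 + r))
    mr_ivw(harmonise(g$exposure, g$outcome)$variants)$q_statistic
  }, numeric(1L))
  # mean of a chi-square(19) is 19
  expect_lt(abs(mean(qs) - 19), 2 * sd(qs) / sqrt(100))
})

test_that("sub-3-variant inputs downgrade to IVW and median", {
  g <- generate_mr_summary(mr_sim_config(n_variants = 2, seed = 3,
                                         flip_fraction = 0))
  expect_warning(s <- mr_suite(g$exposure, g$outcome, n_bootstrap = 20),
                 "Egger omitted")
  expect_setequal(s$results$method, c("ivw", "weighted_median"))
})
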