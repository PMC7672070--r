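#' Configuration for the two-sample MR summary-statistics simulator
#'
#' @param n_variants number of genetic instruments.
#' @param theta true causal effect of the exposure on the outcome.
#' @param pleiotropy_mean mean direct (horizontal) effect of invalid
#'   instruments on the outcome.
#' @param pleiotropy_sd sd of the direct effect around its mean.
#' @param invalid_fraction fraction of instruments with a direct effect,
#'   in [0, 1].
#' @param se_x,se_y standard errors of the exposure and outcome effect
#'   estimates (recycled per variant; must be > 0 unless exactly 0 for a
#'   noiseless check).
#' @param gamma_range range of the (positive) true instrument strengths,
#'   drawn uniformly.
#' @param flip_fraction fraction of variants whose outcome row is emitted
#'   in the opposite allele orientation, so harmonisation must flip it.
#' @param palindromic_fraction fraction of variants assigned a
#'   palindromic (A/T or C/G) allele pair.
#' @param n_exposure,n_outcome notional GWAS sample sizes (metadata only).
#' @param seed integer seed.
#' @return an `mr_sim_config` list.
#' @export
mr_sim_config <- function(n_variants = 30L, theta = 0,
                          pleiotropy_mean = 0, pleiotropy_sd = 0,
                          invalid_fraction = 0,
                          se_x = 0.01, se_y = 0.02,
                          gamma_range = c(0.05, 0.25),
                          flip_fraction = 0.3, palindromic_fraction = 0,
                          n_exposure = 1e5, n_outcome = 1e4, seed = 1L) {
  if (invalid_fraction < 0 || invalid_fraction > 1)
    stop_bad_arg("`invalid_fraction` must be in [0, 1]")
  if (any(se_x < 0) || any(se_y < 0))
    stop_bad_arg("`se_x` and `se_y` must be non-negative")
  structure(list(n_variants = as.integer(n_variants), theta = theta,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 se_x = se_x, se_y = se_y, gamma_range = gamma_range,
                 flip_fraction = flip_fraction,
                 palindromic_fraction = palindromic_fraction,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 seed = as.integer(seed)),
            class = "mr_sim_config")
}

#' Simulate harmonisable exposure/outcome GWAS summary statistics
#'
#' Per variant j: a positive instrument strength `gamma_j` is drawn; the
#' exposure effect is `gamma_j + N(0, se_x)`; the outcome effect is
#' `theta * gamma_j + alpha_j + N(0, se_y)`, where the direct effect
#' `alpha_j` is zero for valid instruments and drawn from the pleiotropy
#' distribution for the invalid fraction. A configurable subset of
#' outcome rows is emitted with swapped alleles (beta negated, allele
#' frequency complemented) so harmonisation has real work to do, and a
#' configurable subset is palindromic.
#'
#' @param cfg an [mr_sim_config()].
#' @return list with `exposure` and `outcome` data frames (columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`,
#'   `eaf`) and `truth` (gamma, alpha, theta, flipped, palindromic).
#' @export
generate_mr_summary <- function(cfg) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  m <- cfg$n_variants
  se_x <- rep_len(cfg$se_x, m)
  se_y <- rep_len(cfg$se_y, m)

  with_rng(cfg$seed, {
    gamma <- runif(m, cfg$gamma_range[1L], cfg$gamma_range[2L])
    invalid <- runif(m) < cfg$invalid_fraction
    alpha <- ifelse(invalid,
                    rnorm(m, cfg$pleiotropy_mean, cfg$pleiotropy_sd), 0)
    beta_x <- gamma + rnorm(m, 0, se_x)
    beta_y <- cfg$theta * gamma + alpha + rnorm(m, 0, se_y)

    palin <- runif(m) < cfg$palindromic_fraction
    pairs_np <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    pairs_p <- list(c("A", "T"), c("C", "G"))
    al <- t(vapply(seq_len(m), function(j) {
      if (palin[j]) pairs_p[[sample.int(2L, 1L)]]
      else pairs_np[[sample.int(4L, 1L)]]
    }, character(2L)))
    eaf <- runif(m, 0.1, 0.9)

    ids <- sprintf("rs%05d", seq_len(m))
    p_of <- function(b, se) ifelse(se > 0, 2 * pnorm(-abs(b) / se), 0)
    exposure <- data.frame(
      variant_id = ids, effect_allele = al[, 1L], other_allele = al[, 2L],
      beta = beta_x, se = se_x, pval = p_of(beta_x, se_x), eaf = eaf,
      stringsAsFactors = FALSE)

    flipped <- runif(m) < cfg$flip_fraction
    outcome <- data.frame(
      variant_id = ids,
      effect_allele = ifelse(flipped, al[, 2L], al[, 1L]),
      other_allele = ifelse(flipped, al[, 1L], al[, 2L]),
      beta = ifelse(flipped, -beta_y, beta_y),
      se = se_y, pval = p_of(beta_y, se_y),
      eaf = ifelse(flipped, 1 - eaf, eaf),
      stringsAsFactors = FALSE)

    list(exposure = exposure, outcome = outcome,
         truth = list(gamma = gamma, alpha = alpha, theta = cfg$theta,
                      invalid = invalid, flipped = flipped,
                      palindromic = palin))
  })
}
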