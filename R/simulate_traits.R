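#' Declare a simulated trait
#'
#' @param name column name in the generated trait table.
#' @param kind `"continuous"`, `"binary"` or `"ordinal"`.
#' @param link_effect planted effect per standard deviation of the true
#'   brain-age gap: a regression beta for continuous traits, a log-odds
#'   ratio for binary and ordinal traits.
#' @param baseline intercept for continuous traits; prevalence in (0,1)
#'   for binary traits; ignored for ordinal traits (levels start roughly
#'   uniform).
#' @param noise_sd residual standard deviation for continuous traits.
#' @param n_levels number of ordered levels for ordinal traits (>= 3).
#' @param missing_rate fraction of values set missing completely at
#'   random, in [0, 1).
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(name, kind = c("continuous", "binary", "ordinal"),
                       link_effect = 0, baseline = 0, noise_sd = 1,
                       n_levels = 4L, missing_rate = 0) {
  kind <- match.arg(kind)
  if (missing_rate < 0 || missing_rate >= 1)
    stop_bad_arg("`missing_rate` must be in [0, 1)")
  if (kind == "binary" && (baseline <= 0 || baseline >= 1))
    stop_bad_arg("binary `baseline` is a prevalence and must be in (0, 1)")
  if (kind == "ordinal" && n_levels < 3L)
    stop_bad_arg("ordinal traits need >= 3 levels")
  structure(list(name = name, kind = kind, link_effect = link_effect,
                 baseline = baseline, noise_sd = noise_sd,
                 n_levels = as.integer(n_levels),
                 missing_rate = missing_rate),
            class = "trait_spec")
}

#' Simulate a typed trait table linked to the true brain-age gap
#'
#' Each trait is generated from the standardized planted gap
#' `z = delta_true / sd(delta_true)`:
#' continuous traits as `baseline + link_effect * z + N(0, noise_sd)`;
#' binary traits from a logistic model whose intercept matches the
#' requested prevalence and whose log-odds per SD is `link_effect`;
#' ordinal traits from a cumulative-logit (proportional odds) model with
#' approximately uniform baseline level probabilities. Missingness is
#' applied completely at random per trait.
#'
#' @param delta_true per-subject planted brain-age gap (years).
#' @param specs list of [trait_spec()] objects.
#' @param covariates data frame with one row per subject; must contain
#'   `age`; `sex` and `centre` are generated when absent. May be `NULL`.
#' @param seed integer seed.
#' @return a `data.frame` with `subject_id`, covariates (`age`, `sex`,
#'   `centre`), one column per trait, and a `trait_types` attribute
#'   naming each trait's declared type.
#' @export
generate_traits <- function(delta_true, specs, covariates = NULL, seed = 1L) {
  n <- length(delta_true)
  if (n < 2L) stop_bad_arg("need >= 2 subjects")
  if (inherits(specs, "trait_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1L), "trait_spec")))
  s <- sd(delta_true)
  z <- if (s > 0) delta_true / s else delta_true

  with_rng(seed, {
    if (is.null(covariates)) covariates <- data.frame(age = runif(n, 45, 80))
    stopifnot(nrow(covariates) == n, "age" %in% names(covariates))
    if (is.null(covariates$sex))
      covariates$sex <- factor(sample(c("F", "M"), n, replace = TRUE))
    if (is.null(covariates$centre))
      covariates$centre <- factor(sample(paste0("C", 1:3), n, replace = TRUE))
    out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                      covariates, stringsAsFactors = FALSE)

    types <- character(0)
    for (sp in specs) {
      val <- switch(sp$kind,
        continuous = sp$baseline + sp$link_effect * z +
          (if (sp$noise_sd > 0) rnorm(n, 0, sp$noise_sd) else 0),
        binary = {
          p <- plogis(qlogis(sp$baseline) + sp$link_effect * z)
          y <- rbinom(n, 1L, p)
          tab <- table(y)
          if (length(tab) < 2L || min(tab) < 2L)
            stop_bad_arg("binary trait '", sp$name,
                         "' is degenerate: a realized class has < 2 members")
          y
        },
        ordinal = {
          # latent proportional-odds draw; cutpoints give ~uniform levels
          cuts <- qlogis(seq_len(sp$n_levels - 1L) / sp$n_levels)
          lat <- sp$link_effect * z + rlogis(n)
          as.integer(cut(lat, c(-Inf, cuts, Inf), labels = FALSE))
        })
      if (sp$missing_rate > 0)
        val[runif(n) < sp$missing_rate] <- NA
      out[[sp$name]] <- val
      types[sp$name] <- sp$kind
    }
    attr(out, "trait_types") <- types
    out
  })
}
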