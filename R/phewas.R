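#' Phenome-wide association scan against the brain-age difference
#'
#' Regresses each declared trait on the brain-age difference
#' standardized to SD units (computed on the analysis cohort), adjusting
#' for age, sex and assessment centre: linear models for continuous
#' traits, logistic for binary, cumulative-logit (proportional odds) for
#' ordinal. Rows with missing values are excluded per trait; traits
#' failing preconditions are reported as skipped with a reason, never
#' silently dropped, and non-converged fits are flagged.
#'
#' @param deltas data frame with `subject_id` and `delta` (years), e.g.
#'   the record table from [apply_bias_correction()].
#' @param traits trait table: `subject_id`, covariates `age`, `sex`,
#'   `centre`, and typed trait columns; types come from the
#'   `trait_types` attribute (as written by [generate_traits()]) or the
#'   `trait_types` argument.
#' @param trait_types optional named character vector
#'   (`continuous`/`binary`/`ordinal`) overriding the attribute.
#' @param covariates covariate column names to adjust for.
#' @param min_n minimum non-missing subjects per trait (default 10).
#' @param inverse_normal apply a rank-based inverse-normal transform to
#'   continuous traits before fitting (default FALSE).
#' @return data frame of class `phewas_result`: `trait`, `type`,
#'   `effect` (beta per SD for continuous, OR per SD otherwise),
#'   `ci_low`, `ci_high`, `p_value`, `n_used`, `n_missing`, `n_cases`,
#'   `n_controls`, `status`.
#' @export
association_scan <- function(deltas, traits, trait_types = NULL,
                             covariates = c("age", "sex", "centre"),
                             min_n = 10L, inverse_normal = FALSE) {
  stopifnot(all(c("subject_id", "delta") %in% names(deltas)))
  types <- trait_types %||% attr(traits, "trait_types")
  if (is.null(types))
    stop_bad_arg("trait types must be declared (attribute or argument)")
  covariates <- intersect(covariates, names(traits))
  dat <- merge(deltas[, c("subject_id", "delta")], traits,
               by = "subject_id")
  if (nrow(dat) < 2L) stop_bad_arg("deltas and traits do not join")
  sd_delta <- sd(dat$delta)
  if (sd_delta == 0) stop_bad_arg("constant delta: cannot standardize")
  dat$.z <- dat$delta / sd_delta
  n_total <- nrow(dat)

  one_trait <- function(tr) {
    type <- types[[tr]]
    res <- list(trait = tr, type = type, effect = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, n_used = 0L,
                n_missing = n_total, n_cases = NA_integer_,
                n_controls = NA_integer_, status = "ok")
    cols <- c(".z", covariates, tr)
    d <- dat[complete.cases(dat[, cols]), cols]
    res$n_used <- nrow(d)
    res$n_missing <- n_total - nrow(d)
    if (nrow(d) < min_n) {
      res$status <- paste0("skipped: n=", nrow(d), " < ", min_n)
      return(res)
    }
    rhs <- paste(c(".z", covariates), collapse = " + ")
    fit_wald <- function(beta, se, df = Inf) {
      crit <- if (is.finite(df)) stats::qt(0.975, df) else qnorm(0.975)
      p <- if (is.finite(df)) 2 * pt(-abs(beta / se), df)
           else 2 * pnorm(-abs(beta / se))
      list(lo = beta - crit * se, hi = beta + crit * se, p = p)
    }
    out <- tryCatch({
      if (type == "continuous") {
        y <- d[[tr]]
        if (inverse_normal)
          y <- qnorm((rank(y) - 0.5) / length(y))
        d$.y <- y
        fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = d)
        sm <- summary(fit)$coefficients
        b <- sm[".z", 1L]; se <- sm[".z", 2L]
        w <- fit_wald(b, se, fit$df.residual)
        res$effect <- b; res$ci_low <- w$lo; res$ci_high <- w$hi
        res$p_value <- sm[".z", 4L]
      } else if (type == "binary") {
        tab <- table(d[[tr]])
        if (length(tab) < 2L || min(tab) < 2L) {
          res$status <- "skipped: < 2 members in a class"
          return(res)
        }
        res$n_cases <- as.integer(tab[which.max(as.numeric(names(tab)))])
        res$n_controls <- res$n_used - res$n_cases
        d$.y <- as.integer(factor(d[[tr]])) - 1L
        fit <- glm(stats::as.formula(paste(".y ~", rhs)), data = d,
                   family = binomial())
        if (!fit$converged) res$status <- "failed: glm did not converge"
        sm <- summary(fit)$coefficients
        b <- sm[".z", 1L]; se <- sm[".z", 2L]
        if (abs(b) > 15) res$status <- "failed: probable separation"
        w <- fit_wald(b, se)
        res$effect <- exp(b); res$ci_low <- exp(w$lo)
        res$ci_high <- exp(w$hi); res$p_value <- sm[".z", 4L]
      } else if (type == "ordinal") {
        yf <- factor(d[[tr]], ordered = TRUE)
        if (nlevels(yf) < 3L) {
          res$status <- "skipped: < 3 observed levels"
          return(res)
        }
        d$.y <- yf
        fit <- MASS::polr(stats::as.formula(paste(".y ~", rhs)), data = d,
                          Hess = TRUE)
        b <- coef(fit)[".z"]
        se <- sqrt(diag(vcov(fit))[".z"])
        w <- fit_wald(b, se)
        res$effect <- exp(unname(b)); res$ci_low <- exp(unname(w$lo))
        res$ci_high <- exp(unname(w$hi)); res$p_value <- unname(w$p)
      } else stop_bad_arg("unknown trait type '", type, "'")
      res
    }, error = function(e) {
      res$status <- paste0("failed: ", conditionMessage(e))
      res
    })
    out
  }

  rows <- lapply(names(types), one_trait)
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "sd_delta") <- sd_delta
  class(out) <- c("phewas_result", class(out))
  out
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return the per-test p-value threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop_bad_arg("`alpha` must be in (0, 1)")
  if (n_tests < 1L) stop_bad_arg("`n_tests` must be >= 1")
  alpha / n_tests
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up rule: sort p-values ascending, find the largest k
#' with `p(k) <= k * q / m` and reject those k hypotheses. The adaptive
#' threshold reported is `p(k)` (or 0 when nothing is rejected).
#'
#' @param p_values numeric vector in [0, 1] (NAs are never rejected).
#' @param q target false discovery rate, in (0, 1).
#' @return list with `rejected` (indices into `p_values`) and
#'   `threshold`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (q <= 0 || q >= 1) stop_bad_arg("`q` must be in (0, 1)")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop_bad_arg("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  rejected <- which(!is.na(adj) & adj <= q)
  threshold <- if (length(rejected)) max(p_values[rejected]) else 0
  list(rejected = rejected, threshold = threshold)
}

#' Ranked multiplicity-flagged scan report
#'
#' Sorts scan results by p-value and flags each trait's significance
#' under Bonferroni and Benjamini-Hochberg control, plus the direction
#' of association (direct for positive effects, inverse otherwise; for
#' odds ratios the reference is 1).
#'
#' @param results a `phewas_result` from [association_scan()].
#' @param alpha family-wise alpha for Bonferroni (default 0.05).
#' @param fdr_q FDR level for Benjamini-Hochberg (default 0.05).
#' @param n_tests number of tests for the Bonferroni divisor; defaults
#'   to the number of testable (non-skipped) traits.
#' @return the results sorted by p, with `direction`, `bonferroni_sig`,
#'   `fdr_sig` columns; thresholds in attributes `bonferroni_p` and
#'   `fdr_threshold`.
#' @export
scan_report <- function(results, alpha = 0.05, fdr_q = 0.05,
                        n_tests = NULL) {
  stopifnot(nrow(results) >= 1L)
  tested <- !is.na(results$p_value)
  n_tests <- n_tests %||% sum(tested)
  bonf_p <- bonferroni_threshold(alpha, n_tests)
  bh <- bh_fdr(results$p_value, fdr_q)
  results$direction <- ifelse(
    results$type == "continuous",
    ifelse(results$effect >= 0, "direct", "inverse"),
    ifelse(results$effect >= 1, "direct", "inverse"))
  results$bonferroni_sig <- tested & results$p_value < bonf_p
  results$fdr_sig <- seq_len(nrow(results)) %in% bh$rejected
  out <- results[order(results$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bonferroni_p") <- bonf_p
  attr(out, "fdr_threshold") <- bh$threshold
  out
}

#' Manhattan-style plot of a scan report
#'
#' @param report output of [scan_report()].
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_scan <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_bad_arg("plot_scan needs the ggplot2 package")
  d <- report[!is.na(report$p_value), ]
  d$index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = index, y = -log10(p_value),
                                  colour = type)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(attr(report, "bonferroni_p")),
                        colour = "red") +
    ggplot2::labs(x = "trait", y = expression(-log[10](p)))
}
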