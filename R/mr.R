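#' Harmonise exposure and outcome summary statistics
#'
#' Joins the two tables on `variant_id` and aligns the outcome effects
#' to the exposure's effect allele. Where the outcome's effect allele
#' equals the exposure's other allele (and vice versa), the outcome beta
#' is sign-flipped and its allele frequency complemented. Palindromic
#' variants (A/T, C/G) are ambiguous and dropped by default, or resolved
#' from allele frequency when `palindromic = "infer"` and both
#' frequencies are informative (`|eaf - 0.5| > eaf_tol`). Variants whose
#' allele pairs are incompatible with any flip are dropped with a
#' reason. Every flip and drop is recorded in an audit table.
#'
#' @param exposure,outcome data frames with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and
#'   optionally `eaf`.
#' @param palindromic `"drop"` (default) or `"infer"`.
#' @param eaf_tol minimum distance of eaf from 0.5 for inference.
#' @return list with `variants` (harmonised table: `variant_id`,
#'   alleles, `beta_x`, `se_x`, `p_x`, `eaf_x`, `beta_y`, `se_y`, `p_y`,
#'   `eaf_y`) and `audit` (variant_id, action, reason).
#' @export
harmonise <- function(exposure, outcome, palindromic = c("drop", "infer"),
                      eaf_tol = 0.08) {
  palindromic <- match.arg(palindromic)
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
            "pval")
  stopifnot(all(need %in% names(exposure)), all(need %in% names(outcome)))
  m <- merge(exposure, outcome, by = "variant_id",
             suffixes = c("_x", "_y"))
  audit <- data.frame(variant_id = character(), action = character(),
                      reason = character(), stringsAsFactors = FALSE)
  log_it <- function(id, action, reason) {
    audit <<- rbind(audit, data.frame(variant_id = id, action = action,
                                      reason = reason,
                                      stringsAsFactors = FALSE))
  }
  is_palin <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")

  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    id <- m$variant_id[i]
    ex_ea <- m$effect_allele_x[i]; ex_oa <- m$other_allele_x[i]
    oc_ea <- m$effect_allele_y[i]; oc_oa <- m$other_allele_y[i]
    if (is_palin(ex_ea, ex_oa)) {
      if (palindromic == "drop") {
        log_it(id, "drop", "palindromic")
        next
      }
      ex_eaf <- m$eaf_x[i]; oc_eaf <- m$eaf_y[i]
      if (is.null(ex_eaf) || is.na(ex_eaf) || is.na(oc_eaf) ||
          abs(ex_eaf - 0.5) <= eaf_tol || abs(oc_eaf - 0.5) <= eaf_tol) {
        log_it(id, "drop", "palindromic, eaf uninformative")
        next
      }
      # same-side frequencies mean same strand/orientation
      if ((ex_eaf > 0.5) != (oc_eaf > 0.5)) {
        m$beta_y[i] <- -m$beta_y[i]
        m$eaf_y[i] <- 1 - m$eaf_y[i]
        log_it(id, "flip", "palindromic, inferred from eaf")
      }
      keep[i] <- TRUE
      next
    }
    if (oc_ea == ex_ea && oc_oa == ex_oa) {
      keep[i] <- TRUE
    } else if (oc_ea == ex_oa && oc_oa == ex_ea) {
      m$beta_y[i] <- -m$beta_y[i]
      if ("eaf_y" %in% names(m)) m$eaf_y[i] <- 1 - m$eaf_y[i]
      log_it(id, "flip", "outcome alleles swapped")
      keep[i] <- TRUE
    } else {
      log_it(id, "drop", sprintf("incompatible alleles %s/%s vs %s/%s",
                                 ex_ea, ex_oa, oc_ea, oc_oa))
    }
  }
  v <- m[keep, , drop = FALSE]
  out <- data.frame(variant_id = v$variant_id,
                    effect_allele = v$effect_allele_x,
                    other_allele = v$other_allele_x,
                    beta_x = v$beta_x, se_x = v$se_x, p_x = v$pval_x,
                    eaf_x = if ("eaf_x" %in% names(v)) v$eaf_x else NA,
                    beta_y = v$beta_y, se_y = v$se_y, p_y = v$pval_y,
                    eaf_y = if ("eaf_y" %in% names(v)) v$eaf_y else NA,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(variants = out, audit = audit)
}

#' Greedy LD clumping on a user-supplied r-squared matrix
#'
#' Repeatedly keeps the remaining variant with the smallest exposure
#' p-value (ties broken by `variant_id`) and drops all others whose r2
#' with it is at or above the threshold.
#'
#' @param variants harmonised variant table (needs `variant_id`, `p_x`).
#' @param ld_r2 square symmetric r2 matrix with dimnames (or order)
#'   matching `variants$variant_id`.
#' @param r2_threshold clumping threshold in (0, 1], default 0.1.
#' @return the pruned variant table, in original row order.
#' @export
ld_clump <- function(variants, ld_r2, r2_threshold = 0.1) {
  n <- nrow(variants)
  if (!is.matrix(ld_r2) || nrow(ld_r2) != n || ncol(ld_r2) != n)
    stop_bad_arg("`ld_r2` must be a square matrix aligned to `variants`")
  if (!is.null(rownames(ld_r2)) &&
      !identical(rownames(ld_r2), variants$variant_id))
    stop_bad_arg("`ld_r2` dimnames do not match `variants$variant_id`")
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop_bad_arg("`r2_threshold` must be in (0, 1]")
  remaining <- seq_len(n)
  kept <- integer(0)
  ord <- order(variants$p_x, variants$variant_id)
  while (length(remaining)) {
    cand <- ord[ord %in% remaining][1L]
    kept <- c(kept, cand)
    drop <- remaining[ld_r2[cand, remaining] >= r2_threshold]
    remaining <- setdiff(remaining, union(cand, drop))
  }
  variants[sort(kept), , drop = FALSE]
}

mr_result <- function(method, estimate, se, p_value, n_variants,
                      intercept = NA_real_, intercept_se = NA_real_,
                      intercept_p = NA_real_, q_statistic = NA_real_,
                      q_df = NA_integer_, q_p = NA_real_) {
  structure(list(method = method, estimate = estimate, se = se,
                 p_value = p_value, n_variants = n_variants,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_p = intercept_p, q_statistic = q_statistic,
                 q_df = q_df, q_p = q_p),
            class = "mr_result")
}

#' @export
#' @method print mr_result
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g (se %.3g, p %.3g, n = %d)\n",
              x$method, x$estimate, x$se, x$p_value, x$n_variants))
  if (!is.na(x$intercept))
    cat(sprintf("  intercept %.4g (se %.3g, p %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_p))
  if (!is.na(x$q_statistic))
    cat(sprintf("  Cochran's Q %.4g on %d df (p %.3g)\n",
                x$q_statistic, x$q_df, x$q_p))
  invisible(x)
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect IVW: the weighted regression of outcome betas on
#' exposure betas through the origin with weights `1/se_y^2`, i.e.
#' `sum(bx*by/se_y^2) / sum(bx^2/se_y^2)`, with the fixed-effect
#' standard error `1/sqrt(sum(bx^2/se_y^2))` and a normal two-sided p.
#' Cochran's Q over per-variant ratio estimates is attached with
#' `df = n - 1`.
#'
#' @param variants harmonised variant table (needs `beta_x`, `beta_y`,
#'   `se_y`).
#' @return an `mr_result`.
#' @export
mr_ivw <- function(variants) {
  n <- nrow(variants)
  if (n < 1L) stop_bad_arg("IVW needs >= 1 variant")
  bx <- variants$beta_x; by <- variants$beta_y; sy <- variants$se_y
  if (n == 1L && bx[1L] == 0)
    stop_bad_arg("single variant with zero exposure effect")
  w <- 1 / sy^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  p <- 2 * pnorm(-abs(est / se))
  # Q over ratio estimates with delta-method weights
  ratio <- by / bx
  wq <- bx^2 / sy^2
  q <- sum(wq * (ratio - est)^2)
  q_df <- n - 1L
  q_p <- if (q_df >= 1L) stats::pchisq(q, q_df, lower.tail = FALSE)
         else NA_real_
  mr_result("ivw", est, se, p, n, q_statistic = q, q_df = q_df, q_p = q_p)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept (weights `1/se_y^2`), after orienting every variant so the
#' exposure beta is non-negative. The slope is the causal estimate; the
#' intercept estimates average directional pleiotropy and carries its
#' own test. Standard errors use the weighted-OLS residual variance and
#' t reference with `n - 2` df; Cochran's Q uses `df = n - 2`.
#'
#' @param variants harmonised variant table, >= 3 variants.
#' @return an `mr_result` with intercept fields.
#' @export
mr_egger <- function(variants) {
  n <- nrow(variants)
  if (n < 3L) stop_bad_arg("MR-Egger needs >= 3 variants")
  flip <- sign(variants$beta_x)
  flip[flip == 0] <- 1
  bx <- variants$beta_x * flip
  by <- variants$beta_y * flip
  sy <- variants$se_y
  if (sd(bx) == 0) stop_bad_arg("degenerate design: all beta_x equal")
  w <- 1 / sy^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  sigma2 <- sum(w * resid^2) / (n - 2L)
  se_slope <- sqrt(sigma2 * sw / det)
  se_int <- sqrt(sigma2 * swxx / det)
  tq <- function(b, se) {
    if (se == 0) return(if (b == 0) 1 else 0)
    2 * pt(-abs(b / se), n - 2L)
  }
  q <- sum(w * resid^2)
  mr_result("egger", slope, se_slope, tq(slope, se_slope), n,
            intercept = intercept, intercept_se = se_int,
            intercept_p = tq(intercept, se_int),
            q_statistic = q, q_df = n - 2L,
            q_p = stats::pchisq(q, n - 2L, lower.tail = FALSE))
}

# weighted median interpolated at cumulative weight 0.5
weighted_median_value <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1L] >= 0.5) return(x[1L])
  n <- length(x)
  if (cw[n] <= 0.5) return(x[n])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1L] - x[below]) *
    (0.5 - cw[below]) / (cw[below + 1L] - cw[below])
}

#' Weighted-median causal estimate
#'
#' Per-variant ratio estimates `beta_y / beta_x` are weighted by the
#' inverse variance of the ratio (first-order delta method,
#' `se = se_y / |beta_x|`); the estimate is the weighted median
#' interpolated at cumulative weight 0.5, consistent when valid
#' instruments carry more than half of the weight. The standard error
#' comes from a seeded parametric bootstrap of `(beta_x, beta_y)`.
#'
#' @param variants harmonised variant table (needs `beta_x`, `se_x`,
#'   `beta_y`, `se_y`).
#' @param n_bootstrap bootstrap draws for the se (default 1000; fewer
#'   than 2 draws reports the se and p as `NA`).
#' @param seed integer seed for the bootstrap.
#' @return an `mr_result`.
#' @export
mr_weighted_median <- function(variants, n_bootstrap = 1000L, seed = 1L) {
  n <- nrow(variants)
  if (n < 1L) stop_bad_arg("weighted median needs >= 1 variant")
  if (any(variants$beta_x == 0))
    stop_bad_arg("zero exposure beta makes a ratio undefined")
  bx <- variants$beta_x; by <- variants$beta_y
  sx <- variants$se_x; sy <- variants$se_y
  ratio <- by / bx
  w <- (bx / sy)^2
  est <- weighted_median_value(ratio, w)
  se <- if (n_bootstrap >= 2L && any(sx > 0 | sy > 0)) {
    boots <- with_rng(seed, vapply(seq_len(n_bootstrap), function(i) {
      bxs <- rnorm(n, bx, sx)
      bys <- rnorm(n, by, sy)
      bad <- bxs == 0
      if (any(bad)) bxs[bad] <- bx[bad]
      weighted_median_value(bys / bxs, (bxs / sy)^2)
    }, numeric(1L)))
    sd(boots)
  } else NA_real_
  p <- if (is.na(se)) NA_real_
       else if (se > 0) 2 * pnorm(-abs(est / se))
       else if (est == 0) 1 else 0
  mr_result("weighted_median", est, se, p, n)
}

#' Full two-sample MR analysis
#'
#' Harmonises the two summary-statistics tables, optionally LD-clumps
#' with a supplied r2 matrix, and runs IVW, MR-Egger and the weighted
#' median with heterogeneity (Cochran's Q) and pleiotropy (Egger
#' intercept) tests. With fewer than 3 post-clump variants, Egger is
#' omitted with a warning and IVW plus weighted median are reported.
#'
#' @param exposure,outcome summary-statistics data frames (see
#'   [harmonise()]).
#' @param ld optional square r2 matrix aligned to the harmonised
#'   variants (by `variant_id` dimnames or order).
#' @param r2_threshold clumping threshold (default 0.1).
#' @param n_bootstrap weighted-median bootstrap draws.
#' @param seed integer seed.
#' @param palindromic `"drop"` or `"infer"`, passed to [harmonise()].
#' @return list of class `mr_report`: `results` (one data-frame row per
#'   method with estimate, se, ci, p, intercept and Q columns),
#'   `variants`, `audit`, and flags `pleiotropy_flag` /
#'   `heterogeneity_flag` (Egger intercept p < 0.05, any Q p < 0.05).
#' @export
mr_suite <- function(exposure, outcome, ld = NULL, r2_threshold = 0.1,
                     n_bootstrap = 1000L, seed = 1L,
                     palindromic = c("drop", "infer")) {
  h <- harmonise(exposure, outcome, palindromic = match.arg(palindromic))
  v <- h$variants
  if (!is.null(ld)) {
    if (!is.null(rownames(ld)))
      ld <- ld[v$variant_id, v$variant_id, drop = FALSE]
    v <- ld_clump(v, ld, r2_threshold)
  }
  if (nrow(v) < 1L) stop_bad_arg("no variants left after harmonisation")
  res <- list(mr_ivw(v))
  if (nrow(v) >= 3L) res <- c(res, list(mr_egger(v)))
  else warning("fewer than 3 variants after clumping; MR-Egger omitted")
  res <- c(res, list(mr_weighted_median(v, n_bootstrap, seed)))

  tab <- do.call(rbind, lapply(res, function(r) {
    data.frame(method = r$method, estimate = r$estimate, se = r$se,
               ci_low = r$estimate - qnorm(0.975) * r$se,
               ci_high = r$estimate + qnorm(0.975) * r$se,
               p_value = r$p_value, intercept = r$intercept,
               intercept_se = r$intercept_se, intercept_p = r$intercept_p,
               q_statistic = r$q_statistic, q_df = r$q_df, q_p = r$q_p,
               n_variants = r$n_variants, stringsAsFactors = FALSE)
  }))
  egger <- tab[tab$method == "egger", ]
  structure(list(
    results = tab, variants = v, audit = h$audit,
    pleiotropy_flag = nrow(egger) == 1L && !is.na(egger$intercept_p) &&
      egger$intercept_p < 0.05,
    heterogeneity_flag = any(!is.na(tab$q_p) & tab$q_p < 0.05)),
    class = "mr_report")
}

#' @export
#' @method print mr_report
print.mr_report <- function(x, ...) {
  print(x$results[, c("method", "estimate", "se", "p_value",
                      "q_statistic", "q_p", "n_variants")], row.names = FALSE)
  if (x$pleiotropy_flag) cat("flag: Egger intercept p < 0.05 (pleiotropy)\n")
  if (x$heterogeneity_flag) cat("flag: heterogeneity (Q p < 0.05)\n")
  invisible(x)
}
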