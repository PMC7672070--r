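#' Split a cohort into train / validation / healthy-test / general-test
#'
#' Random, seed-reproducible assignment mirroring a healthy-stratified
#' study design: the training, validation and healthy-test sets contain
#' only subjects flagged healthy; every unhealthy subject lands in the
#' general (unselected) test set, alongside the remaining healthy
#' subjects.
#'
#' @param subjects character vector of subject ids (unique).
#' @param healthy_flags logical vector, same length.
#' @param fractions numeric length 4 summing to 1: target fractions of
#'   the full cohort for train, validation, healthy-test and
#'   general-test.
#' @param seed integer seed.
#' @return a `split_plan`: list of id vectors `train`, `validation`,
#'   `healthy_test`, `general_test`, plus `healthy` (named logical).
#' @export
make_split <- function(subjects, healthy_flags,
                       fractions = c(0.25, 0.25, 0.25, 0.25), seed = 1L) {
  n <- length(subjects)
  stopifnot(length(healthy_flags) == n, !anyDuplicated(subjects))
  if (length(fractions) != 4L || abs(sum(fractions) - 1) > 1e-8)
    stop_bad_arg("`fractions` must be 4 values summing to 1")
  sizes <- floor(fractions[1:3] * n)
  healthy_ids <- subjects[healthy_flags]
  if (length(healthy_ids) < sum(sizes))
    stop_bad_arg("healthy pool (", length(healthy_ids),
                 ") smaller than requested healthy-only sets (",
                 sum(sizes), ")")
  with_rng(seed, {
    pick <- sample(healthy_ids, sum(sizes))
    train <- pick[seq_len(sizes[1L])]
    validation <- pick[sizes[1L] + seq_len(sizes[2L])]
    healthy_test <- pick[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]
    general_test <- setdiff(subjects, pick)
    structure(list(train = train, validation = validation,
                   healthy_test = healthy_test,
                   general_test = general_test,
                   healthy = setNames(healthy_flags, subjects)),
              class = "split_plan")
  })
}

#' @export
#' @method print split_plan
print.split_plan <- function(x, ...) {
  cat("split_plan: train", length(x$train),
      "| validation", length(x$validation),
      "| healthy_test", length(x$healthy_test),
      "| general_test", length(x$general_test), "\n")
  invisible(x)
}
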