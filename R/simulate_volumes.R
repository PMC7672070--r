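#' Simulate a cohort of volumes with planted age signal
#'
#' Generates `n_subjects` single-channel volumes on the atlas grid.
#' Each atlas region gets a region-specific baseline intensity; in the
#' designated signal regions the region mean additionally shifts linearly
#' with the subject's "brain-apparent" age, i.e. chronological age plus an
#' optional subject-level gap `delta_true`. Non-signal regions are
#' age-independent. i.i.d. Gaussian voxel noise is added on top. This is
#' the simplest mechanism both a 3D CNN and a voxel-regression oracle can
#' detect, giving every downstream stage a recoverable ground truth.
#'
#' The apparent age entering the signal is `age + delta_true`, so a
#' subject with a positive planted gap genuinely looks older to any
#' predictor, and trait associations with `delta_true` have a ground
#' truth independent of model error.
#'
#' @param atlas an `atlas` from [generate_atlas()].
#' @param n_subjects number of subjects (>= 2).
#' @param age_range numeric length 2; ages drawn uniformly in this range
#'   (years). Default `c(45, 80)`, matching a middle/older-aged cohort.
#' @param signal_regions region ids carrying age signal (subset of
#'   `atlas$region_ids`). May be empty for a pure-noise cohort.
#' @param effect_size intensity change per year of apparent age in signal
#'   regions (default 0.2).
#' @param noise_sd voxel noise standard deviation (default 1).
#' @param delta_sd standard deviation of the planted brain-age gap
#'   `delta_true` in years (default 3.72); set 0 for no gap.
#' @param seed integer seed.
#' @return list with `volumes` (list of `volume_sample`: `subject_id`,
#'   `voxels` 3D array, `age`), and `truth` (class `cohort_truth`:
#'   `delta_true`, `signal_regions`, `effect_size`, `noise_sd`, `ages`,
#'   `age_mid`, `pure_noise` flag, `seed`).
#' @export
generate_volumes <- function(atlas, n_subjects, age_range = c(45, 80),
                             signal_regions = integer(),
                             effect_size = 0.2, noise_sd = 1,
                             delta_sd = 3.72, seed = 1L) {
  stopifnot(inherits(atlas, "atlas"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop_bad_arg("`n_subjects` must be >= 2")
  signal_regions <- as.integer(signal_regions)
  if (!all(signal_regions %in% atlas$region_ids))
    stop_bad_arg("`signal_regions` must be a subset of atlas$region_ids")
  if (noise_sd < 0 || delta_sd < 0)
    stop_bad_arg("`noise_sd` and `delta_sd` must be non-negative")

  dimv <- atlas$shape
  nvox <- prod(dimv)
  lab <- as.integer(atlas$labels)
  age_mid <- mean(age_range)

  with_rng(seed, {
    ages <- runif(n_subjects, age_range[1L], age_range[2L])
    delta_true <- if (delta_sd > 0) rnorm(n_subjects, 0, delta_sd)
                  else numeric(n_subjects)
    # fixed per-region baseline intensities, shared by the whole cohort
    base_by_region <- runif(length(atlas$region_ids), 10, 20)
    base <- numeric(nvox)
    base[lab > 0L] <- base_by_region[match(lab[lab > 0L], atlas$region_ids)]
    sig_mask <- lab %in% signal_regions

    volumes <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      apparent <- ages[i] + delta_true[i]
      v <- base
      if (any(sig_mask))
        v[sig_mask] <- v[sig_mask] + effect_size * (apparent - age_mid)
      if (noise_sd > 0)
        v <- v + rnorm(nvox, 0, noise_sd)
      volumes[[i]] <- structure(
        list(subject_id = sprintf("S%04d", i),
             voxels = array(v, dim = dimv),
             age = ages[i]),
        class = "volume_sample")
    }
    truth <- structure(
      list(delta_true = delta_true, signal_regions = signal_regions,
           effect_size = effect_size, noise_sd = noise_sd,
           ages = ages, age_mid = age_mid,
           pure_noise = length(signal_regions) == 0L, seed = seed),
      class = "cohort_truth")
    list(volumes = volumes, truth = truth)
  })
}

# stack a list of volume_samples into a matrix (voxels x subjects)
volumes_to_matrix <- function(volumes) {
  stopifnot(length(volumes) >= 1L)
  d <- dim(volumes[[1L]]$voxels)
  vapply(volumes, function(v) {
    if (!identical(dim(v$voxels), d))
      stop_bad_arg("volumes have inconsistent shapes")
    as.numeric(v$voxels)
  }, numeric(prod(d)))
}

cohort_ages <- function(volumes) vapply(volumes, `[[`, numeric(1L), "age")
cohort_ids  <- function(volumes) vapply(volumes, `[[`, character(1L), "subject_id")
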