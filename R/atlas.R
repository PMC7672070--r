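#' Generate a synthetic brain parcellation
#'
#' Builds an integer-labelled atlas on a 3D grid: a central ellipsoidal
#' "brain" mask is partitioned into `n_regions` contiguous regions by
#' nearest-seed (Voronoi) assignment from randomly placed seed voxels.
#' Voxels outside the mask keep the background label 0. Any disjoint
#' partition of the mask satisfies downstream contracts; the Voronoi
#' construction simply guarantees contiguous, non-empty regions.
#'
#' @param shape integer vector of length 3, grid dimensions (each >= 4).
#' @param n_regions number of regions (>= 1).
#' @param seed integer seed; the same seed reproduces the atlas exactly.
#' @return An object of class `atlas`: list with `labels` (3D integer
#'   array, 0 = background), `shape`, and `region_ids` (sorted distinct
#'   non-zero labels).
#' @examples
#' atl <- generate_atlas(c(16, 16, 16), n_regions = 5, seed = 1)
#' table(atl$labels[atl$labels > 0])
#' @export
generate_atlas <- function(shape, n_regions, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop_bad_arg("`shape` must be three dimensions, each >= 4")
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop_bad_arg("`n_regions` must be >= 1")

  # ellipsoidal mask centred in the grid, semi-axes at 40% of each extent
  cx <- (shape + 1) / 2
  ax <- pmax(shape * 0.4, 1)
  g <- expand.grid(x = seq_len(shape[1L]), y = seq_len(shape[2L]),
                   z = seq_len(shape[3L]))
  d2 <- ((g$x - cx[1L]) / ax[1L])^2 + ((g$y - cx[2L]) / ax[2L])^2 +
    ((g$z - cx[3L]) / ax[3L])^2
  in_mask <- d2 <= 1
  n_mask <- sum(in_mask)
  if (n_mask < n_regions)
    stop_bad_arg("shape too small: mask holds ", n_mask, " voxels for ",
                 n_regions, " regions")

  labels <- integer(prod(shape))
  mask_idx <- which(in_mask)
  if (n_regions == 1L) {
    labels[mask_idx] <- 1L
  } else {
    seeds <- with_rng(seed, sample(mask_idx, n_regions))
    sx <- g$x[seeds]; sy <- g$y[seeds]; sz <- g$z[seeds]
    # nearest seed per mask voxel; ties go to the lower region id
    best_d <- rep(Inf, n_mask)
    best_r <- integer(n_mask)
    mx <- g$x[mask_idx]; my <- g$y[mask_idx]; mz <- g$z[mask_idx]
    for (r in seq_len(n_regions)) {
      dr <- (mx - sx[r])^2 + (my - sy[r])^2 + (mz - sz[r])^2
      upd <- dr < best_d
      best_d[upd] <- dr[upd]
      best_r[upd] <- r
    }
    labels[mask_idx] <- best_r
  }
  labels <- array(labels, dim = shape)
  structure(
    list(labels = labels, shape = shape,
         region_ids = sort(unique(as.integer(labels[labels > 0L])))),
    class = "atlas"
  )
}

#' @export
#' @method print atlas
print.atlas <- function(x, ...) {
  cat("atlas:", paste(x$shape, collapse = " x "), "grid,",
      length(x$region_ids), "regions,",
      sum(x$labels > 0L), "foreground voxels\n")
  invisible(x)
}

# voxel linear indices of one region
region_voxels <- function(atlas, region_id) {
  idx <- which(atlas$labels == region_id)
  if (length(idx) == 0L)
    stop_bad_arg("region ", region_id, " not present in atlas")
  idx
}
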