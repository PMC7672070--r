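# File interchange: NIfTI volumes/atlas via RNifti, tables as TSV.

#' Write a cohort as a 4D NIfTI plus an age table
#'
#' Volumes are stacked on the 4th axis of a single `.nii.gz` with a
#' shared identity-scaled affine; subject ids and ages go to a TSV next
#' to it.
#'
#' @param volumes list of `volume_sample`s.
#' @param path output path for the NIfTI (e.g. `cohort.nii.gz`); the
#'   age table is written to `<path>.ages.tsv`.
#' @return `path`, invisibly.
#' @export
write_cohort_nifti <- function(volumes, path) {
  X <- volumes_to_matrix(volumes)
  d <- dim(volumes[[1L]]$voxels)
  arr <- array(X, dim = c(d, length(volumes)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  write.table(data.frame(subject_id = cohort_ids(volumes),
                         age = cohort_ages(volumes)),
              paste0(path, ".ages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort_nifti()]
#'
#' @param path path to the NIfTI file.
#' @return list of `volume_sample`s.
#' @export
read_cohort_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  meta <- read.delim(paste0(path, ".ages.tsv"), stringsAsFactors = FALSE)
  d <- dim(arr)
  stopifnot(length(d) == 4L, d[4L] == nrow(meta))
  lapply(seq_len(d[4L]), function(i) {
    structure(list(subject_id = meta$subject_id[i],
                   voxels = array(arr[, , , i], dim = d[1:3]),
                   age = meta$age[i]),
              class = "volume_sample")
  })
}

#' Write an atlas as an integer-labelled NIfTI
#' @param atlas an `atlas`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas_nifti <- function(atlas, path) {
  RNifti::writeNifti(RNifti::asNifti(atlas$labels), path,
                     datatype = "int16")
  invisible(path)
}

#' Read an atlas from a labelled NIfTI
#' @param path path to the NIfTI file.
#' @return an `atlas`.
#' @export
read_atlas_nifti <- function(path) {
  img <- as.array(RNifti::readNifti(path))
  lab <- array(as.integer(round(img)), dim = dim(img))
  structure(list(labels = lab, shape = dim(lab),
                 region_ids = sort(unique(as.integer(lab[lab > 0L])))),
            class = "atlas")
}

#' Write a trait table with its type sidecar
#'
#' The table goes to `path` as TSV; the declared trait types go to
#' `<path>.types.tsv` as a two-column key-value file.
#'
#' @param traits table from [generate_traits()] (or any data frame with
#'   a `trait_types` attribute).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_traits_tsv <- function(traits, path) {
  write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  types <- attr(traits, "trait_types")
  write.table(data.frame(trait = names(types), type = unname(types)),
              paste0(path, ".types.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a trait table and its type sidecar
#' @param path TSV path written by [write_traits_tsv()].
#' @return data frame with the `trait_types` attribute restored and
#'   `sex`/`centre` as factors.
#' @export
read_traits_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("sex", "centre"), names(out)))
    out[[col]] <- factor(out[[col]])
  ty <- read.delim(paste0(path, ".types.tsv"), stringsAsFactors = FALSE)
  attr(out, "trait_types") <- setNames(ty$type, ty$trait)
  out
}

#' Write GWAS-style summary statistics as TSV
#' @param stats data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`, `eaf`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sumstats_tsv <- function(stats, path) {
  cols <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
            "pval", "eaf")
  stopifnot(all(cols %in% names(stats)))
  write.table(stats[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read GWAS-style summary statistics from TSV
#' @param path TSV path.
#' @return data frame.
#' @export
read_sumstats_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write prediction records as TSV
#' @param records data frame from [apply_bias_correction()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
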