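# Voxel-to-region bookkeeping: masks per atlas region and per-region
# mean uptake summaries. A voxel belongs wholly to its label (hard
# parcellation); background (label 0) is never a region.

#' Extract one region's voxel mask
#'
#' @param atlas a [label_volume()].
#' @param region_id a positive region id present in the atlas registry.
#' @return A `region_mask`: list with `region_id`, `voxel_indices`
#'   (linear 1-based indices into the label array, sorted), and
#'   `n_voxels`.
#' @export
region_mask <- function(atlas, region_id) {
  stopifnot(inherits(atlas, "label_volume"))
  region_id <- as.integer(region_id)
  if (length(region_id) != 1L || is.na(region_id) || region_id < 1L)
    stop("region_id must be a single positive integer (0 is background)",
         call. = FALSE)
  idx <- which(atlas$labels == region_id)
  if (length(idx) == 0L)
    stop(sprintf("region %d has no voxels in this atlas", region_id),
         call. = FALSE)
  structure(list(region_id = region_id, voxel_indices = idx,
                 n_voxels = length(idx), grid = atlas$grid),
            class = "region_mask")
}

#' Mean uptake over a region
#'
#' @param volume a [pet_volume()] grid-congruent with the mask's atlas.
#' @param mask a [region_mask()].
#' @return Arithmetic mean of the volume's values over the mask voxels.
#' @export
region_mean_uptake <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "region_mask"))
  stop_if_incongruent(volume$grid, mask$grid, "scan and region mask")
  if (mask$n_voxels == 0L)
    stop(sprintf("region %d is empty", mask$region_id), call. = FALSE)
  mean(volume$values[mask$voxel_indices])
}

#' Per-subject, per-region mean uptake table
#'
#' Computes the dense subjects x regions matrix of regional mean uptake.
#' Regions absent from the atlas are dropped with a warning (and thus
#' excluded from the downstream multiple-testing count); on the bundled
#' phantom atlas all 116 regions are always present.
#'
#' @param cohort a [cohort()].
#' @param atlas a [label_volume()].
#' @param registry matching region registry.
#' @param denoise `NULL`, or a [shrinkage_config()] to apply to each
#'   volume before averaging.
#' @return Numeric matrix, rows ordered as the cohort (rownames =
#'   subject ids), columns ordered by region id (colnames = ids).
#' @export
regional_mean_table <- function(cohort, atlas, registry, denoise = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(atlas, "label_volume"))
  validate_registry(registry)
  present <- sort(unique(as.vector(atlas$labels)))
  present <- present[present > 0L]
  keep <- registry$region_id[registry$region_id %in% present]
  missing <- setdiff(registry$region_id, present)
  if (length(missing) > 0L)
    warning(sprintf("%d registry region(s) absent from atlas, dropped: %s",
                    length(missing),
                    paste(utils::head(missing, 10L), collapse = ", ")))
  labs <- as.vector(atlas$labels)
  sel <- labs > 0L
  labs <- labs[sel]
  n <- length(cohort)
  out <- matrix(NA_real_, n, length(keep),
                dimnames = list(cohort$subject_id, keep))
  for (i in seq_len(n)) {
    vol <- cohort_volume(cohort, i)
    if (!check_grid_congruent(vol$grid, atlas$grid))
      stop(sprintf("subject %s: volume grid incongruent with atlas",
                   cohort$subject_id[i]), call. = FALSE)
    if (!is.null(denoise)) vol <- denoise_volume(vol, denoise)
    sums <- rowsum(vol$values[sel], labs)
    cnts <- rowsum(rep(1, length(labs)), labs)
    m <- sums / cnts
    out[i, ] <- m[match(keep, as.integer(rownames(sums))), 1L]
  }
  out
}
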