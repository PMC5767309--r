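# Synthetic phantom cohorts: a deterministic 116-parcel atlas inside an
# ellipsoidal "brain", plus seeded NC-like and MCI-like uptake volumes.
# MCI subjects receive localized, radially symmetric Gaussian deposits
# in a configurable set of affected regions; both groups share a smooth
# multiplicative bias field and additive Gaussian noise.

# Regions reported significant in the reference analysis; the phantom
# plants its deposits there by default.
DEFAULT_AFFECTED_REGIONS <- c(
  "Cerebelum_3_L", "Cerebelum_8_R", "Cingulum_Post_L",
  "Olfactory_L", "Olfactory_R",
  "Vermis_1_2", "Vermis_3", "Vermis_8", "Vermis_9")

#' Simulation profile for the synthetic cohort
#'
#' Bundles every tunable of the phantom generator. Defaults mirror the
#' study demography (19 NC, 65 MCI) and a strongly separable effect:
#' deposit peak amplitude four times the noise SD. `blob_amplitude = NULL`
#' resolves to `amplitude_factor * noise_sd`.
#'
#' @param n_nc,n_mci group sizes.
#' @param grid_shape voxel counts per axis (each >= 32).
#' @param affected_regions names of regions receiving deposits in MCI.
#' @param blobs_per_region deposits per affected region.
#' @param blob_amplitude deposit peak height (uptake units), or `NULL`.
#' @param amplitude_factor deposit peak as a multiple of `noise_sd`
#'   (used when `blob_amplitude` is `NULL`; 4 = strong default, 1 = weak).
#' @param blob_width deposit Gaussian sigma, voxels.
#' @param background_level baseline uptake inside the brain mask.
#' @param noise_sd additive Gaussian noise SD.
#' @param bias_amplitude peak fractional deviation of the smooth
#'   multiplicative bias field (0.05 = +-5 percent).
#' @param seed master seed; per-subject streams are derived from it.
#' @return A `sim_profile` list.
#' @export
simulation_profile <- function(n_nc = 19L, n_mci = 65L,
                               grid_shape = c(64L, 64L, 64L),
                               affected_regions = DEFAULT_AFFECTED_REGIONS,
                               blobs_per_region = 3L,
                               blob_amplitude = NULL,
                               amplitude_factor = 4,
                               blob_width = 2.5,
                               background_level = 100,
                               noise_sd = 10,
                               bias_amplitude = 0.05,
                               seed = 42L) {
  if (is.null(blob_amplitude)) blob_amplitude <- amplitude_factor * noise_sd
  stopifnot(n_nc >= 0L, n_mci >= 0L, blob_width > 0, noise_sd >= 0,
            blobs_per_region >= 0L, bias_amplitude >= 0)
  structure(list(
    n_nc = as.integer(n_nc), n_mci = as.integer(n_mci),
    grid_shape = as.integer(grid_shape),
    affected_regions = affected_regions,
    blobs_per_region = as.integer(blobs_per_region),
    blob_amplitude = blob_amplitude, blob_width = blob_width,
    background_level = background_level, noise_sd = noise_sd,
    bias_amplitude = bias_amplitude, seed = as.integer(seed)),
    class = "sim_profile")
}

# Run `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Build the deterministic phantom atlas
#'
#' Partitions an ellipsoidal brain mask (semi-axes 0.45 of each grid
#' dimension) into exactly 116 contiguous, near-equal-sized parcels by
#' recursive balanced bisection along the longest axis (a KD-style
#' median cut). Region ids 1..116 follow the recursion order
#' (lower-coordinate half first), so the labelling is fully deterministic.
#'
#' @param grid_shape voxel counts per axis, each >= 32.
#' @param n_regions number of parcels (116 for the standard registry).
#' @return A list with elements `atlas` (a [label_volume()]) and
#'   `registry` (from [aal_region_registry()]).
#' @export
build_phantom_atlas <- function(grid_shape = c(64L, 64L, 64L),
                                n_regions = 116L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L))
    stop("each grid dimension must be >= 32", call. = FALSE)
  grid <- vol_grid(grid_shape, voxel_size = c(2, 2, 2))
  ctr <- (grid_shape - 1) / 2
  ax <- 0.45 * grid_shape
  # 0-based voxel coordinates inside the ellipsoid
  xs <- (seq_len(grid_shape[1]) - 1 - ctr[1]) / ax[1]
  ys <- (seq_len(grid_shape[2]) - 1 - ctr[2]) / ax[2]
  zs <- (seq_len(grid_shape[3]) - 1 - ctr[3]) / ax[3]
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  inside <- which(r2 <= 1)
  if (length(inside) < 50L * n_regions)
    stop(sprintf("grid too small: %d brain voxels cannot host %d parcels",
                 length(inside), n_regions), call. = FALSE)
  coord <- arrayInd(inside, grid_shape)
  labels <- integer(prod(grid_shape))
  next_id <- 1L
  # iterative balanced bisection; stack holds (row indices, region count)
  stack <- list(list(rows = seq_len(nrow(coord)), n = as.integer(n_regions)))
  while (length(stack) > 0L) {
    task <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (task$n == 1L) {
      labels[inside[task$rows]] <- next_id
      next_id <- next_id + 1L
      next
    }
    sub <- coord[task$rows, , drop = FALSE]
    span <- apply(sub, 2, function(v) diff(range(v)))
    axis <- which.max(span)
    ord <- order(sub[, axis], sub[, (axis %% 3L) + 1L],
                 sub[, ((axis + 1L) %% 3L) + 1L])
    n1 <- task$n %/% 2L
    k <- round(length(task$rows) * n1 / task$n)
    left <- task$rows[ord[seq_len(k)]]
    right <- task$rows[ord[(k + 1L):length(ord)]]
    # push right first so the lower half is labelled first (LIFO)
    stack[[length(stack) + 1L]] <- list(rows = right, n = task$n - n1)
    stack[[length(stack) + 1L]] <- list(rows = left, n = n1)
  }
  atlas <- label_volume(array(labels, dim = grid_shape), grid)
  registry <- aal_region_registry()
  if (n_regions != nrow(registry))
    registry <- data.frame(region_id = seq_len(n_regions),
                           name = sprintf("Region_%03d", seq_len(n_regions)),
                           compartment = "custom",
                           stringsAsFactors = FALSE)
  list(atlas = atlas, registry = registry)
}

#' Simulate one subject volume on a phantom atlas
#'
#' Baseline uptake inside the brain mask is modulated by a smooth
#' subject-specific multiplicative bias field (low-order polynomial,
#' peak deviation `bias_amplitude`) and perturbed by additive Gaussian
#' noise. For `group = "MCI"`, each affected region additionally receives
#' `blobs_per_region` radially symmetric Gaussian deposits (peak
#' `blob_amplitude`, width `blob_width` voxels) at seeded random centres;
#' deposits are confined to their region's mask so the planted effect
#' stays region-specific. Voxels outside the brain mask are exactly 0.
#' An NC and an MCI subject simulated with the same `seed` share the
#' identical bias field and noise realisation, differing only by the
#' deposits.
#'
#' @param atlas a [label_volume()] from [build_phantom_atlas()].
#' @param registry matching region registry.
#' @param profile a [simulation_profile()].
#' @param group `"NC"` or `"MCI"`.
#' @param seed per-subject RNG seed.
#' @return A [pet_volume()].
#' @export
simulate_subject <- function(atlas, registry, profile, group, seed) {
  stopifnot(inherits(atlas, "label_volume"), inherits(profile, "sim_profile"))
  group <- as.character(normalize_group(group))
  shape <- atlas$grid$shape
  labels <- atlas$labels
  mask <- labels > 0L
  nmask <- sum(mask)
  with_seed(seed, {
    # smooth multiplicative bias: quadratic polynomial in centred coords
    u <- lapply(1:3, function(a)
      2 * (seq_len(shape[a]) - 1) / max(shape[a] - 1, 1) - 1)
    cf <- stats::rnorm(9)
    b <- array(0, dim = shape)
    terms <- list(
      function() outer(outer(u[[1]], rep(1, shape[2])), rep(1, shape[3])),
      function() outer(outer(rep(1, shape[1]), u[[2]]), rep(1, shape[3])),
      function() outer(outer(rep(1, shape[1]), rep(1, shape[2])), u[[3]]),
      function() outer(outer(u[[1]], u[[2]]), rep(1, shape[3])),
      function() outer(outer(u[[1]], rep(1, shape[2])), u[[3]]),
      function() outer(outer(rep(1, shape[1]), u[[2]]), u[[3]]),
      function() outer(outer(u[[1]]^2, rep(1, shape[2])), rep(1, shape[3])),
      function() outer(outer(rep(1, shape[1]), u[[2]]^2), rep(1, shape[3])),
      function() outer(outer(rep(1, shape[1]), rep(1, shape[2])), u[[3]]^2))
    for (i in seq_along(terms)) b <- b + cf[i] * terms[[i]]()
    mx <- max(abs(b))
    if (mx > 0) b <- profile$bias_amplitude * b / mx
    vals <- array(0, dim = shape)
    vals[mask] <- profile$background_level * (1 + b[mask])
    noise <- stats::rnorm(nmask, sd = profile$noise_sd)
    if (group == "MCI" && profile$blob_amplitude != 0 &&
        profile$blobs_per_region > 0L) {
      ids <- region_id_by_name(registry, profile$affected_regions)
      for (rid in ids) {
        vox <- which(labels == rid)
        if (length(vox) < profile$blobs_per_region)
          stop(sprintf(
            "region %d has %d voxels; cannot place %d deposits",
            rid, length(vox), profile$blobs_per_region), call. = FALSE)
        centers <- vox[sample.int(length(vox), profile$blobs_per_region)]
        cc <- arrayInd(centers, shape)
        # add deposits over the region's bounding box, clipped to the region
        rc <- arrayInd(vox, shape)
        for (k in seq_len(nrow(cc))) {
          d2 <- (rc[, 1] - cc[k, 1])^2 + (rc[, 2] - cc[k, 2])^2 +
            (rc[, 3] - cc[k, 3])^2
          vals[vox] <- vals[vox] +
            profile$blob_amplitude * exp(-d2 / (2 * profile$blob_width^2))
        }
      }
    }
    vals[mask] <- vals[mask] + noise
    pet_volume(vals, atlas$grid)
  })
}

#' Simulate a full cohort
#'
#' Builds the phantom atlas for `profile$grid_shape`, derives one
#' independent RNG seed per subject from `profile$seed`, and simulates
#' `n_nc` NC plus `n_mci` MCI subjects. Deterministic given the profile.
#'
#' @param profile a [simulation_profile()].
#' @param dir optional directory: when given, every volume plus
#'   `atlas.nii.gz`, `registry.tsv` and `manifest.tsv` are written there
#'   and the cohort references files; otherwise volumes stay in memory.
#' @return A list with elements `cohort`, `atlas`, `registry`.
#' @export
simulate_cohort <- function(profile = simulation_profile(), dir = NULL) {
  ph <- build_phantom_atlas(profile$grid_shape)
  n <- profile$n_nc + profile$n_mci
  groups <- c(rep("NC", profile$n_nc), rep("MCI", profile$n_mci))
  ids <- c(sprintf("NC_%03d", seq_len(profile$n_nc)),
           sprintf("MCI_%03d", seq_len(profile$n_mci)))
  seeds <- with_seed(profile$seed,
                     sample.int(.Machine$integer.max, max(n, 1L)))
  refs <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- simulate_subject(ph$atlas, ph$registry, profile, groups[i],
                            seeds[i])
    if (is.null(dir)) {
      refs[[i]] <- vol
    } else {
      p <- file.path(dir, paste0(ids[i], ".nii.gz"))
      write_volume(vol, p)
      refs[[i]] <- p
    }
  }
  co <- cohort(ids, groups, refs)
  if (!is.null(dir)) {
    write_volume(ph$atlas, file.path(dir, "atlas.nii.gz"))
    write_registry(ph$registry, file.path(dir, "registry.tsv"))
    # manifest paths relative to its own directory, for portability
    write_manifest(cohort(ids, groups, vapply(refs, basename, "")),
                   file.path(dir, "manifest.tsv"))
  }
  list(cohort = co, atlas = ph$atlas, registry = ph$registry)
}
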