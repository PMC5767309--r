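#' Voxel grid of a volume
#'
#' A `vol_grid` ties a voxel lattice to world space: the voxel counts per
#' axis, the physical voxel size in mm, and the 4x4 homogeneous affine
#' mapping 0-based voxel indices to world coordinates (RAS+ convention,
#' as in the NIfTI standard).
#'
#' @param shape integer vector of length 3, voxel counts per axis.
#' @param voxel_size numeric vector of length 3, mm per voxel along each
#'   axis. Ignored when `affine` is supplied (it is then derived from the
#'   affine's column norms).
#' @param affine 4x4 voxel-index-to-world transform. Defaults to a
#'   diagonal scaling by `voxel_size` centred on the volume.
#' @return A `vol_grid` object with fields `shape`, `voxel_size`, `affine`.
#' @export
vol_grid <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (is.null(affine)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
        any(voxel_size <= 0))
      stop("`voxel_size` must be 3 positive reals", call. = FALSE)
    affine <- diag(c(voxel_size, 1))
    # centre the grid on the world origin
    affine[1:3, 4] <- -voxel_size * (shape - 1L) / 2
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
      stop("`affine` must be a finite 4x4 matrix", call. = FALSE)
    if (abs(det(affine)) < 1e-12)
      stop("`affine` must be invertible", call. = FALSE)
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(voxel_size <= 0))
      stop("degenerate affine: zero-length voxel axis", call. = FALSE)
  }
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Test whether two grids are congruent
#'
#' Two grids are congruent when their shapes are identical and their
#' affines agree entrywise within `tol`. Every cross-volume operation in
#' the pipeline (scan vs. atlas, scan vs. scan) requires congruent grids;
#' this encodes the assumption that all inputs live on one common
#' template grid.
#'
#' @param a,b `vol_grid` objects.
#' @param tol entrywise tolerance on the affines (mm).
#' @return `TRUE` or `FALSE`.
#' @export
check_grid_congruent <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "vol_grid"), inherits(b, "vol_grid"))
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

stop_if_incongruent <- function(a, b, what = "volumes", tol = 1e-4) {
  if (!check_grid_congruent(a, b, tol))
    stop(sprintf("grid mismatch between %s: shapes %s vs %s", what,
                 paste(a$shape, collapse = "x"),
                 paste(b$shape, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Scalar intensity volume
#'
#' Container for one 3D scalar field (tracer uptake, arbitrary units) on
#' a [vol_grid()]. Values must be finite.
#'
#' @param values 3D numeric array matching `grid$shape`.
#' @param grid a [vol_grid()].
#' @return A `pet_volume` object with fields `grid` and `values`.
#' @export
pet_volume <- function(values, grid) {
  stopifnot(inherits(grid, "vol_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop("value array shape does not match grid shape", call. = FALSE)
  nbad <- sum(!is.finite(values))
  if (nbad > 0L)
    stop(sprintf("volume contains %d non-finite voxel(s)", nbad),
         call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s, range [%.4g, %.4g]\n",
              paste(x$grid$shape, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Integer label volume (parcellation atlas)
#'
#' Nonnegative integer label per voxel; 0 is background. Nonzero labels
#' index regions of an accompanying region registry.
#'
#' @param labels 3D integer array matching `grid$shape`.
#' @param grid a [vol_grid()].
#' @return A `label_volume` with fields `grid` and `labels`.
#' @export
label_volume <- function(labels, grid) {
  stopifnot(inherits(grid, "vol_grid"))
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L || !all(dim(labels) == grid$shape))
    stop("label array shape does not match grid shape", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("labels must be nonnegative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(grid = grid, labels = labels), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, %d regions\n",
              paste(x$grid$shape, collapse = "x"),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}
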