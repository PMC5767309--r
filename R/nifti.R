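# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Only the fields the pipeline needs are interpreted: dim, datatype,
# pixdim, scl_slope/inter, and the sform/qform affines. Data are always
# written as float32 with an sform affine; gzip compression is chosen by
# the file extension.

NIFTI_TYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

quaternion_to_affine <- function(b, c, d, qoffset, pixdim, qfac) {
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 > 0) sqrt(a2) else 0
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c),
    nrow = 3, byrow = FALSE)
  S <- diag(pixdim[1:3])
  S[3, 3] <- S[3, 3] * qfac
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% S
  aff[1:3, 4] <- qoffset
  aff
}

read_nifti_header <- function(con) {
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header", call. = FALSE)
  rd <- function(off, what, n, size, endian, signed = TRUE) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic)", call. = FALSE)
  dim <- rd(40L, "integer", 8L, 2L, endian)
  pixdim <- rd(76L, "double", 8L, 4L, endian)
  list(
    endian = endian,
    ndim = dim[1], dim = dim[2:8],
    datatype = rd(70L, "integer", 1L, 2L, endian),
    bitpix = rd(72L, "integer", 1L, 2L, endian),
    qfac = if (pixdim[1] < 0) -1 else 1,
    pixdim = pixdim[2:8],
    vox_offset = rd(108L, "double", 1L, 4L, endian),
    scl_slope = rd(112L, "double", 1L, 4L, endian),
    scl_inter = rd(116L, "double", 1L, 4L, endian),
    qform_code = rd(252L, "integer", 1L, 2L, endian),
    sform_code = rd(254L, "integer", 1L, 2L, endian),
    quatern = rd(256L, "double", 3L, 4L, endian),
    qoffset = rd(268L, "double", 3L, 4L, endian),
    srow = rbind(rd(280L, "double", 4L, 4L, endian),
                 rd(296L, "double", 4L, 4L, endian),
                 rd(312L, "double", 4L, 4L, endian))
  )
}

nifti_affine <- function(h) {
  if (h$sform_code > 0L) {
    aff <- diag(4)
    aff[1:3, ] <- h$srow
    aff
  } else if (h$qform_code > 0L) {
    quaternion_to_affine(h$quatern[1], h$quatern[2], h$quatern[3],
                         h$qoffset, h$pixdim, h$qfac)
  } else {
    pd <- ifelse(h$pixdim[1:3] > 0, h$pixdim[1:3], 1)
    diag(c(pd, 1))
  }
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a
#' [pet_volume()]. Integer and float data types are converted to double;
#' `scl_slope`/`scl_inter` scaling is applied when set. The sform affine
#' is preferred, then the qform, then a diagonal `pixdim` affine.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [pet_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  h <- read_nifti_header(con)
  extra <- h$dim[seq_len(h$ndim)][-(1:3)]
  if (h$ndim < 3L || (h$ndim > 3L && any(extra > 1L)))
    stop(sprintf("expected a 3D volume, got %dD (dim = %s)", h$ndim,
                 paste(h$dim[seq_len(h$ndim)], collapse = "x")),
         call. = FALSE)
  spec <- NIFTI_TYPES[[as.character(h$datatype)]]
  if (is.null(spec))
    stop(sprintf("unsupported NIfTI datatype code %d", h$datatype),
         call. = FALSE)
  shape <- h$dim[1:3]
  nvox <- prod(shape)
  # skip from end of header to vox_offset
  skip <- as.integer(round(h$vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  endian = h$endian, signed = spec$signed)
  if (length(vals) < nvox)
    stop("truncated NIfTI data section", call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter
  nbad <- sum(!is.finite(vals))
  if (nbad > 0L)
    stop(sprintf("volume %s contains %d non-finite voxel(s)", path, nbad),
         call. = FALSE)
  grid <- vol_grid(shape, affine = nifti_affine(h))
  pet_volume(array(vals, dim = shape), grid)
}

#' Write a volume as NIfTI-1
#'
#' Writes a [pet_volume()] or [label_volume()] as a single-file NIfTI-1
#' image, float32 for intensities and int16 for labels, with the grid's
#' affine stored as the sform (and mirrored in pixdim). A path ending in
#' `.nii.gz` is gzip-compressed.
#'
#' @param volume a [pet_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "label_volume")) {
    vals <- volume$labels
    datatype <- 4L; bitpix <- 16L
    if (any(vals > 32767L)) { datatype <- 8L; bitpix <- 32L }
  } else if (inherits(volume, "pet_volume")) {
    vals <- volume$values
    datatype <- 16L; bitpix <- 32L
  } else stop("`volume` must be a pet_volume or label_volume", call. = FALSE)
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)),
         call. = FALSE)
  grid <- volume$grid
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L,
                             endian = "little")
  wi(348L, 4L)                          # sizeof_hdr
  writeBin(raw(36L), con)               # data_type..dim_info (unused)
  wi(c(3L, grid$shape, 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wf(c(0, 0, 0))                        # intent_p1..p3
  wi(0L, 2L)                            # intent_code
  wi(datatype, 2L); wi(bitpix, 2L); wi(0L, 2L)  # slice_start
  wf(c(1, grid$voxel_size, 0, 0, 0, 0)) # pixdim[8] (qfac = 1)
  wf(352)                               # vox_offset
  wf(1); wf(0)                          # scl_slope, scl_inter
  wi(0L, 2L); writeBin(raw(1L), con); writeBin(raw(1L), con) # slice_end..xyzt
  wf(c(0, 0, 0))                        # cal_max, cal_min, slice_duration
  wf(0)                                 # toffset
  wi(c(0L, 0L), 4L)                     # glmax, glmin
  writeBin(raw(104L), con)              # descrip[80] + aux_file[24]
  wi(0L, 2L); wi(1L, 2L)                # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))        # quatern b,c,d + qoffset
  wf(grid$affine[1, ]); wf(grid$affine[2, ]); wf(grid$affine[3, ])
  writeBin(raw(16L), con)               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                # extension flag
  if (datatype == 16L) {
    wf(as.vector(vals))
  } else {
    wi(as.vector(vals), bitpix %/% 8L)
  }
  invisible(path)
}

#' Read a label volume (atlas) from NIfTI
#'
#' Like [read_volume()] but validates that every voxel carries a
#' nonnegative integer label and returns a [label_volume()].
#'
#' @param path path to a `.nii` or `.nii.gz` label image.
#' @return A [label_volume()].
#' @export
read_atlas <- function(path) {
  v <- read_volume(path)
  lab <- v$values
  if (max(abs(lab - round(lab))) > 1e-3)
    stop("atlas volume contains non-integer labels", call. = FALSE)
  label_volume(array(as.integer(round(lab)), dim = dim(lab)), v$grid)
}
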