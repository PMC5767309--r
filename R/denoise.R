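# Wavelet shrinkage denoising: separable multilevel symlet-8 transform,
# per-subband SURE threshold selection, soft thresholding, reconstruction.
# The transform is the standard orthonormal periodic DWT (analysis
# a_k = sum_j h_j x_{(2k+j) mod n}), so white noise keeps a constant SD
# in every subband and a single global noise estimate suffices.

# Symlet-8 decomposition low-pass filter (16 taps, orthonormal).
SYM8_DEC_LO <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
  0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
  0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
  0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
  0.0018899503327594609)

wavelet_filters <- function(name = "sym8") {
  h <- switch(name,
              sym8 = SYM8_DEC_LO,
              haar = c(1, 1) / sqrt(2),
              stop(sprintf("unknown or non-orthogonal wavelet '%s'", name),
                   call. = FALSE))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # QMF high-pass
  list(h = h, g = g, length = L)
}

#' Soft thresholding
#'
#' Shrinks `x` towards zero: 0 where `|x| <= t`, else
#' `sign(x) * (|x| - t)`. Vectorised in `x`.
#'
#' @param x numeric coefficients.
#' @param t threshold, a single value >= 0.
#' @return Shrunk coefficients, same shape as `x`.
#' @export
soft_threshold <- function(x, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop("threshold must be a single finite value >= 0", call. = FALSE)
  sign(x) * pmax(abs(x) - t, 0)
}

#' SURE threshold selection
#'
#' Selects the soft-threshold minimising Stein's unbiased risk estimate
#' for coefficients with noise SD `noise_sd`. With `w = coeffs/noise_sd`
#' and `n` coefficients, `SURE(t) = n - 2 * #(|w| <= t) + sum(min(w^2,
#' t^2))` is minimised over candidate thresholds `{0} U {|w|}`, ties
#' resolved towards the smaller threshold. In the sparse regime (signal
#' energy `(sum(w^2) - n)/n` below `(log2 n)^{3/2}/sqrt(n)`) the SURE
#' estimate is unreliable and the universal threshold `sqrt(2 log n)` is
#' used instead; otherwise the result is capped at the universal
#' threshold (the classical hybrid rule).
#'
#' @param coeffs nonempty numeric vector of detail coefficients.
#' @param noise_sd noise standard deviation, > 0.
#' @return A single threshold on the scale of `coeffs` (>= 0).
#' @export
sure_threshold <- function(coeffs, noise_sd) {
  if (length(coeffs) == 0L) stop("empty coefficient vector", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  w <- as.vector(coeffs) / noise_sd
  n <- length(w)
  universal <- sqrt(2 * log(n))
  sparsity <- (sum(w^2) - n) / n
  crit <- (log2(n))^1.5 / sqrt(n)
  if (sparsity <= crit) return(noise_sd * universal)
  s <- sort(abs(w))
  cs2 <- cumsum(s^2)
  k <- seq_len(n)
  # risk at t = s[k]; for tied |w| the last duplicate carries the true
  # count, and earlier duplicates only overestimate the risk
  risk <- n - 2 * k + (cs2 + (n - k) * s^2)
  risk0 <- n - 2 * sum(w == 0)
  cand_t <- c(0, s)
  cand_r <- c(risk0, risk)
  t_sure <- cand_t[which.min(cand_r)]
  noise_sd * min(t_sure, universal)
}

# -- periodic orthogonal DWT along one axis of a 3D array ---------------

# analysis: returns array with approx in the first half along `axis`
dwt_axis <- function(x, axis, flt) {
  d <- dim(x)
  n <- d[axis]
  n2 <- n %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  xm <- matrix(aperm(x, perm), nrow = n)
  A <- matrix(0, n2, ncol(xm))
  D <- matrix(0, n2, ncol(xm))
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_len(flt$length)) {
    idx <- (base + (j - 1L)) %% n + 1L
    A <- A + flt$h[j] * xm[idx, , drop = FALSE]
    D <- D + flt$g[j] * xm[idx, , drop = FALSE]
  }
  out <- rbind(A, D)
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

idwt_axis <- function(x, axis, flt) {
  d <- dim(x)
  n <- d[axis]
  n2 <- n %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  xm <- matrix(aperm(x, perm), nrow = n)
  A <- xm[seq_len(n2), , drop = FALSE]
  D <- xm[(n2 + 1L):n, , drop = FALSE]
  out <- matrix(0, n, ncol(xm))
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_len(flt$length)) {
    idx <- (base + (j - 1L)) %% n + 1L  # distinct for fixed j
    out[idx, ] <- out[idx, ] + flt$h[j] * A + flt$g[j] * D
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# one separable analysis level along the given axes
dwt_level <- function(x, flt, axes) {
  for (a in axes) x <- dwt_axis(x, a, flt)
  x
}

idwt_level <- function(x, flt, axes) {
  for (a in rev(axes)) x <- idwt_axis(x, a, flt)
  x
}

approx_corner <- function(d, axes) {
  ix <- lapply(1:3, function(a)
    if (a %in% axes) seq_len(d[a] %/% 2L) else seq_len(d[a]))
  ix
}

#' Shrinkage configuration
#'
#' @param wavelet_name orthogonal wavelet (`"sym8"`, the default, or
#'   `"haar"`).
#' @param levels requested decomposition depth (capped automatically at
#'   the deepest admissible level for the volume size).
#' @param apply_mode `"3d"` (separable transform along all three axes)
#'   or `"slicewise-2d"` (independent 2D transform in each axial slice).
#' @return A `shrinkage_config` list.
#' @export
shrinkage_config <- function(wavelet_name = "sym8", levels = 3L,
                             apply_mode = c("3d", "slicewise-2d")) {
  apply_mode <- match.arg(apply_mode)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  structure(list(wavelet_name = wavelet_name, levels = as.integer(levels),
                 threshold_rule = "sure", threshold_mode = "soft",
                 apply_mode = apply_mode),
            class = "shrinkage_config")
}

max_levels <- function(shape, flt_len, axes) {
  lv <- 0L
  n <- shape[axes]
  while (all(n %% 2L == 0L) && min(n) >= flt_len) {
    lv <- lv + 1L
    n <- n %/% 2L
  }
  lv
}

#' Denoise a volume by wavelet shrinkage
#'
#' Multilevel separable symlet-8 decomposition; the noise SD is
#' estimated once from the finest-level detail coefficients as
#' `median(|d|) / 0.6745`, each detail subband is soft-thresholded at
#' its own SURE threshold, the approximation band is left untouched, and
#' the volume is reconstructed on the same grid.
#'
#' @param volume a [pet_volume()].
#' @param config a [shrinkage_config()].
#' @return A denoised [pet_volume()] on the same grid.
#' @export
denoise_volume <- function(volume, config = shrinkage_config()) {
  stopifnot(inherits(volume, "pet_volume"),
            inherits(config, "shrinkage_config"))
  flt <- wavelet_filters(config$wavelet_name)
  axes <- if (config$apply_mode == "3d") 1:3 else 1:2
  shape <- volume$grid$shape
  cap <- max_levels(shape, flt$length, axes)
  if (cap < 1L)
    stop(sprintf(
      "axes %s too small (or odd) for a level-1 '%s' transform",
      paste(shape[axes], collapse = "x"), config$wavelet_name),
      call. = FALSE)
  levels <- config$levels
  if (levels > cap) {
    warning(sprintf("decomposition depth reduced from %d to %d for shape %s",
                    levels, cap, paste(shape, collapse = "x")))
    levels <- cap
  }
  x <- volume$values
  if (config$apply_mode == "slicewise-2d") {
    for (z in seq_len(shape[3])) {
      sl <- array(x[, , z], dim = c(shape[1], shape[2], 1L))
      x[, , z] <- denoise_block(sl, flt, levels, axes)[, , 1L]
    }
  } else {
    x <- denoise_block(x, flt, levels, axes)
  }
  pet_volume(x, volume$grid)
}

denoise_block <- function(x, flt, levels, axes) {
  d <- dim(x)
  stacks <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    tr <- dwt_level(cur, flt, axes)
    stacks[[l]] <- tr
    ac <- approx_corner(dim(tr), axes)
    cur <- tr[ac[[1]], ac[[2]], ac[[3]], drop = FALSE]
  }
  # global noise estimate from the finest-level details (MAD / 0.6745)
  t1 <- stacks[[1L]]
  ac1 <- approx_corner(dim(t1), axes)
  amask <- array(FALSE, dim = dim(t1))
  amask[ac1[[1]], ac1[[2]], ac1[[3]]] <- TRUE
  fine <- t1[!amask]
  sigma <- stats::median(abs(fine)) / 0.6745
  for (l in seq_len(levels)) {
    tr <- stacks[[l]]
    if (sigma > 0) {
      for (sb in detail_subbands(dim(tr), axes)) {
        cf <- tr[sb[[1]], sb[[2]], sb[[3]]]
        thr <- sure_threshold(cf, sigma)
        tr[sb[[1]], sb[[2]], sb[[3]]] <- soft_threshold(cf, thr)
      }
    }
    stacks[[l]] <- tr
  }
  # reconstruct from the deepest level up
  cur <- NULL
  for (l in rev(seq_len(levels))) {
    tr <- stacks[[l]]
    if (!is.null(cur)) {
      ac <- approx_corner(dim(tr), axes)
      tr[ac[[1]], ac[[2]], ac[[3]]] <- cur
    }
    cur <- idwt_level(tr, flt, axes)
  }
  cur
}

# index sets of the 2^|axes| - 1 detail subbands of one analysis level
detail_subbands <- function(d, axes) {
  halves <- lapply(1:3, function(a) {
    if (a %in% axes)
      list(lo = seq_len(d[a] %/% 2L),
           hi = (d[a] %/% 2L + 1L):d[a])
    else list(lo = seq_len(d[a]))
  })
  combos <- expand.grid(lapply(1:3, function(a)
    seq_along(halves[[a]])), KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    sel <- as.integer(combos[r, ])
    if (all(sel == 1L)) next  # approximation corner
    out[[length(out) + 1L]] <-
      lapply(1:3, function(a) halves[[a]][[sel[a]]])
  }
  out
}
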