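# Soft-margin C-SVM via SMO (maximal-violating-pair working set, as in
# the classical dual decomposition), kernels {linear, rbf, polynomial},
# and Platt sigmoid calibration for probabilistic output. Problem sizes
# here are tiny (<= a few hundred subjects), so the dense kernel matrix
# is kept in memory.

#' Kernel specification
#'
#' @param kind `"linear"`, `"rbf"` or `"polynomial"`.
#' @param C soft-margin cost (> 0).
#' @param gamma rbf/polynomial width; `NULL` means `1/dim` at fit time.
#' @param degree polynomial degree.
#' @param coef0 polynomial offset.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("linear", "rbf", "polynomial"), C = 1,
                        gamma = NULL, degree = 3, coef0 = 1) {
  kind <- match.arg(kind)
  if (!is.finite(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  structure(list(kind = kind, C = C, gamma = gamma, degree = degree,
                 coef0 = coef0), class = "kernel_spec")
}

kernel_cross <- function(X, Y, spec) {
  G <- X %*% t(Y)
  switch(spec$kind,
         linear = G,
         rbf = {
           d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * G
           exp(-spec$gamma * pmax(d2, 0))
         },
         polynomial = (spec$gamma * G + spec$coef0)^spec$degree)
}

resolve_gamma <- function(spec, dim) {
  if (is.null(spec$gamma)) spec$gamma <- 1 / max(dim, 1L)
  spec
}

# SMO on a precomputed kernel matrix (C++ core). y in {-1, +1}. The
# stopping tolerance follows the LIBSVM default (1e-3 on the maximal
# KKT violation).
smo_solve <- function(K, y, C, eps = 1e-3, max_passes = 1000000L) {
  .smo_solve_cpp(as.matrix(K), as.numeric(y), C, eps,
                 as.integer(max_passes))
}

# Fit an SVM on raw (already standardized) features.
svm_fit <- function(X, y, spec) {
  X <- as.matrix(X)
  spec <- resolve_gamma(spec, ncol(X))
  K <- kernel_cross(X, X, spec)
  sol <- smo_solve(K, y, spec$C)
  sv <- which(sol$alpha > 1e-10)
  structure(list(spec = spec, X_sv = X[sv, , drop = FALSE],
                 coef = (sol$alpha * y)[sv], b = sol$b,
                 dim = ncol(X)), class = "svm_model")
}

svm_decision <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$dim)
    stop(sprintf("feature length %d does not match training length %d",
                 ncol(X), model$dim), call. = FALSE)
  if (nrow(model$X_sv) == 0L) return(rep(model$b, nrow(X)))
  as.vector(kernel_cross(X, model$X_sv, model$spec) %*% model$coef +
              model$b)
}

# Platt's sigmoid fit: P(y = 1 | d) = 1 / (1 + exp(A d + B)), Newton
# iterations with backtracking on the regularized targets.
platt_fit <- function(dec, y1, max_iter = 200L) {
  prior1 <- sum(y1); prior0 <- length(y1) - prior1
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y1 > 0, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    f <- dec * A + B
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  Fv <- fval(A, B)
  sigma <- 1e-12
  for (it in seq_len(max_iter)) {
    f <- dec * A + B
    p <- ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(dec * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(dec^2 * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(dec * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      A2 <- A + step * dA; B2 <- B + step * dB
      F2 <- fval(A2, B2)
      if (F2 < Fv + 1e-4 * step * gd) { A <- A2; B <- B2; Fv <- F2; break }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B))
    }
  }
  list(A = A, B = B)
}

platt_prob <- function(platt, dec) {
  f <- platt$A * dec + platt$B
  p <- ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- which(sd > 0)
  list(mu = mu, sd = sd, keep = keep)
}

standardize_apply <- function(std, X) {
  X <- sweep(X, 2, std$mu, `-`)
  X <- sweep(X, 2, std$sd + (std$sd == 0), `/`)
  X[, std$keep, drop = FALSE]
}

stratified_folds <- function(labels, k, seed) {
  idx <- seq_along(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (g in unique(labels)) {
      members <- idx[labels == g]
      members <- members[sample.int(length(members))]
      fold[members] <- rep_len(seq_len(k), length(members))
    }
  })
  fold
}

#' Train a per-region probabilistic classifier
#'
#' Standardizes the region's feature vectors (zero-variance features are
#' dropped and recorded), fits a soft-margin SVM, and calibrates a Platt
#' sigmoid on out-of-fold decision values from an internal stratified
#' 3-fold split. When any internal fold lacks a class (very small
#' cohorts), in-sample decision values are used with the standard
#' regularized targets.
#'
#' @param features subjects x features matrix for one region.
#' @param labels group labels (`NC`/`MCI`); MCI is the positive class.
#' @param kernel a [kernel_spec()].
#' @param seed integer seed for the internal calibration split.
#' @param region_id stored for bookkeeping.
#' @return A `region_classifier`.
#' @export
train_region_classifier <- function(features, labels, kernel, seed = 1L,
                                    region_id = NA_integer_) {
  X <- as.matrix(features)
  labels <- normalize_group(labels)
  if (length(unique(labels)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  y <- ifelse(labels == "MCI", 1, -1)
  std <- standardize_fit(X)
  if (length(std$keep) == 0L)
    stop("all features have zero variance", call. = FALSE)
  Xs <- standardize_apply(std, X)
  model <- svm_fit(Xs, y, kernel)
  # out-of-fold decision values for calibration
  k <- 3L
  fold <- stratified_folds(as.character(labels), k, seed)
  dec <- rep(NA_real_, length(y))
  ok <- TRUE
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    if (length(unique(y[tr])) < 2L) { ok <- FALSE; break }
    sub <- svm_fit(Xs[tr, , drop = FALSE], y[tr], kernel)
    dec[te] <- svm_decision(sub, Xs[te, , drop = FALSE])
  }
  if (!ok || anyNA(dec)) dec <- svm_decision(model, Xs)
  platt <- platt_fit(dec, as.integer(y > 0))
  structure(list(region_id = region_id, kernel = model$spec, svm = model,
                 std = std, platt_a = platt$A, platt_b = platt$B),
            class = "region_classifier")
}

#' Probability of MCI from a region classifier
#'
#' Applies the stored standardization and Platt sigmoid to the SVM
#' decision value; the result is strictly inside (0, 1) and monotone in
#' the decision value.
#'
#' @param model a `region_classifier`.
#' @param features vector (or matrix of rows) of raw region features of
#'   the training length.
#' @return P(MCI) in (0, 1), one per row.
#' @export
predict_region_prob <- function(model, features) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1L)
       else as.matrix(features)
  if (ncol(X) != length(model$std$mu))
    stop(sprintf("expected %d features, got %d", length(model$std$mu),
                 ncol(X)), call. = FALSE)
  dec <- svm_decision(model$svm, standardize_apply(model$std, X))
  platt_prob(list(A = model$platt_a, B = model$platt_b), dec)
}

#' Train the fusion (level-2) classifier
#'
#' A single SVM on the per-subject vectors of level-1 region
#' probabilities, in a fixed region order.
#'
#' @param prob_vectors subjects x regions matrix of level-1
#'   probabilities; column names are region ids.
#' @param labels group labels; MCI positive.
#' @param kernel a [kernel_spec()].
#' @param seed reserved for interface symmetry (the fit itself is
#'   deterministic).
#' @return A `fusion_classifier` with the stored `region_order`.
#' @export
train_fusion <- function(prob_vectors, labels, kernel, seed = 1L) {
  P <- as.matrix(prob_vectors)
  labels <- normalize_group(labels)
  if (length(unique(labels)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  y <- ifelse(labels == "MCI", 1, -1)
  model <- svm_fit(P, y, kernel)
  structure(list(region_order = as.integer(colnames(P)), svm = model),
            class = "fusion_classifier")
}

#' Global decision value from the fusion classifier
#'
#' @param model a `fusion_classifier`.
#' @param prob_vectors vector or matrix of level-1 probabilities in the
#'   model's region order.
#' @return Decision value(s); >= 0 is called MCI.
#' @export
predict_fusion <- function(model, prob_vectors) {
  P <- if (is.null(dim(prob_vectors))) matrix(prob_vectors, nrow = 1L)
       else as.matrix(prob_vectors)
  if (ncol(P) != length(model$region_order))
    stop(sprintf("expected %d region probabilities, got %d",
                 length(model$region_order), ncol(P)), call. = FALSE)
  svm_decision(model$svm, P)
}
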