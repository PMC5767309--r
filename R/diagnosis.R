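# Two-level diagnosis: per-region Platt-calibrated SVMs (level 1,
# local abnormality probabilities) fused by one SVM (level 2, global
# NC vs. MCI call), plus cross-validated evaluation and the standard
# accuracy / specificity / sensitivity metrics (MCI positive).

#' Performance metrics from confusion counts
#'
#' MCI is the positive class: `acc = 100 (TP+TN)/N`,
#' `sens = 100 TP/(TP+FN)`, `spec = 100 TN/(TN+FP)`, each rounded
#' half-up to two decimals.
#'
#' @param tp,fp,tn,fn nonnegative confusion counts.
#' @return List with `acc_pct`, `spec_pct`, `sens_pct`.
#' @export
metrics <- function(tp, fp, tn, fn) {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  n <- sum(cnt)
  if (n < 1L) stop("undefined metric: no predictions (N = 0)", call. = FALSE)
  if (tp + fn < 1L) stop("undefined metric: sensitivity (TP+FN = 0)",
                         call. = FALSE)
  if (tn + fp < 1L) stop("undefined metric: specificity (TN+FP = 0)",
                         call. = FALSE)
  round2 <- function(x) floor(x * 100 + 0.5) / 100  # half-up
  list(acc_pct = round2(100 * (tp + tn) / n),
       spec_pct = round2(100 * tn / (tn + fp)),
       sens_pct = round2(100 * tp / (tp + fn)))
}

#' Evaluation scheme
#'
#' @param kind `"LOSO"` or `"KFOLD"`.
#' @param k number of folds (used for KFOLD; the reference grid is 2
#'   and 4).
#' @param stratified stratify folds by group (KFOLD only).
#' @param shuffle_seed seed for fold construction.
#' @param selection_scope `"paper"` selects significant regions once on
#'   the full cohort before cross-validation (replicating the reference
#'   protocol, which leaks test information into the selection);
#'   `"nested"` re-selects inside each training fold.
#' @return An `eval_scheme` list.
#' @export
eval_scheme <- function(kind = c("LOSO", "KFOLD"), k = 2L,
                        stratified = TRUE, shuffle_seed = 1L,
                        selection_scope = c("paper", "nested")) {
  kind <- match.arg(kind)
  selection_scope <- match.arg(selection_scope)
  if (kind == "KFOLD" && k < 2L) stop("k must be >= 2", call. = FALSE)
  structure(list(kind = kind, k = as.integer(k), stratified = stratified,
                 shuffle_seed = as.integer(shuffle_seed),
                 selection_scope = selection_scope),
            class = "eval_scheme")
}

# features long data frame -> list of subjects x 8 matrices per region
feature_matrices <- function(feat_df, subject_ids) {
  ids <- sort(unique(feat_df$region_id))
  lapply(stats::setNames(ids, ids), function(r) {
    sub <- feat_df[feat_df$region_id == r, , drop = FALSE]
    rows <- match(subject_ids, sub$subject_id)
    if (anyNA(rows))
      stop(sprintf("missing features for region %d", r), call. = FALSE)
    m <- as.matrix(sub[rows, REGION_FEATURE_NAMES, drop = FALSE])
    rownames(m) <- subject_ids
    m
  })
}

# mean-uptake table (subjects x regions) from the feature data frame
mean_table_from_features <- function(feat_df, subject_ids) {
  ids <- sort(unique(feat_df$region_id))
  out <- sapply(ids, function(r) {
    sub <- feat_df[feat_df$region_id == r, , drop = FALSE]
    sub$region_mean_uptake[match(subject_ids, sub$subject_id)]
  })
  dimnames(out) <- list(subject_ids, ids)
  out
}

train_two_level <- function(feat_mats, labels, selected, kernel1, kernel2,
                            seed) {
  check_trainable(normalize_group(labels))
  level1 <- lapply(selected, function(r) {
    train_region_classifier(feat_mats[[as.character(r)]], labels, kernel1,
                            seed = seed, region_id = r)
  })
  names(level1) <- selected
  P <- sapply(level1, function(m)
    predict_region_prob(m, feat_mats[[as.character(m$region_id)]]))
  colnames(P) <- selected
  level2 <- train_fusion(P, labels, kernel2, seed)
  list(level1 = level1, level2 = level2)
}

predict_two_level <- function(two, feat_mats, rows) {
  P <- sapply(two$level1, function(m) {
    X <- feat_mats[[as.character(m$region_id)]][rows, , drop = FALSE]
    predict_region_prob(m, X)
  })
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  score <- predict_fusion(two$level2, P)
  list(region_probs = P, score = score,
       label = ifelse(score >= 0, "MCI", "NC"))
}

#' Cross-validated evaluation of the two-level classifier
#'
#' Works from a precomputed feature table (see [cohort_feature_table()]),
#' so repeated evaluations do not re-run the image pipeline. For each
#' fold: select regions (per `selection_scope`), train the per-region
#' classifiers on the training subjects, compute their training
#' probabilities, train the fusion SVM, and predict the held-out
#' subjects. Every subject is predicted exactly once.
#'
#' @param feat_df long feature table (subject_id, group, region_id, 8
#'   feature columns).
#' @param scheme an [eval_scheme()].
#' @param kernel1,kernel2 level-1 and level-2 [kernel_spec()]s.
#' @param alpha_family family-wise alpha for region selection.
#' @param region_subset optional explicit region ids to use instead of
#'   significance selection (e.g. "all regions" or "all but significant"
#'   ablations); overrides `alpha_family`.
#' @return An `eval_result`: list with `scheme`, `counts` (TP/FP/TN/FN),
#'   `acc_pct`, `spec_pct`, `sens_pct`, `predictions` (data frame), and
#'   `selected_per_fold`.
#' @export
evaluate_features <- function(feat_df, scheme = eval_scheme("LOSO"),
                              kernel1 = kernel_spec("linear"),
                              kernel2 = kernel_spec("linear"),
                              alpha_family = 0.05,
                              region_subset = NULL) {
  subject_ids <- unique(feat_df$subject_id)
  labels <- feat_df$group[match(subject_ids, feat_df$subject_id)]
  labels <- normalize_group(labels)
  n <- length(subject_ids)
  feat_mats <- feature_matrices(feat_df, subject_ids)
  mt <- mean_table_from_features(feat_df, subject_ids)
  fold <- if (scheme$kind == "LOSO") seq_len(n)
          else if (scheme$stratified)
            stratified_folds(as.character(labels), scheme$k,
                             scheme$shuffle_seed)
          else with_seed(scheme$shuffle_seed,
                         sample(rep_len(seq_len(min(scheme$k, n)), n)))
  select_on <- function(rows) {
    if (!is.null(region_subset)) return(sort(as.integer(region_subset)))
    rep <- select_regions(mt[rows, , drop = FALSE], labels[rows],
                          alpha_family)
    rep$selected
  }
  selected_full <- select_on(seq_len(n))
  pred <- character(n)
  score <- numeric(n)
  sel_per_fold <- list()
  for (f in sort(unique(fold))) {
    te <- which(fold == f)
    tr <- which(fold != f)
    stopifnot(length(intersect(te, tr)) == 0L)
    if (length(unique(labels[tr])) < 2L)
      stop(sprintf("fold %s: training portion has a single class (%s)",
                   f, paste(table(labels[tr]), collapse = "/")),
           call. = FALSE)
    selected <- if (scheme$selection_scope == "paper") selected_full
                else select_on(tr)
    if (length(selected) == 0L)
      stop(sprintf("fold %s: no regions selected", f), call. = FALSE)
    sel_per_fold[[as.character(f)]] <- selected
    tr_mats <- lapply(feat_mats, function(m) m[tr, , drop = FALSE])
    two <- train_two_level(tr_mats, labels[tr], selected, kernel1,
                           kernel2, seed = scheme$shuffle_seed + f)
    pr <- predict_two_level(two, feat_mats, te)
    pred[te] <- pr$label
    score[te] <- pr$score
  }
  tp <- sum(pred == "MCI" & labels == "MCI")
  fp <- sum(pred == "MCI" & labels == "NC")
  tn <- sum(pred == "NC" & labels == "NC")
  fn <- sum(pred == "NC" & labels == "MCI")
  met <- metrics(tp, fp, tn, fn)
  structure(c(list(scheme = scheme,
                   counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                   predictions = data.frame(subject_id = subject_ids,
                                            group = as.character(labels),
                                            predicted = pred,
                                            score = score),
                   selected_per_fold = sel_per_fold), met),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s%s: ACC %.2f / Spec %.2f / Sens %.2f (n = %d)\n",
              x$scheme$kind,
              if (x$scheme$kind == "KFOLD") sprintf(" k=%d", x$scheme$k)
              else "",
              x$acc_pct, x$spec_pct, x$sens_pct, sum(x$counts)))
  invisible(x)
}

#' End-to-end evaluation from volumes
#'
#' Runs denoising and feature extraction over the cohort, then
#' [evaluate_features()].
#'
#' @param cohort,atlas,registry the cohort and its atlas.
#' @param scheme an [eval_scheme()].
#' @param kernel1,kernel2 [kernel_spec()]s for the two levels.
#' @param alpha_family family-wise alpha for region selection.
#' @param ladder a [scale_ladder()].
#' @param denoise a [shrinkage_config()] or `NULL`.
#' @return An `eval_result` (see [evaluate_features()]).
#' @export
evaluate <- function(cohort, atlas, registry,
                     scheme = eval_scheme("LOSO"),
                     kernel1 = kernel_spec("linear"),
                     kernel2 = kernel_spec("linear"),
                     alpha_family = 0.05, ladder = scale_ladder(),
                     denoise = shrinkage_config()) {
  feat <- cohort_feature_table(cohort, atlas, registry, ladder, denoise)
  evaluate_features(feat, scheme, kernel1, kernel2, alpha_family)
}

#' Fit the full pipeline model on a cohort
#'
#' Region selection on the cohort's regional mean uptake, then the
#' two-level classifier on all subjects. The returned model carries a
#' config snapshot and can diagnose new scans.
#'
#' @inheritParams evaluate
#' @param kernel1,kernel2 level-1 / level-2 kernels.
#' @param seed seed for the internal calibration splits.
#' @param feat_df optional precomputed feature table (skips the image
#'   pipeline).
#' @return A `pipeline_model`.
#' @export
fit_pipeline_model <- function(cohort, atlas, registry,
                               kernel1 = kernel_spec("linear"),
                               kernel2 = kernel_spec("linear"),
                               alpha_family = 0.05,
                               ladder = scale_ladder(),
                               denoise = shrinkage_config(),
                               seed = 1L, feat_df = NULL) {
  if (is.null(feat_df))
    feat_df <- cohort_feature_table(cohort, atlas, registry, ladder,
                                    denoise)
  subject_ids <- unique(feat_df$subject_id)
  labels <- normalize_group(
    feat_df$group[match(subject_ids, feat_df$subject_id)])
  mt <- mean_table_from_features(feat_df, subject_ids)
  sel <- select_regions(mt, labels, alpha_family)
  if (length(sel$selected) == 0L)
    stop("no significant regions at the requested alpha", call. = FALSE)
  feat_mats <- feature_matrices(feat_df, subject_ids)
  two <- train_two_level(feat_mats, labels, sel$selected, kernel1,
                         kernel2, seed)
  config <- list(ladder = as.numeric(ladder),
                 denoise = if (is.null(denoise)) NULL
                           else unclass(denoise),
                 kernel1 = unclass(kernel1), kernel2 = unclass(kernel2),
                 alpha_family = alpha_family, seed = seed)
  structure(list(selection = sel, level1 = two$level1,
                 level2 = two$level2, config = config,
                 config_hash = config_hash(config)),
            class = "pipeline_model")
}

#' @export
print.pipeline_model <- function(x, ...) {
  cat(sprintf("<pipeline_model> %d region classifiers (%s level 1, %s fusion)\n",
              length(x$level1), x$config$kernel1$kind,
              x$config$kernel2$kind))
  invisible(x)
}

#' Diagnose a single scan
#'
#' Denoises the scan (per the model's config), extracts region features,
#' applies the per-region probabilistic classifiers to the model's
#' selected regions, and fuses them into the global call. The local
#' result is a per-region P(MCI) in (0, 1) — the region-level degree of
#' abnormality from 0 (unaffected) to 1 (indicative of MCI).
#'
#' @param scan a [pet_volume()].
#' @param atlas grid-congruent [label_volume()].
#' @param registry region registry.
#' @param model a `pipeline_model`.
#' @param overlay also build an overlay volume painting each selected
#'   region with its abnormality probability.
#' @return A `diagnosis_report`: `region_probs` (named vector),
#'   `global_score`, `global_label`, and optionally `overlay`
#'   (a [pet_volume()] with values in \[0, 1\]).
#' @export
diagnose <- function(scan, atlas, registry, model, overlay = FALSE) {
  stopifnot(inherits(model, "pipeline_model"))
  stop_if_incongruent(scan$grid, atlas$grid, "scan and atlas")
  vol <- scan
  if (!is.null(model$config$denoise)) {
    cfgd <- model$config$denoise
    vol <- suppressWarnings(denoise_volume(
      scan, shrinkage_config(cfgd$wavelet_name, cfgd$levels,
                             cfgd$apply_mode)))
  }
  ladder <- structure(model$config$ladder, class = "scale_ladder")
  ft <- extract_region_features(vol, atlas, registry, ladder)
  probs <- vapply(model$level1, function(m)
    predict_region_prob(m, ft[as.character(m$region_id), ]), numeric(1))
  names(probs) <- vapply(model$level1, `[[`, 0L, "region_id")
  score <- predict_fusion(model$level2, probs)
  rep <- list(region_probs = probs, global_score = score,
              global_label = if (score >= 0) "MCI" else "NC")
  if (overlay) {
    ov <- array(0, dim = atlas$grid$shape)
    for (r in names(probs)) {
      ov[atlas$labels == as.integer(r)] <- probs[[r]]
    }
    rep$overlay <- pet_volume(ov, atlas$grid)
  }
  structure(rep, class = "diagnosis_report")
}

#' @export
print.diagnosis_report <- function(x, ...) {
  cat(sprintf("<diagnosis_report> %s (score %.3f)\n", x$global_label,
              x$global_score))
  p <- sort(x$region_probs, decreasing = TRUE)
  for (r in names(p))
    cat(sprintf("  region %3s: P(MCI) = %.3f\n", r, p[[r]]))
  invisible(x)
}
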