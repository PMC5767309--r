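# Region screening: an independent two-sample t-test on regional mean
# uptake (MCI vs. NC) per atlas region, with Bonferroni family-wise
# control at alpha / m over the m regions actually tested.

#' Two-sample t-test
#'
#' Pooled-variance Student's t by default (`var_equal = TRUE`):
#' `t = (mean(x) - mean(y)) / sqrt(sp2 * (1/nx + 1/ny))` with the pooled
#' variance `sp2 = ((nx-1) sx2 + (ny-1) sy2) / (nx+ny-2)` and
#' `df = nx + ny - 2`; two-sided p-value. Welch's unequal-variance
#' variant is available with `var_equal = FALSE`. Degenerate inputs with
#' zero pooled variance give `t = 0, p = 1` when the means are equal and
#' `p = 0` (infinite t, flagged by a warning) when they differ.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param var_equal pooled (classical) or Welch variance handling.
#' @return List with `t_stat`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("both samples need at least 2 observations", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    se2 <- sp2 * (1 / nx + 1 / ny)
  } else {
    se2 <- vx / nx + vy / ny
    df <- if (se2 > 0)
      se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    else nx + ny - 2
  }
  dm <- mean(x) - mean(y)
  if (se2 <= 0) {
    if (dm == 0) return(list(t_stat = 0, df = df, p_value = 1))
    warning("zero variance with unequal means: degenerate t-test (p = 0)")
    return(list(t_stat = sign(dm) * Inf, df = df, p_value = 0))
  }
  t_stat <- dm / sqrt(se2)
  list(t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Bonferroni per-test level
#'
#' @param alpha_family family-wise error level in (0, 1].
#' @param m number of tests, >= 1.
#' @return `alpha_family / m` (exact division).
#' @export
bonferroni_alpha <- function(alpha_family, m) {
  if (!is.finite(alpha_family) || alpha_family <= 0 || alpha_family > 1)
    stop("alpha_family must be in (0, 1]", call. = FALSE)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1", call. = FALSE)
  alpha_family / m
}

#' Select significant regions
#'
#' Runs one two-sample t-test per region on the columns of the regional
#' mean-uptake table (MCI sample vs. NC sample) and flags regions with
#' `p < alpha_family / m`, `m` being the number of regions tested.
#'
#' @param mean_table subjects x regions matrix from
#'   [regional_mean_table()] (column names are region ids).
#' @param group factor/character of group labels aligned with the rows.
#' @param alpha_family family-wise alpha (default 0.05).
#' @param var_equal passed to [two_sample_t()].
#' @return A `selection_report`: list with `alpha_family`, `m`,
#'   `alpha_per_test`, `results` (data frame with one row per region:
#'   region_id, t_stat, df, p_value, mean_nc, mean_mci, significant) and
#'   `selected` (significant region ids, ascending).
#' @export
select_regions <- function(mean_table, group, alpha_family = 0.05,
                           var_equal = TRUE) {
  group <- normalize_group(group)
  if (nrow(mean_table) != length(group))
    stop("mean_table rows and group labels differ in length", call. = FALSE)
  check_trainable(group)
  if (anyNA(mean_table)) stop("mean_table has missing entries", call. = FALSE)
  ids <- as.integer(colnames(mean_table))
  m <- ncol(mean_table)
  alpha_per_test <- bonferroni_alpha(alpha_family, m)
  nc <- group == "NC"
  res <- lapply(seq_len(m), function(j) {
    tt <- two_sample_t(mean_table[!nc, j], mean_table[nc, j],
                       var_equal = var_equal)
    data.frame(region_id = ids[j], t_stat = tt$t_stat, df = tt$df,
               p_value = tt$p_value,
               mean_nc = mean(mean_table[nc, j]),
               mean_mci = mean(mean_table[!nc, j]))
  })
  res <- do.call(rbind, res)
  res$significant <- res$p_value < alpha_per_test
  structure(list(alpha_family = alpha_family, m = m,
                 alpha_per_test = alpha_per_test, results = res,
                 selected = sort(res$region_id[res$significant])),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> %d/%d regions significant at %.3g (= %.3g / %d)\n",
    length(x$selected), x$m, x$alpha_per_test, x$alpha_family, x$m))
  invisible(x)
}

#' Write a selection report as TSV
#'
#' @param report a `selection_report` from [select_regions()].
#' @param registry optional registry to attach region names.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(report, path, registry = NULL) {
  df <- report$results
  if (!is.null(registry))
    df <- cbind(df[, "region_id", drop = FALSE],
                name = registry$name[match(df$region_id,
                                           registry$region_id)],
                df[, setdiff(names(df), "region_id")])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
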