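#' Subject cohort and TSV manifest handling
#'
#' A cohort is an ordered set of subject records, each carrying a unique
#' `subject_id`, a group label (`"NC"` or `"MCI"`), and a volume
#' reference: either a file path or an in-memory [pet_volume()].
#'
#' @param subject_id character vector of unique ids.
#' @param group character vector, case-insensitively one of `NC`, `MCI`.
#' @param volume_ref list of file paths and/or [pet_volume()] objects
#'   (a character vector is accepted).
#' @return A `cohort` object (list with element `records`, a data-frame-like
#'   list of records).
#' @export
cohort <- function(subject_id, group, volume_ref) {
  subject_id <- as.character(subject_id)
  if (any(!nzchar(subject_id)))
    stop("subject ids must be nonempty", call. = FALSE)
  dup <- subject_id[duplicated(subject_id)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate subject id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  group <- normalize_group(group)
  if (is.character(volume_ref)) volume_ref <- as.list(volume_ref)
  if (length(subject_id) != length(group) ||
      length(subject_id) != length(volume_ref))
    stop("subject_id, group and volume_ref lengths differ", call. = FALSE)
  structure(list(subject_id = subject_id, group = group,
                 volume_ref = volume_ref),
            class = "cohort")
}

normalize_group <- function(group) {
  g <- toupper(trimws(as.character(group)))
  bad <- which(!g %in% c("NC", "MCI"))
  if (length(bad) > 0L)
    stop(sprintf("unknown group label(s) in row(s) %s: %s",
                 paste(bad, collapse = ", "),
                 paste(unique(group[bad]), collapse = ", ")), call. = FALSE)
  factor(g, levels = c("NC", "MCI"))
}

#' @export
length.cohort <- function(x) length(x$subject_id)

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d NC, %d MCI)\n", length(x),
              sum(x$group == "NC"), sum(x$group == "MCI")))
  invisible(x)
}

#' @export
`[.cohort` <- function(x, i) {
  cohort(x$subject_id[i], x$group[i], x$volume_ref[i])
}

#' Fetch a subject's volume, reading from disk if needed
#'
#' @param x a [cohort()].
#' @param i subject index.
#' @return A [pet_volume()].
#' @export
cohort_volume <- function(x, i) {
  ref <- x$volume_ref[[i]]
  if (inherits(ref, "pet_volume")) ref else read_volume(ref)
}

#' Read a cohort manifest
#'
#' The manifest is a TSV file with header columns `subject_id`, `group`,
#' `volume_path`. Group strings are mapped case-insensitively onto
#' `NC`/`MCI`. Relative volume paths are resolved against the manifest's
#' directory.
#'
#' @param path path to the manifest TSV.
#' @return A [cohort()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("subject_id", "group", "volume_path")
  if (!all(need %in% names(df)))
    stop(sprintf("manifest must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  paths <- df$volume_path
  rel <- !grepl("^(/|[A-Za-z]:)", paths) & nzchar(paths)
  paths[rel] <- file.path(dirname(path), paths[rel])
  cohort(df$subject_id, df$group, paths)
}

#' Write a cohort manifest
#'
#' @param x a [cohort()] whose volume references are file paths.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  refs <- vapply(x$volume_ref, function(r) {
    if (!is.character(r))
      stop("write_manifest needs path-backed volume references",
           call. = FALSE)
    r
  }, character(1))
  df <- data.frame(subject_id = x$subject_id,
                   group = as.character(x$group),
                   volume_path = refs, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_trainable <- function(group, min_per_class = 2L) {
  tab <- table(group)
  if (any(tab < min_per_class))
    stop(sprintf("need at least %d subjects per group, got NC=%d MCI=%d",
                 min_per_class, tab[["NC"]], tab[["MCI"]]), call. = FALSE)
  invisible(TRUE)
}
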