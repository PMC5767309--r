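# Lossless JSON persistence of the fitted pipeline model, with a config
# hash embedded in every artifact so outputs from different
# configurations cannot be mixed silently.

# Polynomial rolling hash of the serialized config (exact in doubles);
# no cryptographic intent, just a stable fingerprint.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

ser_matrix <- function(m) list(dim = dim(m), data = as.vector(m),
                               dimnames = dimnames(m))
deser_matrix <- function(s) {
  m <- matrix(as.numeric(s$data), nrow = s$dim[1], ncol = s$dim[2])
  if (!is.null(s$dimnames))
    dimnames(m) <- lapply(s$dimnames, function(d)
      if (length(d) == 0) NULL else as.character(d))
  m
}

ser_svm <- function(m) {
  list(spec = unclass(m$spec), X_sv = ser_matrix(m$X_sv),
       coef = m$coef, b = m$b, dim = m$dim)
}
deser_svm <- function(s) {
  structure(list(spec = structure(s$spec, class = "kernel_spec"),
                 X_sv = deser_matrix(s$X_sv),
                 coef = as.numeric(s$coef), b = s$b,
                 dim = as.integer(s$dim)),
            class = "svm_model")
}

ser_region_classifier <- function(m) {
  list(region_id = m$region_id, svm = ser_svm(m$svm),
       std = list(mu = m$std$mu, sd = m$std$sd, keep = m$std$keep),
       platt_a = m$platt_a, platt_b = m$platt_b)
}
deser_region_classifier <- function(s) {
  structure(list(region_id = as.integer(s$region_id),
                 kernel = structure(s$svm$spec, class = "kernel_spec"),
                 svm = deser_svm(s$svm),
                 std = list(mu = as.numeric(s$std$mu),
                            sd = as.numeric(s$std$sd),
                            keep = as.integer(s$std$keep)),
                 platt_a = s$platt_a, platt_b = s$platt_b),
            class = "region_classifier")
}

#' Save / load a fitted pipeline model as JSON
#'
#' The JSON carries the selection report, every level-1 classifier
#' (support vectors, weights, standardization, Platt coefficients), the
#' fusion classifier, the config snapshot and its hash. [read_model()]
#' refuses a file whose embedded hash does not match its config
#' (tampered or mixed-config artifact).
#'
#' @param model a `pipeline_model`.
#' @param path JSON path.
#' @return `path` (write) / the restored `pipeline_model` (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pipeline_model"))
  payload <- list(
    format = "petcad_model",
    version = 1L,
    config = model$config,
    config_hash = model$config_hash,
    selection = list(alpha_family = model$selection$alpha_family,
                     m = model$selection$m,
                     alpha_per_test = model$selection$alpha_per_test,
                     results = model$selection$results,
                     selected = model$selection$selected),
    level1 = lapply(model$level1, ser_region_classifier),
    level2 = list(region_order = model$level2$region_order,
                  svm = ser_svm(model$level2$svm)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE,
                           simplifyDataFrame = TRUE)
  if (!identical(s$format, "petcad_model"))
    stop("not a petcad model file", call. = FALSE)
  if (!identical(config_hash(s$config), s$config_hash))
    stop("config hash mismatch: mixed-config or corrupted artifact",
         call. = FALSE)
  sel <- structure(list(alpha_family = s$selection$alpha_family,
                        m = as.integer(s$selection$m),
                        alpha_per_test = s$selection$alpha_per_test,
                        results = s$selection$results,
                        selected = as.integer(s$selection$selected)),
                   class = "selection_report")
  level1 <- lapply(s$level1, deser_region_classifier)
  names(level1) <- vapply(level1, `[[`, 0L, "region_id")
  level2 <- structure(list(region_order = as.integer(s$level2$region_order),
                           svm = deser_svm(s$level2$svm)),
                      class = "fusion_classifier")
  structure(list(selection = sel, level1 = level1, level2 = level2,
                 config = s$config, config_hash = s$config_hash),
            class = "pipeline_model")
}
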