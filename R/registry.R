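# The AAL-style region catalogue: 116 named parcels — 45 per cerebral
# hemisphere, 9 per cerebellar hemisphere, 8 vermian lobules — with ids
# 1..116 in the conventional interleaved left/right order.

AAL_CEREBRAL_STEMS <- c(
  "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
  "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
  "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
  "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
  "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
  "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
  "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
  "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
  "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
  "Pallidum", "Thalamus", "Heschl", "Temporal_Sup",
  "Temporal_Pole_Sup", "Temporal_Mid", "Temporal_Pole_Mid",
  "Temporal_Inf")

AAL_CEREBELLAR_STEMS <- c(
  "Cerebelum_Crus1", "Cerebelum_Crus2", "Cerebelum_3", "Cerebelum_4_5",
  "Cerebelum_6", "Cerebelum_7b", "Cerebelum_8", "Cerebelum_9",
  "Cerebelum_10")

AAL_VERMIS <- c("Vermis_1_2", "Vermis_3", "Vermis_4_5", "Vermis_6",
                "Vermis_7", "Vermis_8", "Vermis_9", "Vermis_10")

#' The 116-region AAL-style registry
#'
#' Returns the catalogue of the 116 atlas regions used throughout the
#' pipeline: 45 regions per cerebral hemisphere, 9 per cerebellar
#' hemisphere, and 8 vermian lobules, with contiguous ids 1..116 in the
#' conventional interleaved left/right order.
#'
#' @return A `region_registry`: a data frame with columns `region_id`
#'   (integer 1..116), `name` (character), `compartment` (one of
#'   `cerebral-L`, `cerebral-R`, `cerebellar-L`, `cerebellar-R`,
#'   `vermis`).
#' @export
aal_region_registry <- function() {
  interleave <- function(stems, comp_l, comp_r) {
    data.frame(
      name = as.vector(rbind(paste0(stems, "_L"), paste0(stems, "_R"))),
      compartment = rep(c(comp_l, comp_r), length(stems)),
      stringsAsFactors = FALSE)
  }
  df <- rbind(
    interleave(AAL_CEREBRAL_STEMS, "cerebral-L", "cerebral-R"),
    interleave(AAL_CEREBELLAR_STEMS, "cerebellar-L", "cerebellar-R"),
    data.frame(name = AAL_VERMIS, compartment = "vermis",
               stringsAsFactors = FALSE))
  df <- cbind(region_id = seq_len(nrow(df)), df)
  class(df) <- c("region_registry", "data.frame")
  df
}

validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  need <- c("region_id", "name", "compartment")
  if (!all(need %in% names(registry)))
    stop("registry needs columns region_id, name, compartment",
         call. = FALSE)
  if (anyDuplicated(registry$region_id) || anyDuplicated(registry$name))
    stop("registry ids and names must be unique", call. = FALSE)
  invisible(registry)
}

#' Write / read a region registry TSV
#'
#' @param registry a registry data frame as from [aal_region_registry()].
#' @param path TSV path.
#' @return `path` (write) or the registry data frame (read).
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$region_id <- as.integer(df$region_id)
  validate_registry(df)
  class(df) <- c("region_registry", "data.frame")
  df
}

region_id_by_name <- function(registry, names) {
  idx <- match(names, registry$name)
  if (anyNA(idx))
    stop(sprintf("unknown region name(s): %s",
                 paste(names[is.na(idx)], collapse = ", ")), call. = FALSE)
  registry$region_id[idx]
}
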