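#' White-matter tract atlas registry
#'
#' Returns the packaged registry of 48 white-matter tracts, each labelled with
#' one of seven tract types: limbic, association, projection, and transcallosal
#' (TC) groups for prefrontal, motor, parietal and occipital cortex. Tract
#' means of the five free-water metrics over this registry give the standard
#' 240-column feature block (48 tracts x 5 metrics).
#'
#' Two modes are supported. In tabular mode (the default) each tract carries a
#' column-name key used to address feature columns in a study table. In image
#' mode, masks can be attached afterwards with [attach_atlas_masks()] for use
#' with [extract_features()].
#'
#' @return A data.frame of class `tract_atlas` with columns `tract`,
#'   `tract_type`, and `key`.
#' @examples
#' atlas <- atlas_registry()
#' nrow(atlas)            # 48
#' table(atlas$tract_type)
#' @export
atlas_registry <- function() {
  tracts <- list(
    limbic = c("cingulum", "fornix", "uncinate_fasciculus",
               "parahippocampal_cingulum"),
    association = c("SLF", "SLF_TP", "ILF", "IFOF", "arcuate_fasciculus",
                    "middle_longitudinal_fasciculus", "frontal_aslant_tract",
                    "extreme_capsule"),
    projection = c("corticospinal_tract", "anterior_thalamic_radiation",
                   "superior_thalamic_radiation", "posterior_thalamic_radiation",
                   "corticostriatal_tract", "optic_radiation"),
    prefrontal_TC = c("TC_superior_frontal_gyrus", "TC_middle_frontal_gyrus",
                      "TC_IFG", "TC_medial_frontal_gyrus",
                      "TC_orbitofrontal_cortex", "TC_frontal_pole",
                      "TC_lateral_orbitofrontal", "TC_dorsolateral_prefrontal",
                      "TC_ventromedial_prefrontal", "TC_anterior_cingulate"),
    motor_TC = c("TC_M1", "TC_SMA", "TC_preSMA", "TC_PMd", "TC_PMv",
                 "TC_paracentral_lobule", "TC_S1", "TC_frontal_eye_field"),
    parietal_TC = c("TC_SPL", "TC_IPL", "TC_angular_gyrus",
                    "TC_supramarginal_gyrus", "TC_precuneus",
                    "TC_postcentral_gyrus", "TC_posterior_cingulate"),
    occipital_TC = c("TC_V1", "TC_lateral_occipital", "TC_cuneus",
                     "TC_lingual_gyrus", "TC_fusiform_gyrus")
  )
  out <- data.frame(
    tract = unlist(tracts, use.names = FALSE),
    tract_type = rep(names(tracts), lengths(tracts)),
    stringsAsFactors = FALSE
  )
  out$key <- out$tract
  stopifnot(nrow(out) == 48L, !anyDuplicated(out$tract))
  class(out) <- c("tract_atlas", "data.frame")
  out
}

#' The five microstructural metrics
#'
#' Free water (FW) plus the four free-water-corrected tensor scalars:
#' corrected fractional anisotropy (FAt), mean (MDt), axial (AxDt) and radial
#' (RDt) diffusivity.
#' @return Character vector of length 5.
#' @export
fw_metrics <- function() c("FW", "FAt", "MDt", "AxDt", "RDt")

#' Feature column names for a tract atlas
#'
#' @param atlas a `tract_atlas`, or a character vector of tract names.
#' @param metrics metric names, default all five.
#' @return Character vector `"<tract>.<metric>"`, tracts varying slowest.
#' @export
feature_names <- function(atlas = atlas_registry(), metrics = fw_metrics()) {
  tracts <- if (is.data.frame(atlas)) atlas$tract else as.character(atlas)
  as.vector(t(outer(tracts, metrics, paste, sep = ".")))
}

#' Attach 3-D masks to an atlas for image-mode feature extraction
#'
#' @param atlas a `tract_atlas`.
#' @param masks named list of 3-D arrays (binary or probabilistic weights),
#'   names matching `atlas$tract`.
#' @return The atlas with a `masks` attribute.
#' @export
attach_atlas_masks <- function(atlas, masks) {
  stopifnot(inherits(atlas, "tract_atlas"), is.list(masks))
  missing <- setdiff(atlas$tract, names(masks))
  if (length(missing)) {
    fw_stop(paste0("masks missing for tracts: ", paste(missing, collapse = ", ")),
            "fwtrace_config_error")
  }
  attr(atlas, "masks") <- masks[atlas$tract]
  atlas
}

#' @export
print.tract_atlas <- function(x, ...) {
  cat("<tract_atlas> ", nrow(x), " tracts in ", length(unique(x$tract_type)),
      " types\n", sep = "")
  tt <- table(x$tract_type)
  for (nm in names(tt)) cat(sprintf("  %-14s %d\n", nm, tt[[nm]]))
  invisible(x)
}
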