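#' Region-of-interest registry
#'
#' The named brain regions and white-matter tracts that the pipeline knows
#' about: 13 bilateral cortical grey matter regions, whole subcortical
#' structures (plus whole brain), a set of subfield-level grey matter
#' regions, and 15 JHU-atlas white matter tracts. Grey matter regions carry
#' a volume measure (mm^3); tracts carry fractional anisotropy (FA,
#' unitless in \[0, 1\]) and mean diffusivity (MD, mm^2/s).
#'
#' Subfield-level regions (amygdala, hippocampus, thalamus and hypothalamus
#' subdivisions) are registry entries usable in effect maps and abnormality
#' maps but are excluded from default progression runs, which focus on
#' whole structures.
#'
#' @return A data frame with columns `roi`, `class` (one of `"cortical"`,
#'   `"subcortical"`, `"subfield"`, `"wm_tract"`) and `default_progression`
#'   (logical; whether the region enters progression analyses by default).
#' @examples
#' head(roi_registry())
#' @export
roi_registry <- function() {
  cortical <- c("orbitofrontal", "dlpfc", "vmpfc", "motor", "insula",
                "temporal_pole", "dorsolateral_temporal", "medial_temporal",
                "cingulate", "sensory", "medial_parietal", "lateral_parietal",
                "occipital")
  subcortical <- c("nucleus_accumbens", "caudate", "putamen", "globus_pallidus",
                   "basal_forebrain", "amygdala", "hippocampus", "thalamus",
                   "hypothalamus", "cerebellum", "brainstem", "whole_brain")
  subfield <- c("pulvinar", "mediodorsal_thalamus", "lateral_geniculate",
                "presubiculum", "subiculum", "ca1", "dentate_gyrus",
                "lateral_nucleus_amygdala", "posterior_hypothalamus",
                "superior_tuberal_hypothalamus")
  tracts <- c("UF", "SLF", "cingulum", "SS", "pTR", "aCR", "pCR", "sCR",
              "EC", "aIC", "pIC", "rIC", "gCC", "bCC", "sCC")
  data.frame(
    roi = c(cortical, subcortical, subfield, tracts),
    class = rep(c("cortical", "subcortical", "subfield", "wm_tract"),
                times = c(length(cortical), length(subcortical),
                          length(subfield), length(tracts))),
    default_progression = rep(c(TRUE, TRUE, FALSE, TRUE),
                              times = c(length(cortical), length(subcortical),
                                        length(subfield), length(tracts))),
    stringsAsFactors = FALSE
  )
}

#' Modalities carried by each registry class
#' @keywords internal
roi_modalities <- function(class) {
  if (class == "wm_tract") c("FA", "MD") else "volume"
}

#' Scanner categories used throughout the package
#'
#' Five 3T scanner types; the multi-site design is modelled with one
#' additive offset per non-reference category.
#' @return Character vector of the five scanner category labels.
#' @export
scanner_types <- function() {
  c("SiemensTrio", "SiemensSkyra", "SiemensPrisma",
    "PhilipsAchieva", "GEDiscoveryMR750")
}

#' Default (roi, modality) grid
#'
#' @param include_subfields Include subfield-level regions?
#' @return Data frame with columns `roi`, `modality`.
#' @keywords internal
roi_modality_grid <- function(include_subfields = TRUE) {
  reg <- roi_registry()
  if (!include_subfields) reg <- reg[reg$class != "subfield", , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    data.frame(roi = reg$roi[i], modality = roi_modalities(reg$class[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
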