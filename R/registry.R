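#' The default radiomics feature registry
#'
#' Returns the ordered catalogue of the 47 regional radiomics features the
#' package extracts per brain region: 14 first-order intensity statistics,
#' 8 shape descriptors of the region mask, 13 grey-level co-occurrence
#' matrix (GLCM) texture features and 12 grey-level run-length matrix
#' (GLRLM) texture features. Feature order is fixed and is serialized with
#' every output so that feature spaces are comparable across subjects and
#' modalities.
#'
#' @return A data frame with columns `name` and `family`
#'   (`firstorder`, `shape`, `glcm`, `glrlm`), one row per feature,
#'   in extraction order.
#' @examples
#' reg <- feature_registry()
#' nrow(reg)          # 47
#' table(reg$family)
#' @export
feature_registry <- function() {
  firstorder <- c(
    "fo_mean", "fo_median", "fo_sd", "fo_variance", "fo_skewness",
    "fo_kurtosis", "fo_energy", "fo_entropy", "fo_min", "fo_max",
    "fo_range", "fo_mad", "fo_rms", "fo_uniformity"
  )
  shape <- c(
    "sh_volume", "sh_surface_area", "sh_surface_to_volume", "sh_sphericity",
    "sh_compactness1", "sh_compactness2", "sh_spherical_disproportion",
    "sh_max_diameter"
  )
  glcm <- c(
    "glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity",
    "glcm_entropy", "glcm_dissimilarity", "glcm_cluster_shade",
    "glcm_cluster_prominence", "glcm_max_probability", "glcm_sum_average",
    "glcm_sum_entropy", "glcm_difference_entropy", "glcm_inverse_difference"
  )
  glrlm <- c(
    "glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln", "glrlm_rp",
    "glrlm_lgre", "glrlm_hgre", "glrlm_srlge", "glrlm_srhge",
    "glrlm_lrlge", "glrlm_lrhge", "glrlm_rlv"
  )
  data.frame(
    name = c(firstorder, shape, glcm, glrlm),
    family = rep(
      c("firstorder", "shape", "glcm", "glrlm"),
      times = c(length(firstorder), length(shape), length(glcm), length(glrlm))
    ),
    stringsAsFactors = FALSE
  )
}
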