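# The 647-feature radiomics bank: 8 shape features computed once on the
# mask, plus 71 intensity/texture features (14 first-order + 22 GLCM +
# 16 GLRLM + 14 GLSZM + 5 NGTDM) on each of 9 image sources (the
# original volume and its 8 undecimated-wavelet bands).
# 8 + 9 * 71 = 647.

intensity_names <- c("mean", "median", "min", "max", "range", "variance",
                     "sd", "skewness", "kurtosis", "energy", "rms", "mad",
                     "entropy", "uniformity")
glcm_names <- c("autocorrelation", "cluster_prominence", "cluster_shade",
                "cluster_tendency", "contrast", "correlation",
                "difference_average", "difference_entropy",
                "difference_variance", "dissimilarity", "energy", "entropy",
                "homogeneity", "idm", "idmn", "idn", "imc1", "imc2",
                "inverse_variance", "max_probability", "sum_average",
                "sum_entropy")
glrlm_names <- c("short_run_emphasis", "long_run_emphasis",
                 "gray_level_nonuniformity",
                 "gray_level_nonuniformity_normalized",
                 "run_length_nonuniformity",
                 "run_length_nonuniformity_normalized", "run_percentage",
                 "gray_level_variance", "run_length_variance", "run_entropy",
                 "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
                 "short_run_low_gray_level_emphasis",
                 "short_run_high_gray_level_emphasis",
                 "long_run_low_gray_level_emphasis",
                 "long_run_high_gray_level_emphasis")
glszm_names <- c("small_area_emphasis", "large_area_emphasis",
                 "gray_level_nonuniformity",
                 "gray_level_nonuniformity_normalized",
                 "size_zone_nonuniformity",
                 "size_zone_nonuniformity_normalized", "zone_percentage",
                 "gray_level_variance", "zone_size_variance", "zone_entropy",
                 "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
                 "small_area_low_gray_level_emphasis",
                 "small_area_high_gray_level_emphasis")
ngtdm_names <- c("coarseness", "contrast", "busyness", "complexity",
                 "strength")
shape_names <- c("volume_mm3", "surface_mm2", "surface_to_volume",
                 "sphericity", "compactness1", "compactness2",
                 "spherical_disproportion", "max_diameter_mm")
band_labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' The canonical radiomics feature-name vocabulary
#'
#' Enumerates the full bank of 647 feature names in their stable order:
#' 8 shape features (mask only), then for each of the 9 image sources
#' (`original`, `wavelet_LLL` ... `wavelet_HHH`) 14 first-order, 22 GLCM,
#' 16 GLRLM, 14 GLSZM and 5 NGTDM features.  Names follow
#' `<source>_<family>_<feature>` and are collision-free.
#'
#' @param manifest if `TRUE`, return a data.frame with columns `name`,
#'   `source`, `family`, `feature` instead of the bare name vector.
#' @return Character vector of length 647, or the manifest data.frame.
#' @export
feature_bank <- function(manifest = FALSE) {
  sources <- c("original", paste0("wavelet_", band_labels))
  rows <- data.frame(name = paste0("original_shape_", shape_names),
                     source = "original", family = "shape",
                     feature = shape_names, stringsAsFactors = FALSE)
  fam <- list(firstorder = intensity_names, glcm = glcm_names,
              glrlm = glrlm_names, glszm = glszm_names, ngtdm = ngtdm_names)
  for (src in sources) {
    for (f in names(fam)) {
      rows <- rbind(rows, data.frame(
        name = paste(src, f, fam[[f]], sep = "_"),
        source = src, family = f, feature = fam[[f]],
        stringsAsFactors = FALSE))
    }
  }
  stopifnot(nrow(rows) == 647L, !anyDuplicated(rows$name))
  if (manifest) rows else rows$name
}

# 71 intensity + texture features for one image source
source_features <- function(values, patch_template, n_bins) {
  patch <- patch_template
  patch$values <- values
  q <- quantize(patch, n_bins)
  c(stats::setNames(intensity_features(patch, n_bins),
                    paste0("firstorder_", intensity_names)),
    stats::setNames(glcm_features(q), paste0("glcm_", glcm_names)),
    stats::setNames(glrlm_features(q), paste0("glrlm_", glrlm_names)),
    stats::setNames(glszm_features(q), paste0("glszm_", glszm_names)),
    stats::setNames(ngtdm_features(q), paste0("ngtdm_", ngtdm_names)))
}

#' Extract the full 647-feature vector for one volume/mask pair
#'
#' Computes the 8 shape features from the mask, decomposes the volume
#' with the one-level undecimated wavelet transform, and computes the 71
#' first-order + texture features on the original image and on each of
#' the 8 bands, always over the same ROI voxels.  Quantization (default
#' 32 equal-width bins over the ROI range) is done per image source.
#'
#' @param volume a [phase_volume()].
#' @param mask its aligned [roi_mask()].
#' @param n_bins gray levels for quantization (default 32).
#' @return Named numeric vector of length 647, names as in
#'   [feature_bank()], all finite for non-degenerate ROIs.
#' @export
extract_feature_vector <- function(volume, mask, n_bins = 32L) {
  check_aligned(volume, mask)
  patch <- extract_roi(volume, mask)
  idx <- patch$positions
  bands <- undecimated_wavelet3d(volume)

  fv0 <- source_features(patch$values, patch, n_bins)
  out <- c(stats::setNames(shape_features(mask),
                           paste0("original_shape_", shape_names)),
           stats::setNames(fv0, paste0("original_", names(fv0))))
  for (lab in band_labels) {
    vals <- as.numeric(bands[[lab]][idx])
    fv <- source_features(vals, patch, n_bins)
    names(fv) <- paste0("wavelet_", lab, "_", names(fv))
    out <- c(out, fv)
  }
  stopifnot(identical(names(out), feature_bank()))
  out
}

#' Extract the feature matrix for a cohort phase
#'
#' Runs [extract_feature_vector()] for every patient of a cohort on one
#' contrast phase.
#'
#' @param cohort an `ablarec_cohort` with images.
#' @param phase `"arterial"`, `"portal_venous"` or `"parenchymal"`.
#' @param n_bins gray levels for quantization.
#' @return Numeric matrix, patients x 647, rownames = patient ids.
#' @export
extract_feature_matrix <- function(cohort, phase, n_bins = 32L) {
  mats <- lapply(cohort, function(p) {
    if (is.null(p$volumes)) stop("cohort was generated without images")
    extract_feature_vector(p$volumes[[phase]], p$mask, n_bins)
  })
  X <- do.call(rbind, mats)
  rownames(X) <- vapply(cohort, function(p) p$record$patient_id, character(1))
  X
}
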