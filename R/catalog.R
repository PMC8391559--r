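# canonical feature name lists, pinned: changing any entry is a contract
# change for every stored feature table

FIRSTORDER_FEATURES <- c(
  "Energy", "Entropy", "Minimum", "Percentile10", "Percentile90",
  "Maximum", "Mean", "Median", "InterquartileRange", "Range",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "Skewness", "Kurtosis", "Variance", "Uniformity"
)

SHAPE_FEATURES <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
  "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
  "Elongation", "Flatness"
)

GLCM_FEATURES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
  "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
  "JointEntropy", "MaximumProbability", "Mcc", "SumAverage",
  "SumEntropy", "SumSquares"
)

GLDM_FEATURES <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis"
)

GLSZM_FEATURES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance"
)

GLRLM_FEATURES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis"
)

NGTDM_FEATURES <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                    "Strength")

TEXTURE_GROUPS <- list(glcm = GLCM_FEATURES, gldm = GLDM_FEATURES,
                       glszm = GLSZM_FEATURES, glrlm = GLRLM_FEATURES,
                       ngtdm = NGTDM_FEATURES)

WAVELET_SUBBANDS <- c("HHH", "HHL", "HLH", "HLL", "LHH", "LHL", "LLH",
                      "LLL")

#' The canonical radiomics feature catalogue
#'
#' Per 3D image: 16 first-order + 14 shape + 24 GLCM + 14 GLDM + 16 GLSZM
#' + 16 GLRLM + 5 NGTDM = 105 original-image features, plus 91 features
#' (everything but shape) for each of the 8 wavelet sub-bands = 728, i.e.
#' 833 per time-point image and 2499 per patient over T0/Tmax/T2. The
#' ordering is canonical and stable; feature columns are named
#' `timepoint_imagetype_group_feature`.
#'
#' @param timepoints Character vector of time-point labels.
#' @return Tibble with columns `name`, `timepoint`, `image_type`, `group`,
#'   `feature`.
#' @export
feature_catalog <- function(timepoints = c("T0", "Tmax", "T2")) {
  one_image <- function(image_type) {
    groups <- if (image_type == "original") {
      c(list(firstorder = FIRSTORDER_FEATURES, shape = SHAPE_FEATURES),
        TEXTURE_GROUPS)
    } else {
      c(list(firstorder = FIRSTORDER_FEATURES), TEXTURE_GROUPS)
    }
    dplyr::bind_rows(purrr::imap(groups, function(feats, grp)
      tibble::tibble(image_type = image_type, group = grp,
                     feature = feats)))
  }
  per_tp <- dplyr::bind_rows(purrr::map(c("original", WAVELET_SUBBANDS),
                                        one_image))
  out <- dplyr::bind_rows(purrr::map(timepoints, function(tp)
    dplyr::mutate(per_tp, timepoint = tp, .before = 1)))
  dplyr::mutate(out,
                name = paste(timepoint, image_type, group, feature,
                             sep = "_"),
                .before = 1)
}

#' Persist the catalogue manifest
#' @param path JSON output path.
#' @param timepoints Passed to [feature_catalog()].
#' @return Invisibly, `path`.
#' @export
write_catalog_manifest <- function(path,
                                   timepoints = c("T0", "Tmax", "T2")) {
  jsonlite::write_json(feature_catalog(timepoints), path, digits = NA)
  invisible(path)
}
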