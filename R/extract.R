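# crop a 3D volume to the mask bounding box plus a physical margin
crop_to_mask <- function(mask, margin_mm, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  d <- dim(mask)
  rng <- lapply(1:3, function(a) {
    pad <- ceiling(margin_mm / spacing[a])
    c(max(1L, min(idx[, a]) - pad), min(d[a], max(idx[, a]) + pad))
  })
  lapply(rng, function(r) r[1]:r[2])
}

#' Preprocess one patient into standardized multi-band images
#'
#' Runs the per-patient half of the pipeline: VOI mean curve, baseline
#' detection, time-point selection, extraction of the three 3D volumes,
#' resampling to isotropic voxels (cropped to the lesion bounding box plus
#' a margin), the chosen standardization (conventional z-score `np`, or
#' relaxation-rate `p`), and the eight-band wavelet decomposition of each
#' volume.
#'
#' @param patient List with `series`, `mask`, `meta` (see
#'   [synthesize_patient()] / [cohort_patient()]).
#' @param version `"np"` (z-score, scale 100, cohort shift applied later)
#'   or `"p"` (dynamic relaxation-rate standardization).
#' @param target_spacing Isotropic output spacing, mm.
#' @param margin_mm Crop margin around the lesion, mm.
#' @param k_sd,return_tolerance_sd Curve thresholds, see
#'   [detect_baseline()] and [select_time_points()].
#' @param np_scale Scaling factor of the z-scored version.
#' @return List: `timepoints`, `mask` (resampled, cropped), `spacing`,
#'   `images` (list `[[timepoint]][[image_type]]` of 3D arrays, image
#'   types `original` plus the 8 sub-bands), `shape` (14 shape features),
#'   `n_clamped` (p version only).
#' @export
preprocess_patient <- function(patient, version = c("np", "p"),
                               target_spacing = 1, margin_mm = 8,
                               k_sd = 3, return_tolerance_sd = 1,
                               np_scale = 100) {
  version <- match.arg(version)
  meta <- patient$meta
  spacing <- as.numeric(meta$spacing)
  curve <- mean_voi_curve(patient$series, patient$mask, meta$time_step)
  tp <- select_time_points(detect_baseline(curve, k_sd = k_sd),
                           return_tolerance_sd = return_tolerance_sd)
  idxs <- c(T0 = tp$t0_idx, Tmax = tp$tmax_idx, T2 = tp$t2_idx)

  cr <- crop_to_mask(patient$mask, margin_mm, spacing)
  mask_c <- patient$mask[cr[[1]], cr[[2]], cr[[3]]]
  rs_mask <- NULL
  vols <- list()
  for (k in seq_along(idxs)) {
    v <- patient$series[cr[[1]], cr[[2]], cr[[3]], idxs[k]]
    rs <- resample_isotropic(v, spacing,
                             mask = if (k == 1) mask_c else NULL,
                             target = target_spacing)
    if (k == 1) rs_mask <- rs$mask
    vols[[names(idxs)[k]]] <- rs$volume
  }
  if (sum(rs_mask) == 0) stop("VOI vanished during resampling")

  n_clamped <- 0L
  if (version == "p") {
    vols <- lapply(vols, function(v) {
      out <- delta_r2(v, tp$baseline_mean, meta$te)
      n_clamped <<- n_clamped + attr(out, "n_clamped")
      out
    })
  } else {
    voi_all <- {
      d <- dim(patient$series)
      m <- matrix(patient$series, nrow = prod(d[1:3]))
      as.vector(m[which(patient$mask != 0), ])
    }
    vols <- np_normalize(vols, voi_all, scale = np_scale,
                         shift_reference = NULL)
  }

  images <- lapply(vols, function(v) c(list(original = v),
                                       wavelet_decompose(v)))
  shape <- shape_features(rs_mask, rep(target_spacing, 3))
  list(timepoints = tp, mask = rs_mask,
       spacing = rep(target_spacing, 3), images = images, shape = shape,
       n_clamped = n_clamped)
}

# reduce a preprocessed patient to the VOI-sparse representation the
# feature pass needs: bbox dims, VOI linear indices, one intensity column
# per (timepoint, image type)
reduce_preprocessed <- function(pp) {
  voi <- which(pp$mask != 0)
  cols <- list()
  for (tpn in names(pp$images))
    for (it in names(pp$images[[tpn]]))
      cols[[paste(tpn, it, sep = ".")]] <- pp$images[[tpn]][[it]][voi]
  list(dims = dim(pp$mask), voi = voi,
       values = do.call(cbind, cols), shape = pp$shape,
       timepoints = pp$timepoints, n_clamped = pp$n_clamped)
}

# features of one patient from the sparse representation
features_from_reduced <- function(red, disc_specs, np_shift = 0) {
  lll_shift <- np_shift * sum(COIF1_LO)^3
  tps <- c("T0", "Tmax", "T2")
  out <- numeric(0)
  for (tpn in tps) {
    for (it in c("original", WAVELET_SUBBANDS)) {
      v <- red$values[, paste(tpn, it, sep = ".")]
      if (it == "original") v <- v + np_shift
      if (it == "LLL") v <- v + lll_shift
      spec <- disc_specs[[it]]
      lev_v <- floor((v - min(v)) / spec$fbs) + 1
      lev_v[lev_v < 1] <- 1
      ng <- max(lev_v)
      fo <- firstorder_features(v, as.integer(lev_v))
      arr <- array(0L, dim = red$dims)
      arr[red$voi] <- as.integer(lev_v)
      tx <- texture_features(arr, ng)
      block <- if (it == "original") {
        c(stats::setNames(fo, paste0("firstorder_", names(fo))),
          stats::setNames(red$shape, paste0("shape_", names(red$shape))),
          tx)
      } else {
        c(stats::setNames(fo, paste0("firstorder_", names(fo))), tx)
      }
      names(block) <- paste(tpn, it, names(block), sep = "_")
      out <- c(out, block)
    }
  }
  bad <- !is.finite(out)
  if (any(bad)) out[bad] <- 0
  attr(out, "n_nonfinite") <- sum(bad)
  out
}

#' Extract the full 2499-feature vector of one preprocessed patient
#'
#' Features are ordered by [feature_catalog()]: per time point, the 105
#' original-image features (first-order, shape, GLCM, GLDM, GLSZM, GLRLM,
#' NGTDM) followed by 91 features for each of the 8 wavelet sub-bands.
#' Any non-finite feature is replaced by 0 and counted in the
#' `n_nonfinite` attribute; the output never contains NaN.
#'
#' @param pp A [preprocess_patient()] result.
#' @param disc_specs Named list of [build_discretization()] specs, one per
#'   image type (`original`, `HHH`, ..., `LLL`).
#' @param np_shift Cohort-level shift constant for the z-scored version
#'   (0 for the relaxation-rate version).
#' @return Named numeric vector of length 2499.
#' @export
extract_patient_features <- function(pp, disc_specs, np_shift = 0) {
  features_from_reduced(reduce_preprocessed(pp), disc_specs, np_shift)
}

#' Extract the feature table of a whole cohort
#'
#' Two passes over the cohort: the first preprocesses every patient and
#' collects per-patient VOI intensity ranges per image type; these define
#' the cohort-level fixed bin sizes (and, for the z-scored version, the
#' histogram-minimum shift). The second pass discretizes and computes all
#' 2499 features per patient. Passing `frozen` (from a previous cohort's
#' result) reuses that cohort's constants instead, which is how a
#' validation cohort must be processed.
#'
#' @param cohort A `dsc_cohort` (or a list with `manifest` and `patients`).
#' @param version `"np"` or `"p"`.
#' @param fbn Fixed bin number (32 or 64).
#' @param frozen Optional list with `disc_specs` and `np_shift` to reuse.
#' @param target_spacing,margin_mm,k_sd,return_tolerance_sd Passed to
#'   [preprocess_patient()].
#' @param verbose Print per-patient progress.
#' @return A tibble of class `radiomics_features`: `patient_id`, `center`,
#'   `label`, then the 2499 feature columns; attributes `version`, `fbn`,
#'   `disc_specs`, `np_shift`, `timepoints` (per-patient tibble),
#'   `qc` (clamped/non-finite counts).
#' @export
extract_cohort_features <- function(cohort, version = c("np", "p"),
                                    fbn = 32L, frozen = NULL,
                                    target_spacing = 1, margin_mm = 8,
                                    k_sd = 3, return_tolerance_sd = 1,
                                    verbose = FALSE) {
  version <- match.arg(version)
  man <- cohort$manifest
  n <- nrow(man)
  reduced <- vector("list", n)
  cache_dir <- NULL
  in_memory_budget <- n <= 64
  if (!in_memory_budget) cache_dir <- tempfile("dscr_cache_")
  if (!is.null(cache_dir)) dir.create(cache_dir)
  ranges <- vector("list", n)
  np_min <- Inf
  for (i in seq_len(n)) {
    pat <- cohort_patient(cohort, i)
    pp <- preprocess_patient(pat, version, target_spacing, margin_mm,
                             k_sd, return_tolerance_sd)
    red <- reduce_preprocessed(pp)
    itypes <- sub("^[^.]+\\.", "", colnames(red$values))
    rng <- vapply(c("original", WAVELET_SUBBANDS), function(it) {
      v <- red$values[, itypes == it]
      max(v) - min(v)
    }, numeric(1))
    ranges[[i]] <- rng
    if (version == "np")
      np_min <- min(np_min, min(red$values[, itypes == "original"]))
    if (is.null(cache_dir)) {
      reduced[[i]] <- red
    } else {
      saveRDS(red, file.path(cache_dir, paste0(i, ".rds")))
    }
    if (verbose) message("preprocessed ", man$patient_id[i])
  }
  range_mat <- do.call(rbind, ranges)
  if (is.null(frozen)) {
    disc_specs <- lapply(stats::setNames(nm = colnames(range_mat)),
                         function(it)
                           build_discretization(range_mat[, it], fbn))
    np_shift <- if (version == "np") -np_min else 0
  } else {
    disc_specs <- frozen$disc_specs
    np_shift <- frozen$np_shift
  }

  rows <- vector("list", n)
  tps <- vector("list", n)
  qc <- vector("list", n)
  for (i in seq_len(n)) {
    red <- if (is.null(cache_dir)) reduced[[i]] else
      readRDS(file.path(cache_dir, paste0(i, ".rds")))
    fv <- features_from_reduced(red, disc_specs,
                                if (version == "np") np_shift else 0)
    rows[[i]] <- fv
    tpi <- red$timepoints
    tps[[i]] <- tibble::tibble(patient_id = man$patient_id[i],
                               t0_idx = tpi$t0_idx,
                               tmax_idx = tpi$tmax_idx,
                               t2_idx = tpi$t2_idx)
    qc[[i]] <- tibble::tibble(patient_id = man$patient_id[i],
                              n_clamped = red$n_clamped,
                              n_nonfinite = attr(fv, "n_nonfinite"))
  }
  if (!is.null(cache_dir)) unlink(cache_dir, recursive = TRUE)
  fm <- do.call(rbind, rows)
  stopifnot(identical(colnames(fm), feature_catalog()$name))
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = man$patient_id, center = man$center,
                   label = man$label),
    tibble::as_tibble(fm)
  )
  structure(out, class = c("radiomics_features", class(out)),
            version = version, fbn = fbn, disc_specs = disc_specs,
            np_shift = np_shift, timepoints = dplyr::bind_rows(tps),
            qc = dplyr::bind_rows(qc))
}

#' Frozen cohort-level constants of a feature table
#'
#' @param features A `radiomics_features` tibble.
#' @return List with `disc_specs` and `np_shift`, suitable as the
#'   `frozen` argument of [extract_cohort_features()].
#' @export
frozen_constants <- function(features) {
  list(disc_specs = attr(features, "disc_specs"),
       np_shift = attr(features, "np_shift"))
}

#' Write / read a feature table as CSV with a catalogue check
#' @param features A `radiomics_features` tibble.
#' @param path CSV path.
#' @return `write_features` invisibly returns `path`; `read_features`
#'   returns a tibble whose feature columns are validated against the
#'   canonical catalogue order.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  want <- feature_catalog()$name
  got <- setdiff(colnames(x), c("patient_id", "center", "label"))
  if (!identical(got, want))
    stop("feature columns do not match the canonical catalogue order")
  x
}
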