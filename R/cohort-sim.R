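#' Acquisition protocol of one imaging center
#'
#' Describes a DSC-MRI acquisition the way a scanner protocol sheet would:
#' echo time, repetition time, number of dynamic frames, matrix and voxel
#' geometry, plus an arbitrary-unit intensity scale/offset standing in for
#' vendor- and reconstruction-specific signal calibration.
#'
#' @param center_id Character label of the center.
#' @param te Echo time in seconds (e.g. 0.030--0.040).
#' @param tr Repetition time in seconds.
#' @param n_timepoints Number of dynamic frames (>= 10, so that at least 5
#'   baseline frames are possible).
#' @param time_step Temporal resolution in seconds per frame.
#' @param matrix_size Integer vector (nx, ny), in-plane matrix.
#' @param n_slices Number of axial slices.
#' @param in_plane_spacing In-plane voxel spacing, mm.
#' @param slice_thickness Slice thickness (= slice spacing), mm.
#' @param intensity_scale Baseline tissue signal in arbitrary units.
#' @param intensity_offset Additive signal offset in arbitrary units.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(center_id, te, tr, n_timepoints, time_step,
                          matrix_size = c(128L, 128L), n_slices = 20L,
                          in_plane_spacing = 1.718, slice_thickness = 5,
                          intensity_scale = 1000, intensity_offset = 0) {
  stopifnot(te > 0, tr > 0, n_timepoints >= 10, time_step > 0,
            all(matrix_size > 0), n_slices > 0, in_plane_spacing > 0,
            slice_thickness > 0, intensity_scale > 0, intensity_offset >= 0)
  structure(list(
    center_id = as.character(center_id), te = te, tr = tr,
    n_timepoints = as.integer(n_timepoints), time_step = time_step,
    matrix_size = as.integer(matrix_size), n_slices = as.integer(n_slices),
    in_plane_spacing = in_plane_spacing, slice_thickness = slice_thickness,
    intensity_scale = intensity_scale, intensity_offset = intensity_offset
  ), class = "protocol_spec")
}

#' Tumor phenotype driving bolus kinetics and texture
#'
#' The phenotype parametrizes what the downstream features must detect:
#' the depth and steepness of the first-pass signal drop (gamma-variate
#' relaxation-rate kinetics) and the spatial heterogeneity of the lesion
#' (a smoothed Gaussian random field modulating the mean curve).
#' The wildtype-like phenotype defaults to a deeper, steeper bolus and a
#' shorter texture correlation length (more heterogeneous) than the
#' mutant-like one.
#'
#' `bolus_depth` is the fractional signal drop realized at `te_ref`; the
#' underlying peak relaxation-rate change is `-log(1 - bolus_depth) / te_ref`
#' and is what the phenotype fixes across centers. When `te_ref` is `NULL`
#' the protocol's own echo time is used, so the drop equals `bolus_depth`
#' exactly on that scanner.
#'
#' @param label `"wildtype"` or `"mutant"`.
#' @param bolus_depth Fractional signal drop at the gamma-variate peak, in
#'   (0, 1), realized at `te_ref`.
#' @param bolus_steepness Gamma-variate shape parameter alpha (> 0); larger
#'   with shorter `bolus_recovery` means a steeper downslope.
#' @param bolus_recovery Gamma-variate time scale beta in seconds.
#' @param texture_corr_length Correlation length of the lesion texture
#'   field, mm (Gaussian smoothing sigma in physical units).
#' @param texture_noise_sd Standard deviation of the multiplicative texture
#'   field, as a fraction of the local mean signal.
#' @param lesion_radius_range Two-element range of the spherical lesion
#'   radius, mm.
#' @param arrival_window Two-element range of bolus arrival time, seconds.
#' @param measurement_noise_sd Per-voxel, per-frame white measurement noise
#'   as a fraction of the baseline signal.
#' @param plateau_offset Optional post-bolus relaxation-rate plateau as a
#'   fraction of the peak (0 = full recovery, the default).
#' @param param_cv Lognormal coefficient of variation applied per patient to
#'   the kinetic and texture parameters (0 = all patients identical).
#' @param te_ref Reference echo time (s) at which `bolus_depth` is defined;
#'   `NULL` uses each protocol's own TE.
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(label = c("wildtype", "mutant"),
                           bolus_depth = 0.4, bolus_steepness = 2,
                           bolus_recovery = 2.5,
                           texture_corr_length = 3, texture_noise_sd = 0.1,
                           lesion_radius_range = c(8, 14),
                           arrival_window = c(18, 26),
                           measurement_noise_sd = 0.01,
                           plateau_offset = 0, param_cv = 0, te_ref = NULL) {
  label <- match.arg(label)
  stopifnot(bolus_depth > 0, bolus_depth < 1, bolus_steepness > 0,
            bolus_recovery > 0, texture_corr_length > 0,
            texture_noise_sd >= 0, all(lesion_radius_range > 0),
            length(lesion_radius_range) == 2,
            measurement_noise_sd >= 0, plateau_offset >= 0,
            plateau_offset < 1, param_cv >= 0)
  structure(list(
    label = label, bolus_depth = bolus_depth,
    bolus_steepness = bolus_steepness, bolus_recovery = bolus_recovery,
    texture_corr_length = texture_corr_length,
    texture_noise_sd = texture_noise_sd,
    lesion_radius_range = as.numeric(lesion_radius_range),
    arrival_window = as.numeric(arrival_window),
    measurement_noise_sd = measurement_noise_sd,
    plateau_offset = plateau_offset, param_cv = param_cv, te_ref = te_ref
  ), class = "phenotype_spec")
}

#' Default phenotypes for the two IDH classes
#'
#' Wildtype-like lesions have a deeper and steeper first-pass drop and a
#' shorter, stronger texture field than mutant-like lesions; both carry
#' patient-to-patient lognormal parameter jitter so the classes overlap.
#'
#' @param effect If `FALSE`, the wildtype phenotype is replaced by a copy of
#'   the mutant one (a null cohort: labels carry no image information).
#' @return Named list with elements `wildtype` and `mutant`.
#' @export
default_phenotypes <- function(effect = TRUE) {
  mutant <- phenotype_spec("mutant",
    bolus_depth = 0.30, bolus_steepness = 1.6, bolus_recovery = 3.0,
    texture_corr_length = 4, texture_noise_sd = 0.11,
    param_cv = 0.2, te_ref = 0.040)
  wildtype <- phenotype_spec("wildtype",
    bolus_depth = 0.45, bolus_steepness = 2.2, bolus_recovery = 2.0,
    texture_corr_length = 3, texture_noise_sd = 0.13,
    param_cv = 0.2, te_ref = 0.040)
  if (!effect) {
    wildtype <- mutant
    wildtype$label <- "wildtype"
  }
  list(wildtype = wildtype, mutant = mutant)
}

#' Default three-center protocol mix
#'
#' Three tertiary centers with distinct scanners: center A (3T, TE 40 ms,
#' TR 1.8 s, 60 frames at 1.87 s), center B with two protocol variants
#' (TE 30 ms; 60 frames at 2.07 s and 40 frames at 1.53 s) and center C
#' (1.5T, TE 40 ms, TR 1.525 s, 60 frames at 1.8 s). All use a 128 x 128
#' matrix with ~1.7 mm in-plane resolution and 5 mm slices; intensity
#' scales and offsets differ per scanner.
#'
#' @param matrix_size,n_slices Optional overrides of the simulated grid, to
#'   scale the problem size down (the lesion, not the grid, carries the
#'   information).
#' @return List of `protocol_spec` objects named by protocol variant.
#' @export
default_protocols <- function(matrix_size = c(128L, 128L), n_slices = 20L) {
  list(
    A  = protocol_spec("A", te = 0.040, tr = 1.800, n_timepoints = 60,
                       time_step = 1.87, matrix_size = matrix_size,
                       n_slices = n_slices, in_plane_spacing = 1.718,
                       intensity_scale = 1000, intensity_offset = 0),
    B1 = protocol_spec("B", te = 0.030, tr = 1.870, n_timepoints = 60,
                       time_step = 2.07, matrix_size = matrix_size,
                       n_slices = n_slices, in_plane_spacing = 1.719,
                       intensity_scale = 1450, intensity_offset = 60),
    B2 = protocol_spec("B", te = 0.030, tr = 1.850, n_timepoints = 40,
                       time_step = 1.53, matrix_size = matrix_size,
                       n_slices = n_slices, in_plane_spacing = 1.796,
                       intensity_scale = 1450, intensity_offset = 60),
    C  = protocol_spec("C", te = 0.040, tr = 1.525, n_timepoints = 60,
                       time_step = 1.80, matrix_size = matrix_size,
                       n_slices = n_slices, in_plane_spacing = 1.750,
                       intensity_scale = 650, intensity_offset = 30)
  )
}

#' Cohort specification
#'
#' Binds protocols, phenotypes, per-protocol patient counts and wildtype
#' fractions into a reproducible cohort recipe. Defaults follow the
#' three-center composition 92/50/18 with 26, 11 and 4 wildtype patients
#' respectively (mutant majority, 119/160).
#'
#' @param protocols List of [protocol_spec()] objects.
#' @param n_per_center Integer patient count per protocol entry.
#' @param wildtype_fraction_per_center Wildtype proportion per protocol
#'   entry, each strictly in (0, 1).
#' @param phenotypes List with elements `wildtype` and `mutant`
#'   ([phenotype_spec()]).
#' @param seed Integer seed; the whole cohort regenerates identically from
#'   it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(protocols = default_protocols(),
                        n_per_center = c(92L, 25L, 25L, 18L),
                        wildtype_fraction_per_center =
                          c(26 / 92, 5 / 25, 6 / 25, 4 / 18),
                        phenotypes = default_phenotypes(),
                        seed = 1L) {
  stopifnot(length(protocols) == length(n_per_center),
            length(n_per_center) == length(wildtype_fraction_per_center),
            all(wildtype_fraction_per_center > 0),
            all(wildtype_fraction_per_center < 1),
            all(n_per_center >= 1))
  structure(list(
    protocols = protocols, n_per_center = as.integer(n_per_center),
    wildtype_fraction_per_center = wildtype_fraction_per_center,
    phenotypes = phenotypes, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# per-patient realization of phenotype parameters (lognormal jitter)
draw_patient_params <- function(protocol, phenotype) {
  te_ref <- if (is.null(phenotype$te_ref)) protocol$te else phenotype$te_ref
  r2_peak <- -log(1 - phenotype$bolus_depth) / te_ref
  jit <- function(x) {
    if (phenotype$param_cv == 0) return(x)
    x * exp(stats::rnorm(1, 0, phenotype$param_cv))
  }
  list(
    r2_peak = jit(r2_peak),
    alpha = phenotype$bolus_steepness,
    beta = jit(phenotype$bolus_recovery),
    t_arrival = stats::runif(1, phenotype$arrival_window[1],
                             phenotype$arrival_window[2]),
    corr_length = jit(phenotype$texture_corr_length),
    noise_sd = jit(phenotype$texture_noise_sd),
    radius = stats::runif(1, phenotype$lesion_radius_range[1],
                          phenotype$lesion_radius_range[2]),
    plateau = phenotype$plateau_offset
  )
}

# gamma-variate relaxation-rate kinetics on the protocol's time grid;
# arrival snapped so the continuous peak lands on a sampled frame
gamma_variate_r2 <- function(params, protocol) {
  tt <- (seq_len(protocol$n_timepoints) - 1) * protocol$time_step
  ttp <- params$alpha * params$beta
  peak_t <- protocol$time_step * round((params$t_arrival + ttp) /
                                         protocol$time_step)
  ta <- peak_t - ttp
  x <- tt - ta
  r2 <- numeric(length(tt))
  pos <- x > 0
  r2[pos] <- params$r2_peak *
    (x[pos] / ttp)^params$alpha * exp(params$alpha - x[pos] / params$beta)
  if (params$plateau > 0) {
    post <- tt > peak_t
    r2[post] <- pmax(r2[post], params$plateau * params$r2_peak)
  }
  list(r2 = r2, t_arrival = ta, arrival_idx = which(pos)[1],
       peak_idx = which.max(r2), time = tt)
}

#' Simulate the mean tissue bolus curve of one patient
#'
#' Gamma-variate relaxation-rate kinetics mapped to signal through the
#' mono-exponential echo-time decay `S(t) = offset + S0 exp(-TE dR2(t))`:
#' a flat baseline, a drop to a unique minimum at the gamma-variate peak,
#' and recovery toward baseline.
#'
#' @param protocol A [protocol_spec()].
#' @param phenotype A [phenotype_spec()].
#' @param seed Integer seed; identical inputs give identical curves.
#' @return A tibble (class `dsc_curve`) with columns `index`, `time_s`,
#'   `signal`, and attributes `r2` (the injected kinetics), `s0` (baseline
#'   signal), `arrival_idx`, `peak_idx`, `te`, `time_step`.
#' @export
simulate_bolus_curve <- function(protocol, phenotype, seed = 1L) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(phenotype, "phenotype_spec"))
  withr::local_seed(seed)
  params <- draw_patient_params(protocol, phenotype)
  kin <- gamma_variate_r2(params, protocol)
  s0 <- protocol$intensity_scale
  signal <- protocol$intensity_offset + s0 * exp(-protocol$te * kin$r2)
  if (phenotype$measurement_noise_sd > 0)
    signal <- signal + stats::rnorm(length(signal), 0,
                                    phenotype$measurement_noise_sd * s0)
  out <- tibble::tibble(index = seq_along(signal), time_s = kin$time,
                        signal = signal)
  structure(out,
            class = c("dsc_curve", class(out)),
            r2 = kin$r2, s0 = s0 + protocol$intensity_offset,
            arrival_idx = kin$arrival_idx, peak_idx = kin$peak_idx,
            te = protocol$te, time_step = protocol$time_step,
            params = params)
}

# spatially correlated multiplicative field on a grid block;
# smoothed white noise, rescaled to an exact sd over the VOI voxels
correlated_field <- function(dims, spacing, sigma_mm, target_sd, voi_idx) {
  g <- array(stats::rnorm(prod(dims)), dim = dims)
  for (ax in 1:3) {
    sig_vox <- sigma_mm / spacing[ax]
    half <- max(1L, ceiling(3 * sig_vox))
    k <- stats::dnorm(seq(-half, half), sd = sig_vox)
    k <- k / sum(k)
    g <- filter_axis_kernel(g, k, ax)
  }
  s <- stats::sd(g[voi_idx])
  if (s == 0) return(array(0, dims))
  g <- g - mean(g[voi_idx])
  g * (target_sd / s)
}

# separable correlation along one axis with reflected boundaries
filter_axis_kernel <- function(vol, k, axis) {
  d <- dim(vol)
  n <- d[axis]
  half <- (length(k) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  base <- seq_len(n)
  for (j in seq_along(k)) {
    idx <- base + (j - half - 1L)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  v <- array(out, dim = d[perm])
  aperm(v, order(perm))
}

#' Synthesize one patient's 4D dynamic series and tumor mask
#'
#' A spherical lesion is placed at a random position inside the matrix; VOI
#' voxels follow the patient's bolus curve modulated by a multiplicative
#' spatially correlated texture field, voxels outside follow a flat
#' background, and optional white measurement noise is added everywhere.
#'
#' @inheritParams simulate_bolus_curve
#' @param seed Integer seed.
#' @return List with elements `series` (4D array, x-y-z-t), `mask` (3D
#'   integer array of 0/1) and `meta` (list: te, tr, time_step, spacing,
#'   center_id, label, ground-truth kinetics and texture parameters).
#' @export
synthesize_patient <- function(protocol, phenotype, seed = 1L) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(phenotype, "phenotype_spec"))
  withr::local_seed(seed)
  params <- draw_patient_params(protocol, phenotype)
  kin <- gamma_variate_r2(params, protocol)
  spacing <- c(protocol$in_plane_spacing, protocol$in_plane_spacing,
               protocol$slice_thickness)
  dims <- c(protocol$matrix_size, protocol$n_slices)
  extent <- dims * spacing
  r <- params$radius
  margin <- 2
  if (any(2 * (r + margin) > extent))
    stop("lesion radius ", round(r, 1), " mm does not fit inside the ",
         paste(round(extent, 1), collapse = " x "), " mm matrix")
  center <- vapply(1:3, function(a)
    stats::runif(1, r + margin, extent[a] - r - margin), numeric(1))
  # voxel centres at (i - 1) * spacing
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) * spacing[a]))
  dx2 <- outer((ax[[1]] - center[1])^2,
               outer((ax[[2]] - center[2])^2, (ax[[3]] - center[3])^2, "+"),
               "+")
  mask <- array(as.integer(dx2 <= r^2), dim = dims)
  if (sum(mask) == 0) stop("empty lesion mask; radius too small for grid")
  voi_idx <- which(mask == 1L)

  g <- if (params$noise_sd > 0) {
    correlated_field(dims, spacing, params$corr_length, params$noise_sd,
                     voi_idx)
  } else {
    array(0, dims)
  }

  s0 <- protocol$intensity_scale
  curve <- s0 * exp(-protocol$te * kin$r2) # without offset
  nt <- protocol$n_timepoints
  series <- array(0, dim = c(dims, nt))
  bg <- protocol$intensity_offset + 0.6 * s0
  vox_scale <- 1 + g[voi_idx]
  nvox <- prod(dims)
  for (t in seq_len(nt)) {
    frame <- array(bg, dim = dims)
    frame[voi_idx] <- protocol$intensity_offset + curve[t] * vox_scale
    if (phenotype$measurement_noise_sd > 0)
      frame <- frame + stats::rnorm(nvox, 0,
                                    phenotype$measurement_noise_sd * s0)
    series[, , , t] <- frame
  }
  meta <- list(
    center_id = protocol$center_id, te = protocol$te, tr = protocol$tr,
    time_step = protocol$time_step, spacing = spacing,
    label = phenotype$label, radius_mm = r,
    r2_truth = kin$r2, arrival_idx = kin$arrival_idx,
    peak_idx = kin$peak_idx, params = params
  )
  list(series = series, mask = mask, meta = meta)
}

#' Generate a multi-center synthetic cohort
#'
#' Draws per-protocol patient counts with rounded wildtype fractions,
#' synthesizes every patient and either keeps the volumes in memory or
#' writes one 4D NIfTI (series), one 3D NIfTI (mask) and one JSON metadata
#' file per patient plus a cohort manifest CSV.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory; `NULL` keeps patients in memory (element
#'   `patients` of the result).
#' @return A list of class `dsc_cohort`: `manifest` (tibble with
#'   patient_id, center, protocol, label, file paths when written) and
#'   `patients` (list of [synthesize_patient()] results, `NULL` when
#'   written to disk), plus the generating `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)
  n_proto <- length(spec$protocols)
  rows <- list()
  patient_seeds <- sample.int(.Machine$integer.max - 1L,
                              sum(spec$n_per_center))
  k <- 0L
  for (p in seq_len(n_proto)) {
    n <- spec$n_per_center[p]
    n_wt <- round(spec$wildtype_fraction_per_center[p] * n)
    labels <- c(rep("wildtype", n_wt), rep("mutant", n - n_wt))
    for (i in seq_len(n)) {
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        patient_id = sprintf("P%03d", k),
        center = spec$protocols[[p]]$center_id,
        protocol = names(spec$protocols)[p] %||% as.character(p),
        label = labels[i],
        seed = patient_seeds[k]
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)

  patients <- vector("list", nrow(manifest))
  names(patients) <- manifest$patient_id
  series_path <- mask_path <- meta_path <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- match(manifest$protocol[i], names(spec$protocols))
    pat <- synthesize_patient(
      spec$protocols[[p]],
      spec$phenotypes[[manifest$label[i]]],
      seed = manifest$seed[i]
    )
    if (is.null(dir)) {
      patients[[i]] <- pat
    } else {
      id <- manifest$patient_id[i]
      series_path[i] <- file.path(dir, paste0(id, "_series.nii"))
      mask_path[i] <- file.path(dir, paste0(id, "_mask.nii"))
      meta_path[i] <- file.path(dir, paste0(id, "_meta.json"))
      write_patient_nifti(pat, series_path[i], mask_path[i], meta_path[i])
    }
  }
  if (!is.null(dir)) {
    manifest$series_path <- series_path
    manifest$mask_path <- mask_path
    manifest$meta_path <- meta_path
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    patients <- NULL
  }
  structure(list(manifest = manifest, patients = patients, spec = spec,
                 dir = dir),
            class = "dsc_cohort")
}

write_patient_nifti <- function(pat, series_path, mask_path, meta_path) {
  sp <- pat$meta$spacing
  img <- RNifti::asNifti(pat$series,
                         pixdim = c(sp, pat$meta$time_step),
                         datatype = "float")
  RNifti::writeNifti(img, series_path)
  msk <- RNifti::asNifti(pat$mask, pixdim = sp, datatype = "uint8")
  RNifti::writeNifti(msk, mask_path)
  meta <- pat$meta
  meta$r2_truth <- NULL # ground truth stays out of the on-disk analysis view
  meta$params <- NULL
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Load one patient of a written cohort
#'
#' @param cohort A `dsc_cohort`.
#' @param i Row index or patient id in the manifest.
#' @return The in-memory patient (list: `series`, `mask`, `meta`).
#' @export
cohort_patient <- function(cohort, i) {
  stopifnot(inherits(cohort, "dsc_cohort"))
  if (is.character(i)) i <- match(i, cohort$manifest$patient_id)
  if (!is.null(cohort$patients)) return(cohort$patients[[i]])
  series <- unclass(RNifti::readNifti(cohort$manifest$series_path[i]))
  mask <- unclass(RNifti::readNifti(cohort$manifest$mask_path[i]))
  storage.mode(mask) <- "integer"
  meta <- jsonlite::read_json(cohort$manifest$meta_path[i],
                              simplifyVector = TRUE)
  attributes(series) <- list(dim = dim(series))
  attributes(mask) <- list(dim = dim(mask))
  list(series = series, mask = mask, meta = meta)
}
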