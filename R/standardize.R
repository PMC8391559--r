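#' Baseline-correct a dynamic series
#'
#' Subtracts the last baseline signal (the frame at which contrast enters
#' the vasculature) from every frame, voxel-wise, using one patient-level
#' constant.
#'
#' @param series 4D array (or 3D volume / numeric vector).
#' @param baseline_last The last signal of the baseline (scalar).
#' @return Object of the same shape with the constant removed.
#' @export
baseline_correct <- function(series, baseline_last) {
  stopifnot(is.numeric(baseline_last), length(baseline_last) == 1)
  series - baseline_last
}

#' Relaxation-rate transform of a signal volume
#'
#' Converts raw DSC signal to the change in transverse relaxation rate,
#' `dR2 = (1/TE) log(baseline_mean / S)`, removing echo-time and
#' intensity-scale dependence: baseline voxels map to ~0 and deeper signal
#' drops map to larger dR2. Non-positive (or tiny) signal voxels are
#' clamped to `eps_frac * baseline_mean` so the output is always finite;
#' the number of clamped voxels is recorded.
#'
#' @param volume Numeric array of raw signal at one time point.
#' @param baseline_mean Patient-level mean baseline signal (scalar, from
#'   the VOI mean curve).
#' @param te Echo time, seconds.
#' @param eps_frac Clamp floor as a fraction of `baseline_mean`.
#' @return dR2 array (1/seconds) with attribute `n_clamped`.
#' @export
delta_r2 <- function(volume, baseline_mean, te, eps_frac = 1e-4) {
  stopifnot(te > 0, baseline_mean > 0, eps_frac > 0)
  floor_val <- eps_frac * baseline_mean
  n_clamped <- sum(volume < floor_val)
  v <- pmax(volume, floor_val)
  out <- log(baseline_mean / v) / te
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Conventional z-score standardization (np version)
#'
#' Z-scores the selected volumes with the mean and SD of all VOI voxels
#' across the full dynamic acquisition, multiplies by a scaling factor
#' (default 100) and, when a shift reference is supplied, subtracts it so
#' that all VOI voxels of the cohort that defined the reference are
#' non-negative.
#'
#' @param volumes List of numeric arrays (e.g. the T0/Tmax/T2 volumes).
#' @param voi_values Numeric vector of all VOI voxel values across all time
#'   points of this patient (defines the z-score moments).
#' @param scale Scaling factor applied after z-scoring (default 100).
#' @param shift_reference Minimum scaled z value over the cohort's VOI
#'   histograms; `NULL` leaves the volumes unshifted (the cohort pipeline
#'   computes and applies one shared constant).
#' @return List of standardized arrays, with attributes `mu`, `sigma`.
#' @export
np_normalize <- function(volumes, voi_values, scale = 100,
                         shift_reference = NULL) {
  mu <- mean(voi_values)
  sigma <- stats::sd(voi_values)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate VOI intensities: zero standard deviation")
  out <- lapply(volumes, function(v) {
    z <- scale * (v - mu) / sigma
    if (!is.null(shift_reference)) z <- z - shift_reference
    z
  })
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

# ---- cubic B-spline resampling -------------------------------------------

# in-place recursive prefilter turning samples into cubic B-spline
# coefficients (mirror boundaries), vectorized across columns
bspline_prefilter <- function(m) {
  z <- sqrt(3) - 2
  n <- nrow(m)
  if (n == 1) return(m)
  # exact causal init for whole-sample mirror boundaries:
  # c+(1) = sum over one mirror period / (1 - z^period)
  p <- 2L * (n - 1L)
  k <- 0:(p - 1)
  idx <- ifelse(k < n, k + 1L, p - k + 1L)
  w <- z^k / (1 - z^p)
  cp <- m
  cp[1, ] <- drop(w %*% m[idx, , drop = FALSE])
  for (k in 2:n) cp[k, ] <- m[k, ] + z * cp[k - 1, ]
  cm <- cp
  cm[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (k in (n - 1):1) cm[k, ] <- z * (cm[k + 1, ] - cp[k, ])
  6 * cm
}

mirror_idx <- function(i, n) {
  # reflect 1..n about the end samples (whole-sample symmetry)
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i - 1L) %% p + p) %% p
  ifelse(i >= n, p - i, i) + 1L
}

# dense interpolation matrix mapping n_in B-spline coefficients to values
# at positions x (in 0-based input index units)
bspline_weight_matrix <- function(x, n_in) {
  i0 <- floor(x)
  t <- x - i0
  w <- cbind((1 - t)^3 / 6,
             (3 * t^3 - 6 * t^2 + 4) / 6,
             (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
             t^3 / 6)
  W <- matrix(0, length(x), n_in)
  for (d in 0:3) {
    col <- mirror_idx(i0 + d, n_in) # i0 is 0-based; offsets -1..2 plus 1
    W[cbind(seq_along(x), col)] <- W[cbind(seq_along(x), col)] + w[, d + 1]
  }
  W
}

linear_weight_matrix <- function(x, n_in) {
  i0 <- floor(x)
  t <- x - i0
  W <- matrix(0, length(x), n_in)
  for (d in 0:1) {
    col <- mirror_idx(i0 + d + 1L, n_in)
    wt <- if (d == 0) 1 - t else t
    W[cbind(seq_along(x), col)] <- W[cbind(seq_along(x), col)] + wt
  }
  W
}

apply_axis_matrix <- function(vol, W, axis, prefilter = FALSE) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = d[axis])
  if (prefilter) m <- bspline_prefilter(m)
  out <- W %*% m
  array(out, dim = c(nrow(W), d[perm][-1])) |> aperm(order(perm))
}

#' Resample a volume (and mask) to isotropic voxels
#'
#' Separable cubic B-spline interpolation (exact interpolating prefilter,
#' mirror boundaries) of the image; the mask is interpolated linearly and
#' re-binarized at 0.5. Input samples sit at `(i - 1) * spacing`, output
#' samples at `(j - 1) * target`; the output grid has
#' `ceil(n * spacing / target)` samples per axis, preserving the physical
#' extent within one voxel.
#'
#' @param volume 3D numeric array.
#' @param spacing Input voxel spacing, mm (length 3).
#' @param mask Optional 3D mask resampled alongside.
#' @param target Output spacing in mm (default 1, isotropic).
#' @return List with `volume`, `mask` (or `NULL`) and `spacing`.
#' @export
resample_isotropic <- function(volume, spacing, mask = NULL, target = 1) {
  stopifnot(length(spacing) == 3, all(spacing > 0), target > 0)
  d <- dim(volume)
  n_out <- ceiling(d * spacing / target)
  Ws <- lapply(1:3, function(a) {
    x <- (seq_len(n_out[a]) - 1) * target / spacing[a] # 0-based index units
    bspline_weight_matrix(x, d[a])
  })
  out <- volume
  for (a in 1:3) out <- apply_axis_matrix(out, Ws[[a]], a, prefilter = TRUE)
  new_mask <- NULL
  if (!is.null(mask)) {
    Wl <- lapply(1:3, function(a) {
      x <- (seq_len(n_out[a]) - 1) * target / spacing[a]
      linear_weight_matrix(x, d[a])
    })
    mm <- mask * 1.0
    for (a in 1:3) mm <- apply_axis_matrix(mm, Wl[[a]], a)
    new_mask <- array(as.integer(mm >= 0.5), dim = dim(mm))
  }
  list(volume = out, mask = new_mask, spacing = rep(target, 3))
}

# ---- cohort-level fixed-bin-size discretization ---------------------------

#' Build a cohort-level discretization specification
#'
#' The fixed bin size is the mean per-patient VOI intensity range divided
#' by the fixed bin number: `FBS = meanRange / FBN`. Patients with zero
#' intensity range are excluded with a warning.
#'
#' @param voi_ranges Numeric vector of per-patient VOI intensity ranges
#'   (max - min), one entry per patient, within one intensity domain
#'   (one image version and image type).
#' @param fbn Fixed bin number, conventionally 32 or 64.
#' @return Object of class `discretization_spec`: `fbn`, `mean_range`,
#'   `fbs`.
#' @export
build_discretization <- function(voi_ranges, fbn = 32L) {
  stopifnot(length(voi_ranges) >= 1, fbn >= 2)
  bad <- !is.finite(voi_ranges) | voi_ranges <= 0
  if (any(bad)) {
    warning(sum(bad), " patient(s) with zero/invalid VOI range excluded")
    voi_ranges <- voi_ranges[!bad]
  }
  if (length(voi_ranges) == 0) stop("no usable VOI ranges")
  mean_range <- mean(voi_ranges)
  structure(list(fbn = as.integer(fbn), mean_range = mean_range,
                 fbs = mean_range / fbn),
            class = "discretization_spec")
}

#' Discretize a standardized volume to integer gray levels
#'
#' Fixed-bin-size binning anchored at the per-patient VOI minimum:
#' `level = floor((v - min_voi) / fbs) + 1`, floored at level 1. Voxels
#' outside the mask get level 0.
#'
#' @param volume 3D numeric array.
#' @param mask 3D 0/1 array.
#' @param spec A [build_discretization()] result (or a list with `fbs`).
#' @return Integer array of gray levels (0 outside the VOI) with attribute
#'   `ng`, the maximum occupied level.
#' @export
discretize <- function(volume, mask, spec) {
  voi <- which(mask != 0)
  if (length(voi) == 0) stop("empty mask")
  v <- volume[voi]
  lev <- floor((v - min(v)) / spec$fbs) + 1
  lev[lev < 1] <- 1
  out <- array(0L, dim = dim(volume))
  out[voi] <- as.integer(lev)
  attr(out, "ng") <- max(lev)
  out
}

#' Persist / restore a discretization specification
#' @param spec A `discretization_spec` (or named list of them).
#' @param path JSON file path.
#' @return `write_discretization` invisibly returns `path`;
#'   `read_discretization` returns the spec(s).
#' @export
write_discretization <- function(spec, path) {
  strip <- function(s) if (inherits(s, "discretization_spec"))
    unclass(s) else lapply(s, unclass)
  jsonlite::write_json(strip(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_discretization
#' @export
read_discretization <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(s)
    structure(list(fbn = as.integer(s$fbn), mean_range = s$mean_range,
                   fbs = s$fbs), class = "discretization_spec")
  if (!is.null(x$fbs)) rebuild(x) else lapply(x, rebuild)
}
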