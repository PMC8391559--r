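#' Mean VOI signal-time curve
#'
#' Averages the dynamic signal over all tumor voxels at each frame; all
#' later time-point decisions are taken once per patient on this curve.
#'
#' @param series 4D numeric array (x, y, z, t).
#' @param mask 3D array of 0/1 aligned with the first three dimensions.
#' @param time_step Temporal resolution, seconds.
#' @return Tibble of class `dsc_curve` with columns `index`, `time_s`,
#'   `signal`.
#' @export
mean_voi_curve <- function(series, mask, time_step = 1) {
  d <- dim(series)
  if (length(d) != 4) stop("series must be a 4D array")
  if (!identical(dim(mask), d[1:3]))
    stop("mask dimensions do not match the series grid")
  voi <- which(mask != 0)
  if (length(voi) == 0) stop("empty mask: no VOI voxels")
  m <- matrix(series, nrow = prod(d[1:3]), ncol = d[4])
  values <- colMeans(m[voi, , drop = FALSE])
  out <- tibble::tibble(index = seq_len(d[4]),
                        time_s = (seq_len(d[4]) - 1) * time_step,
                        signal = values)
  structure(out, class = c("dsc_curve", class(out)), time_step = time_step)
}

as_dsc_curve <- function(signal, time_step = 1) {
  out <- tibble::tibble(index = seq_along(signal),
                        time_s = (seq_along(signal) - 1) * time_step,
                        signal = as.numeric(signal))
  structure(out, class = c("dsc_curve", class(out)), time_step = time_step)
}

#' Detect the pre-bolus baseline of a mean curve
#'
#' Walks the curve causally: at frame t the running mean and SD of frames
#' 1..(t-1) define a detection threshold `mean - k_sd * sd`; the first
#' frame falling below it marks contrast arrival and the frame before it
#' ends the baseline. At least 5 baseline frames are required.
#'
#' @param curve A `dsc_curve` (or numeric vector).
#' @param k_sd Threshold multiplier for contrast detection (default 3).
#' @param min_baseline Minimum number of baseline frames (default 5).
#' @param min_drop_frac Additional relative-drop requirement: the signal
#'   must also fall below `(1 - min_drop_frac)` times the running
#'   baseline mean (default 0.03, far below any first-pass bolus drop but
#'   above baseline noise); set to 0 to disable.
#' @return The curve with attributes `baseline_end`, `n_baseline`,
#'   `baseline_mean`, `baseline_sd`, `baseline_last` and a logical column
#'   `baseline`.
#' @export
detect_baseline <- function(curve, k_sd = 3, min_baseline = 5L,
                            min_drop_frac = 0.03) {
  if (!inherits(curve, "dsc_curve")) curve <- as_dsc_curve(curve)
  v <- curve$signal
  n <- length(v)
  if (n < 10) stop("need at least 10 time points")
  detect <- NA_integer_
  for (t in 3:n) {
    m <- mean(v[1:(t - 1)])
    s <- stats::sd(v[1:(t - 1)])
    thr <- min(m - k_sd * s, m * (1 - min_drop_frac))
    # the drop must persist for two consecutive frames: a bolus stays
    # below the threshold, an early noise blip does not
    if (v[t] < thr && (t == n || v[t + 1] < thr)) {
      detect <- t
      break
    }
  }
  if (is.na(detect))
    stop("no bolus detected: curve never drops below the baseline threshold")
  baseline_end <- detect - 1L
  if (baseline_end < min_baseline)
    stop("inadequate baseline: only ", baseline_end,
         " frames before contrast detection (minimum ", min_baseline, ")")
  bm <- mean(v[1:baseline_end])
  bs <- stats::sd(v[1:baseline_end])
  curve$baseline <- curve$index <= baseline_end
  structure(curve,
            baseline_end = baseline_end, n_baseline = baseline_end,
            baseline_mean = bm, baseline_sd = bs,
            baseline_last = v[baseline_end], k_sd = k_sd,
            time_step = attr(curve, "time_step"))
}

#' Select the characteristic perfusion time points T0, Tmax, T2
#'
#' T0 is the first frame after contrast detection (the detection frame
#' itself), Tmax the frame of maximum signal drop (first index on ties),
#' and T2 the first frame after Tmax recovering to within
#' `return_tolerance_sd` baseline SDs of the baseline mean, falling back
#' to the last frame for non-recovering curves.
#'
#' @param curve A `dsc_curve` processed by [detect_baseline()] (a raw curve
#'   is passed through `detect_baseline` with defaults).
#' @param return_tolerance_sd Baseline-SD multiplier defining "returned to
#'   baseline" (default 1).
#' @return List of class `time_points` with `t0_idx`, `tmax_idx`, `t2_idx`,
#'   `baseline_end`, `baseline_mean`, `baseline_sd`, `baseline_last`.
#' @export
select_time_points <- function(curve, return_tolerance_sd = 1) {
  if (is.null(attr(curve, "baseline_end"))) curve <- detect_baseline(curve)
  v <- curve$signal
  n <- length(v)
  be <- attr(curve, "baseline_end")
  t0 <- be + 1L
  post <- (be + 1L):n
  tmax <- post[which.min(v[post])]
  bm <- attr(curve, "baseline_mean")
  bs <- attr(curve, "baseline_sd")
  thr <- bm - return_tolerance_sd * bs
  t2 <- NA_integer_
  if (tmax < n) {
    after <- (tmax + 1L):n
    hit <- after[v[after] >= thr]
    t2 <- if (length(hit)) hit[1] else n
  } else {
    t2 <- n
  }
  structure(list(t0_idx = t0, tmax_idx = tmax, t2_idx = t2,
                 baseline_end = be, baseline_mean = bm, baseline_sd = bs,
                 baseline_last = attr(curve, "baseline_last")),
            class = "time_points")
}

#' @exportS3Method base::print
print.time_points <- function(x, ...) {
  cat("Perfusion time points: T0 =", x$t0_idx, " Tmax =", x$tmax_idx,
      " T2 =", x$t2_idx, "\n")
  cat("Baseline: frames 1..", x$baseline_end, " mean = ",
      signif(x$baseline_mean, 6), " sd = ", signif(x$baseline_sd, 4), "\n",
      sep = "")
  invisible(x)
}

#' Export a curve and its time points for QC
#'
#' @param curve A `dsc_curve`.
#' @param tp A `time_points` object.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the exported tibble.
#' @export
export_curve_qc <- function(curve, tp, csv_path = NULL, json_path = NULL) {
  out <- tibble::tibble(time_index = curve$index, seconds = curve$time_s,
                        mean_signal = curve$signal)
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(t0_idx = tp$t0_idx, tmax_idx = tp$tmax_idx,
                              t2_idx = tp$t2_idx),
                         json_path, auto_unbox = TRUE)
  invisible(out)
}
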