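test_that("mean VOI curve is the arithmetic mean over mask voxels", {
  d <- c(4L, 4L, 2L, 6L)
  series <- array(7, d)
  mask <- array(0L, d[1:3])
  mask[1, 1, 1] <- 1L
  mask[2, 1, 1] <- 1L
  expect_equal(mean_voi_curve(series, mask)$signal, rep(7, 6))
  series[1, 1, 1, ] <- 1:6
  series[2, 1, 1, ] <- 11:16
  expect_equal(mean_voi_curve(series, mask)$signal, (1:6 + 11:16) / 2)
  expect_error(mean_voi_curve(series, array(0L, d[1:3])), "empty mask")
  expect_error(mean_voi_curve(series, array(1L, c(3, 3, 3))),
               "dimensions")
})

test_that("flat curves and early drops raise the documented errors", {
  expect_error(detect_baseline(rep(100, 20)), "no bolus")
  drop_at_3 <- c(100, 100, 60, 40, 30, 30, 40, 70, 90, 100, 100, 100)
  expect_error(detect_baseline(drop_at_3), "inadequate baseline")
  expect_error(detect_baseline(rep(100, 5)), "at least 10")
})

test_that("time points recover the generator's ground truth", {
  pr <- tiny_protocol()
  ph <- noise_free_phenotype()
  for (s in c(1, 2, 9)) {
    cv <- simulate_bolus_curve(pr, ph, seed = s)
    tp <- select_time_points(detect_baseline(cv))
    expect_equal(tp$baseline_end + 1L, tp$t0_idx)
    # noise-free: detection within one frame of the continuous arrival
    expect_lte(abs(tp$t0_idx - attr(cv, "arrival_idx")), 1)
    expect_equal(tp$tmax_idx, attr(cv, "peak_idx"))
    expect_lt(tp$tmax_idx, tp$t2_idx)
    # T2: recovered to within tolerance of baseline, or the last-index
    # fallback for an asymptotic noise-free tail
    expect_true(tp$t2_idx == nrow(cv) ||
                  cv$signal[tp$t2_idx] >=
                    tp$baseline_mean - tp$baseline_sd)
  }
})

test_that("hand-built curve: known arrival, tie at minimum, fallback T2", {
  base <- rep(100, 12)
  curve <- c(base, 70, 40, 40, 60, 80, 99.9, 100, 100)
  tp <- select_time_points(detect_baseline(curve))
  expect_equal(tp$baseline_end, 12L)
  expect_equal(tp$t0_idx, 13L)
  expect_equal(tp$tmax_idx, 14L) # first of the two equal minima
  expect_equal(tp$t2_idx, 19L)   # sd = 0: first frame >= baseline mean
  # monotone non-recovering tail: T2 falls back to the last index
  curve2 <- c(base, 70, 60, 50, 45, 44, 43, 42, 41)
  tp2 <- select_time_points(detect_baseline(curve2))
  expect_equal(tp2$t2_idx, length(curve2))
})

test_that("time-point indices are shift- and scale-equivariant", {
  pr <- tiny_protocol()
  ph <- default_phenotypes()$wildtype
  cv <- simulate_bolus_curve(pr, ph, seed = 21)
  tp0 <- select_time_points(detect_baseline(cv$signal))
  for (f in list(function(v) v + 250, function(v) v * 3.7,
                 function(v) 0.2 * v + 40)) {
    tp <- select_time_points(detect_baseline(f(cv$signal)))
    expect_equal(tp[c("t0_idx", "tmax_idx", "t2_idx")],
                 tp0[c("t0_idx", "tmax_idx", "t2_idx")])
  }
})

test_that("curve QC export writes CSV and JSON", {
  cv <- detect_baseline(c(rep(100, 10), 60, 40, 55, 75, 95, 100, 100, 100,
                          100, 100))
  tp <- select_time_points(cv)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_curve_qc(cv, tp, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$mean_signal, cv$signal)
  j <- jsonlite::read_json(js)
  expect_equal(j$tmax_idx, tp$tmax_idx)
})
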