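test_that("baseline correction subtracts a patient-level constant", {
  v <- array(55, c(3, 3, 2, 4))
  expect_equal(baseline_correct(v, 55), array(0, dim(v)))
  s <- array(rnorm(36, 100, 5), c(3, 3, 2, 2))
  a <- 2.5
  expect_equal(baseline_correct(a * s, a * 70), a * baseline_correct(s, 70))
})

test_that("deltaR2 is the closed-form relaxation-rate inverse", {
  te <- 0.04
  b <- 900
  expect_equal(delta_r2(array(b, c(2, 2, 2)), b, te),
               array(0, c(2, 2, 2)), ignore_attr = TRUE)
  x <- 25
  v <- array(b * exp(-te * x), c(4, 4, 2))
  out <- delta_r2(v, b, te)
  expect_equal(as.vector(out), rep(x, 32), tolerance = 1e-12)
  expect_equal(attr(out, "n_clamped"), 0L)
  # non-positive voxels are clamped, never NaN/Inf
  v[1, 1, 1] <- -3
  out2 <- delta_r2(v, b, te)
  expect_true(all(is.finite(out2)))
  expect_equal(attr(out2, "n_clamped"), 1L)
})

test_that("deltaR2 removes echo-time and intensity-scale differences", {
  # same underlying kinetics rendered under two protocols
  mk <- function(te, scale) tiny_protocol(te = te, scale = scale,
                                          matrix_size = c(24L, 24L),
                                          n_slices = 10L)
  ph <- noise_free_phenotype(depth = 0.4, radius = c(6, 7))
  ph$te_ref <- 0.040 # kinetics pinned to a scanner-independent scale
  p1 <- synthesize_patient(mk(0.040, 1000), ph, seed = 6)
  p2 <- synthesize_patient(mk(0.030, 1450), ph, seed = 6)
  expect_identical(p1$mask, p2$mask)
  expect_gt(max(abs(p1$series - p2$series)), 1) # raw signals differ
  tp1 <- select_time_points(detect_baseline(
    mean_voi_curve(p1$series, p1$mask, 1.87)))
  tp2 <- select_time_points(detect_baseline(
    mean_voi_curve(p2$series, p2$mask, 1.87)))
  t <- tp1$tmax_idx
  d1 <- delta_r2(p1$series[, , , t], tp1$baseline_mean, 0.040)
  d2 <- delta_r2(p2$series[, , , t], tp2$baseline_mean, 0.030)
  voi <- which(p1$mask == 1)
  expect_lt(max(abs(d1[voi] - d2[voi])) / max(abs(d1[voi])), 1e-8)
})

test_that("z-score normalization is the documented affine contract", {
  voi <- rnorm(4000, 50, 10)
  vols <- list(array(voi[1:1000], c(10, 10, 10)))
  out <- np_normalize(vols, voi, scale = 100, shift_reference = NULL)
  z <- out[[1]]
  expect_equal(mean(100 * (voi[1:1000] - mean(voi)) / sd(voi) - z), 0,
               tolerance = 1e-10)
  # moments over all VOI values: mean 0 sd 1 before scale/shift
  zz <- (voi - attr(out, "mu")) / attr(out, "sigma")
  expect_equal(mean(zz), 0, tolerance = 1e-12)
  expect_equal(sd(zz), 1, tolerance = 1e-12)
  # shift makes everything non-negative and preserves differences
  shifted <- np_normalize(vols, voi, shift_reference = min(z))[[1]]
  expect_gte(min(shifted), 0)
  expect_equal(diff(as.vector(shifted)[1:5]), diff(as.vector(z)[1:5]))
  expect_error(np_normalize(vols, rep(3, 100)), "degenerate")
})

test_that("isotropic resampling preserves grid values, constants and extent", {
  set.seed(31)
  v <- array(rnorm(14 * 14 * 8), c(14, 14, 8))
  id <- resample_isotropic(v, c(1, 1, 1))
  expect_lt(max(abs(id$volume - v)), 1e-6)
  cst <- resample_isotropic(array(4.4, c(9, 9, 5)), c(1.7, 1.7, 5))
  expect_lt(max(abs(cst$volume - 4.4)), 1e-6)
  big <- resample_isotropic(array(0, c(128, 16, 20)), c(1.718, 1.718, 5))
  expect_equal(dim(big$volume), c(220L, 28L, 100L))
  # mask: binary output, physical extent preserved within a voxel
  m <- array(0L, c(14, 14, 8))
  m[4:10, 4:10, 3:6] <- 1L
  rs <- resample_isotropic(v, c(2, 2, 2.5), mask = m)
  expect_setequal(unique(as.vector(rs$mask)), c(0L, 1L))
  idx <- which(rs$mask == 1, arr.ind = TRUE)
  # half-maximum crossings dilate the 6-voxel span by one input voxel
  expect_lte(abs(max(idx[, 1]) - min(idx[, 1]) - 14), 1)
})

test_that("discretization spec follows FBS = meanRange / FBN", {
  spec <- build_discretization(c(300, 340), 32)
  expect_equal(spec$mean_range, 320)
  expect_equal(spec$fbs, 10)
  expect_identical(spec$fbs * spec$fbn, spec$mean_range)
  expect_equal(build_discretization(64, 64)$fbs, 1)
  r <- runif(20, 10, 50)
  expect_equal(build_discretization(r, 32)$fbs,
               2 * build_discretization(r, 64)$fbs)
  expect_warning(s2 <- build_discretization(c(100, 0), 32), "excluded")
  expect_equal(s2$mean_range, 100)
  # JSON round trip for reuse on a validation cohort
  path <- withr::local_tempfile(fileext = ".json")
  write_discretization(spec, path)
  expect_equal(read_discretization(path)$fbs, spec$fbs)
})

test_that("discretization floors into fixed-size bins and is monotone", {
  m <- array(1L, c(2, 2, 3))
  v <- array(c(0, 3, 9.99, 25, 10, 19.9, 31, 5, 7, 2, 40, 0.5), c(2, 2, 3))
  spec <- list(fbs = 10)
  lev <- discretize(v, m, spec)
  expect_equal(lev[which(v == 10)], 2L) # second bin
  expect_equal(lev[which(v == 25)], 3L) # third bin
  expect_equal(lev[which(v == 9.99)], 1L)
  expect_equal(max(lev), 5L)            # v = 40 -> level 5
  # monotone: ordering of values implies ordering of levels
  o <- order(as.vector(v))
  expect_true(all(diff(as.vector(lev)[o]) >= 0))
  # histogram occupancy equals brute-force binning
  brute <- table(floor((as.vector(v) - min(v)) / 10) + 1)
  expect_equal(as.vector(table(as.vector(lev))), as.vector(brute))
})
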