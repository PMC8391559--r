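test_that("noise-free bolus curve drops by exactly the phenotype depth", {
  pr <- tiny_protocol()
  ph <- noise_free_phenotype(depth = 0.4)
  cv <- simulate_bolus_curve(pr, ph, seed = 7)
  expect_equal(min(cv$signal) / attr(cv, "s0"), 0.6, tolerance = 1e-12)
  # minimum at the gamma-variate peak sample
  expect_equal(which.min(cv$signal), attr(cv, "peak_idx"))
  # flat baseline before arrival
  arr <- attr(cv, "arrival_idx")
  expect_true(all(cv$signal[seq_len(arr - 1)] == attr(cv, "s0")))
  expect_gte(arr - 1, 5)
  # recovery: last frame back within 1% of baseline
  expect_lt(abs(cv$signal[nrow(cv)] - attr(cv, "s0")) / attr(cv, "s0"),
            0.01)
})

test_that("relaxation-rate transform inverts the forward model exactly", {
  pr <- tiny_protocol(te = 0.034)
  ph <- noise_free_phenotype(depth = 0.35)
  cv <- simulate_bolus_curve(pr, ph, seed = 3)
  r2_rec <- log(attr(cv, "s0") / cv$signal) / pr$te
  expect_lt(max(abs(r2_rec - attr(cv, "r2"))) / max(attr(cv, "r2")),
            1e-10)
})

test_that("curves are deterministic in the seed and only the seed", {
  pr <- tiny_protocol()
  ph <- default_phenotypes()$mutant
  a <- simulate_bolus_curve(pr, ph, seed = 5)
  b <- simulate_bolus_curve(pr, ph, seed = 5)
  c <- simulate_bolus_curve(pr, ph, seed = 6)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
})

test_that("noise-free patient voxels are copies of the mean curve", {
  pr <- tiny_protocol(matrix_size = c(20L, 20L), n_slices = 8L)
  ph <- noise_free_phenotype(radius = c(5, 6))
  pat <- synthesize_patient(pr, ph, seed = 2)
  voi <- which(pat$mask == 1)
  expect_gt(length(voi), 0)
  # spatial variance zero at every frame
  d <- dim(pat$series)
  m <- matrix(pat$series, nrow = prod(d[1:3]))
  vv <- apply(m[voi, , drop = FALSE], 2, stats::var)
  expect_equal(max(vv), 0)
  curve <- mean_voi_curve(pat$series, pat$mask, pr$time_step)
  ref <- simulate_bolus_curve(pr, ph, seed = 2)
  expect_equal(curve$signal, ref$signal, tolerance = 1e-12)
})

test_that("mask is the discretized sphere for the drawn radius", {
  pr <- tiny_protocol(matrix_size = c(20L, 20L), n_slices = 8L)
  ph <- noise_free_phenotype(radius = c(5, 6))
  pat <- synthesize_patient(pr, ph, seed = 4)
  r <- pat$meta$radius_mm
  sp <- pat$meta$spacing
  d <- dim(pat$mask)
  # brute-force voxel-in-sphere count around the realized centre
  idx <- which(pat$mask == 1, arr.ind = TRUE)
  ctr <- colSums(sweep(idx - 1, 2, sp, "*") * 1) / nrow(idx)
  cnt <- 0
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    pos <- (c(x, y, z) - 1) * sp
    if (sum((pos - ctr)^2) <= r^2 * (1 + 1e-9)) cnt <- cnt + 1
  }
  # centre recovered from the mask is approximate: allow one shell voxel
  expect_lt(abs(cnt - sum(pat$mask)) / sum(pat$mask), 0.1)
  # mask is binary and nonempty
  expect_setequal(unique(as.vector(pat$mask)), c(0L, 1L))
})

test_that("shorter correlation length / larger texture sd raises VOI variance", {
  pr <- protocol_spec("A", te = 0.04, tr = 1.8, n_timepoints = 60,
                      time_step = 1.87, matrix_size = c(36L, 36L),
                      n_slices = 14L, in_plane_spacing = 1.2,
                      slice_thickness = 5)
  ph <- default_phenotypes()
  for (nm in names(ph)) {
    ph[[nm]]$lesion_radius_range <- c(14, 14.0001)
    ph[[nm]]$measurement_noise_sd <- 0
    ph[[nm]]$param_cv <- 0
  }
  wt <- synthesize_patient(pr, ph$wildtype, seed = 11)
  mu <- synthesize_patient(pr, ph$mutant, seed = 11)
  t0 <- wt$meta$arrival_idx
  vvar <- function(pat, t) {
    voi <- which(pat$mask == 1)
    stats::var(pat$series[, , , t][voi])
  }
  expect_gt(length(which(wt$mask == 1)), 1000)
  expect_gt(vvar(wt, t0), vvar(mu, mu$meta$arrival_idx))
})

test_that("texture noise strictly increases first-order variance at every frame", {
  pr <- tiny_protocol(matrix_size = c(28L, 28L), n_slices = 10L)
  base <- noise_free_phenotype(radius = c(7, 7.0001))
  noisy <- base
  noisy$texture_noise_sd <- 0.12
  a <- synthesize_patient(pr, base, seed = 8)
  b <- synthesize_patient(pr, noisy, seed = 8)
  voi <- which(a$mask == 1)
  d <- dim(a$series)
  ma <- matrix(a$series, nrow = prod(d[1:3]))[voi, ]
  mb <- matrix(b$series, nrow = prod(d[1:3]))[voi, ]
  va <- apply(ma, 2, stats::var)
  vb <- apply(mb, 2, stats::var)
  expect_true(all(vb > va))
})

test_that("cohort counts, manifest and determinism match the spec recipe", {
  spec <- small_cohort_spec(seed = 13L)
  coh <- generate_cohort(spec)
  man <- coh$manifest
  expect_equal(nrow(man), 30)
  tab <- table(man$center, man$label)
  expect_equal(unname(tab["A", "wildtype"]), 5)
  expect_equal(unname(tab["B", "wildtype"]), 4)
  expect_equal(unname(tab["C", "wildtype"]), 2)
  # default full-size recipe: 160 patients, 41 wildtype / 119 mutant
  full <- cohort_spec()
  n_wt <- sum(round(full$wildtype_fraction_per_center * full$n_per_center))
  expect_equal(sum(full$n_per_center), 160L)
  expect_equal(n_wt, 41)
  # byte-identical manifests on regeneration
  coh2 <- generate_cohort(spec)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$patients[[3]]$series, coh2$patients[[3]]$series)
})

test_that("a 50/50 fraction gives an even split and NIfTI round trip works", {
  spec <- small_cohort_spec(n = c(10L), wt = c(0.5), seed = 3L)
  spec$protocols <- spec$protocols[1]
  dir <- withr::local_tempdir()
  coh <- generate_cohort(spec, dir = dir)
  expect_equal(sum(coh$manifest$label == "wildtype"), 5)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  pat <- cohort_patient(coh, 1)
  mem <- generate_cohort(spec)$patients[[1]]
  expect_equal(dim(pat$series), dim(mem$series))
  expect_equal(pat$mask, mem$mask)
  # float32 on disk: values agree to single precision
  expect_lt(max(abs(pat$series - mem$series)) / max(mem$series), 1e-6)
  expect_equal(pat$meta$te, mem$meta$te)
})

test_that("oversized lesions are rejected", {
  pr <- tiny_protocol(matrix_size = c(12L, 12L), n_slices = 4L)
  ph <- noise_free_phenotype(radius = c(30, 31))
  expect_error(synthesize_patient(pr, ph, seed = 1), "does not fit")
})
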