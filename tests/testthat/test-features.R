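test_that("the catalogue arithmetic is exactly the published structure", {
  cat <- feature_catalog()
  expect_equal(nrow(cat), 2499)
  per_tp <- dplyr::count(cat, timepoint)
  expect_true(all(per_tp$n == 833))
  orig <- dplyr::filter(cat, timepoint == "T0", image_type == "original")
  expect_equal(nrow(orig), 105)
  by_group <- dplyr::count(orig, group)
  expect_equal(stats::setNames(by_group$n, by_group$group),
               c(firstorder = 16L, glcm = 24L, gldm = 14L, glszm = 16L,
                 glrlm = 16L, ngtdm = 5L, shape = 14L)[by_group$group])
  wav <- dplyr::filter(cat, timepoint == "T0", image_type != "original")
  expect_equal(nrow(wav), 728)
  expect_equal(length(unique(wav$image_type)), 8)
  expect_false(any(wav$group == "shape"))
  expect_equal(105L + 91L * 8L, 833L)
  expect_equal(16L + 14L + 24L + 14L + 16L + 16L + 5L, 105L)
})

test_that("first-order features match hand arithmetic and the degenerate rule", {
  fo <- firstorder_features(c(1, 2, 3, 4), 1:4)
  expect_equal(unname(fo["Mean"]), 2.5)
  expect_equal(unname(fo["Variance"]), 1.25)
  expect_equal(unname(fo["Range"]), 3)
  expect_equal(unname(fo["Energy"]), 30)
  cst <- firstorder_features(rep(7, 20), rep(1L, 20))
  expect_equal(unname(cst[c("Variance", "Skewness", "Kurtosis",
                            "Entropy")]), c(0, 0, 0, 0))
  expect_equal(unname(cst["Uniformity"]), 1)
})

test_that("first-order features equal the naive oracle on random data", {
  for (s in 1:10) {
    withr::local_seed(s)
    x <- rnorm(1000, 40, 12)
    lev <- as.integer(cut(x, 8))
    expect_equal(firstorder_features(x, lev), oracle_firstorder(x, lev),
                 tolerance = 1e-10)
  }
})

test_that("all 75 texture features equal the brute-force oracle", {
  # random small volumes, mixed shapes and gray-level counts
  cases <- list(
    list(seed = 1, ng = 6L, full = FALSE),
    list(seed = 2, ng = 4L, full = TRUE),
    list(seed = 3, ng = 8L, full = FALSE),
    list(seed = 4, ng = 2L, full = TRUE),
    list(seed = 5, ng = 12L, full = FALSE)
  )
  for (cs in cases) {
    lv <- random_levels(cs$seed, ng = cs$ng, full = cs$full)
    ng <- max(lv)
    expect_equal(glcm_features(lv, ng), oracle_glcm_features(lv, ng),
                 tolerance = 1e-10)
    expect_equal(glrlm_features(lv, ng), oracle_glrlm_features(lv, ng),
                 tolerance = 1e-10)
    expect_equal(glszm_features(lv, ng), oracle_glszm_features(lv, ng),
                 tolerance = 1e-10)
    expect_equal(gldm_features(lv, ng), oracle_gldm_features(lv, ng),
                 tolerance = 1e-10)
    expect_equal(ngtdm_features(lv, ng), oracle_ngtdm_features(lv, ng),
                 tolerance = 1e-10)
  }
})

test_that("hand-enumerable 2x2 checkerboard GLCM matches hand counts", {
  lv <- array(0L, c(4, 4, 3))
  lv[2:3, 2:3, 2] <- c(1L, 2L, 2L, 1L)
  # in-plane x-direction pairs: (1,2) and (2,1) -> symmetric counts 4
  P <- dscradiomics:::cpp_glcm(lv, 2L)[, , 1]
  expect_equal(P, matrix(c(0, 2, 2, 0), 2))
  # contrast per that direction = 1; difference entropy = 0
  p <- P / sum(P)
  expect_equal(sum((row(p) - col(p))^2 * p), 1)
})

test_that("degenerate single-level VOIs take the convention values", {
  lv <- array(0L, c(6, 6, 6))
  lv[2:5, 2:5, 2:5] <- 1L
  tx <- texture_features(lv, 1)
  expect_equal(unname(tx["glcm_DifferenceEntropy"]), 0)
  expect_equal(unname(tx["glcm_Correlation"]), 1)
  expect_equal(unname(tx["ngtdm_Coarseness"]), 1e6)
  expect_equal(unname(tx["glszm_GrayLevelVariance"]), 0)
  expect_true(all(is.finite(tx)))
})

test_that("direction-aggregated texture features are rotation-robust", {
  lv <- random_levels(17, dim = c(9L, 9L, 9L), ng = 5L, full = TRUE)
  rot <- aperm(lv, c(2, 3, 1)) # 90-degree axis rotation
  for (f in list(glcm_features, glrlm_features)) {
    a <- f(lv, 5L)
    b <- f(rot, 5L)
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("shape features approach analytic values on digital solids", {
  sf1 <- shape_features(array(1L, c(1, 1, 1)), c(1, 1, 1)) |>
    suppressWarnings()
  expect_equal(unname(sf1["VoxelVolume"]), 1)
  expect_equal(unname(sf1["MeshVolume"]), 1)
  ball <- ball_mask(20)
  sfb <- shape_features(ball, c(1, 1, 1))
  expect_lt(abs(sfb["Sphericity"] - 1), 0.02)
  expect_lt(abs(sfb["MeshVolume"] - 4 / 3 * pi * 20^3) /
              (4 / 3 * pi * 20^3), 0.03)
  expect_equal(unname(sfb["Maximum3DDiameter"]), 40)
  expect_equal(unname(sfb["Elongation"]), 1, tolerance = 0.02)
  # axis-aligned box: diagonal within one voxel
  bm <- array(0L, c(20, 16, 12))
  bm[3:12, 3:10, 3:8] <- 1L
  sfx <- shape_features(bm, c(1, 1, 1))
  full_diag <- sqrt(10^2 + 8^2 + 6^2)
  expect_lt(abs(sfx["Maximum3DDiameter"] - full_diag), sqrt(3))
  expect_equal(unname(sfx["VoxelVolume"]), 10 * 8 * 6)
})

test_that("the assembled patient vector is complete, ordered, deterministic", {
  pr <- tiny_protocol(matrix_size = c(24L, 24L), n_slices = 10L)
  pat <- synthesize_patient(pr, default_phenotypes()$wildtype, seed = 5)
  pp <- preprocess_patient(pat, "p")
  red <- dscradiomics:::reduce_preprocessed(pp)
  itypes <- sub("^[^.]+\\.", "", colnames(red$values))
  specs <- lapply(stats::setNames(nm = unique(itypes)), function(it)
    build_discretization(max(red$values[, itypes == it]) -
                           min(red$values[, itypes == it]), 32))
  fv <- extract_patient_features(pp, specs)
  expect_length(fv, 2499)
  expect_identical(names(fv), feature_catalog()$name)
  expect_true(all(is.finite(fv)))
  fv2 <- extract_patient_features(pp, specs)
  expect_identical(fv, fv2)
  # shape block identical across time points (one mask per patient)
  sh <- function(tp) fv[grepl(paste0("^", tp, "_original_shape_"),
                              names(fv))]
  expect_equal(unname(sh("T0")), unname(sh("Tmax")))
})
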