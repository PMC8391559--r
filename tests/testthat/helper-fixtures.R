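# small deterministic fixtures shared across test files

tiny_protocol <- function(center = "A", te = 0.040, tr = 1.8,
                          n_timepoints = 60L, time_step = 1.87,
                          matrix_size = c(24L, 24L), n_slices = 10L,
                          spacing = 1.75, scale = 1000, offset = 0) {
  protocol_spec(center, te = te, tr = tr, n_timepoints = n_timepoints,
                time_step = time_step, matrix_size = matrix_size,
                n_slices = n_slices, in_plane_spacing = spacing,
                slice_thickness = 5, intensity_scale = scale,
                intensity_offset = offset)
}

noise_free_phenotype <- function(label = "wildtype", depth = 0.4,
                                 radius = c(6, 8), ...) {
  phenotype_spec(label, bolus_depth = depth, texture_noise_sd = 0,
                 measurement_noise_sd = 0, lesion_radius_range = radius,
                 ...)
}

# digital ball mask
ball_mask <- function(r, n = 2 * r + 7, center = r + 4) {
  ax <- seq_len(n) - center
  d2 <- outer(ax^2, outer(ax^2, ax^2, "+"), "+")
  array(as.integer(d2 <= r^2), c(n, n, n))
}

# random discretized VOI volume for oracle comparisons
random_levels <- function(seed, dim = c(8L, 8L, 8L), ng = 6L,
                          full = FALSE) {
  withr::local_seed(seed)
  lv <- array(0L, dim)
  if (full) {
    lv[] <- sample.int(ng, prod(dim), replace = TRUE)
  } else {
    inner <- lapply(dim, function(n) 2:(n - 1))
    lv[inner[[1]], inner[[2]], inner[[3]]] <-
      sample.int(ng, prod(lengths(inner)), replace = TRUE)
  }
  lv
}

# a small cohort spec sized for fast tests
small_cohort_spec <- function(n = c(14L, 5L, 5L, 6L),
                              wt = c(5 / 14, 2 / 5, 2 / 5, 2 / 6),
                              seed = 42L, effect = TRUE,
                              radius = c(7, 10),
                              matrix_size = c(36L, 36L), n_slices = 10L) {
  ph <- default_phenotypes(effect = effect)
  for (nm in names(ph)) ph[[nm]]$lesion_radius_range <- radius
  protos <- default_protocols(matrix_size = matrix_size,
                              n_slices = n_slices)[seq_along(n)]
  cohort_spec(protos, n_per_center = n,
              wildtype_fraction_per_center = wt,
              phenotypes = ph, seed = seed)
}

DIR13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)
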