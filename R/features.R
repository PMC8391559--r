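# separable kernel smoothing with zero padding (background outside grid)
filter_axis_kernel_zero <- function(vol, k, axis) {
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
    ok <- idx >= 1L & idx <= n
    out[ok, ] <- out[ok, ] + k[j] * m[idx[ok], , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

# cached index matrices per gray-level count (GLCM hot path)
glcm_index_cache <- local({
  cache <- list()
  function(ng) {
    key <- as.character(ng)
    if (is.null(cache[[key]])) {
      m <- matrix(0, ng, ng)
      i <- row(m); j <- col(m)
      cache[[key]] <<- list(i = i, j = j, dk = abs(i - j) + 1L, sk = i + j - 1L)
    }
    cache[[key]]
  }
})

# log2 restricted to positive entries; zero-probability terms contribute 0
xlog2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order (histogram) features of a VOI
#'
#' Moments, percentiles and dispersion statistics are computed on the raw
#' (continuous) intensities; Entropy and Uniformity on the discretized
#' gray levels. Degenerate (constant) VOIs take skewness = kurtosis = 0 by
#' convention.
#'
#' @param intensities Numeric vector of VOI voxel intensities.
#' @param levels Integer vector of discretized VOI gray levels.
#' @return Named numeric vector of length 16.
#' @export
firstorder_features <- function(intensities, levels) {
  x <- as.numeric(intensities)
  stopifnot(length(x) >= 1, length(levels) == length(x))
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  sub <- x[x >= q[1] & x <= q[5]]
  rmad <- if (length(sub)) mean(abs(sub - mean(sub))) else 0
  p <- tabulate(levels) / n
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(Energy = sum(x^2),
    Entropy = xlog2(p),
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = rmad,
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}

#' Morphological (shape) features of a 3D mask
#'
#' Mesh-based surface area and volume come from a marching-tetrahedra
#' triangulation of the 0.5 level of the binary mask; axis lengths from
#' the eigenvalues of the physical-coordinate covariance; maximum
#' diameters from pairwise distances between boundary voxel centres.
#' A single-voxel mask falls back to voxel-based volume/surface with a
#' warning.
#'
#' @param mask 3D 0/1 array.
#' @param spacing Voxel spacing, mm (length 3).
#' @return Named numeric vector of length 14.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) stop("empty mask")
  vox_vol <- prod(spacing)
  voxel_volume <- n * vox_vol
  if (n == 1) {
    warning("single-voxel mask: voxel-based volume/surface fallback")
    area <- 2 * (spacing[1] * spacing[2] + spacing[1] * spacing[3] +
                   spacing[2] * spacing[3])
    mesh_vol <- vox_vol
    diam <- c(0, 0, 0, 0)
    ev <- c(0, 0, 0)
  } else {
    # mesh the 0.5 iso-surface of a lightly smoothed indicator: linear
    # interpolation on the smoothed field suppresses the voxelization
    # staircase that inflates the surface of a raw binary mesh
    sm <- mask * 1.0
    sigma <- 0.8
    half <- 3L
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    for (ax in 1:3) sm <- filter_axis_kernel_zero(sm, k, ax)
    mesh <- cpp_mesh(sm, as.numeric(spacing), 0.5)
    area <- mesh$area
    mesh_vol <- mesh$volume
    pts <- sweep(idx - 1, 2, spacing, "*")
    # boundary voxels: any 6-neighbour outside the mask (or the grid)
    d <- dim(mask)
    on_boundary <- logical(n)
    for (a in 1:3) {
      for (s in c(-1L, 1L)) {
        nb <- idx
        nb[, a] <- nb[, a] + s
        inside <- nb[, a] >= 1 & nb[, a] <= d[a]
        val <- rep(0L, n)
        val[inside] <- mask[nb[inside, , drop = FALSE]]
        on_boundary <- on_boundary | val == 0
      }
    }
    diam <- cpp_max_diameters(pts[on_boundary, , drop = FALSE])
    ev <- sort(eigen(stats::cov(pts), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  }
  sph <- (36 * pi * mesh_vol^2)^(1 / 3) / area
  c(MeshVolume = mesh_vol,
    VoxelVolume = voxel_volume,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / mesh_vol,
    Sphericity = sph,
    Maximum3DDiameter = diam[1],
    Maximum2DDiameterSlice = diam[2],
    Maximum2DDiameterColumn = diam[3],
    Maximum2DDiameterRow = diam[4],
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

# ---- per-family texture features (matrices built in C++) ------------------

glcm_features_one <- function(P) {
  ng <- nrow(P)
  s <- sum(P)
  if (s == 0) return(stats::setNames(rep(0, 24), GLCM_FEATURES))
  p <- P / s
  idx <- glcm_index_cache(ng)
  i <- idx$i; j <- idx$j
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  k_diff <- 0:(ng - 1)
  p_diff <- drop(rowsum(as.vector(p), as.vector(idx$dk)))
  da <- sum(k_diff * p_diff)
  k_sum <- 2:(2 * ng)
  p_sum <- drop(rowsum(as.vector(p), as.vector(idx$sk)))
  hxy <- xlog2(p)
  hx <- xlog2(px)
  pos <- p > 0
  hxy1 <- -sum(p[pos] * log2((px[i] * px[j])[pos]))
  opx <- outer(px, px)
  hxy2 <- xlog2(opx)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    # Q = (D^-1 P)^2 with D = diag(px); its eigenvalues are the squared
    # eigenvalues of the symmetric similar matrix D^-1/2 P D^-1/2
    psub <- p[occ, occ, drop = FALSE]
    rs <- sqrt(px[occ])
    S <- psub / outer(rs, rs)
    ev <- sort(abs(eigen(S, symmetric = TRUE,
                         only.values = TRUE)$values), decreasing = TRUE)
    ev[2]
  }
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = xlog2(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    Mcc = mcc,
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = xlog2(p_sum),
    SumSquares = sig2)
}

#' GLCM features averaged over the 13 symmetric 3D directions
#' @param levels Integer 3D array of gray levels (0 outside the VOI).
#' @param ng Number of gray levels.
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(levels, ng = max(levels)) {
  M <- cpp_glcm(levels, ng)
  per_dir <- vapply(seq_len(dim(M)[3]),
                    function(d) glcm_features_one(matrix(M[, , d], ng, ng)),
                    numeric(24))
  rowMeans(per_dir)
}

glrlm_features_one <- function(P, n_vox) {
  nr <- sum(P)
  p <- P / nr
  i <- row(p); jj <- col(p)
  pg <- rowSums(P)
  pr <- colSums(P)
  mui <- sum(i * p)
  muj <- sum(jj * p)
  c(GrayLevelNonUniformity = sum(pg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr^2,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelRunEmphasis = sum(i^2 * p),
    LongRunEmphasis = sum(jj^2 * p),
    LongRunHighGrayLevelEmphasis = sum(i^2 * jj^2 * p),
    LongRunLowGrayLevelEmphasis = sum(jj^2 * p / i^2),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    RunEntropy = xlog2(p),
    RunLengthNonUniformity = sum(pr^2) / nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / nr^2,
    RunPercentage = nr / n_vox,
    RunVariance = sum((jj - muj)^2 * p),
    ShortRunEmphasis = sum(p / jj^2),
    ShortRunHighGrayLevelEmphasis = sum(i^2 * p / jj^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * jj^2)))
}

#' GLRLM features averaged over the 13 directions
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(levels, ng = max(levels)) {
  M <- cpp_glrlm(levels, ng)
  n_vox <- sum(levels > 0)
  nl <- dim(M)[2]
  per_dir <- vapply(seq_len(dim(M)[3]),
                    function(d) glrlm_features_one(matrix(M[, , d], ng, nl),
                                                   n_vox),
                    numeric(16))
  rowMeans(per_dir)
}

#' GLSZM features (26-connected zones)
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(levels, ng = max(levels)) {
  P <- cpp_glszm(levels, ng)
  n_vox <- sum(levels > 0)
  ns <- sum(P)
  p <- P / ns
  i <- row(p); s <- col(p)
  pg <- rowSums(P)
  pz <- colSums(P)
  mui <- sum(i * p)
  mus <- sum(s * p)
  c(GrayLevelNonUniformity = sum(pg^2) / ns,
    GrayLevelNonUniformityNormalized = sum(pg^2) / ns^2,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelZoneEmphasis = sum(i^2 * p),
    LargeAreaEmphasis = sum(s^2 * p),
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2 * p),
    LargeAreaLowGrayLevelEmphasis = sum(s^2 * p / i^2),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    SizeZoneNonUniformity = sum(pz^2) / ns,
    SizeZoneNonUniformityNormalized = sum(pz^2) / ns^2,
    SmallAreaEmphasis = sum(p / s^2),
    SmallAreaHighGrayLevelEmphasis = sum(i^2 * p / s^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * s^2)),
    ZoneEntropy = xlog2(p),
    ZonePercentage = ns / n_vox,
    ZoneVariance = sum((s - mus)^2 * p))
}

#' GLDM features (26-neighbourhood dependence, equality criterion)
#' @inheritParams glcm_features
#' @param alpha Dependence tolerance on the gray-level difference
#'   (default 0: equality).
#' @return Named numeric vector of length 14.
#' @export
gldm_features <- function(levels, ng = max(levels), alpha = 0L) {
  P <- cpp_gldm(levels, ng, alpha)
  nz <- sum(P)
  p <- P / nz
  i <- row(p); jd <- col(p) # dependence j = neighbour count + 1
  pg <- rowSums(P)
  pd <- colSums(P)
  mui <- sum(i * p)
  muj <- sum(jd * p)
  c(DependenceEntropy = xlog2(p),
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    DependenceVariance = sum((jd - muj)^2 * p),
    GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelEmphasis = sum(i^2 * p),
    LargeDependenceEmphasis = sum(jd^2 * p),
    LargeDependenceHighGrayLevelEmphasis = sum(i^2 * jd^2 * p),
    LargeDependenceLowGrayLevelEmphasis = sum(jd^2 * p / i^2),
    LowGrayLevelEmphasis = sum(p / i^2),
    SmallDependenceEmphasis = sum(p / jd^2),
    SmallDependenceHighGrayLevelEmphasis = sum(i^2 * p / jd^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * jd^2)))
}

#' NGTDM features
#' @inheritParams glcm_features
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(levels, ng = max(levels)) {
  r <- cpp_ngtdm(levels, ng)
  ni <- r$n; si <- r$s
  N <- sum(ni)
  pi_ <- ni / N
  occ <- which(pi_ > 0)
  ngp <- length(occ)
  ii <- occ
  coarseness <- {
    den <- sum(pi_ * si)
    if (den == 0) 1e6 else min(1 / den, 1e6)
  }
  contrast <- if (ngp <= 1) 0 else {
    sum(outer(pi_[occ], pi_[occ]) * outer(ii, ii, "-")^2) /
      (ngp * (ngp - 1)) * sum(si) / N
  }
  busyness <- {
    den <- sum(abs(outer(ii * pi_[occ], ii * pi_[occ], "-")))
    if (den == 0) 0 else sum(pi_ * si) / den
  }
  complexity <- if (ngp == 0) 0 else {
    pi_o <- pi_[occ]; si_o <- si[occ]
    num <- outer(ii, ii, "-")
    sum(abs(num) * (outer(pi_o * si_o, pi_o * si_o, "+")) /
          outer(pi_o, pi_o, "+")) / N
  }
  strength <- {
    den <- sum(si)
    if (den == 0) 0 else
      sum(outer(pi_[occ], pi_[occ], "+") * outer(ii, ii, "-")^2) / den
  }
  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}

#' All 75 texture features of a discretized VOI
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 75, names prefixed
#'   `glcm_`, `gldm_`, `glszm_`, `glrlm_`, `ngtdm_`.
#' @export
texture_features <- function(levels, ng = max(levels)) {
  pre <- function(x, g) stats::setNames(x, paste(g, names(x), sep = "_"))
  c(pre(glcm_features(levels, ng), "glcm"),
    pre(gldm_features(levels, ng), "gldm"),
    pre(glszm_features(levels, ng), "glszm"),
    pre(glrlm_features(levels, ng), "glrlm"),
    pre(ngtdm_features(levels, ng), "ngtdm"))
}
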