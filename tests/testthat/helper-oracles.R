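# Naive reference implementations used as independent oracles: explicit
# loops, literal formula translations, no shared code with the package.

oracle_in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm_matrix <- function(lv, dir) {
  d <- dim(lv)
  ng <- max(lv)
  P <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lv[x, y, z]
    if (a == 0) next
    q <- c(x, y, z) + dir
    if (!oracle_in_bounds(q, d)) next
    b <- lv[q[1], q[2], q[3]]
    if (b == 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracle_glcm_features_one <- function(P) {
  ng <- nrow(P)
  p <- P / sum(P)
  px <- rowSums(p)
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  sig2 <- 0
  for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  pd <- numeric(ng)        # |i-j| = k-1
  ps <- numeric(2 * ng - 1) # i+j = k+1
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  da <- sum((0:(ng - 1)) * pd)
  hxy <- ent(p)
  hx <- ent(px)
  hxy1 <- 0
  hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(px[i] * px[j])
    if (px[i] * px[j] > 0)
      hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j])
  }
  acc <- 0; cp <- 0; cs <- 0; ct <- 0; contrast <- 0; id <- 0; idm <- 0
  idmn <- 0; idn <- 0; iv <- 0; je <- 0; mp <- 0
  for (i in 1:ng) for (j in 1:ng) {
    acc <- acc + i * j * p[i, j]
    cp <- cp + (i + j - 2 * mu)^4 * p[i, j]
    cs <- cs + (i + j - 2 * mu)^3 * p[i, j]
    ct <- ct + (i + j - 2 * mu)^2 * p[i, j]
    contrast <- contrast + (i - j)^2 * p[i, j]
    id <- id + p[i, j] / (1 + abs(i - j))
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    idmn <- idmn + p[i, j] / (1 + ((i - j) / ng)^2)
    idn <- idn + p[i, j] / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + p[i, j] / (i - j)^2
    je <- je + p[i, j]^2
    if (p[i, j] > mp) mp <- p[i, j]
  }
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ))
      for (k in seq_along(occ))
        Q[a, b] <- Q[a, b] + p[occ[a], occ[k]] * p[occ[b], occ[k]] /
          (px[occ[a]] * px[occ[k]])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(Autocorrelation = acc,
    ClusterProminence = cp, ClusterShade = cs, ClusterTendency = ct,
    Contrast = contrast,
    Correlation = if (sig2 > 0) (acc - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = sum(((0:(ng - 1)) - da)^2 * pd),
    Id = id, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = iv,
    JointAverage = mu, JointEnergy = je, JointEntropy = hxy,
    MaximumProbability = mp, Mcc = mcc,
    SumAverage = sum((2:(2 * ng)) * ps), SumEntropy = ent(ps),
    SumSquares = sig2)
}

oracle_glcm_features <- function(lv, ng = max(lv)) {
  feats <- sapply(seq_len(nrow(DIR13)), function(d) {
    P <- oracle_glcm_matrix(lv, DIR13[d, ])
    if (nrow(P) < ng) {
      PP <- matrix(0, ng, ng)
      PP[seq_len(nrow(P)), seq_len(ncol(P))] <- P
      P <- PP
    }
    oracle_glcm_features_one(P)
  })
  rowMeans(feats)
}

oracle_glrlm_matrix <- function(lv, dir, ng, maxlen) {
  d <- dim(lv)
  P <- matrix(0, ng, maxlen)
  counted <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lv[x, y, z]
    if (a == 0 || counted[x, y, z]) next
    prev <- c(x, y, z) - dir
    if (oracle_in_bounds(prev, d) && lv[prev[1], prev[2], prev[3]] == a)
      next
    len <- 0
    cur <- c(x, y, z)
    while (oracle_in_bounds(cur, d) && lv[cur[1], cur[2], cur[3]] == a) {
      counted[cur[1], cur[2], cur[3]] <- TRUE
      len <- len + 1
      cur <- cur + dir
    }
    P[a, len] <- P[a, len] + 1
  }
  counted[] <- FALSE
  P
}

oracle_glrlm_features_one <- function(P, nvox) {
  ng <- nrow(P); L <- ncol(P)
  nr <- sum(P)
  p <- P / nr
  mui <- 0; muj <- 0
  for (i in 1:ng) for (j in 1:L) {
    mui <- mui + i * p[i, j]
    muj <- muj + j * p[i, j]
  }
  acc <- function(f) {
    s <- 0
    for (i in 1:ng) for (j in 1:L) s <- s + f(i, j) * p[i, j]
    s
  }
  re <- 0
  for (i in 1:ng) for (j in 1:L) if (p[i, j] > 0)
    re <- re - p[i, j] * log2(p[i, j])
  c(GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    GrayLevelVariance = acc(function(i, j) (i - mui)^2),
    HighGrayLevelRunEmphasis = acc(function(i, j) i^2),
    LongRunEmphasis = acc(function(i, j) j^2),
    LongRunHighGrayLevelEmphasis = acc(function(i, j) i^2 * j^2),
    LongRunLowGrayLevelEmphasis = acc(function(i, j) j^2 / i^2),
    LowGrayLevelRunEmphasis = acc(function(i, j) 1 / i^2),
    RunEntropy = re,
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    RunPercentage = nr / nvox,
    RunVariance = acc(function(i, j) (j - muj)^2),
    ShortRunEmphasis = acc(function(i, j) 1 / j^2),
    ShortRunHighGrayLevelEmphasis = acc(function(i, j) i^2 / j^2),
    ShortRunLowGrayLevelEmphasis = acc(function(i, j) 1 / (i^2 * j^2)))
}

oracle_glrlm_features <- function(lv, ng = max(lv)) {
  nvox <- sum(lv > 0)
  maxlen <- max(dim(lv))
  feats <- sapply(seq_len(nrow(DIR13)), function(d) {
    P <- oracle_glrlm_matrix(lv, DIR13[d, ], ng, maxlen)
    oracle_glrlm_features_one(P, nvox)
  })
  rowMeans(feats)
}

oracle_zones <- function(lv) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- list()
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lv[x, y, z] == 0 || seen[x, y, z]) next
    lev <- lv[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (o in seq_len(nrow(offs))) {
        q <- cur + offs[o, ]
        if (oracle_in_bounds(q, d) && !seen[q[1], q[2], q[3]] &&
            lv[q[1], q[2], q[3]] == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(lv, ng = max(lv)) {
  zs <- oracle_zones(lv)
  nvox <- sum(lv > 0)
  S <- max(zs[, 2])
  P <- matrix(0, ng, S)
  for (r in seq_len(nrow(zs))) P[zs[r, 1], zs[r, 2]] <- P[zs[r, 1], zs[r, 2]] + 1
  ns <- sum(P)
  p <- P / ns
  mui <- 0; mus <- 0
  for (i in 1:ng) for (s in 1:S) {
    mui <- mui + i * p[i, s]
    mus <- mus + s * p[i, s]
  }
  acc <- function(f) {
    v <- 0
    for (i in 1:ng) for (s in 1:S) v <- v + f(i, s) * p[i, s]
    v
  }
  ze <- 0
  for (i in 1:ng) for (s in 1:S) if (p[i, s] > 0)
    ze <- ze - p[i, s] * log2(p[i, s])
  c(GrayLevelNonUniformity = sum(rowSums(P)^2) / ns,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / ns^2,
    GrayLevelVariance = acc(function(i, s) (i - mui)^2),
    HighGrayLevelZoneEmphasis = acc(function(i, s) i^2),
    LargeAreaEmphasis = acc(function(i, s) s^2),
    LargeAreaHighGrayLevelEmphasis = acc(function(i, s) i^2 * s^2),
    LargeAreaLowGrayLevelEmphasis = acc(function(i, s) s^2 / i^2),
    LowGrayLevelZoneEmphasis = acc(function(i, s) 1 / i^2),
    SizeZoneNonUniformity = sum(colSums(P)^2) / ns,
    SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / ns^2,
    SmallAreaEmphasis = acc(function(i, s) 1 / s^2),
    SmallAreaHighGrayLevelEmphasis = acc(function(i, s) i^2 / s^2),
    SmallAreaLowGrayLevelEmphasis = acc(function(i, s) 1 / (i^2 * s^2)),
    ZoneEntropy = ze,
    ZonePercentage = ns / nvox,
    ZoneVariance = acc(function(i, s) (s - mus)^2))
}

oracle_gldm_features <- function(lv, ng = max(lv), alpha = 0) {
  d <- dim(lv)
  P <- matrix(0, ng, 27)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lv[x, y, z]
    if (a == 0) next
    dep <- 0
    for (o in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[o, ]
      if (!oracle_in_bounds(q, d)) next
      b <- lv[q[1], q[2], q[3]]
      if (b != 0 && abs(b - a) <= alpha) dep <- dep + 1
    }
    P[a, dep + 1] <- P[a, dep + 1] + 1
  }
  nz <- sum(P)
  p <- P / nz
  mui <- 0; muj <- 0
  for (i in 1:ng) for (j in 1:27) {
    mui <- mui + i * p[i, j]
    muj <- muj + j * p[i, j]
  }
  acc <- function(f) {
    v <- 0
    for (i in 1:ng) for (j in 1:27) v <- v + f(i, j) * p[i, j]
    v
  }
  de <- 0
  for (i in 1:ng) for (j in 1:27) if (p[i, j] > 0)
    de <- de - p[i, j] * log2(p[i, j])
  c(DependenceEntropy = de,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    DependenceVariance = acc(function(i, j) (j - muj)^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    GrayLevelVariance = acc(function(i, j) (i - mui)^2),
    HighGrayLevelEmphasis = acc(function(i, j) i^2),
    LargeDependenceEmphasis = acc(function(i, j) j^2),
    LargeDependenceHighGrayLevelEmphasis = acc(function(i, j) i^2 * j^2),
    LargeDependenceLowGrayLevelEmphasis = acc(function(i, j) j^2 / i^2),
    LowGrayLevelEmphasis = acc(function(i, j) 1 / i^2),
    SmallDependenceEmphasis = acc(function(i, j) 1 / j^2),
    SmallDependenceHighGrayLevelEmphasis = acc(function(i, j) i^2 / j^2),
    SmallDependenceLowGrayLevelEmphasis = acc(function(i, j) 1 / (i^2 * j^2)))
}

oracle_ngtdm_features <- function(lv, ng = max(lv)) {
  d <- dim(lv)
  ni <- numeric(ng)
  si <- numeric(ng)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lv[x, y, z]
    if (a == 0) next
    vals <- c()
    for (o in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[o, ]
      if (oracle_in_bounds(q, d) && lv[q[1], q[2], q[3]] != 0)
        vals <- c(vals, lv[q[1], q[2], q[3]])
    }
    ni[a] <- ni[a] + 1
    if (length(vals)) si[a] <- si[a] + abs(a - mean(vals))
  }
  N <- sum(ni)
  pv <- ni / N
  occ <- which(pv > 0)
  ngp <- length(occ)
  coars <- if (sum(pv * si) == 0) 1e6 else min(1 / sum(pv * si), 1e6)
  contr <- 0
  if (ngp > 1) {
    for (i in occ) for (j in occ)
      contr <- contr + pv[i] * pv[j] * (i - j)^2
    contr <- contr / (ngp * (ngp - 1)) * sum(si) / N
  }
  busy_den <- 0
  for (i in occ) for (j in occ)
    busy_den <- busy_den + abs(i * pv[i] - j * pv[j])
  busy <- if (busy_den == 0) 0 else sum(pv * si) / busy_den
  comp <- 0
  for (i in occ) for (j in occ)
    comp <- comp + abs(i - j) * (pv[i] * si[i] + pv[j] * si[j]) /
      (pv[i] + pv[j])
  comp <- comp / N
  stren <- 0
  for (i in occ) for (j in occ)
    stren <- stren + (pv[i] + pv[j]) * (i - j)^2
  stren <- if (sum(si) == 0) 0 else stren / sum(si)
  c(Busyness = busy, Coarseness = coars, Complexity = comp,
    Contrast = contr, Strength = stren)
}

oracle_firstorder <- function(x, lev) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  p <- as.vector(table(factor(lev, levels = seq_len(max(lev))))) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  sub <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x), Percentile10 = q[1], Percentile90 = q[5],
    Maximum = max(x), Mean = mu, Median = q[3],
    InterquartileRange = q[4] - q[2], Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation =
      if (length(sub)) sum(abs(sub - mean(sub))) / length(sub) else 0,
    Skewness = if (m2 > 0) (sum((x - mu)^3) / n) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) (sum((x - mu)^4) / n) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

# exact Shapley values by full coalition enumeration for an arbitrary
# value function v(S) (S = logical subset of features)
oracle_shapley <- function(value_fn, p) {
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  vals <- apply(subsets, 1, function(s) value_fn(as.logical(s)))
  for (i in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      s <- as.logical(subsets[r, ])
      if (s[i]) next
      s2 <- s
      s2[i] <- TRUE
      k <- sum(s)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      r2 <- which(apply(subsets, 1, function(q) all(as.logical(q) == s2)))
      phi[i] <- phi[i] + w * (vals[r2] - vals[r])
    }
  }
  phi
}
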