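# Coiflet-1 analysis filters (6 taps)
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
              0.3848648468648578, 0.8525720202116004,
              0.3378976624574818, -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818,
              -0.8525720202116004, 0.3848648468648578,
              0.07273261951252645, -0.015655728135791993)

# undecimated FIR filtering along one axis with half-sample symmetric
# boundary extension; taps applied at offsets -3..2 around each sample
swt_filter_axis <- function(vol, f, axis) {
  d <- dim(vol)
  n <- d[axis]
  if (n < length(f))
    stop("volume too small along axis ", axis, ": ", n, " < ", length(f),
         " (filter length)")
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = n)
  out <- matrix(0, n, ncol(m))
  base <- seq_len(n)
  offsets <- seq_along(f) - 4L # -3..2
  for (j in seq_along(f)) {
    idx <- base + offsets[j]
    # half-sample reflection: ..., x2, x1 | x1, x2, ..., xn | xn, xn-1, ...
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    out <- out + f[j] * m[idx, , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

#' Single-level undecimated Coiflet-1 wavelet decomposition
#'
#' Separable stationary (undecimated) 3D wavelet transform: low- (L) or
#' high-pass (H) Coiflet-1 filters are applied along the X, Y and Z axes
#' in turn, producing eight sub-bands of the same shape as the input so
#' that the VOI mask applies unchanged. Sub-band names give the filters in
#' (X, Y, Z) order.
#'
#' @param volume 3D numeric array; every dimension must be at least the
#'   filter length (6).
#' @return Named list of eight arrays, in the order HHH, HHL, HLH, HLL,
#'   LHH, LHL, LLH, LLL.
#' @export
wavelet_decompose <- function(volume) {
  stopifnot(length(dim(volume)) == 3)
  lx <- swt_filter_axis(volume, COIF1_LO, 1)
  hx <- swt_filter_axis(volume, COIF1_HI, 1)
  xs <- list(L = lx, H = hx)
  out <- list()
  for (fx in c("H", "L"))
    for (fy in c("H", "L")) {
      xy <- swt_filter_axis(xs[[fx]],
                            if (fy == "L") COIF1_LO else COIF1_HI, 2)
      for (fz in c("H", "L")) {
        nm <- paste0(fx, fy, fz)
        out[[nm]] <- swt_filter_axis(xy,
                                     if (fz == "L") COIF1_LO else COIF1_HI,
                                     3)
      }
    }
  out[c("HHH", "HHL", "HLH", "HLL", "LHH", "LHL", "LLH", "LLL")]
}
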