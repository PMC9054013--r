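#' @keywords internal
"_PACKAGE"

FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

#' Convert a full width at half maximum to a Gaussian sigma
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return Sigma in the same unit; `fwhm / (2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_PER_SIGMA

#' Convert a Gaussian sigma to a full width at half maximum
#'
#' @param sigma Gaussian standard deviation.
#' @return FWHM in the same unit.
#' @export
sigma_to_fwhm <- function(sigma) sigma * FWHM_PER_SIGMA

# Deterministic 32-bit seed derivation so that independent random streams
# (per object, per frame, per channel) can be split from one base seed.
# Mixing is a small LCG-style hash; all arithmetic kept in double precision
# below 2^53 and reduced mod (2^31 - 1) so the result is a valid R seed.
derive_seed <- function(base, ...) {
  idx <- c(...)
  h <- (abs(base) %% 2147483647) + 1
  for (i in seq_along(idx)) {
    h <- (h * 48271 + (idx[i] %% 65521) * 7919 + i * 104729) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Periodic (circular) 2D convolution via FFT. `kernel` is a small odd-sized
# matrix centred at its middle element; it is embedded into a field-sized
# matrix with wrap-around so that sum(out) == sum(img) * sum(kernel) exactly
# up to floating point.
fft_convolve2 <- function(img, kernel) {
  ny <- nrow(img); nx <- ncol(img)
  ky <- nrow(kernel); kx <- ncol(kernel)
  if (ky > ny || kx > nx) stop("kernel larger than image")
  big <- matrix(0, ny, nx)
  cy <- (ky + 1) %/% 2; cx <- (kx + 1) %/% 2
  ys <- ((seq_len(ky) - cy) %% ny) + 1
  xs <- ((seq_len(kx) - cx) %% nx) + 1
  big[ys, xs] <- big[ys, xs] + kernel
  out <- Re(stats::fft(stats::fft(img) * stats::fft(big), inverse = TRUE)) / (ny * nx)
  out
}

# Isotropic Gaussian kernel, truncated at `truncate` sigmas, normalised to
# sum exactly 1 so that convolution conserves total intensity.
gaussian_kernel <- function(sigma_px, truncate = 5) {
  r <- max(1L, as.integer(ceiling(truncate * sigma_px)))
  ax <- seq(-r, r)
  g <- exp(-ax^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

# Laplacian-of-Gaussian kernel at scale sigma (sign flipped so bright blobs
# give positive response), zero-mean.
log_kernel <- function(sigma_px, truncate = 5) {
  r <- max(2L, as.integer(ceiling(truncate * sigma_px)))
  ax <- seq(-r, r)
  xx <- outer(rep(1, length(ax)), ax)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^4 * exp(-r2 / (2 * sigma_px^2))
  k - mean(k)
}

# Logical matrix marking strict local maxima over the 8-neighbourhood.
local_maxima <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  res <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    res <- res & (m > pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)])
  }
  res
}

# Bilinear interpolation of matrix `m` at 0-based pixel-centre coordinates
# (x = column, y = row). Out-of-range samples return `fill`.
bilinear_sample <- function(m, x, y, fill = NA_real_) {
  ny <- nrow(m); nx <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nx - 1 & y0 <= ny - 1
  # clamp the upper neighbour so samples exactly on the last row/col work
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  out <- rep(fill, length(x))
  if (any(ok)) {
    i00 <- cbind(y0[ok] + 1, x0[ok] + 1)
    i01 <- cbind(y0[ok] + 1, x1[ok] + 1)
    i10 <- cbind(y1[ok] + 1, x0[ok] + 1)
    i11 <- cbind(y1[ok] + 1, x1[ok] + 1)
    out[ok] <- m[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      m[i01] * fx[ok] * (1 - fy[ok]) +
      m[i10] * (1 - fx[ok]) * fy[ok] +
      m[i11] * fx[ok] * fy[ok]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Catmull-Rom bicubic interpolation at 0-based coordinates; clamped at the
# borders, NA outside. Used for image resampling where bilinear smoothing
# would cost measurable peak amplitude.
bicubic_sample <- function(m, x, y, fill = NA_real_) {
  ny <- nrow(m); nx <- ncol(m)
  ok <- x >= 0 & y >= 0 & x <= nx - 1 & y <= ny - 1
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  xo <- x[ok]; yo <- y[ok]
  x0 <- floor(xo); y0 <- floor(yo)
  fx <- xo - x0; fy <- yo - y0
  w <- function(t, i) {
    # Catmull-Rom weights for offsets -1, 0, 1, 2
    switch(i,
           ((-t + 2) * t - 1) * t / 2,
           (((3 * t - 5) * t) * t + 2) / 2,
           ((-3 * t + 4) * t + 1) * t / 2,
           ((t - 1) * t * t) / 2)
  }
  acc <- numeric(length(xo))
  for (j in 1:4) {
    yy <- pmin(pmax(y0 + (j - 2), 0), ny - 1)
    wy <- w(fy, j)
    row_acc <- numeric(length(xo))
    for (i in 1:4) {
      xx <- pmin(pmax(x0 + (i - 2), 0), nx - 1)
      row_acc <- row_acc + w(fx, i) * m[cbind(yy + 1, xx + 1)]
    }
    acc <- acc + wy * row_acc
  }
  out[ok] <- acc
  out
}
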