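#' Average raw sub-frames into one snapshot per time point
#'
#' SIM acquisitions record several raw images (pattern angles x phases) per
#' time point; for detection and tracking each group of `n_raw` consecutive
#' sub-frames is replaced by its arithmetic mean.
#'
#' @param movie A [ccp_movie()] whose frame count is divisible by `n_raw`.
#' @param n_raw Sub-frames per time point; defaults to the movie's own
#'   `n_raw` attribute.
#' @return A [ccp_movie()] with one frame per time point and `n_raw = 1`.
#' @export
average_raw_frames <- function(movie, n_raw = movie$n_raw) {
  n_raw <- as.integer(n_raw)
  nt_raw <- n_frames(movie)
  if (nt_raw %% n_raw != 0) {
    stop(sprintf("frame count (%d) not divisible by n_raw (%d)", nt_raw, n_raw))
  }
  if (n_raw == 1) {
    movie$n_raw <- 1L
    return(movie)
  }
  nt <- nt_raw %/% n_raw
  d <- dim(movie$frames)
  out <- array(0, dim = c(d[1], d[2], nt))
  for (t in seq_len(nt)) {
    idx <- ((t - 1) * n_raw + 1):(t * n_raw)
    out[, , t] <- apply(movie$frames[, , idx, drop = FALSE], c(1, 2), mean)
  }
  ccp_movie(out, movie$pixel_size, movie$frame_interval, 1L)
}

# Least-squares fit of I(x, y) = A * G_sigma(x - x0, y - y0) + b on a square
# window. sigma is fixed (from the optics); x0, y0 are optimised by
# Gauss-Newton with (A, b) profiled out linearly at each step, which is the
# standard fixed-sigma PSF-fitting scheme. Returns NULL on divergence.
fit_gaussian_spot <- function(win, x0, y0, sigma, max_iter = 50) {
  ny <- nrow(win); nx <- ncol(win)
  xs <- seq_len(nx) - 1; ys <- seq_len(ny) - 1
  X <- outer(rep(1, ny), xs); Y <- outer(ys, rep(1, nx))
  v <- as.numeric(win)
  n <- length(v)
  pos <- c(x0, y0)
  for (it in seq_len(max_iter)) {
    g <- exp(-((X - pos[1])^2 + (Y - pos[2])^2) / (2 * sigma^2))
    gv <- as.numeric(g)
    # profile A, b by linear least squares
    sg <- sum(gv); sgg <- sum(gv * gv)
    den <- n * sgg - sg^2
    if (den <= 1e-12) return(NULL)
    A <- (n * sum(gv * v) - sg * sum(v)) / den
    b <- (sum(v) - A * sg) / n
    r <- v - (A * gv + b)
    # Gauss-Newton step on (x0, y0)
    dgx <- as.numeric(g * (X - pos[1]) / sigma^2) * A
    dgy <- as.numeric(g * (Y - pos[2]) / sigma^2) * A
    J <- cbind(dgx, dgy)
    JtJ <- crossprod(J)
    if (!all(is.finite(JtJ)) || rcond_2x2(JtJ) < 1e-12) break
    step <- solve(JtJ, crossprod(J, r))
    step <- pmin(pmax(step, -1), 1)
    pos <- pos + as.numeric(step)
    if (pos[1] < -1 || pos[1] > nx || pos[2] < -1 || pos[2] > ny) return(NULL)
    if (max(abs(step)) < 1e-4) break
  }
  g <- exp(-((X - pos[1])^2 + (Y - pos[2])^2) / (2 * sigma^2))
  gv <- as.numeric(g)
  sg <- sum(gv); sgg <- sum(gv * gv)
  den <- n * sgg - sg^2
  A <- (n * sum(gv * v) - sg * sum(v)) / den
  b <- (sum(v) - A * sg) / n
  r <- v - (A * gv + b)
  df <- n - 4
  sd_res <- sqrt(sum(r^2) / df)
  # standard error of A from the linear (A, b) subproblem
  se_A <- sd_res * sqrt(n / den)
  tval <- A / se_A
  pval <- stats::pt(tval, df, lower.tail = FALSE)
  list(x = pos[1], y = pos[2], A = A, b = b, sd_res = sd_res,
       se_A = se_A, p = pval)
}

rcond_2x2 <- function(m) {
  e <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (e[1] <= 0) return(0)
  e[2] / e[1]
}

#' Detect diffraction-limited spots in one frame
#'
#' Models a spot as an isotropic 2D Gaussian approximation of the PSF above a
#' local background: candidates come from local maxima of a
#' Laplacian-of-Gaussian filter at the PSF scale, each candidate is refined
#' by least-squares fitting of `A * G_sigma + b` on a window of half-size
#' `ceil(4 * sigma)`, and a candidate is kept when the one-sided t-test of
#' the fitted amplitude against the local residual noise gives `p < alpha`.
#' Duplicate fits converging within 1 px are merged keeping the higher
#' amplitude.
#'
#' @param frame Numeric matrix (one movie frame), at least 15 x 15 px.
#' @param optics An [optics_params()]; supplies the PSF sigma.
#' @param alpha Significance level of the amplitude test.
#' @param log_threshold Candidate threshold in robust standard deviations of
#'   the filter response.
#' @return Data frame with columns `frame` (NA; filled by [detect_movie()]),
#'   `x`, `y` (0-based sub-pixel), `A`, `b`, `sigma`, `significance`, plus an
#'   attribute `n_diverged` counting dropped candidates.
#' @export
detect_spots <- function(frame, optics, alpha = 0.05, log_threshold = 4.5) {
  if (nrow(frame) < 15 || ncol(frame) < 15) stop("frame must be >= 15x15 px")
  sigma <- psf_sigma_px(optics)
  resp <- fft_convolve2(frame, log_kernel(sigma))
  thr <- stats::median(resp) + log_threshold * stats::mad(resp)
  cand <- which(local_maxima(resp) & resp > thr, arr.ind = TRUE)
  hw <- as.integer(ceiling(4 * sigma))
  ny <- nrow(frame); nx <- ncol(frame)
  res <- list()
  n_div <- 0L
  if (nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      cy <- cand[i, 1]; cx <- cand[i, 2]
      y1 <- max(1, cy - hw); y2 <- min(ny, cy + hw)
      x1 <- max(1, cx - hw); x2 <- min(nx, cx + hw)
      if ((y2 - y1) < hw || (x2 - x1) < hw) next # too close to the border
      win <- frame[y1:y2, x1:x2]
      fit <- fit_gaussian_spot(win, cx - x1, cy - y1, sigma)
      if (is.null(fit) || !is.finite(fit$A)) { n_div <- n_div + 1L; next }
      if (fit$A <= 0 || fit$p >= alpha) next
      res[[length(res) + 1]] <- data.frame(
        frame = NA_integer_,
        x = fit$x + (x1 - 1), y = fit$y + (y1 - 1),
        A = fit$A, b = fit$b, sigma = sigma, significance = fit$p
      )
    }
  }
  det <- if (length(res)) do.call(rbind, res) else
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               A = numeric(0), b = numeric(0), sigma = numeric(0),
               significance = numeric(0))
  det <- merge_duplicates(det, min_dist = 1)
  det <- det[det$x >= 0 & det$x <= nx - 1 & det$y >= 0 & det$y <= ny - 1, ]
  rownames(det) <- NULL
  attr(det, "n_diverged") <- n_div
  det
}

merge_duplicates <- function(det, min_dist = 1) {
  if (nrow(det) < 2) return(det)
  ord <- order(-det$A)
  det <- det[ord, ]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det) - 1)) {
    if (!keep[i]) next
    j <- (i + 1):nrow(det)
    d2 <- (det$x[j] - det$x[i])^2 + (det$y[j] - det$y[i])^2
    keep[j][d2 < min_dist^2 & keep[j]] <- FALSE
  }
  det <- det[keep, ]
  det[order(det$y, det$x), ]
}

#' Detect spots in every frame of a movie
#'
#' Runs [detect_spots()] per time point (after averaging raw sub-frames when
#' necessary) and stacks the results with 0-based frame indices.
#'
#' @inheritParams detect_spots
#' @param movie A [ccp_movie()].
#' @return Data frame of detections with the `frame` column filled.
#' @export
detect_movie <- function(movie, optics, alpha = 0.05, log_threshold = 4.5) {
  if (movie$n_raw > 1) movie <- average_raw_frames(movie)
  out <- vector("list", n_frames(movie))
  for (t in seq_len(n_frames(movie))) {
    d <- detect_spots(movie$frames[, , t], optics, alpha, log_threshold)
    if (nrow(d)) d$frame <- t - 1L
    out[[t]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
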