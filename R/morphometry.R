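#' Extract a snapshot ROI around a CCP with automated centroid refinement
#'
#' Cuts an odd-sized window at the rounded track position and refines the
#' centroid by the intensity-weighted centre of mass of the
#' background-subtracted window, re-cutting the window when the estimate
#' moves across a pixel boundary, iterated to convergence (< 0.01 px). The
#' centre of mass is unbiased for both peaked and annular (ring-shaped)
#' spots, which is why it is used instead of a Gaussian fit here.
#'
#' @param movie A [ccp_movie()] or a single matrix.
#' @param frame Frame index (0-based; ignored for a matrix).
#' @param x,y Approximate 0-based position.
#' @param size Odd window side, pixels (default 21, the standard ROI).
#' @return An object of class `ccp_snapshot`: `image` (size x size matrix),
#'   `center` (refined sub-pixel centre in 0-based snapshot coordinates),
#'   `origin` (0-based field coordinates of the snapshot's [0, 0] pixel),
#'   `source` (frame, x, y). Errors if the ROI is clipped by the border or
#'   the refined centroid leaves the central 5 x 5 px.
#' @export
extract_snapshot <- function(movie, frame = 0, x, y, size = 21) {
  if (size %% 2 == 0) stop("snapshot size must be odd")
  fr <- if (is.matrix(movie)) movie else movie_frame(movie, frame + 1)
  ny <- nrow(fr); nx <- ncol(fr)
  hw <- (size - 1) / 2
  cx <- round(x); cy <- round(y)
  cut_at <- function(cx, cy) {
    if (cx - hw < 0 || cy - hw < 0 || cx + hw > nx - 1 || cy + hw > ny - 1) {
      stop("ROI clipped by the frame border; snapshot rejected")
    }
    fr[(cy - hw):(cy + hw) + 1, (cx - hw):(cx + hw) + 1]
  }
  cx0 <- cx; cy0 <- cy
  win <- cut_at(cx, cy)
  local_xy <- c(hw, hw)
  # centre of mass restricted to a central circular mask so that a
  # neighbouring structure in the window corner cannot drag the centroid
  mask_r <- 0.6 * hw
  xs <- 0:(size - 1)
  mask <- sqrt(outer((xs - hw)^2, (xs - hw)^2, `+`)) <= mask_r
  for (it in 1:50) {
    w <- win - stats::median(win)
    w[w < 0] <- 0
    w[!mask] <- 0
    tot <- sum(w)
    if (tot <= 0) { local_xy <- c(hw, hw); break }
    comx <- sum(colSums(w) * xs) / tot
    comy <- sum(rowSums(w) * xs) / tot
    shift <- c(comx, comy) - c(hw, hw)
    new_c <- c(cx, cy) + round(shift)
    # total walk from the initial position is capped at 2 px (the refined
    # centroid must stay within the central 5x5 px)
    new_c <- pmin(pmax(new_c, c(cx0, cy0) - 2), c(cx0, cy0) + 2)
    moved <- sqrt(sum((c(comx, comy) - local_xy)^2))
    if (any(new_c != c(cx, cy)) && max(abs(shift)) > 0.5) {
      cx <- new_c[1]; cy <- new_c[2]
      win <- cut_at(cx, cy)
      local_xy <- c(hw, hw)
    } else {
      local_xy <- c(comx, comy)
      if (moved < 0.01) break
    }
  }
  if (any(abs(local_xy - hw) > 2)) {
    stop("refined centroid left the central 5x5 px; snapshot rejected")
  }
  structure(
    list(image = win, center = local_xy, origin = c(cx - hw, cy - hw),
         source = list(frame = frame, x = x, y = y), size = size),
    class = "ccp_snapshot"
  )
}

#' Average a stack of snapshots
#'
#' Optionally re-centres each snapshot to its refined centroid by sub-pixel
#' bilinear shifting, then takes the per-pixel mean.
#'
#' @param snapshots List of `ccp_snapshot`s (same size).
#' @param align Re-centre each snapshot before averaging.
#' @param min_count Minimum number of snapshots (default 50, the
#'   standard requirement for a phase average).
#' @return The averaged image (matrix) with attribute `n`.
#' @export
average_snapshots <- function(snapshots, align = TRUE, min_count = 50) {
  n <- length(snapshots)
  if (n < min_count) {
    stop(sprintf("only %d snapshot(s); at least %d required", n, min_count))
  }
  size <- snapshots[[1]]$size
  hw <- (size - 1) / 2
  acc <- matrix(0, size, size)
  cnt <- matrix(0, size, size)
  gx <- rep(0:(size - 1), each = size)
  gy <- rep(0:(size - 1), times = size)
  for (s in snapshots) {
    img <- s$image
    if (align) {
      dx <- s$center[1] - hw; dy <- s$center[2] - hw
      v <- bilinear_sample(img, gx + dx, gy + dy, fill = NA_real_)
      img <- matrix(v, size, size)
    }
    ok <- !is.na(img)
    acc[ok] <- acc[ok] + img[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- NA
  attr(out, "n") <- n
  out
}

#' Azimuthally averaged radial intensity profile
#'
#' Assigns pixels to annular bins by distance from the centre and averages
#' the intensity per bin.
#'
#' @param image Matrix.
#' @param center `(x, y)` 0-based centre.
#' @param pixel_size nm per pixel.
#' @param bin_width Radial bin width, nm (default one pixel).
#' @return Data frame of class `radial_profile`: `radius_nm` (bin centres),
#'   `intensity` (mean per bin; `NA` for empty bins), `n_pixels`.
#' @export
radial_profile <- function(image, center, pixel_size, bin_width = pixel_size) {
  ny <- nrow(image); nx <- ncol(image)
  if (center[1] < 0 || center[1] > nx - 1 || center[2] < 0 || center[2] > ny - 1) {
    stop("center must lie inside the image")
  }
  xs <- (0:(nx - 1) - center[1]) * pixel_size
  ys <- (0:(ny - 1) - center[2]) * pixel_size
  r <- sqrt(outer(ys^2, xs^2, `+`))
  bin <- floor(r / bin_width)
  nb <- max(bin) + 1
  sums <- tapply(as.numeric(image), as.numeric(bin), sum)
  cnts <- tapply(rep(1, length(bin)), as.numeric(bin), sum)
  idx <- as.integer(names(sums))
  intensity <- rep(NA_real_, nb)
  npix <- rep(0L, nb)
  intensity[idx + 1] <- sums / cnts
  npix[idx + 1] <- cnts
  out <- data.frame(radius_nm = (seq_len(nb) - 0.5) * bin_width,
                    intensity = intensity, n_pixels = npix)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Through-centre 1D intensity profile averaged over orientations
#'
#' Samples the image along lines through the centre at the given
#' orientations (bilinear interpolation) and averages the resulting 1D
#' profiles. Position is signed distance from the centre in nm.
#'
#' @param image Matrix.
#' @param center `(x, y)` 0-based centre.
#' @param pixel_size nm per pixel.
#' @param orientations Angles in degrees (default the 4 half-axes).
#' @param step Sampling step in pixels.
#' @return Data frame with `position_nm` and `intensity`.
#' @export
line_profile <- function(image, center, pixel_size,
                         orientations = c(0, 45, 90, 135), step = 0.25) {
  ny <- nrow(image); nx <- ncol(image)
  rmax <- min(center[1], nx - 1 - center[1], center[2], ny - 1 - center[2])
  ss <- seq(-rmax, rmax, by = step)
  acc <- matrix(NA_real_, length(orientations), length(ss))
  for (i in seq_along(orientations)) {
    th <- orientations[i] * pi / 180
    px <- center[1] + ss * cos(th)
    py <- center[2] + ss * sin(th)
    acc[i, ] <- bilinear_sample(image, px, py)
  }
  data.frame(position_nm = ss * pixel_size,
             intensity = colMeans(acc, na.rm = TRUE))
}

#' Full width at half maximum of a 1D profile
#'
#' Background is the mean of the outer 10% of samples; the half level is
#' `background + (max - background) / 2`; crossings are located by linear
#' interpolation on each side of the maximum and the width is the distance
#' between the outermost crossings. Works for single-peak and
#' double-peak (annular through-centre) profiles alike.
#'
#' @param position Positions (nm).
#' @param intensity Intensities (same length).
#' @return FWHM in the units of `position`.
#' @export
fwhm <- function(position, intensity) {
  ok <- !is.na(intensity)
  position <- position[ok]; intensity <- intensity[ok]
  n <- length(position)
  if (n < 5) stop("profile too short")
  n_bg <- max(2, ceiling(0.1 * n))
  bg <- mean(intensity[c(seq_len(ceiling(n_bg / 2)),
                         (n - floor(n_bg / 2) + 1):n)])
  mx <- max(intensity)
  if (mx <= bg) stop("profile has no peak above background")
  half <- bg + (mx - bg) / 2
  imax <- which.max(intensity)
  above <- intensity >= half
  # outermost upward crossing on the left of the leftmost above-half run
  left_idx <- which(above)[1]
  right_idx <- which(above)[sum(above)]
  if (left_idx == 1 || right_idx == n) {
    stop("profile not enclosed: no half-maximum crossing on one side")
  }
  interp <- function(i1, i2) {
    x1 <- position[i1]; x2 <- position[i2]
    y1 <- intensity[i1]; y2 <- intensity[i2]
    x1 + (half - y1) / (y2 - y1) * (x2 - x1)
  }
  xl <- interp(left_idx - 1, left_idx)
  xr <- interp(right_idx, right_idx + 1)
  xr - xl
}

# Parabolic interpolation of the peak of a sampled profile; returns the
# refined peak position (same units as x) and the peak value.
refine_peak <- function(x, y) {
  ok <- which(!is.na(y))
  if (length(ok) < 3) stop("too few samples to locate a peak")
  x <- x[ok]; y <- y[ok]
  i <- which.max(y)
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1)) {
    stop("flat profile: no peak to locate")
  }
  if (i == 1 || i == length(y)) return(list(x = x[i], y = y[i]))
  # vertex of the parabola through the peak bin and its two neighbours
  X <- c(x[i - 1], x[i], x[i + 1])
  Y <- c(y[i - 1], y[i], y[i + 1])
  cf <- stats::coef(stats::lm(Y ~ X + I(X^2)))
  if (is.na(cf[3]) || cf[3] >= 0) return(list(x = x[i], y = y[i]))
  xv <- unname(-cf[2] / (2 * cf[3]))
  if (xv < X[1] || xv > X[3]) xv <- x[i]
  list(x = xv, y = max(y))
}

#' Ring-versus-patch morphometry of a CCP image
#'
#' Computes a fine radial profile around the centre (on a bilinearly
#' resampled grid, half-pixel bins, which suppresses the bin-migration
#' noise of coarse binning), locates the profile peak by parabolic
#' interpolation, the central dip `1 - I(0) / I(peak)` (with `I(0)` averaged
#' over the central pixel-sized disk), and the through-centre FWHM averaged
#' over 4 orientations. The image is classified as a ring when the peak
#' radius is at least one pixel-equivalent in nm and the central dip is at
#' least `dip_threshold`; otherwise it is a patch. The thresholds are chosen
#' so that a PSF-limited point source is never a ring.
#'
#' @param image Matrix (snapshot or averaged snapshot).
#' @param center `(x, y)` 0-based centre.
#' @param pixel_size nm per pixel.
#' @param dip_threshold Minimum central dip for a ring (default 0.1).
#' @param oversample Bilinear resampling factor for the fine profile.
#' @param max_radius_nm Peak search limit; bins beyond it only inform the
#'   background level.
#' @param psf_fwhm Optional PSF FWHM (nm). When given, the reported
#'   `peak_radius` is corrected for the inward peak shift of a blurred
#'   annulus by inverting the Gaussian-blurred thin-ring model
#'   (see [ring_radius_from_profile()]); the ring/patch decision itself uses
#'   the uncorrected profile.
#' @return An object of class `ring_metrics`: `peak_radius` (nm),
#'   `central_dip`, `fwhm` (nm), `diameter` (nm, = fwhm), `shape_class`
#'   (`"ring"` or `"patch"`), and the fine `profile` used.
#' @export
classify_shape <- function(image, center, pixel_size, dip_threshold = 0.1,
                           oversample = 3L, max_radius_nm = 200,
                           psf_fwhm = NULL) {
  os <- as.integer(oversample)
  size_y <- nrow(image); size_x <- ncol(image)
  gx <- seq(0, size_x - 1, by = 1 / os)
  gy <- seq(0, size_y - 1, by = 1 / os)
  v <- bilinear_sample(image, rep(gx, each = length(gy)),
                       rep(gy, times = length(gx)))
  fine <- matrix(v, length(gy), length(gx))
  prof <- radial_profile(fine, center * os, pixel_size / os,
                         bin_width = pixel_size / 2)
  ok <- !is.na(prof$intensity)
  bg <- mean(utils::tail(prof$intensity[ok], 6))
  ii <- prof$intensity - bg
  sel <- prof$radius_nm <= max_radius_nm
  pk <- refine_peak(prof$radius_nm[sel], ii[sel])
  i0 <- mean(ii[prof$radius_nm < pixel_size], na.rm = TRUE)
  dip <- if (pk$y > 0) max(0, min(1, 1 - i0 / pk$y)) else 0
  lp <- line_profile(image, center, pixel_size)
  w <- tryCatch(fwhm(lp$position_nm, lp$intensity), error = function(e) NA_real_)
  # a peak inside the first half-pixel bin is treated as centred (radius 0)
  peak_radius <- if (pk$x <= pixel_size / 2) 0 else pk$x
  is_ring <- peak_radius >= pixel_size && dip >= dip_threshold
  if (!is.null(psf_fwhm) && peak_radius > 0) {
    sig <- fwhm_to_sigma(psf_fwhm)
    f <- function(r0) blurred_ring_peak(r0, sig) - peak_radius
    if (f(peak_radius) < 0) {
      peak_radius <- stats::uniroot(f, c(peak_radius,
                                         peak_radius + 5 * sig),
                                    tol = 1e-6)$root
    }
  }
  structure(
    list(peak_radius = peak_radius, central_dip = dip, fwhm = w,
         diameter = w, shape_class = if (is_ring) "ring" else "patch",
         profile = prof),
    class = "ring_metrics"
  )
}

#' @export
print.ring_metrics <- function(x, ...) {
  cat(sprintf("<ring_metrics> %s: peak radius %.1f nm, dip %.2f, FWHM %.1f nm\n",
              x$shape_class, x$peak_radius, x$central_dip, x$fwhm))
  invisible(x)
}

#' Signed radial peak offset between two profiles
#'
#' Locates each profile's intensity maximum by parabolic interpolation around
#' the peak bin and returns `peak_radius(a) - peak_radius(b)` in nm.
#'
#' @param profile_a,profile_b `radial_profile` data frames.
#' @return Signed offset, nm.
#' @export
peak_offset <- function(profile_a, profile_b) {
  pa <- refine_peak(profile_a$radius_nm, profile_a$intensity)
  pb <- refine_peak(profile_b$radius_nm, profile_b$intensity)
  pa$x - pb$x
}

#' Summary statistics of CCP diameters
#'
#' @param diameters Numeric vector of diameters (nm), length >= 2.
#' @return Named list: `mean`, `sd`, `max_rel_deviation`
#'   (`max |d - mean| / mean`) and `cv` (`sd / mean`).
#' @export
size_statistics <- function(diameters) {
  if (length(diameters) < 2) stop("need at least 2 diameters")
  m <- mean(diameters)
  list(mean = m, sd = stats::sd(diameters),
       max_rel_deviation = max(abs(diameters - m)) / m,
       cv = stats::sd(diameters) / m)
}

#' Vesicle diameter equivalent to a flat coat footprint
#'
#' Treats the CCP footprint as a flat circular disk of the given diameter
#' and returns the diameter of the sphere with the same surface area:
#' `pi (d/2)^2 = 4 pi (D/2)^2`, so `D = d / 2`. The non-default
#' `"hemisphere"` mode instead equates the area of a hemispherical coat,
#' `2 pi (d/2)^2`, giving `D = d / sqrt(2)`.
#'
#' @param ccp_diameter Footprint diameter, nm (> 0).
#' @param mode `"disk"` (default) or `"hemisphere"`.
#' @return Equivalent vesicle diameter, nm.
#' @export
vesicle_diameter_from_footprint <- function(ccp_diameter,
                                            mode = c("disk", "hemisphere")) {
  mode <- match.arg(mode)
  if (any(!is.na(ccp_diameter) & ccp_diameter < 0)) {
    stop("diameter must be non-negative")
  }
  if (mode == "disk") ccp_diameter / 2 else ccp_diameter / sqrt(2)
}

#' Five-phase lifetime classification of a tracked CCP
#'
#' Rule-based per-frame labels from two-channel amplitudes and pioneer-ring
#' morphometry: phase 1 while only the pioneer channel is above detection;
#' phase 2 once clathrin is above detection (pioneer still patch or freshly
#' ringed); phase 3 when the pioneer ring has expanded beyond its initial
#' ring radius by at least `expand_nm`; phase 4 when the pioneer amplitude
#' has fallen below `decay_frac` of its track maximum with a negative
#' smoothed slope while clathrin persists; phase 5 when the pioneer is below
#' detection and clathrin persists. Labels are forced monotone
#' non-decreasing by a running maximum. The detection level for a channel is
#' `detect_k` times its local background sd.
#'
#' @param metrics Data frame with one row per frame and columns `fcho_A`,
#'   `fcho_bg_sd`, `fcho_is_ring` (logical), `fcho_peak_radius` (nm),
#'   `clat_A`, `clat_bg_sd`.
#' @param expand_nm Ring-expansion criterion (default one SIM pixel,
#'   32.5 nm).
#' @param decay_frac Pioneer decay fraction (default 0.5).
#' @param detect_k Detection threshold in background sds (default 3).
#' @param smooth Half-width (frames) of the moving average used for the
#'   slope.
#' @return Integer vector of phases (1-5), one per frame. A track whose
#'   clathrin channel never rises above detection stays all phase 1 and
#'   carries attribute `degenerate = TRUE`.
#' @export
classify_phase <- function(metrics, expand_nm = 32.5, decay_frac = 0.5,
                           detect_k = 3, smooth = 2) {
  n <- nrow(metrics)
  fch <- metrics$fcho_A
  cla <- metrics$clat_A
  # smoothed pioneer amplitude: detection and decay decisions use it so a
  # single noisy frame cannot flip a label (labels are monotone anyway)
  k <- 2 * smooth + 1
  fs <- as.numeric(stats::filter(fch, rep(1 / k, k), sides = 2))
  fs[is.na(fs)] <- fch[is.na(fs)]
  fdet <- fs > detect_k * metrics$fcho_bg_sd
  cdet <- cla > detect_k * metrics$clat_bg_sd
  fdet[is.na(fdet)] <- FALSE; cdet[is.na(cdet)] <- FALSE

  if (!any(cdet)) {
    out <- rep(1L, n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }

  ring <- metrics$fcho_is_ring & fdet
  ring[is.na(ring)] <- FALSE
  first_ring <- if (any(ring)) which(ring)[1] else NA_integer_
  base_r <- if (!is.na(first_ring)) {
    stats::median(metrics$fcho_peak_radius[ring][seq_len(min(3, sum(ring)))],
                  na.rm = TRUE)
  } else NA_real_
  expanded <- if (is.na(base_r)) rep(FALSE, n) else {
    ring & !is.na(metrics$fcho_peak_radius) &
      metrics$fcho_peak_radius >= (base_r + expand_nm)
  }

  slope <- c(0, diff(fs))
  fmax <- max(fs, na.rm = TRUE)

  lab <- integer(n)
  for (i in seq_len(n)) {
    lab[i] <- if (!cdet[i]) {
      1L
    } else if (!fdet[i] && isTRUE(fs[i] < 0.1 * fmax)) {
      5L
    } else if (!is.na(fs[i]) && fs[i] < decay_frac * fmax && slope[i] <= 0) {
      4L
    } else if (expanded[i]) {
      3L
    } else {
      2L
    }
  }
  out <- as.integer(cummax(lab))
  attr(out, "degenerate") <- FALSE
  out
}

#' Per-frame two-channel phase metrics along a track
#'
#' Reads both channels at the given positions frame by frame, computing the
#' background-subtracted amplitudes, local background sds, and pioneer-ring
#' morphometry needed by [classify_phase()].
#'
#' @param movie1 Pioneer-channel [ccp_movie()] (averaged to one frame per
#'   time point).
#' @param movie2 Clathrin-channel [ccp_movie()].
#' @param frames 0-based frame indices.
#' @param x,y Positions per frame (0-based, recycled if scalar).
#' @param pixel_size nm per pixel.
#' @param size Snapshot side for the ring morphometry.
#' @param smooth_frames Half-width of the moving average applied to the
#'   image before the ring morphometry (0 disables it); the amplitude
#'   readouts always come from the single frame.
#' @return Data frame consumable by [classify_phase()]. The `*_bg_sd`
#'   columns hold the standard deviation of the windowed-mean readout (the
#'   per-pixel background sd scaled by the effective number of independent
#'   samples in the window, which PSF correlation roughly quarters).
#' @export
track_phase_metrics <- function(movie1, movie2, frames, x, y, pixel_size,
                                size = 21, smooth_frames = 1L) {
  n <- length(frames)
  x <- rep_len(x, n); y <- rep_len(y, n)
  nt1 <- n_frames(movie1)
  out <- data.frame(frame = frames, fcho_A = NA_real_, fcho_bg_sd = NA_real_,
                    fcho_is_ring = FALSE, fcho_peak_radius = NA_real_,
                    clat_A = NA_real_, clat_bg_sd = NA_real_)
  for (i in seq_len(n)) {
    f1 <- movie_frame(movie1, frames[i] + 1)
    f2 <- movie_frame(movie2, frames[i] + 1)
    # pioneer readout must contain the expanded ring (~150 nm extent) and
    # its background annulus must sit beyond the ring tail
    r1 <- read_point_intensity(f1, x[i], y[i], inner = 5, bg_radii = c(7, 9))
    r2 <- read_point_intensity(f2, x[i], y[i], inner = 3, bg_radii = c(6, 8))
    out$fcho_A[i] <- r1$value
    out$fcho_bg_sd[i] <- r1$bg_sd / sqrt(r1$n_win / 4)
    out$clat_A[i] <- r2$value
    out$clat_bg_sd[i] <- r2$bg_sd / sqrt(r2$n_win / 4)
    fr1 <- f1
    if (smooth_frames > 0) {
      lo <- max(0, frames[i] - smooth_frames)
      hi <- min(nt1 - 1, frames[i] + smooth_frames)
      fr1 <- matrix(0, nrow(f1), ncol(f1))
      for (t in lo:hi) fr1 <- fr1 + movie_frame(movie1, t + 1)
      fr1 <- fr1 / (hi - lo + 1)
    }
    sm <- tryCatch(extract_snapshot(fr1, frames[i], x[i], y[i], size),
                   error = function(e) NULL)
    if (!is.null(sm)) {
      m <- tryCatch(classify_shape(sm$image, sm$center, pixel_size),
                    error = function(e) NULL)
      if (!is.null(m)) {
        out$fcho_is_ring[i] <- m$shape_class == "ring"
        out$fcho_peak_radius[i] <- m$peak_radius
      }
    }
  }
  out
}

# Peak location of a Gaussian-blurred delta ring of radius r0: the radial
# profile is I(r) = exp(-(r^2 + r0^2) / (2 s^2)) * I0(r * r0 / s^2), whose
# maximum satisfies r = r0 * I1(x) / I0(x) with x = r * r0 / s^2. Solved by
# fixed-point iteration; returns 0 when the blurred ring has no off-centre
# maximum (r0 below the resolution limit of the blur).
blurred_ring_peak <- function(r0, sigma) {
  if (r0 <= 0) return(0)
  r <- r0
  for (i in 1:200) {
    x <- r * r0 / sigma^2
    ratio <- if (x > 50) 1 - 1 / (2 * x) else
      besselI(x, 1, expon.scaled = TRUE) / besselI(x, 0, expon.scaled = TRUE)
    rn <- r0 * ratio
    if (abs(rn - r) < 1e-9) { r <- rn; break }
    r <- rn
  }
  r
}

#' Model-based annulus radius from a blurred radial profile
#'
#' A thin annulus blurred by the PSF peaks inside its true radius, severely
#' so near the resolution limit. This estimator locates the measured profile
#' peak (parabolic interpolation) and inverts the Gaussian-blurred thin-ring
#' model to recover the generating annulus radius. `sigma_nm` should be the
#' effective blur: the PSF sigma, optionally combined in quadrature with the
#' annulus width sigma when it is known.
#'
#' @param profile A `radial_profile`.
#' @param sigma_nm Effective Gaussian blur sigma, nm.
#' @return Estimated true annulus radius, nm.
#' @export
ring_radius_from_profile <- function(profile, sigma_nm) {
  pk <- refine_peak(profile$radius_nm, profile$intensity)
  r_meas <- pk$x
  if (r_meas <= 0) stop("profile peaks at the centre: annulus radius is not identifiable")
  f <- function(r0) blurred_ring_peak(r0, sigma_nm) - r_meas
  upper <- r_meas + 5 * sigma_nm
  lo <- r_meas
  if (f(lo) > 0) return(r_meas) # peak beyond model prediction; blur negligible
  stats::uniroot(f, c(lo, upper), tol = 1e-6)$root
}
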