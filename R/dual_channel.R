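#' Read a background-subtracted point intensity from a frame
#'
#' Mean of the 3 x 3 pixel window centred on the rounded position, minus the
#' median of an annular local-background region (radii 4-6 px).
#'
#' @param frame Matrix.
#' @param x,y 0-based position.
#' @param inner Half-size of the readout window (1 = 3x3).
#' @param bg_radii Annulus radii `(r_in, r_out)` for the local background.
#' @return List with `value` (background-subtracted mean), `bg` and `bg_sd`.
#' @export
read_point_intensity <- function(frame, x, y, inner = 1, bg_radii = c(4, 6)) {
  ny <- nrow(frame); nx <- ncol(frame)
  cx <- round(x); cy <- round(y)
  if (cx < 0 || cy < 0 || cx > nx - 1 || cy > ny - 1) {
    return(list(value = NA_real_, bg = NA_real_, bg_sd = NA_real_))
  }
  x1 <- max(0, cx - inner); x2 <- min(nx - 1, cx + inner)
  y1 <- max(0, cy - inner); y2 <- min(ny - 1, cy + inner)
  win <- frame[(y1:y2) + 1, (x1:x2) + 1]
  r_out <- bg_radii[2]
  bx <- max(0, cx - r_out):min(nx - 1, cx + r_out)
  by <- max(0, cy - r_out):min(ny - 1, cy + r_out)
  rr <- sqrt(outer((by - cy)^2, (bx - cx)^2, `+`))
  ann <- frame[by + 1, bx + 1][rr >= bg_radii[1] & rr <= bg_radii[2]]
  bg <- stats::median(ann)
  list(value = mean(win) - bg, bg = bg, bg_sd = stats::mad(ann),
       n_win = length(win))
}

# Per-frame positions of a track over its lifetime with gap frames
# interpolated linearly between flanking detections.
track_positions <- function(track) {
  d <- track$detections
  x <- d$x; y <- d$y
  ok <- !is.na(x)
  if (any(!ok)) {
    x <- stats::approx(d$frame[ok], x[ok], xout = d$frame, rule = 2)$y
    y <- stats::approx(d$frame[ok], y[ok], xout = d$frame, rule = 2)$y
  }
  data.frame(frame = d$frame, x = x, y = y)
}

#' Extract master/slave paired intensity traces
#'
#' For each master-channel track, reads the slave-channel intensity at the
#' master positions over the window `[birth - n_buffer, death + n_buffer]`.
#' Buffer frames reuse the track's first/last position; frames outside the
#' movie are marked missing (`NA`), not zero-filled. Master amplitudes
#' populate the lifetime part of the master trace; when `master_movie` is
#' given, buffer frames of the master trace are read photometrically the
#' same way as the slave. Hotspot-member tracks are dropped when
#' `exclude_hotspots`: hotspot events cannot show de novo pioneer
#' recruitment.
#'
#' @param tracks Classified `ccp_tracks` (master channel).
#' @param slave_movie Registered, photometry-corrected slave [ccp_movie()].
#' @param n_buffer Buffer frames before appearance / after disappearance.
#' @param exclude_hotspots Drop hotspot-member tracks.
#' @param master_movie Optional master [ccp_movie()] for buffer-frame reads.
#' @return List of `paired_trace` objects: `track_id`, `frames` (0-based,
#'   possibly outside the movie), `master`, `slave`, `slave_bg_sd`,
#'   `positions`, `n_buffer`, `appearance_index` (index of the birth frame
#'   within the trace). An attribute `n_skipped` counts tracks fully outside
#'   the slave bounds.
#' @export
extract_paired_traces <- function(tracks, slave_movie, n_buffer = 25,
                                  exclude_hotspots = TRUE,
                                  master_movie = NULL) {
  nt <- n_frames(slave_movie)
  out <- list()
  n_skipped <- 0L
  for (tr in tracks) {
    if (exclude_hotspots && isTRUE(tr$hotspot_member)) next
    pos <- track_positions(tr)
    frames <- (tr$birth_frame - n_buffer):(tr$death_frame + n_buffer)
    n <- length(frames)
    px <- c(rep(pos$x[1], n_buffer), pos$x, rep(pos$x[nrow(pos)], n_buffer))
    py <- c(rep(pos$y[1], n_buffer), pos$y, rep(pos$y[nrow(pos)], n_buffer))
    inside <- frames >= 0 & frames <= nt - 1
    if (!any(inside)) { n_skipped <- n_skipped + 1L; next }
    slave <- rep(NA_real_, n); bg_sd <- rep(NA_real_, n)
    for (k in which(inside)) {
      r <- read_point_intensity(movie_frame(slave_movie, frames[k] + 1),
                                px[k], py[k])
      slave[k] <- r$value; bg_sd[k] <- r$bg_sd
    }
    if (all(is.na(slave))) { n_skipped <- n_skipped + 1L; next }
    master <- rep(NA_real_, n)
    life <- (n_buffer + 1):(n - n_buffer)
    master[life] <- tr$detections$A
    if (!is.null(master_movie)) {
      buf <- setdiff(which(inside), life)
      for (k in buf) {
        master[k] <- read_point_intensity(
          movie_frame(master_movie, frames[k] + 1), px[k], py[k])$value
      }
    }
    out[[length(out) + 1]] <- structure(
      list(track_id = tr$id, frames = frames, master = master, slave = slave,
           slave_bg_sd = bg_sd,
           positions = data.frame(frame = frames, x = px, y = py),
           n_buffer = n_buffer, appearance_index = n_buffer + 1L,
           lifetime_s = tr$lifetime_s %||% NA_real_),
      class = "paired_trace"
    )
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Average paired traces into lifetime cohorts
#'
#' Bins traces by master-track lifetime, aligns them at the appearance frame
#' and averages per frame position. Optionally normalises each event to its
#' own peak before averaging.
#'
#' @param traces List of `paired_trace`s from [extract_paired_traces()].
#' @param lifetime_bins Numeric vector of bin edges, seconds
#'   (`[min, max)` per bin).
#' @param normalize Per-event peak normalisation of each channel.
#' @param min_events Minimum events per bin; emptier bins are dropped with a
#'   warning.
#' @return List of `cohort_average` objects: `bin` (c(min, max)), `n_events`,
#'   `time_s` (relative to appearance), `mean_master`, `sd_master`,
#'   `mean_slave`, `sd_slave`, `n_per_frame`.
#' @export
cohort_average <- function(traces, lifetime_bins, normalize = FALSE,
                           min_events = 5) {
  if (!length(traces)) return(list())
  lt <- vapply(traces, function(t) t$lifetime_s, numeric(1))
  dt_guess <- NULL
  out <- list()
  for (b in seq_len(length(lifetime_bins) - 1)) {
    lo <- lifetime_bins[b]; hi <- lifetime_bins[b + 1]
    sel <- which(lt >= lo & lt < hi & !is.na(lt))
    if (length(sel) < min_events) {
      warning(sprintf("cohort [%g, %g) has %d event(s) (< %d); omitted",
                      lo, hi, length(sel), min_events))
      next
    }
    nb <- traces[[sel[1]]]$n_buffer
    len <- max(vapply(traces[sel], function(t) length(t$slave), integer(1)))
    acc <- function(field) {
      m <- matrix(NA_real_, length(sel), len)
      for (i in seq_along(sel)) {
        v <- traces[[sel[i]]][[field]]
        if (normalize) {
          pk <- suppressWarnings(max(v, na.rm = TRUE))
          if (is.finite(pk) && pk > 0) v <- v / pk
        }
        m[i, seq_along(v)] <- v
      }
      m
    }
    ms <- acc("master"); sl <- acc("slave")
    nper <- colSums(!is.na(sl))
    out[[length(out) + 1]] <- structure(
      list(bin = c(lo, hi), n_events = length(sel),
           appearance_index = nb + 1L,
           rel_frames = seq_len(len) - (nb + 1L),
           mean_master = colMeans(ms, na.rm = TRUE),
           sd_master = apply(ms, 2, stats::sd, na.rm = TRUE),
           mean_slave = colMeans(sl, na.rm = TRUE),
           sd_slave = apply(sl, 2, stats::sd, na.rm = TRUE),
           n_per_frame = nper),
      class = "cohort_average"
    )
  }
  out
}

#' Inflection time of a rising intensity trace
#'
#' Fits a least-squares cubic polynomial
#' `y = c3 t^3 + c2 t^2 + c1 t + c0` over the given window and returns the
#' inflection point `t* = -c2 / (3 c3)` in seconds relative to the
#' appearance time.
#'
#' @param y Intensity trace (one value per frame).
#' @param time_s Frame times in seconds, relative to appearance (same length
#'   as `y`).
#' @param window Indices into `y` delimiting the fit window (>= 5 frames).
#' @param c3_tol Relative tolerance below which the cubic term is considered
#'   absent ("no curvature change").
#' @return Inflection time, seconds.
#' @export
inflection_time <- function(y, time_s, window = seq_along(y), c3_tol = 1e-10) {
  window <- window[!is.na(y[window])]
  if (length(window) < 5) stop("fit window must cover at least 5 frames")
  t <- time_s[window]; yy <- y[window]
  # centre and scale time for numerical stability, then map back
  t0 <- mean(t); sc <- stats::sd(t)
  u <- (t - t0) / sc
  cf <- stats::coef(stats::lm(yy ~ u + I(u^2) + I(u^3)))
  c3 <- cf[[4]]; c2 <- cf[[3]]
  if (abs(c3) < c3_tol * (abs(c2) + abs(c3) + 1e-300)) {
    stop("no inflection in window (cubic term vanishes)")
  }
  u_star <- -c2 / (3 * c3)
  t_star <- u_star * sc + t0
  if (t_star < min(t) || t_star > max(t)) {
    stop(sprintf("inflection %.3g s falls outside the fit window [%.3g, %.3g]",
                 t_star, min(t), max(t)))
  }
  t_star
}

#' Inflection time of one channel of a cohort average
#'
#' Applies the package's default window rule and calls [inflection_time()].
#' The window brackets the channel's own rise: it opens 2 frames before the
#' last frame on which the smoothed trace is still within 10% of baseline,
#' and closes where the trace first reaches 95% of its maximum. For the
#' master channel the rise starts at the appearance frame; the slave channel
#' rises before the master track is born -- that is what the buffer frames
#' are for -- so its rise is searched over the whole trace including the
#' buffer.
#'
#' @param cohort A `cohort_average`.
#' @param channel `"master"` or `"slave"`.
#' @param frame_interval Seconds per frame.
#' @return Inflection time in seconds relative to appearance.
#' @export
cohort_inflection <- function(cohort, channel = c("master", "slave"),
                              frame_interval) {
  channel <- match.arg(channel)
  y <- cohort[[paste0("mean_", channel)]]
  tt <- cohort$rel_frames * frame_interval
  ys <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  ok <- which(!is.na(ys))
  if (length(ok) < 8) stop("cohort trace too short")
  imax <- ok[which.max(ys[ok])]
  base <- stats::quantile(ys[ok], 0.05, names = FALSE)
  rng <- ys[imax] - base
  if (rng <= 0) stop("cohort trace has no rise")
  pre <- ok[ok < imax & ys[ok] <= base + 0.1 * rng]
  onset <- if (length(pre)) max(pre) else ok[1]
  hi <- ok[ok >= onset & ok <= imax & ys[ok] >= base + 0.95 * rng]
  end <- if (length(hi)) min(hi) else imax
  window <- max(ok[1], onset - 2):end
  inflection_time(y, tt, window)
}
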