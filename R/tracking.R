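#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour frame-to-frame assignment: at each frame
#' transition the closest (track end, detection) pair under `max_disp` is
#' linked first, then the next closest among the remainder, and so on (this
#' ordering makes every accepted pair mutually nearest among unassigned
#' candidates). Ties break deterministically by smaller distance, then lower
#' detection index. A track end left unmatched stays open for up to
#' `max_gap` frames (gap frames carry `NA` positions) before the track is
#' closed at its last detection.
#'
#' @param detections Data frame from [detect_movie()] (columns `frame`, `x`,
#'   `y`, `A`, `b`, `significance`).
#' @param max_disp Maximum frame-to-frame displacement, pixels.
#' @param max_gap Maximum number of consecutive missed frames bridged.
#' @return A list of tracks of class `ccp_tracks`; each track is a list with
#'   `id`, `birth_frame`, `death_frame`, and `detections` (one row per frame
#'   from birth to death; gap rows have `NA` coordinates).
#' @export
link_tracks <- function(detections, max_disp = 2, max_gap = 2) {
  det <- detections[order(detections$frame), ]
  if (!nrow(det)) return(structure(list(), class = "ccp_tracks"))
  frames <- sort(unique(det$frame))
  all_frames <- seq(min(frames), max(frames))

  active <- list()   # open tracks: list(rows = data.frame, last_frame, gap)
  done <- list()

  for (f in all_frames) {
    dd <- det[det$frame == f, , drop = FALSE]
    rownames(dd) <- NULL
    n_act <- length(active)
    n_det <- nrow(dd)
    assigned_det <- rep(FALSE, n_det)
    assigned_act <- rep(FALSE, n_act)

    if (n_act && n_det) {
      ax <- vapply(active, function(tr) tr$last_x, numeric(1))
      ay <- vapply(active, function(tr) tr$last_y, numeric(1))
      dmat <- sqrt(outer(ax, dd$x, `-`)^2 + outer(ay, dd$y, `-`)^2)
      repeat {
        dmat_m <- dmat
        dmat_m[assigned_act, ] <- Inf
        dmat_m[, assigned_det] <- Inf
        mn <- min(dmat_m)
        if (!is.finite(mn) || mn > max_disp) break
        hit <- which(dmat_m == mn, arr.ind = TRUE)
        # deterministic tie-break: lower detection index, then lower track
        hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE]
        i <- hit[1, 1]; j <- hit[1, 2]
        # fill any gap frames with NA rows
        tr <- active[[i]]
        if (f - tr$last_frame > 1) {
          for (gf in (tr$last_frame + 1):(f - 1)) {
            tr$rows[[length(tr$rows) + 1]] <- gap_row(gf)
          }
        }
        tr$rows[[length(tr$rows) + 1]] <- dd[j, c("frame", "x", "y", "A", "b",
                                                  "significance")]
        tr$last_frame <- f
        tr$last_x <- dd$x[j]; tr$last_y <- dd$y[j]
        active[[i]] <- tr
        assigned_act[i] <- TRUE
        assigned_det[j] <- TRUE
      }
    }

    # close tracks whose gap exceeded max_gap
    still <- logical(n_act)
    for (i in seq_len(n_act)) {
      if (assigned_act[i]) { still[i] <- TRUE; next }
      if (f - active[[i]]$last_frame >= max_gap + 1) {
        done[[length(done) + 1]] <- active[[i]]
      } else {
        still[i] <- TRUE
      }
    }
    active <- active[still]

    # start new tracks from unassigned detections
    for (j in which(!assigned_det)) {
      active[[length(active) + 1]] <- list(
        rows = list(dd[j, c("frame", "x", "y", "A", "b", "significance")]),
        last_frame = f, last_x = dd$x[j], last_y = dd$y[j]
      )
    }
  }
  done <- c(done, active)

  tracks <- lapply(seq_along(done), function(i) {
    rows <- do.call(rbind, done[[i]]$rows)
    rownames(rows) <- NULL
    list(id = i, birth_frame = rows$frame[1],
         death_frame = rows$frame[nrow(rows)], detections = rows)
  })
  # stable order: by birth frame, then x of first detection
  ord <- order(vapply(tracks, `[[`, numeric(1), "birth_frame"),
               vapply(tracks, function(t) t$detections$x[1], numeric(1)))
  tracks <- tracks[ord]
  for (i in seq_along(tracks)) tracks[[i]]$id <- i
  structure(tracks, class = "ccp_tracks")
}

gap_row <- function(f) {
  data.frame(frame = f, x = NA_real_, y = NA_real_, A = NA_real_,
             b = NA_real_, significance = NA_real_)
}

#' @export
print.ccp_tracks <- function(x, ...) {
  cat(sprintf("<ccp_tracks> %d track(s)\n", length(x)))
  invisible(x)
}

#' Classify tracks as valid, censored, subthreshold, hotspot or border
#'
#' Flags each track: `censored` when it is alive at the movie start or end;
#' `border_touching` when any detected position is within `3 * sigma` of the
#' field edge; `hotspot_member` when the track starts within `r_h` pixels and
#' `delta_t` frames of another track's end (both members are flagged);
#' `subthreshold` when its lifetime is below `l_min_s` seconds or its peak
#' amplitude is below `f_a` times the median peak amplitude of non-censored
#' tracks; `valid` otherwise.
#'
#' @param tracks A `ccp_tracks` from [link_tracks()].
#' @param movie The [ccp_movie()] the tracks came from (for bounds, frame
#'   count, frame interval and PSF-scaled border margin).
#' @param optics An [optics_params()].
#' @param l_min_s Minimum lifetime of a bona fide CCP, seconds.
#' @param f_a Amplitude fraction defining "dim" relative to the median peak.
#' @param r_h Hotspot radius, pixels.
#' @param delta_t Hotspot window, frames.
#' @return The tracks with added fields `lifetime_s`, `peak_A`, and logical
#'   flags `censored`, `border_touching`, `hotspot_member`, `subthreshold`,
#'   `valid`.
#' @export
classify_tracks <- function(tracks, movie, optics, l_min_s = 20, f_a = 0.4,
                            r_h = 2, delta_t = 5) {
  if (!length(tracks)) return(tracks)
  nt <- if (movie$n_raw > 1) n_frames(movie) / movie$n_raw else n_frames(movie)
  dt <- movie$frame_interval
  sig <- psf_sigma_px(optics)
  ny <- dim(movie$frames)[1]; nx <- dim(movie$frames)[2]
  margin <- 3 * sig

  births <- vapply(tracks, `[[`, numeric(1), "birth_frame")
  deaths <- vapply(tracks, `[[`, numeric(1), "death_frame")
  ends_x <- vapply(tracks, function(t) {
    d <- t$detections; tail_ok <- which(!is.na(d$x)); d$x[max(tail_ok)]
  }, numeric(1))
  ends_y <- vapply(tracks, function(t) {
    d <- t$detections; tail_ok <- which(!is.na(d$y)); d$y[max(tail_ok)]
  }, numeric(1))
  starts_x <- vapply(tracks, function(t) t$detections$x[1], numeric(1))
  starts_y <- vapply(tracks, function(t) t$detections$y[1], numeric(1))

  n <- length(tracks)
  censored <- births <= 0 | deaths >= nt - 1
  border <- vapply(tracks, function(t) {
    d <- t$detections
    any(d$x < margin | d$x > nx - 1 - margin |
          d$y < margin | d$y > ny - 1 - margin, na.rm = TRUE)
  }, logical(1))

  hotspot <- rep(FALSE, n)
  for (j in seq_len(n)) {
    dtf <- births[j] - deaths
    cand <- which(dtf > 0 & dtf <= delta_t)
    cand <- cand[cand != j]
    if (!length(cand)) next
    dd <- sqrt((starts_x[j] - ends_x[cand])^2 + (starts_y[j] - ends_y[cand])^2)
    hit <- cand[dd <= r_h]
    if (length(hit)) {
      hotspot[j] <- TRUE
      hotspot[hit] <- TRUE
    }
  }

  peak_A <- vapply(tracks, function(t) {
    suppressWarnings(max(t$detections$A, na.rm = TRUE))
  }, numeric(1))
  lifetime <- (deaths - births + 1) * dt
  med_peak <- stats::median(peak_A[!censored & is.finite(peak_A)])
  subthr <- lifetime < l_min_s |
    (is.finite(med_peak) & peak_A < f_a * med_peak)

  for (i in seq_len(n)) {
    tracks[[i]]$lifetime_s <- lifetime[i]
    tracks[[i]]$peak_A <- peak_A[i]
    tracks[[i]]$censored <- censored[i]
    tracks[[i]]$border_touching <- border[i]
    tracks[[i]]$hotspot_member <- hotspot[i]
    tracks[[i]]$subthreshold <- !censored[i] && subthr[i]
    tracks[[i]]$valid <- !censored[i] && !border[i] && !subthr[i]
  }
  tracks
}

#' Per-track summary table
#' @param tracks Classified `ccp_tracks`.
#' @return Data frame with one row per track.
#' @export
track_summary <- function(tracks) {
  if (!length(tracks)) {
    return(data.frame(track_id = integer(0), birth_frame = integer(0),
                      death_frame = integer(0), lifetime_s = numeric(0),
                      peak_A = numeric(0), censored = logical(0),
                      border_touching = logical(0), hotspot_member = logical(0),
                      subthreshold = logical(0), valid = logical(0)))
  }
  do.call(rbind, lapply(tracks, function(t) {
    data.frame(track_id = t$id, birth_frame = t$birth_frame,
               death_frame = t$death_frame,
               lifetime_s = t$lifetime_s %||% NA_real_,
               peak_A = t$peak_A %||% NA_real_,
               censored = t$censored %||% NA,
               border_touching = t$border_touching %||% NA,
               hotspot_member = t$hotspot_member %||% NA,
               subthreshold = t$subthreshold %||% NA,
               valid = t$valid %||% NA)
  }))
}

#' Initiation densities of valid CCPs and subthreshold structures
#'
#' Counts non-censored track births in each class and divides by the imaged
#' area and the movie duration.
#'
#' @param tracks Classified `ccp_tracks`.
#' @param cell_area Imaged cell area, square micrometres.
#' @param duration Movie duration, minutes.
#' @return Named numeric vector: `valid` and `subthreshold` initiation
#'   densities, per um^2 per min.
#' @export
initiation_density <- function(tracks, cell_area, duration) {
  if (cell_area <= 0 || duration <= 0) {
    stop("cell_area and duration must be positive")
  }
  if (!length(tracks)) return(c(valid = 0, subthreshold = 0))
  s <- track_summary(tracks)
  nc <- s[!s$censored, ]
  c(valid = sum(nc$valid) / (cell_area * duration),
    subthreshold = sum(nc$subthreshold) / (cell_area * duration))
}
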