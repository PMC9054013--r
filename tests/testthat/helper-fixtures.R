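# Shared fixtures: single-object renders and track/object matching.

fast_sim_optics <- function(...) {
  args <- utils::modifyList(list(frame_interval = 1, n_raw_per_timepoint = 1L),
                            list(...))
  do.call(sim_optics, args)
}

# Render one immobile object in a small field and return both channels'
# frames (averaged over raw sub-frames when the optics ask for them).
render_single <- function(fcho = list(type = "patch", r1 = 50, r2 = NA),
                          cap = c(rb = 61, h = 0),
                          amp = c(2000, 0), field = 31, center = NULL,
                          noise = c(0, 0), background = 0, seed = 1,
                          optics = fast_sim_optics(), phase = 2L) {
  if (is.null(center)) center <- rep((field - 1) / 2, 2)
  obj <- ccp_object(0, 0, center, phase,
                    data.frame(type = fcho$type, r1 = fcho$r1, r2 = fcho$r2),
                    data.frame(rb = cap[[1]], h = cap[[2]]),
                    matrix(amp, 1, 2))
  sc <- ccp_scenario(list(obj), c(field, field), 1, noise = noise,
                     background = background, seed = seed)
  r <- render_movie(sc, optics)
  m1 <- if (optics$n_raw_per_timepoint > 1) average_raw_frames(r$channel1) else r$channel1
  m2 <- if (optics$n_raw_per_timepoint > 1) average_raw_frames(r$channel2) else r$channel2
  list(f1 = movie_frame(m1, 1), f2 = movie_frame(m2, 1), center = center,
       truth = r$truth)
}

# Assign each track to its nearest scenario object (by median position) and
# compute the per-pair Jaccard overlap of detected frames against the
# frames in which the object is visible in the clathrin channel.
match_tracks <- function(tracks, scenario, truth) {
  vis <- truth[truth$channel == 2 & truth$amplitude > 0, ]
  obj_frames <- split(vis$frame, vis$object_id)
  res <- lapply(tracks, function(t) {
    d <- t$detections
    ok <- !is.na(d$x)
    mx <- stats::median(d$x[ok]); my <- stats::median(d$y[ok])
    dd <- vapply(scenario$objects,
                 function(o) sqrt(sum((o$center - c(mx, my))^2)), numeric(1))
    oi <- which.min(dd)
    tf <- d$frame[ok]
    of <- obj_frames[[as.character(oi)]]
    jac <- if (is.null(of)) 0 else
      length(intersect(tf, of)) / length(union(tf, of))
    data.frame(track_id = t$id, object = oi, dist = min(dd), jaccard = jac)
  })
  do.call(rbind, res)
}

# True per-frame phases of the object nearest to a track.
true_phases_for_track <- function(track, scenario) {
  pos <- ccptools:::track_positions(track)
  mx <- stats::median(pos$x); my <- stats::median(pos$y)
  oi <- which.min(vapply(scenario$objects,
                         function(o) sum((o$center - c(mx, my))^2), numeric(1)))
  o <- scenario$objects[[oi]]
  truep <- rep(NA_integer_, nrow(pos))
  idx <- pos$frame >= o$birth_frame & pos$frame <= o$death_frame
  truep[idx] <- o$phase[pos$frame[idx] - o$birth_frame + 1]
  list(pos = pos, true = truep, object = o)
}


# Sub-pixel radial profile: bilinear 3x resampling before binning, the same
# scheme classify_shape uses internally.
fine_profile <- function(image, center, pixel_size, os = 3) {
  gx <- seq(0, ncol(image) - 1, by = 1 / os)
  gy <- seq(0, nrow(image) - 1, by = 1 / os)
  v <- ccptools:::bilinear_sample(image, rep(gx, each = length(gy)),
                                  rep(gy, times = length(gx)))
  fine <- matrix(v, length(gy), length(gx))
  radial_profile(fine, center * os, pixel_size / os,
                 bin_width = pixel_size / 2)
}
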