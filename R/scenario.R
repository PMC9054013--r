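#' Default lifecycle parameters for the scenario generator
#'
#' Central place for the geometry, amplitude and timing defaults of
#' [build_scenario()]. Values describe the five lifecycle phases: (1) a
#' pioneer (FCHO2-like) patch assembles while clathrin is absent, (2) clathrin
#' nucleates as a flat disk while the pioneer patch reorganises into a ring,
#' (3) the ring expands as the clathrin coat domes, (4) the pioneer signal
#' decays while the coat completes, (5) the pioneer has dissipated and only
#' clathrin remains until scission.
#'
#' @return Named list of defaults (all lengths in nm, times in s).
#' @export
lifecycle_defaults <- function() {
  list(
    phase_fractions = c(0.18, 0.17, 0.25, 0.20, 0.20),
    mean_lifetime_s = 60,      # canonical CCP lifetime ~1-2 min
    lifetime_cv = 0.25,
    patch_radius_nm = 50,      # initial pioneer patch
    ring_radius_phase2_nm = 80,  # pioneer ring at nucleation
    ring_radius_phase3_nm = 120, # expanded ring (peripheral to the coat)
    ring_width_nm = 60,
    ccp_diameter_mean_nm = 122,  # coat footprint diameter
    ccp_diameter_sd_nm = 2,
    amplitude_mean = 2000,     # photons per object per frame at peak
    amplitude_cv = 0.15,
    sub_lifetime_range_s = c(4, 16),   # subthreshold: < 20 s
    sub_amplitude_frac = c(0.10, 0.30) # and dim (< 40% of regular peak)
  )
}

# Piecewise-linear amplitude profile over the phases, as fractions of the
# object's peak amplitude. Channel 1 (pioneer) assembles in phase 1, holds,
# decays through phase 4 and is gone in phase 5; channel 2 (clathrin) is
# absent in phase 1, grows through phases 2-3 and holds to the end.
phase_amplitude <- function(phase, channel) {
  n <- length(phase)
  out <- numeric(n)
  smoothstep <- function(u) 3 * u^2 - 2 * u^3   # sigmoid-like assembly rise
  for (p in 1:5) {
    idx <- which(phase == p)
    if (!length(idx)) next
    u <- if (length(idx) > 1) seq(0, 1, length.out = length(idx)) else 0.5
    out[idx] <- if (channel == 1) {
      switch(p, 0.3 + 0.7 * smoothstep(u), rep(1, length(idx)),
             rep(1, length(idx)),
             0.45 - 0.30 * u, rep(0, length(idx)))
    } else {
      switch(p, rep(0, length(idx)), 0.2 + 0.6 * smoothstep(u),
             0.8 + 0.2 * u,
             rep(1, length(idx)), rep(1, length(idx)))
    }
  }
  out
}

# Build the per-frame phase vector from a lifetime in frames.
phase_schedule <- function(nf, fractions) {
  if (nf < 5) return(pmin(seq_len(nf), 5L))
  counts <- pmax(1L, round(fractions / sum(fractions) * nf))
  while (sum(counts) > nf) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < nf) counts[which.max(fractions)] <- counts[which.max(fractions)] + 1L
  rep(1:5, times = counts)
}

# Assemble one full-lifecycle object at a given position. Hotspot
# successors start at phase 2: the pioneer machinery persists at the site,
# so clathrin nucleation follows the predecessor without a lag.
make_lifecycle_object <- function(birth, nf, center, peak_amp, diam_nm, pars,
                                  start_phase = 1L) {
  phase <- phase_schedule(nf, pars$phase_fractions)
  if (start_phase > 1) {
    phase <- pmax(phase, start_phase)
  }
  rb <- diam_nm / 2
  fcho <- data.frame(type = "patch", r1 = pars$patch_radius_nm, r2 = NA_real_,
                     stringsAsFactors = FALSE)[rep(1, nf), ]
  clat <- data.frame(rb = rb, h = 0)[rep(1, nf), ]
  for (p in 2:5) {
    idx <- which(phase == p)
    if (!length(idx)) next
    u <- if (length(idx) > 1) seq(0, 1, length.out = length(idx)) else 1
    if (p == 2) {
      fcho$type[idx] <- "ring"
      fcho$r1[idx] <- pars$ring_radius_phase2_nm
      fcho$r2[idx] <- pars$ring_width_nm
      clat$rb[idx] <- rb * (0.5 + 0.5 * u)
    } else {
      fcho$type[idx] <- "ring"
      fcho$r2[idx] <- pars$ring_width_nm
      fcho$r1[idx] <- if (p == 3) {
        # the ring expands rapidly at the start of the growth phase, then
        # holds its expanded radius
        pars$ring_radius_phase2_nm +
          (pars$ring_radius_phase3_nm - pars$ring_radius_phase2_nm) *
          pmin(u / 0.2, 1)
      } else pars$ring_radius_phase3_nm
      clat$rb[idx] <- rb
      clat$h[idx] <- if (p == 3) 0.9 * rb * u else 0.9 * rb
    }
  }
  amp <- cbind(phase_amplitude(phase, 1), phase_amplitude(phase, 2)) * peak_amp
  ccp_object(birth, birth + nf - 1, center, phase, fcho, clat, amp)
}

# Short, dim abortive object: a pioneer patch that briefly nucleates a small
# dim clathrin disk (phases 1-2 only) and disappears.
make_subthreshold_object <- function(birth, nf, center, peak_amp, pars) {
  n1 <- max(1L, round(0.4 * nf))
  phase <- c(rep(1L, n1), rep(2L, nf - n1))
  fcho <- data.frame(type = "patch", r1 = pars$patch_radius_nm * 0.8,
                     r2 = NA_real_, stringsAsFactors = FALSE)[rep(1, nf), ]
  clat <- data.frame(rb = pars$ccp_diameter_mean_nm / 4, h = 0)[rep(1, nf), ]
  a1 <- peak_amp * c(seq(0.5, 1, length.out = n1),
                     seq(1, 0.3, length.out = nf - n1))
  a2 <- peak_amp * c(rep(0, n1), rep(0.8, nf - n1))
  ccp_object(birth, birth + nf - 1, center, phase, fcho, clat,
             cbind(a1, a2), is_subthreshold = TRUE)
}

#' Generate a randomised simulation scenario
#'
#' Draws `n_objects` CCP lifecycles with staggered births, random
#' well-separated positions, lognormal-ish amplitude and lifetime
#' variability, a configurable fraction of short dim subthreshold
#' transients, and optional hotspot successors (an extra object born within
#' 2 px and 5 frames of a predecessor's death). Random streams are split per
#' object from `seed`, so adding objects does not perturb existing ones.
#'
#' @param n_objects Number of primary objects (regular + subthreshold).
#' @param field_size `(nx, ny)` in pixels.
#' @param duration Time points in the movie.
#' @param optics An [optics_params()]; supplies pixel size and frame interval.
#' @param subthreshold_fraction Fraction of primary objects drawn as
#'   subthreshold transients.
#' @param hotspot_fraction Fraction of regular objects that receive a hotspot
#'   successor (appended as extra objects).
#' @param chromatic_offset `(dx, dy)` sub-pixel shift of channel 2, pixels.
#' @param bleach_params_per_channel List of two `c(a, b, c, d)` vectors.
#' @param noise `(poisson_scaling, read_sd)`.
#' @param background Background level, photons per pixel.
#' @param min_separation_px Minimum centre-to-centre distance between objects.
#' @param lifecycle Parameter list, see [lifecycle_defaults()].
#' @param seed Integer seed.
#' @return A [ccp_scenario()].
#' @export
build_scenario <- function(n_objects = 30, field_size = c(192, 192),
                           duration = 100, optics = sim_optics(),
                           subthreshold_fraction = 0.1,
                           hotspot_fraction = 0.1,
                           chromatic_offset = c(0.4, -0.3),
                           bleach_params_per_channel =
                             list(c(0.7, -0.004, 0.3, -0.0004),
                                  c(0.7, -0.003, 0.3, -0.0003)),
                           noise = c(1, 2), background = 10,
                           min_separation_px = 14,
                           lifecycle = lifecycle_defaults(),
                           seed = 1L) {
  pars <- utils::modifyList(lifecycle_defaults(), lifecycle)
  ps <- optics$pixel_size
  dt <- optics$frame_interval
  margin <- ceiling((pars$ring_radius_phase3_nm + 2 * pars$ring_width_nm) / ps) + 4

  n_sub <- round(subthreshold_fraction * n_objects)
  is_sub <- rep(c(TRUE, FALSE), c(n_sub, n_objects - n_sub))

  # rejection-sample well-separated positions, one RNG stream per object
  centers <- matrix(NA_real_, n_objects, 2)
  for (i in seq_len(n_objects)) {
    centers[i, ] <- with_seed(derive_seed(seed, 10, i), {
      repeat {
        cand <- c(stats::runif(1, margin, field_size[1] - 1 - margin),
                  stats::runif(1, margin, field_size[2] - 1 - margin))
        prev <- centers[seq_len(i - 1), , drop = FALSE]
        if (!nrow(prev) ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_separation_px) {
          break
        }
      }
      cand
    })
  }

  objects <- vector("list", n_objects)
  for (i in seq_len(n_objects)) {
    objects[[i]] <- with_seed(derive_seed(seed, 20, i), {
      amp <- pars$amplitude_mean *
        exp(stats::rnorm(1, 0, pars$amplitude_cv) - pars$amplitude_cv^2 / 2)
      if (is_sub[i]) {
        life_s <- stats::runif(1, pars$sub_lifetime_range_s[1],
                               pars$sub_lifetime_range_s[2])
        nf <- max(3L, round(life_s / dt))
        nf <- min(nf, duration)
        birth <- sample.int(duration - nf + 1, 1) - 1L
        make_subthreshold_object(birth, nf, centers[i, ],
                                 amp * stats::runif(1,
                                                    pars$sub_amplitude_frac[1],
                                                    pars$sub_amplitude_frac[2]),
                                 pars)
      } else {
        life_s <- pars$mean_lifetime_s *
          exp(stats::rnorm(1, 0, pars$lifetime_cv) - pars$lifetime_cv^2 / 2)
        nf <- max(10L, round(life_s / dt))
        nf <- min(nf, duration)
        birth <- sample.int(duration - nf + 1, 1) - 1L
        diam <- stats::rnorm(1, pars$ccp_diameter_mean_nm,
                             pars$ccp_diameter_sd_nm)
        make_lifecycle_object(birth, nf, centers[i, ], amp, diam, pars)
      }
    })
  }

  # hotspot successors: born right after a regular predecessor's death,
  # within 2 px of its position
  regular <- which(!is_sub)
  eligible <- regular[vapply(objects[regular], function(o) {
    o$death_frame + 6 < duration - 10
  }, logical(1))]
  n_hot <- min(length(eligible), round(hotspot_fraction * length(regular)))
  hotspot_pairs <- list()
  if (n_hot > 0) {
    preds <- with_seed(derive_seed(seed, 30),
                       eligible[sample.int(length(eligible), n_hot)])
    for (k in seq_len(n_hot)) {
      pr <- objects[[preds[k]]]
      succ <- with_seed(derive_seed(seed, 40, k), {
        # 3-5 dark frames between the events: long enough that gap closing
        # does not merge them into one track, within the hotspot window
        gap <- sample.int(3, 1) + 2L
        birth <- pr$death_frame + gap
        nf <- min(max(10L, round(pars$mean_lifetime_s / dt / 2)),
                  duration - birth)
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0.5, 1.8)
        ctr <- pr$center + rad * c(cos(ang), sin(ang))
        amp <- pars$amplitude_mean *
          exp(stats::rnorm(1, 0, pars$amplitude_cv))
        diam <- stats::rnorm(1, pars$ccp_diameter_mean_nm,
                             pars$ccp_diameter_sd_nm)
        make_lifecycle_object(birth, nf, ctr, amp, diam, pars,
                              start_phase = 2L)
      })
      objects[[length(objects) + 1]] <- succ
      hotspot_pairs[[length(hotspot_pairs) + 1]] <-
        c(preds[k], length(objects))
    }
  }

  ccp_scenario(objects, field_size, duration,
               hotspot_pairs = hotspot_pairs,
               subthreshold_fraction = subthreshold_fraction,
               bleach_params_per_channel = bleach_params_per_channel,
               chromatic_offset = chromatic_offset,
               noise = noise, background = background, seed = seed)
}

#' Write a ground-truth table to CSV
#'
#' Writes the columns `object_id, frame, channel, x_px, y_px, amplitude,
#' phase, geom_type, r1_nm, r2_nm, is_subthreshold, is_hotspot`.
#'
#' @param truth Ground-truth data frame from [render_movie()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(truth, path) {
  cols <- c("object_id", "frame", "channel", "x_px", "y_px", "amplitude",
            "phase", "geom_type", "r1_nm", "r2_nm", "is_subthreshold",
            "is_hotspot")
  utils::write.csv(truth[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Expected phase-3 radial peak offset under given optics
#'
#' The generator specifies 3D geometry (an expanded pioneer ring and a domed
#' clathrin cap); what an experiment can recover is the offset between the
#' channels' radial intensity peaks as imaged, i.e. after projection,
#' evanescent weighting and PSF blur. This helper renders one isolated,
#' noise-free, bleach-free object with the generator's lifecycle parameters,
#' averages its growth-phase (phase 3) snapshots per channel exactly as the
#' analysis does, and returns the resulting peak radii and their offset.
#' It defines the scenario-level ground truth that a blind analysis of a
#' full noisy experiment is expected to reproduce.
#'
#' @param optics An [optics_params()].
#' @param lifecycle Generator parameter list, see [lifecycle_defaults()].
#' @param nf Lifetime (frames) of the reference object.
#' @param snapshot_size Odd ROI side, pixels.
#' @return List with `peak_pioneer_nm`, `peak_clathrin_nm`, `offset_nm`.
#' @export
expected_ring_offset <- function(optics, lifecycle = lifecycle_defaults(),
                                 nf = 30, snapshot_size = 21) {
  pars <- utils::modifyList(lifecycle_defaults(), lifecycle)
  ctr_px <- ceiling((pars$ring_radius_phase3_nm + 2 * pars$ring_width_nm) /
                      optics$pixel_size) + snapshot_size
  fs <- 2 * ctr_px + 1
  obj <- make_lifecycle_object(0, nf, c(ctr_px, ctr_px), 1000,
                               pars$ccp_diameter_mean_nm, pars)
  sc <- ccp_scenario(list(obj), c(fs, fs), nf, noise = c(0, 0),
                     background = 0, seed = 1L)
  opt1 <- optics
  opt1$n_raw_per_timepoint <- 1L
  r <- render_movie(sc, opt1)
  p3 <- which(obj$phase == 3)
  s1 <- list(); s2 <- list()
  for (k in p3) {
    s1[[length(s1) + 1]] <- extract_snapshot(r$channel1, k - 1, ctr_px,
                                             ctr_px, snapshot_size)
    s2[[length(s2) + 1]] <- extract_snapshot(r$channel2, k - 1, ctr_px,
                                             ctr_px, snapshot_size)
  }
  avg1 <- average_snapshots(s1, min_count = 1)
  avg2 <- average_snapshots(s2, min_count = 1)
  hw <- (snapshot_size - 1) / 2
  pr1 <- radial_profile(avg1, c(hw, hw), optics$pixel_size)
  pr2 <- radial_profile(avg2, c(hw, hw), optics$pixel_size)
  pk1 <- refine_peak(pr1$radius_nm, pr1$intensity)
  pk2 <- refine_peak(pr2$radius_nm, pr2$intensity)
  list(peak_pioneer_nm = pk1$x, peak_clathrin_nm = pk2$x,
       offset_nm = pk1$x - pk2$x)
}
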