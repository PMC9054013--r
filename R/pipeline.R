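#' Default run configuration
#'
#' A single nested list drives [run_pipeline()]: optics, simulation scenario
#' parameters, per-stage parameters, stage enable flags and the seed. Every
#' stage parameter appears exactly once; the whole structure round-trips
#' through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param seed Integer seed for the simulated experiment.
#' @param ... Overrides merged into the defaults (nested lists merge
#'   recursively).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    optics = list(psf_fwhm = 90, penetration_depth = 100, pixel_size = 32.5,
                  frame_interval = 1, n_raw_per_timepoint = 1),
    stages = list(simulate = TRUE, register = TRUE, photometry = TRUE,
                  track = TRUE, dual_channel = TRUE, morphometry = TRUE),
    simulate = list(n_objects = 30, field_size = c(192, 192), duration = 100,
                    subthreshold_fraction = 0.1, hotspot_fraction = 0.1,
                    chromatic_offset = c(0.4, -0.3),
                    noise = c(1, 2), background = 10),
    register = list(kind = "translation", n_beads = 12),
    track = list(detect_fwhm = 260, alpha = 0.05, log_threshold = 4.5,
                 max_disp = 2, max_gap = 2,
                 l_min_s = 20, f_a = 0.4, r_h = 2, delta_t = 5),
    dual_channel = list(n_buffer = 25, exclude_hotspots = TRUE,
                        lifetime_bins = c(20, 40, 60, 120), min_events = 3),
    morphometry = list(snapshot_size = 21, min_snapshots = 20)
  )
  over <- list(...)
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write / read a run configuration as YAML
#' @param config A `run_config`.
#' @param path YAML path.
#' @return `path` invisibly, or the configuration.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = cfg$seed),
                        cfg[setdiff(names(cfg), "seed")]))
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_run_config(config, f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate, register, photometry, detect/track, dual-channel and
#' morphometry stages in order into a run directory, writing per-stage CSV /
#' JSON outputs and a manifest (config hash, seed, per-stage row counts).
#' Re-running a completed directory with the same configuration is a no-op
#' unless `force = TRUE`. All stages are seeded from `config$seed`, so a
#' repeated run reproduces its outputs bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created if needed).
#' @param force Re-run even if a manifest for the same configuration exists.
#' @return The summary list, invisibly; on disk: `sim/`, `registration/`,
#'   `photometry/`, `tracks/`, `cohorts/`, `morpho/`, `summary.json` and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, force = FALSE) {
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  man_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(man_path)) {
    man <- jsonlite::read_json(man_path)
    if (identical(man$config_hash, hash) && isTRUE(man$complete)) {
      message("run directory is complete for this configuration; skipping ",
              "(use force = TRUE to re-run)")
      return(invisible(jsonlite::read_json(file.path(out_dir, "summary.json"),
                                           simplifyVector = TRUE)))
    }
  }
  counts <- list()
  summary <- list()
  stage <- function(name, enabled, fn) {
    if (!enabled) return(NULL)
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  optics <- do.call(optics_params, config$optics)
  seed <- config$seed

  ## --- simulate -----------------------------------------------------------
  sim <- stage("simulate", config$stages$simulate, function() {
    sdir <- file.path(out_dir, "sim")
    dir.create(sdir, showWarnings = FALSE)
    sc <- do.call(build_scenario, c(config$simulate,
                                    list(optics = optics, seed = seed)))
    r <- render_movie(sc, optics)
    write_movie_tiff(r$channel1, file.path(sdir, "channel1.tif"))
    write_movie_tiff(r$channel2, file.path(sdir, "channel2.tif"))
    write_ground_truth_csv(r$truth, file.path(sdir, "ground_truth.csv"))
    counts$sim_truth_rows <<- nrow(r$truth)
    c(r, list(scenario = sc))
  })
  if (is.null(sim)) stop("pipeline requires the simulate stage in this build")

  ## --- register -----------------------------------------------------------
  ch2 <- sim$channel2
  reg <- stage("register", config$stages$register, function() {
    rdir <- file.path(out_dir, "registration")
    dir.create(rdir, showWarnings = FALSE)
    beads <- render_bead_field(
      n_beads = config$register$n_beads,
      field_size = sim$scenario$field_size, optics = optics,
      offset = sim$scenario$chromatic_offset,
      seed = derive_seed(seed, 501)
    )
    tr <- estimate_transform(beads$ref, beads$target,
                             kind = config$register$kind, optics = optics)
    write_transform_json(tr, file.path(rdir, "transform.json"))
    counts$registration_beads <<- tr$n_beads
    tr
  })
  if (!is.null(reg)) ch2 <- apply_transform(ch2, reg)

  ## --- photometry ---------------------------------------------------------
  ch1 <- sim$channel1
  pho <- stage("photometry", config$stages$photometry, function() {
    pdir <- file.path(out_dir, "photometry")
    dir.create(pdir, showWarnings = FALSE)
    m1 <- if (ch1$n_raw > 1) average_raw_frames(ch1) else ch1
    m2 <- if (ch2$n_raw > 1) average_raw_frames(ch2) else ch2
    b1 <- fit_bleach(frame_means(m1))
    b2 <- fit_bleach(frame_means(m2))
    m1 <- correct_bleach(m1, b1)
    m2 <- correct_bleach(m2, b2)
    sc2 <- estimate_channel_scale(m1, m2)
    jsonlite::write_json(
      list(bleach_channel1 = b1[c("a", "b", "c", "d", "fit_rmse")],
           bleach_channel2 = b2[c("a", "b", "c", "d", "fit_rmse")],
           channel_scale = sc2$s),
      file.path(pdir, "photometry.json"), auto_unbox = TRUE, digits = NA)
    list(m1 = m1, m2 = m2, b1 = b1, b2 = b2, scale = sc2)
  })
  m1 <- if (is.null(pho)) average_raw_frames(ch1) else pho$m1
  m2 <- if (is.null(pho)) average_raw_frames(ch2) else pho$m2

  ## --- detect / track (clathrin = master channel) -------------------------
  trk <- stage("track", config$stages$track, function() {
    tdir <- file.path(out_dir, "tracks")
    dir.create(tdir, showWarnings = FALSE)
    p <- config$track
    # CCP-scale detection width: a coated pit image is wider than the SIM
    # PSF, and an annular spot breaks a PSF-sigma Gaussian fit, so detection
    # and tracking run at the diffraction-limited CCP image scale
    det_optics <- do.call(optics_params, utils::modifyList(
      config$optics, list(psf_fwhm = max(p$detect_fwhm, optics$psf_fwhm))))
    det <- detect_movie(m2, det_optics, alpha = p$alpha,
                        log_threshold = p$log_threshold)
    tracks <- link_tracks(det, max_disp = p$max_disp, max_gap = p$max_gap)
    tracks <- classify_tracks(tracks, m2, det_optics, l_min_s = p$l_min_s,
                              f_a = p$f_a, r_h = p$r_h, delta_t = p$delta_t)
    ts <- track_summary(tracks)
    utils::write.csv(det, file.path(tdir, "detections.csv"), row.names = FALSE)
    utils::write.csv(ts, file.path(tdir, "track_summary.csv"),
                     row.names = FALSE)
    counts$detections <<- nrow(det)
    counts$tracks <<- length(tracks)
    area_um2 <- prod(dim(m2$frames)[1:2]) * (m2$pixel_size / 1000)^2
    dur_min <- n_frames(m2) * m2$frame_interval / 60
    dens <- initiation_density(tracks, area_um2, dur_min)
    summary$initiation_density_valid_per_um2_min <<- unname(dens["valid"])
    summary$initiation_density_subthreshold_per_um2_min <<-
      unname(dens["subthreshold"])
    tracks
  })

  ## --- dual channel (slave = pioneer channel 1) ----------------------------
  stage("dual_channel", !is.null(trk) && config$stages$dual_channel, function() {
    cdir <- file.path(out_dir, "cohorts")
    dir.create(cdir, showWarnings = FALSE)
    p <- config$dual_channel
    traces <- extract_paired_traces(trk, m1, n_buffer = p$n_buffer,
                                    exclude_hotspots = p$exclude_hotspots,
                                    master_movie = m2)
    traces <- Filter(function(t) isTRUE(t$lifetime_s >= 0), traces)
    cohorts <- suppressWarnings(
      cohort_average(traces, p$lifetime_bins, min_events = p$min_events))
    rows <- list()
    for (co in cohorts) {
      im <- tryCatch(cohort_inflection(co, "master", m2$frame_interval),
                     error = function(e) NA_real_)
      is <- tryCatch(cohort_inflection(co, "slave", m1$frame_interval),
                     error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        bin_lo = co$bin[1], bin_hi = co$bin[2], n_events = co$n_events,
        inflection_master_s = im, inflection_slave_s = is)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                 n_events = integer(0), inflection_master_s = numeric(0),
                 inflection_slave_s = numeric(0))
    utils::write.csv(tab, file.path(cdir, "cohort_inflections.csv"),
                     row.names = FALSE)
    counts$cohorts <<- length(cohorts)
    ok <- stats::complete.cases(tab[, c("inflection_master_s",
                                        "inflection_slave_s")])
    summary$mean_inflection_lead_slave_s <<- if (any(ok)) {
      mean(tab$inflection_master_s[ok] - tab$inflection_slave_s[ok])
    } else NA_real_
    NULL
  })

  ## --- morphometry ---------------------------------------------------------
  stage("morphometry", !is.null(trk) && config$stages$morphometry, function() {
    mdir <- file.path(out_dir, "morpho")
    dir.create(mdir, showWarnings = FALSE)
    p <- config$morphometry
    res <- measure_experiment(m1, m2, trk, optics,
                              snapshot_size = p$snapshot_size,
                              min_snapshots = p$min_snapshots)
    utils::write.csv(res$per_track, file.path(mdir, "track_morphometry.csv"),
                     row.names = FALSE)
    counts$morphometry_tracks <<- nrow(res$per_track)
    summary$mean_ccp_diameter_nm <<- res$mean_diameter_nm
    summary$diameter_max_rel_deviation <<- res$size_stats$max_rel_deviation
    summary$ring_peak_offset_nm <<- res$ring_peak_offset_nm
    summary$vesicle_diameter_nm <<- if (is.finite(res$mean_diameter_nm)) {
      vesicle_diameter_from_footprint(res$mean_diameter_nm)
    } else NA_real_
    NULL
  })

  summary$seed <- seed
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(
    list(config_hash = hash, seed = seed,
         package_version = as.character(utils::packageVersion("ccptools")),
         stage_counts = counts, complete = TRUE),
    man_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Blind morphometric measurement of a tracked two-channel experiment
#'
#' For each valid (or long-lived) track: reads per-frame two-channel metrics
#' at the tracked positions, classifies phases, then measures (a) the coat
#' footprint diameter from the through-centre FWHM of the clathrin snapshot
#' averaged over the track's nucleation frames (early phase 2, while the
#' coat is still flat), and (b) the pioneer-ring versus clathrin radial peak
#' offset from snapshot averages over the expanded-ring frames (phase 3).
#'
#' @param m1 Pioneer-channel movie (one frame per time point).
#' @param m2 Clathrin-channel movie.
#' @param tracks Classified `ccp_tracks` from the clathrin channel.
#' @param optics [optics_params()].
#' @param snapshot_size Odd ROI side in pixels.
#' @param min_snapshots Minimum pooled snapshots for the averaged images.
#' @return List: `per_track` data frame (diameter, phases observed),
#'   `mean_diameter_nm`, `size_stats`, `ring_peak_offset_nm` (pioneer minus
#'   clathrin, from pooled phase-3 snapshots).
#' @export
measure_experiment <- function(m1, m2, tracks, optics, snapshot_size = 21,
                               min_snapshots = 20) {
  ps <- m1$pixel_size
  per_track <- list()
  snaps1 <- list(); snaps2 <- list()
  for (tr in tracks) {
    if (isTRUE(tr$censored) || isTRUE(tr$border_touching) ||
        isTRUE(tr$subthreshold)) next
    pos <- track_positions(tr)
    met <- track_phase_metrics(m1, m2, pos$frame, pos$x, pos$y, ps,
                               size = snapshot_size)
    ph <- classify_phase(met)
    # footprint diameter: average clathrin snapshots over late nucleation
    # frames (second half of phase 2), where the coat is flat and has
    # reached its footprint size
    p2 <- which(ph == 2)
    diam <- NA_real_
    if (length(p2) >= 2) {
      use <- p2[seq(ceiling(length(p2) / 2 + 0.5), length(p2))]
      ss <- list()
      for (k in use) {
        s <- tryCatch(extract_snapshot(m2, pos$frame[k], pos$x[k], pos$y[k],
                                       snapshot_size), error = function(e) NULL)
        if (!is.null(s)) ss[[length(ss) + 1]] <- s
      }
      if (length(ss) >= 2) {
        avg <- average_snapshots(ss, min_count = 2)
        ctr <- c((snapshot_size - 1) / 2, (snapshot_size - 1) / 2)
        lp <- line_profile(avg, ctr, ps)
        diam <- tryCatch(fwhm(lp$position_nm, lp$intensity),
                         error = function(e) NA_real_)
      }
    }
    # pooled phase-3 snapshots for the ring offset
    p3 <- which(ph == 3)
    for (k in p3) {
      s1 <- tryCatch(extract_snapshot(m1, pos$frame[k], pos$x[k], pos$y[k],
                                      snapshot_size), error = function(e) NULL)
      s2 <- tryCatch(extract_snapshot(m2, pos$frame[k], pos$x[k], pos$y[k],
                                      snapshot_size), error = function(e) NULL)
      if (!is.null(s1) && !is.null(s2)) {
        snaps1[[length(snaps1) + 1]] <- s1
        snaps2[[length(snaps2) + 1]] <- s2
      }
    }
    per_track[[length(per_track) + 1]] <- data.frame(
      track_id = tr$id, diameter_nm = diam,
      max_phase = max(ph), n_phase3 = length(p3))
  }
  per_track <- if (length(per_track)) do.call(rbind, per_track) else
    data.frame(track_id = integer(0), diameter_nm = numeric(0),
               max_phase = integer(0), n_phase3 = integer(0))
  diams <- per_track$diameter_nm[!is.na(per_track$diameter_nm)]
  size_stats <- if (length(diams) >= 2) size_statistics(diams) else
    list(mean = NA_real_, sd = NA_real_, max_rel_deviation = NA_real_,
         cv = NA_real_)

  offset <- NA_real_
  if (length(snaps1) >= min_snapshots) {
    avg1 <- average_snapshots(snaps1, min_count = min_snapshots)
    avg2 <- average_snapshots(snaps2, min_count = min_snapshots)
    ctr <- c((snapshot_size - 1) / 2, (snapshot_size - 1) / 2)
    pr1 <- radial_profile(avg1, ctr, ps)
    pr2 <- radial_profile(avg2, ctr, ps)
    offset <- tryCatch(peak_offset(pr1, pr2), error = function(e) NA_real_)
  }
  list(per_track = per_track, mean_diameter_nm = size_stats$mean,
       size_stats = size_stats, ring_peak_offset_nm = offset,
       n_phase3_snapshots = length(snaps1))
}
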