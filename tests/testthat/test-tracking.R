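toy_det <- function(frames, xs, ys) {
  data.frame(frame = frames, x = xs, y = ys, A = 10, b = 0,
             sigma = 1, significance = 0.01)
}

test_that("two immobile well-separated spots give exactly two full tracks", {
  det <- toy_det(rep(0:49, each = 2), rep(c(10, 40), 50), rep(c(10, 40), 50))
  tr <- link_tracks(det)
  expect_length(tr, 2)
  for (t in tr) {
    expect_equal(t$birth_frame, 0)
    expect_equal(t$death_frame, 49)
    expect_equal(nrow(t$detections), 50)
  }
})

test_that("a single missed frame is bridged as a gap, not a new track", {
  frames <- setdiff(0:20, 10)
  det <- toy_det(frames, rep(15, 20), rep(15, 20))
  tr <- link_tracks(det, max_gap = 2)
  expect_length(tr, 1)
  d <- tr[[1]]$detections
  expect_equal(nrow(d), 21)            # gap frame carried as an NA row
  expect_true(is.na(d$x[d$frame == 10]))
  expect_equal(tr[[1]]$death_frame, 20)

  # with max_gap = 0 the same data split into two tracks
  tr0 <- link_tracks(det, max_gap = 0)
  expect_length(tr0, 2)
})

test_that("linking output is invariant to detection order within frames", {
  set.seed(5)
  det <- toy_det(rep(0:9, each = 3),
                 rep(c(10, 25, 40), 10) + rnorm(30, sd = 0.2),
                 rep(c(10, 25, 40), 10) + rnorm(30, sd = 0.2))
  perm <- det[sample(nrow(det)), ]
  t1 <- link_tracks(det)
  t2 <- link_tracks(perm)
  key <- function(tr) {
    s <- lapply(tr, function(t) round(t$detections[, c("frame", "x", "y")], 9))
    s[order(vapply(s, function(d) d$x[1], numeric(1)))]
  }
  expect_equal(key(t1), key(t2))
})

test_that("simulated non-crossing objects map one-to-one onto tracks", {
  opt <- fast_sim_optics()
  det_opt <- fast_sim_optics(psf_fwhm = 260)
  sc <- build_scenario(n_objects = 12, field_size = c(160, 160), duration = 60,
                       optics = opt, subthreshold_fraction = 0,
                       hotspot_fraction = 0, chromatic_offset = c(0, 0),
                       seed = 11)
  r <- render_movie(sc, opt)
  det <- detect_movie(r$channel2, det_opt)
  tracks <- classify_tracks(link_tracks(det), r$channel2, det_opt)
  real <- Filter(function(t) isTRUE(!t$subthreshold), tracks)
  m <- match_tracks(real, sc, r$truth)
  expect_equal(sort(unique(m$object)), seq_along(sc$objects))
  expect_equal(nrow(m), length(sc$objects))
  expect_true(all(m$jaccard >= 0.95))
})

test_that("track classification flags censoring, hotspots and subthreshold events", {
  opt <- fast_sim_optics()
  det_opt <- fast_sim_optics(psf_fwhm = 260)
  sc <- build_scenario(n_objects = 12, field_size = c(192, 192), duration = 80,
                       optics = opt, subthreshold_fraction = 0.25,
                       hotspot_fraction = 0.2, chromatic_offset = c(0, 0),
                       seed = 13)
  r <- render_movie(sc, opt)
  det <- detect_movie(r$channel2, det_opt)
  tracks <- classify_tracks(link_tracks(det), r$channel2, det_opt)
  m <- match_tracks(tracks, sc, r$truth)
  s <- track_summary(tracks)

  is_sub_obj <- vapply(sc$objects, `[[`, logical(1), "is_subthreshold")
  hot_objs <- unique(unlist(sc$hotspot_pairs))

  # simulated subthreshold objects are flagged subthreshold (>= 90%)
  sub_tracks <- s$subthreshold[match(which(is_sub_obj), m$object)]
  sub_tracks <- sub_tracks[!is.na(sub_tracks)]
  expect_gte(mean(sub_tracks), 0.9)

  # both members of each simulated hotspot pair are flagged
  for (pr in sc$hotspot_pairs) {
    flags <- s$hotspot_member[m$object %in% pr & s$lifetime_s > 5]
    expect_true(all(flags))
  }
})

test_that("tracks alive at the movie boundaries are censored and excluded from densities", {
  det <- rbind(toy_det(0:10, rep(10, 11), rep(10, 11)),     # spans start
               toy_det(5:15, rep(40, 11), rep(40, 11)))     # interior
  tr <- link_tracks(det)
  mov <- ccp_movie(array(0, c(64, 64, 30)), 110, 2)
  opt <- tirf_optics()
  tr <- classify_tracks(tr, mov, opt, l_min_s = 10)
  s <- track_summary(tr)
  expect_true(s$censored[s$birth_frame == 0])
  expect_false(s$censored[s$birth_frame == 5])
  dens <- initiation_density(tr, cell_area = 100, duration = 5)
  expect_equal(unname(dens["valid"]), 1 / 500)
})

test_that("initiation densities follow the defining arithmetic", {
  det <- do.call(rbind, lapply(1:10, function(i) {
    toy_det(5:20, rep(5 + 5 * i, 16), rep(30, 16))
  }))
  tr <- link_tracks(det)
  mov <- ccp_movie(array(0, c(96, 96, 30)), 110, 2)
  tr <- classify_tracks(tr, mov, tirf_optics(), l_min_s = 10)
  dens <- initiation_density(tr, cell_area = 100, duration = 5)
  expect_equal(unname(dens["valid"]), 10 / (100 * 5))
  expect_equal(unname(dens["subthreshold"]), 0)
  expect_equal(unname(initiation_density(list(), 100, 5)),
               c(0, 0), ignore_attr = TRUE)
  expect_error(initiation_density(tr, 0, 5), "positive")
})
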