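test_that("noise-free render conserves photons exactly across frames", {
  opt <- fast_sim_optics()
  obj <- ccp_object(0, 4, c(20, 22), rep(2L, 5),
                    data.frame(type = "patch", r1 = 50, r2 = NA)[rep(1, 5), ],
                    data.frame(rb = 61, h = 0)[rep(1, 5), ],
                    cbind(rep(0, 5), rep(1000, 5)))
  sc <- ccp_scenario(list(obj), c(48, 48), 5, noise = c(0, 0),
                     background = 0, seed = 7)
  r <- render_movie(sc, opt)
  sums <- apply(r$channel2$frames, 3, sum)
  expect_true(all(abs(sums - 1000) / 1000 < 1e-6))
  # total intensity identical across frames (no decay, linear operations)
  expect_lt(diff(range(sums)) / 1000, 1e-6)
})

test_that("per-frame integrated intensity equals sum of amplitude x weight", {
  opt <- fast_sim_optics()
  sc <- build_scenario(n_objects = 6, field_size = c(128, 128), duration = 20,
                       optics = opt, noise = c(0, 0), background = 0,
                       subthreshold_fraction = 0, hotspot_fraction = 0,
                       bleach_params_per_channel = list(c(1, 0, 0, 0),
                                                        c(1, 0, 0, 0)),
                       seed = 3)
  r <- render_movie(sc, opt)
  for (t in c(1, 10, 20)) {
    tr <- r$truth[r$truth$frame == t - 1, ]
    for (ch in 1:2) {
      expected <- sum(tr$amplitude[tr$channel == ch] *
                        tr$proj_weight[tr$channel == ch])
      got <- sum(r[[paste0("channel", ch)]]$frames[, , t])
      expect_lt(abs(got - expected) / max(expected, 1), 1e-6)
    }
  }
})

test_that("evanescent weighting of a dome matches numeric quadrature and dims the projection", {
  d <- 100; h <- 100; rb <- 100
  # independent oracle: integrate exp(-z/d) over the spherical zone area
  oracle <- integrate(function(z) exp(-z / d), 0, h)$value / h
  expect_lt(abs(projection_weight("cap", rb, h, d) - oracle), 1e-9)

  opt <- fast_sim_optics()
  dome <- render_single(cap = c(rb = rb, h = h), amp = c(0, 1000), field = 41)
  flat <- render_single(cap = c(rb = rb, h = 0), amp = c(0, 1000), field = 41)
  ctr <- dome$center + 1
  # same total fluorophore count, but the dome's on-axis projection is dimmer
  expect_lt(dome$f2[ctr[2], ctr[1]], flat$f2[ctr[2], ctr[1]])
  # and its radial profile peak moves off-centre
  pr <- radial_profile(dome$f2, dome$center, opt$pixel_size)
  pk <- which.max(pr$intensity)
  expect_gt(pr$radius_nm[pk], opt$pixel_size)
})

test_that("frame-mean trace follows the double-exponential bleach model", {
  opt <- fast_sim_optics()
  bp <- c(0.7, -0.01, 0.3, -0.001)
  obj <- ccp_object(0, 39, c(20, 20), rep(2L, 40),
                    data.frame(type = "patch", r1 = 50, r2 = NA)[rep(1, 40), ],
                    data.frame(rb = 61, h = 0)[rep(1, 40), ],
                    cbind(rep(500, 40), rep(500, 40)))
  sc <- ccp_scenario(list(obj), c(48, 48), 40, noise = c(0, 0),
                     background = 5,
                     bleach_params_per_channel = list(bp, bp), seed = 1)
  r <- render_movie(sc, opt)
  means <- frame_means(r$channel1)
  expected <- means[1] * bleach_curve(bp, 0:39) / bleach_curve(bp, 0)
  expect_lt(max(abs(means - expected) / expected), 1e-9)
})

test_that("rendered annulus peak radius matches the scenario radius within half a pixel", {
  opt <- fast_sim_optics()
  r0 <- 120
  s <- render_single(fcho = list(type = "ring", r1 = r0, r2 = 60),
                     amp = c(2000, 0), field = 41)
  # independent brute-force radial binning: explicit pixel loop, 10-nm bins
  ctr <- s$center
  ps <- opt$pixel_size
  bins <- seq(0, 400, by = 10)
  acc <- rep(0, length(bins) - 1); cnt <- rep(0, length(bins) - 1)
  for (iy in seq_len(nrow(s$f1))) {
    for (ix in seq_len(ncol(s$f1))) {
      rr <- sqrt(((ix - 1) - ctr[1])^2 + ((iy - 1) - ctr[2])^2) * ps
      b <- findInterval(rr, bins)
      if (b >= 1 && b < length(bins)) {
        acc[b] <- acc[b] + s$f1[iy, ix]
        cnt[b] <- cnt[b] + 1
      }
    }
  }
  prof <- acc / pmax(cnt, 1)
  peak_r <- (bins[which.max(prof)] + bins[which.max(prof) + 1]) / 2
  expect_lt(abs(peak_r - r0), ps / 2)
})

test_that("rendering is bit-identical for identical scenario, optics and seed", {
  opt <- fast_sim_optics()
  sc <- build_scenario(n_objects = 5, field_size = c(96, 96), duration = 25,
                       optics = opt, seed = 11)
  r1 <- render_movie(sc, opt)
  r2 <- render_movie(sc, opt)
  expect_identical(r1$channel1$frames, r2$channel1$frames)
  expect_identical(r1$channel2$frames, r2$channel2$frames)
  expect_identical(r1$truth, r2$truth)
})

test_that("object constructors enforce the lifecycle invariants", {
  fg <- data.frame(type = "patch", r1 = 50, r2 = NA)[rep(1, 3), ]
  cg <- data.frame(rb = 61, h = 0)[rep(1, 3), ]
  # clathrin amplitude must vanish in phase 1
  expect_error(ccp_object(0, 2, c(5, 5), c(1L, 1L, 2L), fg, cg,
                          cbind(c(1, 1, 1), c(5, 0, 0))),
               "phase 1")
  # pioneer amplitude must vanish in phase 5
  expect_error(ccp_object(0, 2, c(5, 5), c(4L, 5L, 5L), fg, cg,
                          cbind(c(1, 1, 0), c(5, 5, 5))),
               "phase 5")
  # phases may not decrease
  expect_error(ccp_object(0, 2, c(5, 5), c(3L, 2L, 3L), fg, cg,
                          cbind(c(1, 1, 1), c(5, 5, 5))),
               "non-decreasing")
  # ring may not shrink between nucleation and expansion
  fg2 <- data.frame(type = "ring", r1 = c(120, 100, 100), r2 = 60)
  expect_error(ccp_object(0, 2, c(5, 5), c(2L, 2L, 3L), fg2, cg,
                          cbind(c(1, 1, 1), c(5, 5, 5))),
               "non-decreasing")
  # a cap cannot exceed a hemisphere
  cg2 <- data.frame(rb = 61, h = c(0, 0, 80))
  expect_error(ccp_object(0, 2, c(5, 5), c(2L, 2L, 3L), fg, cg2,
                          cbind(c(1, 1, 1), c(5, 5, 5))),
               "hemisphere")
})

test_that("objects outside the field are rejected with a diagnostic", {
  opt <- fast_sim_optics()
  obj <- ccp_object(0, 0, c(2, 2), 2L,
                    data.frame(type = "patch", r1 = 50, r2 = NA),
                    data.frame(rb = 61, h = 0), matrix(c(100, 100), 1, 2))
  sc <- ccp_scenario(list(obj), c(32, 32), 1)
  expect_error(render_movie(sc, opt), "object 1")
})

test_that("scenario validation catches bad lifetimes and bleach models", {
  obj <- ccp_object(0, 10, c(16, 16), rep(2L, 11),
                    data.frame(type = "patch", r1 = 50, r2 = NA)[rep(1, 11), ],
                    data.frame(rb = 61, h = 0)[rep(1, 11), ],
                    cbind(rep(1, 11), rep(1, 11)))
  expect_error(ccp_scenario(list(obj), c(32, 32), 5), "lifetime")
  expect_error(ccp_scenario(list(obj), c(32, 32), 20,
                            bleach_params_per_channel =
                              list(c(2, -1, -1, 0), c(1, 0, 0, 0))),
               "positive")
  expect_error(ccp_scenario(list(obj), c(32, 32), 20,
                            subthreshold_fraction = 1.5), "subthreshold")
})

test_that("raw sub-frames carry independent noise realisations", {
  opt <- fast_sim_optics(n_raw_per_timepoint = 3L)
  obj <- ccp_object(0, 0, c(15, 15), 2L,
                    data.frame(type = "patch", r1 = 50, r2 = NA),
                    data.frame(rb = 61, h = 0), matrix(c(500, 500), 1, 2))
  sc <- ccp_scenario(list(obj), c(31, 31), 1, noise = c(1, 2),
                     background = 10, seed = 4)
  r <- render_movie(sc, opt)
  expect_equal(n_frames(r$channel1), 3)
  expect_false(identical(r$channel1$frames[, , 1], r$channel1$frames[, , 2]))
})

test_that("ground truth table covers every object, frame and channel", {
  opt <- fast_sim_optics()
  sc <- build_scenario(n_objects = 4, field_size = c(96, 96), duration = 30,
                       optics = opt, seed = 2)
  r <- render_movie(sc, opt)
  for (i in seq_along(sc$objects)) {
    o <- sc$objects[[i]]
    rows <- r$truth[r$truth$object_id == i, ]
    expect_equal(nrow(rows), 2 * (o$death_frame - o$birth_frame + 1))
    expect_true(all(rows$x_px >= 0 & rows$x_px <= 95))
  }
  # CSV writer emits the documented columns
  p <- tempfile(fileext = ".csv")
  write_ground_truth_csv(r$truth, p)
  hdr <- names(utils::read.csv(p, nrows = 1))
  expect_identical(hdr, c("object_id", "frame", "channel", "x_px", "y_px",
                          "amplitude", "phase", "geom_type", "r1_nm", "r2_nm",
                          "is_subthreshold", "is_hotspot"))
})

test_that("movies round-trip through 16-bit TIFF within quantisation", {
  opt <- fast_sim_optics()
  s <- render_single(amp = c(1500, 800), noise = c(1, 2), background = 10)
  mov <- ccp_movie(array(c(s$f1, s$f2), c(31, 31, 2)), opt$pixel_size,
                   opt$frame_interval)
  p <- tempfile(fileext = ".tif")
  write_movie_tiff(mov, p)
  back <- read_movie_tiff(p)
  expect_equal(back$pixel_size, mov$pixel_size)
  expect_equal(n_frames(back), 2)
  expect_lt(max(abs(back$frames - pmax(mov$frames, 0))),
            max(mov$frames) / 2^15)
})
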