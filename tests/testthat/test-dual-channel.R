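make_track <- function(id, birth, death, x, y, A = 50) {
  nf <- death - birth + 1
  list(id = id, birth_frame = birth, death_frame = death,
       detections = data.frame(frame = birth:death, x = x, y = y, A = A,
                               b = 0, significance = 0.01),
       lifetime_s = nf, hotspot_member = FALSE)
}

test_that("paired traces have length lifetime + 2 buffers, with 25-frame default windows", {
  mov <- ccp_movie(array(runif(48 * 48 * 120, 9, 11), c(48, 48, 120)), 32.5, 1)
  tr <- list(make_track(1, 40, 79, 24, 24))   # 40-frame track
  traces <- extract_paired_traces(tr, mov, n_buffer = 25)
  expect_length(traces, 1)
  expect_length(traces[[1]]$slave, 40 + 2 * 25)
  expect_length(traces[[1]]$master, 90)
  expect_equal(traces[[1]]$appearance_index, 26L)
})

test_that("frames outside the movie are missing, not zero-filled", {
  mov <- ccp_movie(array(10, c(32, 32, 30)), 32.5, 1)
  tr <- list(make_track(1, 2, 27, 16, 16))
  traces <- extract_paired_traces(tr, mov, n_buffer = 10)
  sl <- traces[[1]]$slave
  expect_length(sl, 26 + 20)
  expect_true(all(is.na(sl[1:8])))          # frames -8..-1
  expect_true(all(is.na(sl[(length(sl) - 7):length(sl)])))
  expect_false(anyNA(sl[9:(length(sl) - 8)]))
})

test_that("hotspot-member tracks are excluded from trace extraction", {
  mov <- ccp_movie(array(10, c(32, 32, 30)), 32.5, 1)
  t1 <- make_track(1, 5, 20, 10, 10)
  t2 <- make_track(2, 5, 20, 22, 22); t2$hotspot_member <- TRUE
  expect_length(extract_paired_traces(list(t1, t2), mov, n_buffer = 2), 1)
  expect_length(extract_paired_traces(list(t1, t2), mov, n_buffer = 2,
                                      exclude_hotspots = FALSE), 2)
})

test_that("reading the master channel as its own slave reproduces the amplitudes", {
  opt <- fast_sim_optics()
  det_opt <- fast_sim_optics(psf_fwhm = 260)
  sc <- build_scenario(n_objects = 6, field_size = c(128, 128), duration = 60,
                       optics = opt, subthreshold_fraction = 0,
                       hotspot_fraction = 0, chromatic_offset = c(0, 0),
                       noise = c(0, 0),
                       bleach_params_per_channel = list(c(1, 0, 0, 0),
                                                        c(1, 0, 0, 0)),
                       seed = 17)
  r <- render_movie(sc, opt)
  det <- detect_movie(r$channel2, det_opt)
  tracks <- classify_tracks(link_tracks(det), r$channel2, det_opt)
  traces <- extract_paired_traces(tracks, r$channel2, n_buffer = 0)
  # slave windowed readout and master fitted amplitude measure the same
  # object differently; they must agree up to a stable proportionality
  for (t in traces) {
    ok <- !is.na(t$master) & !is.na(t$slave) & t$master > quantile(t$master, 0.5, na.rm = TRUE)
    ratio <- t$slave[ok] / t$master[ok]
    expect_lt(sd(ratio) / mean(ratio), 0.25)
  }
})

test_that("the pioneer signal rises before the clathrin-channel track is born", {
  opt <- fast_sim_optics()
  det_opt <- fast_sim_optics(psf_fwhm = 260)
  sc <- build_scenario(n_objects = 6, field_size = c(160, 160), duration = 80,
                       optics = opt, subthreshold_fraction = 0,
                       hotspot_fraction = 0, chromatic_offset = c(0, 0),
                       seed = 19)
  r <- render_movie(sc, opt)
  det <- detect_movie(r$channel2, det_opt)
  tracks <- classify_tracks(link_tracks(det), r$channel2, det_opt)
  traces <- extract_paired_traces(tracks[vapply(tracks, function(t)
    isTRUE(t$valid), logical(1))], r$channel1, n_buffer = 15)
  lead <- vapply(traces, function(t) {
    ap <- t$appearance_index
    pre <- t$slave[seq_len(ap - 1)]
    base <- stats::median(t$slave[1:5], na.rm = TRUE)
    nsd <- stats::mad(t$slave[1:5], na.rm = TRUE) + 1e-6
    # frames before master birth where the pioneer is already > 3 sd up
    rise <- which(pre > base + 3 * nsd)
    if (length(rise)) ap - rise[1] else 0
  }, numeric(1))
  # the generator gives the pioneer a whole assembly phase before clathrin
  expect_true(mean(lead >= 3) >= 0.8)
})

test_that("cohort averaging reproduces identical traces exactly", {
  mk <- function(v) structure(list(track_id = 1, master = v, slave = v,
                                   n_buffer = 0L, appearance_index = 1L,
                                   lifetime_s = length(v)),
                              class = "paired_trace")
  tr <- list(mk(c(0, 1, 2)), mk(c(0, 1, 2)))
  co <- cohort_average(tr, c(0, 10), min_events = 2)
  expect_length(co, 1)
  expect_equal(co[[1]]$n_events, 2)
  expect_equal(co[[1]]$mean_slave, c(0, 1, 2))
  expect_equal(co[[1]]$sd_slave, c(0, 0, 0))
  # a single event with no buffer reproduces itself
  co1 <- cohort_average(list(mk(c(3, 5, 4))), c(0, 10), min_events = 1)
  expect_equal(co1[[1]]$mean_slave, c(3, 5, 4))
})

test_that("cohort means converge to the shared template at CLT rate", {
  set.seed(33)
  template <- 100 * (1 / (1 + exp(-(0:39 - 10) / 3))) * exp(-(0:39) / 30)
  n <- 100; noise_sd <- 10
  traces <- lapply(1:n, function(i) {
    v <- template + rnorm(40, sd = noise_sd)
    structure(list(track_id = i, master = v, slave = v, n_buffer = 0L,
                   appearance_index = 1L, lifetime_s = 40),
              class = "paired_trace")
  })
  co <- cohort_average(traces, c(0, 100), min_events = 50)[[1]]
  expect_true(all(abs(co$mean_slave - template) < 5 * noise_sd / sqrt(n)))
  # sparse bins are dropped with a warning
  expect_warning(cohort_average(traces[1:2], c(0, 100), min_events = 5),
                 "omitted")
})

test_that("cubic inflection matches analytic inflection points", {
  t <- seq(-1, 3, by = 0.1)
  expect_equal(inflection_time(t^3 - 3 * t^2, t), 1.0, tolerance = 1e-9)
  expect_equal(inflection_time(t^3, t), 0.0, tolerance = 1e-9)
  expect_error(inflection_time(t^2, t), "no inflection")
  expect_error(inflection_time(t^3, t, window = 1:3), "at least 5")
  # inflection outside the window errors
  expect_error(inflection_time((t + 10)^3 - 3 * (t + 10)^2, t),
               "outside")
})

test_that("inflection-time difference of offset sigmoid cohorts is recovered", {
  # rise-then-fall cohort traces offset by 10 s, sampled at 2 s, 2% noise
  diffs <- sapply(1:20, function(sd) {
    set.seed(sd)
    tt <- seq(-20, 60, by = 2)
    shape <- function(t0) {
      y <- 1 / (1 + exp(-(tt - t0) / 4))
      peak_t <- t0 + 14
      decay <- pmax(0, (tt - peak_t)) / 40
      pmin(y, 1) - decay
    }
    y1 <- shape(0) + rnorm(length(tt), sd = 0.02)
    y2 <- shape(10) + rnorm(length(tt), sd = 0.02)
    # documented window rule: 2 frames before appearance to the maximum
    w1 <- (which(tt == -14)):which.max(y1)
    w2 <- (which(tt == -4)):which.max(y2)
    inflection_time(y2, tt, w2) - inflection_time(y1, tt, w1)
  })
  expect_lt(abs(mean(diffs) - 10), 2)
})
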