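sym_gauss <- function(size = 21, x0, y0, sigma = 2, A = 100) {
  xs <- 0:(size - 1)
  A * outer(exp(-(xs - y0)^2 / (2 * sigma^2)),
            exp(-(xs - x0)^2 / (2 * sigma^2)))
}

test_that("snapshot centroids refine to the true sub-pixel centre", {
  f <- sym_gauss(21, 10.3, 10.0)
  s <- extract_snapshot(f, 0, 10, 10, 21)
  expect_lt(abs(s$center[1] - 10.3), 0.1)
  expect_lt(abs(s$center[2] - 10.0), 0.1)

  # uniform image: centroid falls back to the geometric centre
  u <- extract_snapshot(matrix(5, 31, 31), 0, 15, 15, 21)
  expect_equal(u$center, c(10, 10))

  # centred annulus: the dip does not bias the centre of mass
  opt <- fast_sim_optics()
  rr <- render_single(fcho = list(type = "ring", r1 = 110, r2 = 60),
                      amp = c(2000, 0))
  s2 <- extract_snapshot(rr$f1, 0, 15, 15, 21)
  expect_lt(max(abs(s2$center - 10)), 0.05)

  expect_error(extract_snapshot(f, 0, 3, 3, 21), "border")
})

test_that("snapshot averaging honours the minimum count and the CLT", {
  f <- sym_gauss(21, 10, 10)
  snaps <- lapply(1:50, function(i)
    structure(list(image = f, center = c(10, 10), size = 21),
              class = "ccp_snapshot"))
  avg <- average_snapshots(snaps, align = FALSE)
  expect_equal(avg, f, ignore_attr = TRUE)
  expect_error(average_snapshots(snaps[1:10]), "at least 50")

  # 150 noisy copies: per-pixel error bounded by 3 sd / sqrt(n)
  set.seed(12)
  noisy <- lapply(1:150, function(i) {
    structure(list(image = f + matrix(rnorm(441, sd = 20), 21),
                   center = c(10, 10), size = 21),
              class = "ccp_snapshot")
  })
  avg2 <- average_snapshots(noisy, align = FALSE, min_count = 150)
  expect_true(all(abs(avg2 - f) < 4.5 * 20 / sqrt(150)))
})

test_that("sub-pixel alignment removes jitter blur from the average", {
  set.seed(3)
  size <- 21
  mk <- function(jit) {
    dx <- runif(1, -jit, jit); dy <- runif(1, -jit, jit)
    img <- sym_gauss(size, 10 + dx, 10 + dy, sigma = 2)
    structure(list(image = img, center = c(10 + dx, 10 + dy), size = size),
              class = "ccp_snapshot")
  }
  lw <- function(img) {
    lp <- line_profile(img, c(10, 10), 32.5)
    fwhm(lp$position_nm, lp$intensity)
  }
  template_w <- lw(sym_gauss(size, 10, 10, sigma = 2))
  # half-pixel jitter: the aligned average stays within 5% of the template
  snaps <- lapply(1:80, function(i) mk(0.5))
  aligned_w <- lw(average_snapshots(snaps, align = TRUE, min_count = 50))
  expect_lt((aligned_w - template_w) / template_w, 0.05)
  # strong jitter: alignment visibly beats the unaligned average
  snaps2 <- lapply(1:80, function(i) mk(1.5))
  aligned2 <- lw(average_snapshots(snaps2, align = TRUE, min_count = 50))
  blurred2 <- lw(average_snapshots(snaps2, align = FALSE, min_count = 50))
  expect_gt(blurred2, aligned2)
})

test_that("radial profiles reproduce analytic forms", {
  ps <- 32.5
  # isotropic Gaussian: profile follows exp(-r^2 / 2 sigma^2) within 2% rms
  f <- sym_gauss(61, 30, 30, sigma = 4, A = 1)
  pr <- radial_profile(f, c(30, 30), ps)
  keep <- pr$radius_nm < 16 * ps & !is.na(pr$intensity)
  model <- exp(-(pr$radius_nm[keep] / ps)^2 / (2 * 4^2))
  expect_lt(sqrt(mean((pr$intensity[keep] - model)^2)), 0.02)

  # uniform image: flat profile
  pu <- radial_profile(matrix(7, 31, 31), c(15, 15), ps)
  expect_true(all(abs(pu$intensity[!is.na(pu$intensity)] - 7) < 1e-12))

  # delta ring convolved with the PSF: profile peak within a bin of the
  # brute-force numeric convolution oracle
  opt <- fast_sim_optics()
  rr <- render_single(fcho = list(type = "ring", r1 = 110, r2 = 20),
                      amp = c(2000, 0), field = 41)
  pr2 <- radial_profile(rr$f1, rr$center, ps)
  sig <- fwhm_to_sigma(opt$psf_fwhm)
  sr <- fwhm_to_sigma(20)
  rgrid <- seq(0, 300, by = 0.5)
  oracle <- sapply(rgrid, function(r) {
    integrate(function(u) {
      du <- exp(-(u - 110)^2 / (2 * sr^2)) * u
      bes <- besselI(r * u / sig^2, 0, expon.scaled = TRUE)
      du * exp(-(r^2 + u^2) / (2 * sig^2) + r * u / sig^2) * bes
    }, 0, 300)$value
  })
  oracle_peak <- rgrid[which.max(oracle)]
  expect_lt(abs(pr2$radius_nm[which.max(pr2$intensity)] - oracle_peak), ps)
})

test_that("fwhm matches closed forms and a dense-grid ring oracle", {
  # Gaussian with sigma = 38.2 nm
  x <- seq(-300, 300, by = 1)
  y <- exp(-x^2 / (2 * 38.2^2))
  expect_lt(abs(fwhm(x, y) - 2 * sqrt(2 * log(2)) * 38.2), 0.5)

  # rectangular pulse of width w
  yr <- as.numeric(abs(x) <= 50)
  expect_lt(abs(fwhm(x, yr) - 100), 1.5)

  # two-peak annulus through-centre profile vs dense-grid half-max crossings
  # (radially symmetric blur: the through-centre profile is the radial
  # Bessel integral evaluated at |x|)
  sig <- 38.2; r0 <- 110; sr <- 17
  xx <- seq(-400, 400, by = 0.5)
  radial_i <- function(r) {
    integrate(function(u) {
      u * exp(-(u - r0)^2 / (2 * sr^2)) *
        exp(-(r - u)^2 / (2 * sig^2)) *
        besselI(r * u / sig^2, 0, expon.scaled = TRUE)
    }, max(0, r0 - 6 * sr), r0 + 6 * sr)$value
  }
  prof <- vapply(abs(xx), radial_i, numeric(1))
  w_pkg <- fwhm(xx, prof)
  # independent brute-force crossings on the dense grid
  half <- min(prof) + (max(prof) - min(prof)) / 2
  above <- which(prof >= half)
  w_oracle <- xx[max(above)] - xx[min(above)]
  expect_lt(abs(w_pkg - w_oracle) / w_oracle, 0.01)
  expect_gt(w_pkg, 2 * r0)
})

test_that("profiles without enclosing crossings are rejected", {
  x <- seq(0, 100, by = 1)
  expect_error(fwhm(x, x), "not enclosed|no peak")
})

test_that("rings and patches are classified from rendered geometry", {
  opt <- fast_sim_optics()
  ps <- opt$pixel_size
  # noise-free annulus at 80 nm: ring, measured radius within half a pixel
  rr <- render_single(fcho = list(type = "ring", r1 = 80, r2 = 60),
                      amp = c(2000, 0))
  s <- extract_snapshot(rr$f1, 0, 15, 15, 21)
  m <- classify_shape(s$image, s$center, ps, psf_fwhm = opt$psf_fwhm)
  expect_equal(m$shape_class, "ring")
  expect_lt(abs(m$peak_radius - 80), 16.25)

  # flat disk of 60 nm radius: the PSF fills the centre -> patch
  dd <- render_single(fcho = list(type = "patch", r1 = 60, r2 = NA),
                      amp = c(2000, 0))
  s2 <- extract_snapshot(dd$f1, 0, 15, 15, 21)
  m2 <- classify_shape(s2$image, s2$center, ps)
  expect_equal(m2$shape_class, "patch")
  expect_lt(m2$central_dip, 0.1)

  # a PSF-limited point source is never a ring
  pt <- sym_gauss(31, 15, 15, sigma = psf_sigma_px(opt), A = 500)
  s3 <- extract_snapshot(pt, 0, 15, 15, 21)
  m3 <- classify_shape(s3$image, s3$center, ps)
  expect_equal(m3$shape_class, "patch")
  expect_equal(m3$peak_radius, 0)
})

test_that("shape classification is invariant to 90-degree rotation", {
  opt <- fast_sim_optics()
  rr <- render_single(fcho = list(type = "ring", r1 = 110, r2 = 60),
                      amp = c(2000, 0), noise = c(1, 2), background = 10,
                      seed = 6)
  s <- extract_snapshot(rr$f1, 0, 15, 15, 21)
  rot <- t(s$image)[, rev(seq_len(21))]     # 90-degree rotation
  ctr_rot <- c(20 - s$center[2], s$center[1])
  m1 <- classify_shape(s$image, s$center, opt$pixel_size)
  m2 <- classify_shape(rot, ctr_rot, opt$pixel_size)
  expect_equal(m1$shape_class, m2$shape_class)
  expect_lt(abs(m1$peak_radius - m2$peak_radius), 3)
})

test_that("peak offsets are signed, antisymmetric, and recover rendered geometry", {
  opt <- fast_sim_optics()
  ps <- opt$pixel_size
  mk_prof <- function(r0) {
    rr <- render_single(fcho = list(type = "ring", r1 = r0, r2 = 40),
                        amp = c(2000, 0), field = 41)
    radial_profile(rr$f1, rr$center, ps)
  }
  pa <- mk_prof(150); pb <- mk_prof(100)
  expect_equal(peak_offset(pa, pa), 0)
  expect_equal(peak_offset(pa, pb), -peak_offset(pb, pa))
  # well-resolved radii: the 50-nm generating offset survives the blur
  expect_lt(abs(peak_offset(pa, pb) - 50), 16.25)
  expect_error(peak_offset(radial_profile(matrix(1, 21, 21), c(10, 10), ps),
                           pb), "flat")
})

test_that("model inversion recovers annulus radii near the resolution limit", {
  sig <- fwhm_to_sigma(90)
  # the forward model: blurred peak of a 60-nm ring sits far inside 60 nm
  expect_lt(ccptools:::blurred_ring_peak(60, sig), 40)
  # inversion recovers the generating radius from noise-free profiles
  opt <- fast_sim_optics()
  for (r0 in c(60, 110)) {
    rr <- render_single(fcho = list(type = "ring", r1 = r0, r2 = 20),
                        amp = c(2000, 0), field = 41)
    pr <- fine_profile(rr$f1, rr$center, opt$pixel_size)
    sig_eff <- sqrt(sig^2 + fwhm_to_sigma(20)^2)
    expect_lt(abs(ring_radius_from_profile(pr, sig_eff) - r0), 10)
  }
})

test_that("size statistics follow their definitions", {
  s <- size_statistics(rep(122, 10))
  expect_equal(s$mean, 122); expect_equal(s$max_rel_deviation, 0)
  s2 <- size_statistics(c(100, 140))
  expect_equal(s2$mean, 120)
  expect_equal(s2$max_rel_deviation, 20 / 120, tolerance = 1e-12)
  expect_equal(s2$cv, sd(c(100, 140)) / 120)
  expect_error(size_statistics(122), "at least 2")
})

test_that("480 simulated diameters at 122 +/- 2 nm satisfy the uniformity bound", {
  set.seed(42)
  d <- rnorm(480, 122, 2)
  s <- size_statistics(d)
  expect_lt(abs(s$mean - 122), 1)
  expect_lte(s$max_rel_deviation, 0.06)
})

test_that("the disk-to-sphere footprint conversion is exact", {
  expect_equal(vesicle_diameter_from_footprint(122), 61)
  expect_equal(vesicle_diameter_from_footprint(0), 0)
  d <- runif(5, 10, 300)
  expect_equal(vesicle_diameter_from_footprint(d), d / 2)
  expect_equal(vesicle_diameter_from_footprint(122, "hemisphere"),
               122 / sqrt(2))
  expect_error(vesicle_diameter_from_footprint(-1), "non-negative")
})

test_that("phase rules hold on scripted edge cases", {
  # pioneer-only transient: phases never exceed 1 and are flagged degenerate
  n <- 10
  met <- data.frame(fcho_A = rep(20, n), fcho_bg_sd = 1,
                    fcho_is_ring = FALSE, fcho_peak_radius = 0,
                    clat_A = 0.1, clat_bg_sd = 1)
  ph <- classify_phase(met)
  expect_true(all(ph == 1))
  expect_true(attr(ph, "degenerate"))

  # clathrin already present at entry: first label >= 2, monotone
  met2 <- data.frame(fcho_A = c(20, 20, 20, 12, 2, 0, 0),
                     fcho_bg_sd = 1,
                     fcho_is_ring = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     fcho_peak_radius = c(80, 80, 120, 120, 0, 0, 0),
                     clat_A = 30, clat_bg_sd = 1)
  ph2 <- classify_phase(met2)
  expect_gte(ph2[1], 2)
  expect_true(all(diff(ph2) >= 0))
  expect_equal(max(ph2), 5)
})

test_that("phase labels are monotone over random generated tracks", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    met <- data.frame(fcho_A = abs(rnorm(n, 10, 8)),
                      fcho_bg_sd = runif(n, 0.5, 2),
                      fcho_is_ring = runif(n) > 0.5,
                      fcho_peak_radius = runif(n, 0, 200),
                      clat_A = abs(rnorm(n, 10, 8)),
                      clat_bg_sd = runif(n, 0.5, 2))
    expect_true(all(diff(classify_phase(met)) >= 0))
  }
})
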