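#' Double-exponential bleach curve
#'
#' Evaluates `Y(x) = a * exp(b * x) + c * exp(d * x)` at frame indices `x`.
#'
#' @param params Numeric vector `c(a, b, c, d)`.
#' @param x Frame indices (0-based).
#' @return Numeric vector `Y(x)`.
#' @export
bleach_curve <- function(params, x) {
  stopifnot(length(params) == 4)
  params[1] * exp(params[2] * x) + params[3] * exp(params[4] * x)
}

#' Projection weight of an object geometry under the evanescent field
#'
#' The fraction of an object's fluorophores that is detected given the
#' exponential excitation decay `w(z) = exp(-z/d)`. Flat geometries (patch,
#' ring, disk) sit at the membrane (`z = 0`) and have weight 1. A spherical
#' cap of base radius `rb` and height `h` has mean weight
#' `d * (1 - exp(-h/d)) / h`, obtained by integrating `exp(-z/d)` over the
#' spherical zone area element `dA = 2 * pi * R * dz`.
#'
#' @param geom_type One of `"patch"`, `"ring"`, `"cap"`.
#' @param r1 Patch radius, ring peak radius, or cap base radius (nm).
#' @param r2 Ring width (FWHM, nm) or cap height (nm); ignored for patches.
#' @param penetration_depth Evanescent decay constant, nm.
#' @return Scalar weight in (0, 1].
#' @export
projection_weight <- function(geom_type, r1, r2, penetration_depth) {
  if (geom_type != "cap") return(1)
  h <- r2
  if (is.na(h) || h <= 0) return(1)
  d <- penetration_depth
  d * (1 - exp(-h / d)) / h
}

# Spherical-cap geometry: sphere radius from base radius rb and height h
# (requires h <= rb, i.e. up to a hemisphere).
cap_sphere_radius <- function(rb, h) (rb^2 + h^2) / (2 * h)

# Projected fluorophore density of a cap (per unit projected area, for a
# unit total fluorophore count) at projected radius r (nm). The cap surface
# z(r) = z0 + sqrt(R^2 - r^2), z0 = h - R, carries uniform fluorophore
# density 1 / (2*pi*R*h); the secant factor R/sqrt(R^2 - r^2) maps surface
# density to projected density, and exp(-z/d) applies the evanescent weight.
cap_projected_density <- function(r, rb, h, d) {
  if (h <= 0) {
    return(ifelse(r <= rb, 1 / (pi * rb^2), 0))
  }
  R <- cap_sphere_radius(rb, h)
  z0 <- h - R
  s <- sqrt(pmax(R^2 - r^2, (1e-3 * R)^2))
  z <- z0 + s
  ifelse(r <= rb, exp(-z / d) * (R / s) / (2 * pi * R * h), 0)
}

# Unnormalised projected density of the pioneer-protein geometries.
flat_density <- function(r, type, r1, r2) {
  if (type == "patch") {
    as.numeric(r <= r1)
  } else if (type == "ring") {
    sr <- fwhm_to_sigma(r2)
    exp(-(r - r1)^2 / (2 * sr^2))
  } else {
    stop("unknown flat geometry type: ", type)
  }
}

#' Construct one simulated CCP object
#'
#' Describes a single clathrin-coated pit over its lifetime: per-frame phase
#' labels (1-5), pioneer-channel geometry (flat patch or Gaussian ring),
#' clathrin-channel geometry (spherical cap), and per-frame photon amplitudes
#' for both channels. Enforces the lifecycle invariants: phases are
#' non-decreasing, the pioneer amplitude is zero in phase 5 (it has fully
#' dissipated before scission), the clathrin amplitude is zero in phase 1,
#' and the ring peak radius never shrinks across the ring phases.
#'
#' @param birth_frame,death_frame 0-based first and last frame alive.
#' @param center Length-2 vector `(x, y)`, sub-pixel 0-based channel-1
#'   coordinates.
#' @param phase Integer vector of per-frame phases, length
#'   `death_frame - birth_frame + 1`.
#' @param fcho_geom Data frame with columns `type` ("patch"/"ring"),
#'   `r1` (patch radius or ring peak radius, nm), `r2` (ring FWHM width, nm;
#'   `NA` for patches), one row per frame.
#' @param clat_geom Data frame with columns `rb` (cap base radius, nm) and
#'   `h` (cap height, nm; 0 = flat disk), one row per frame.
#' @param amplitude Matrix `[n_frames, 2]` of photon amplitudes
#'   (column 1 = pioneer channel, column 2 = clathrin channel).
#' @param is_subthreshold,is_hotspot Logical flags.
#' @return An object of class `ccp_object`.
#' @export
ccp_object <- function(birth_frame, death_frame, center, phase,
                       fcho_geom, clat_geom, amplitude,
                       is_subthreshold = FALSE, is_hotspot = FALSE) {
  nf <- death_frame - birth_frame + 1
  if (nf < 1) stop("death_frame must be >= birth_frame")
  stopifnot(length(phase) == nf, nrow(fcho_geom) == nf,
            nrow(clat_geom) == nf, nrow(amplitude) == nf,
            ncol(amplitude) == 2, length(center) == 2)
  if (any(diff(phase) < 0)) stop("phase labels must be non-decreasing")
  if (any(phase < 1 | phase > 5)) stop("phases must be in 1..5")
  if (any(amplitude[phase == 5, 1] != 0)) {
    stop("pioneer (channel 1) amplitude must be 0 in phase 5")
  }
  if (any(amplitude[phase == 1, 2] != 0)) {
    stop("clathrin (channel 2) amplitude must be 0 in phase 1")
  }
  ring <- which(fcho_geom$type == "ring" & phase %in% c(2, 3))
  if (length(ring) > 1 && any(diff(fcho_geom$r1[ring]) < -1e-9)) {
    stop("ring peak radius must be non-decreasing across phases 2-3")
  }
  if (any(clat_geom$h > clat_geom$rb + 1e-9)) {
    stop("cap height must not exceed the base radius (up to a hemisphere)")
  }
  structure(
    list(birth_frame = birth_frame, death_frame = death_frame,
         center = as.numeric(center), phase = as.integer(phase),
         fcho_geom = fcho_geom, clat_geom = clat_geom,
         amplitude = amplitude,
         is_subthreshold = isTRUE(is_subthreshold),
         is_hotspot = isTRUE(is_hotspot)),
    class = "ccp_object"
  )
}

#' Construct a simulation scenario
#'
#' @param objects List of [ccp_object()]s.
#' @param field_size Length-2 integer `(nx, ny)` field size in pixels.
#' @param duration Number of time points.
#' @param hotspot_pairs List of length-2 integer vectors
#'   `(predecessor index, successor index)` into `objects`.
#' @param subthreshold_fraction Fraction of objects that are short-lived,
#'   dim, abortive structures.
#' @param bleach_params_per_channel List of two `c(a, b, c, d)` vectors.
#' @param chromatic_offset Length-2 `(dx, dy)` sub-pixel shift (pixels)
#'   applied to channel 2.
#' @param noise Length-2 `(poisson_scaling, gaussian_read_sd)`; zero entries
#'   disable the corresponding noise source.
#' @param background Uniform background level, photons per pixel.
#' @param seed Integer base seed for all random streams.
#' @return An object of class `ccp_scenario`.
#' @export
ccp_scenario <- function(objects, field_size, duration,
                         hotspot_pairs = list(),
                         subthreshold_fraction = 0,
                         bleach_params_per_channel =
                           list(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                         chromatic_offset = c(0, 0),
                         noise = c(0, 0),
                         background = 0,
                         seed = 1L) {
  stopifnot(length(field_size) == 2, duration >= 1,
            length(chromatic_offset) == 2, length(noise) == 2,
            length(bleach_params_per_channel) == 2)
  if (subthreshold_fraction < 0 || subthreshold_fraction > 1) {
    stop("subthreshold_fraction must be in [0, 1]")
  }
  for (i in seq_along(objects)) {
    o <- objects[[i]]
    if (o$birth_frame < 0 || o$death_frame > duration - 1) {
      stop(sprintf("object %d lifetime [%d, %d] outside movie [0, %d]",
                   i, o$birth_frame, o$death_frame, duration - 1))
    }
  }
  for (bp in bleach_params_per_channel) {
    if (any(bleach_curve(bp, c(0, duration - 1)) <= 0)) {
      stop("bleach model must be strictly positive over the movie duration")
    }
  }
  structure(
    list(objects = objects, field_size = as.integer(field_size),
         duration = as.integer(duration), hotspot_pairs = hotspot_pairs,
         subthreshold_fraction = subthreshold_fraction,
         bleach_params_per_channel = bleach_params_per_channel,
         chromatic_offset = as.numeric(chromatic_offset),
         noise = as.numeric(noise), background = background,
         seed = as.integer(seed)),
    class = "ccp_scenario"
  )
}

# Paint one object's projected fluorophore density into a local patch on a
# supersampled grid, box-averaged back to the pixel grid. Returns the patch
# and its 0-based top-left pixel. The patch total is renormalised to
# amplitude * projection_weight exactly, so discretisation only affects the
# shape, never the photon count.
paint_patch <- function(center_px, geom_type, r1, r2, amplitude,
                        pixel_size, penetration_depth, oversample = 4L) {
  ext_nm <- switch(geom_type,
                   patch = r1,
                   ring = r1 + 2 * r2,
                   cap = r1)
  hw <- as.integer(ceiling(ext_nm / pixel_size)) + 2L
  cx <- as.integer(round(center_px[1])); cy <- as.integer(round(center_px[2]))
  px <- seq(cx - hw, cx + hw)
  py <- seq(cy - hw, cy + hw)
  os <- oversample
  sub <- (seq_len(os) - 0.5) / os - 0.5
  xs <- rep(px, each = os) + rep(sub, times = length(px))
  ys <- rep(py, each = os) + rep(sub, times = length(py))
  dx <- (xs - center_px[1]) * pixel_size
  dy <- (ys - center_px[2]) * pixel_size
  r <- sqrt(outer(dy^2, dx^2, `+`))
  dens <- if (geom_type == "cap") {
    cap_projected_density(r, r1, r2, penetration_depth)
  } else {
    flat_density(r, geom_type, r1, r2)
  }
  n <- length(px)
  dim(dens) <- c(os, n, os, n)
  patch <- apply(dens, c(2, 4), sum)
  tot <- sum(patch)
  if (tot <= 0) return(NULL)
  w <- projection_weight(geom_type, r1, r2, penetration_depth)
  patch <- patch * (amplitude * w / tot)
  list(patch = patch, x0 = px[1], y0 = py[1])
}

add_patch <- function(field, p) {
  ny <- nrow(field); nx <- ncol(field)
  rows <- p$y0 + seq_len(nrow(p$patch)) # 1-based row indices = y0+1 .. (0-based y0)
  cols <- p$x0 + seq_len(ncol(p$patch))
  keep_r <- rows >= 1 & rows <= ny
  keep_c <- cols >= 1 & cols <= nx
  field[rows[keep_r], cols[keep_c]] <-
    field[rows[keep_r], cols[keep_c]] + p$patch[keep_r, keep_c]
  field
}

object_extent_nm <- function(o) {
  f <- max(ifelse(o$fcho_geom$type == "ring",
                  o$fcho_geom$r1 + 2 * ifelse(is.na(o$fcho_geom$r2), 0,
                                              o$fcho_geom$r2),
                  o$fcho_geom$r1))
  max(f, max(o$clat_geom$rb))
}

#' Render a two-channel synthetic CCP movie with ground truth
#'
#' Builds each frame by (i) painting every live object's projected
#' fluorophore density (flat patch or Gaussian ring in the pioneer channel;
#' an evanescently weighted spherical cap in the clathrin channel, so that a
#' grown dome projects as an annulus), (ii) convolving with the isotropic
#' Gaussian PSF, (iii) multiplying by the per-channel bleach model,
#' (iv) shifting channel 2 by the chromatic offset (applied while painting,
#' which is exact), and (v) sampling Poisson noise and adding Gaussian read
#' noise. When `optics$n_raw_per_timepoint > 1`, that many independent noise
#' realisations are emitted per time point. All randomness derives from
#' `scenario$seed`, split per channel, time point and sub-frame, so renders
#' are bit-identical for identical inputs.
#'
#' @param scenario A [ccp_scenario()].
#' @param optics An [optics_params()].
#' @param oversample Sub-pixel supersampling factor used while painting.
#' @return List with elements `channel1` and `channel2` ([ccp_movie()]s) and
#'   `truth`, a data frame with one row per (object, frame, channel) holding
#'   true positions, painted amplitudes, phases, geometry and flags.
#' @export
render_movie <- function(scenario, optics, oversample = 4L) {
  nx <- scenario$field_size[1]; ny <- scenario$field_size[2]
  ps <- optics$pixel_size
  sig <- psf_sigma_px(optics)
  off <- scenario$chromatic_offset

  for (i in seq_along(scenario$objects)) {
    o <- scenario$objects[[i]]
    ext <- object_extent_nm(o) / ps + 2
    lo <- o$center - ext
    hi <- o$center + ext + abs(off)
    if (lo[1] < 0 || lo[2] < 0 || hi[1] > nx - 1 || hi[2] > ny - 1) {
      stop(sprintf("object %d geometry exceeds the field bounds", i))
    }
  }

  kern <- gaussian_kernel(sig)
  n_raw <- optics$n_raw_per_timepoint
  nt <- scenario$duration
  out1 <- array(0, dim = c(ny, nx, nt * n_raw))
  out2 <- array(0, dim = c(ny, nx, nt * n_raw))
  truth <- vector("list", length(scenario$objects))

  hot <- rep(FALSE, length(scenario$objects))
  for (pr in scenario$hotspot_pairs) hot[pr] <- TRUE

  bl1 <- bleach_curve(scenario$bleach_params_per_channel[[1]], 0:(nt - 1))
  bl2 <- bleach_curve(scenario$bleach_params_per_channel[[2]], 0:(nt - 1))

  for (t in 0:(nt - 1)) {
    s1 <- matrix(0, ny, nx)
    s2 <- matrix(0, ny, nx)
    painted <- FALSE
    for (i in seq_along(scenario$objects)) {
      o <- scenario$objects[[i]]
      if (t < o$birth_frame || t > o$death_frame) next
      k <- t - o$birth_frame + 1
      a1 <- o$amplitude[k, 1]; a2 <- o$amplitude[k, 2]
      if (a1 > 0) {
        p <- paint_patch(o$center, o$fcho_geom$type[k], o$fcho_geom$r1[k],
                         o$fcho_geom$r2[k], a1, ps, optics$penetration_depth,
                         oversample)
        if (!is.null(p)) { s1 <- add_patch(s1, p); painted <- TRUE }
      }
      if (a2 > 0) {
        p <- paint_patch(o$center + off, "cap", o$clat_geom$rb[k],
                         o$clat_geom$h[k], a2, ps, optics$penetration_depth,
                         oversample)
        if (!is.null(p)) { s2 <- add_patch(s2, p); painted <- TRUE }
      }
    }
    if (painted) {
      s1 <- fft_convolve2(s1, kern)
      s2 <- fft_convolve2(s2, kern)
    }
    f1 <- (s1 + scenario$background) * bl1[t + 1]
    f2 <- (s2 + scenario$background) * bl2[t + 1]
    for (r in seq_len(n_raw)) {
      out1[, , t * n_raw + r] <- apply_noise(f1, scenario$noise,
                                             derive_seed(scenario$seed, 1, t, r))
      out2[, , t * n_raw + r] <- apply_noise(f2, scenario$noise,
                                             derive_seed(scenario$seed, 2, t, r))
    }
  }

  for (i in seq_along(scenario$objects)) {
    o <- scenario$objects[[i]]
    fr <- o$birth_frame:o$death_frame
    k <- seq_along(fr)
    w2 <- mapply(projection_weight, "cap", o$clat_geom$rb, o$clat_geom$h,
                 MoreArgs = list(penetration_depth = optics$penetration_depth))
    truth[[i]] <- rbind(
      data.frame(object_id = i, frame = fr, channel = 1L,
                 x_px = o$center[1], y_px = o$center[2],
                 amplitude = o$amplitude[k, 1] * bl1[fr + 1],
                 proj_weight = 1,
                 phase = o$phase,
                 geom_type = o$fcho_geom$type,
                 r1_nm = o$fcho_geom$r1, r2_nm = o$fcho_geom$r2,
                 is_subthreshold = o$is_subthreshold, is_hotspot = hot[i]),
      data.frame(object_id = i, frame = fr, channel = 2L,
                 x_px = o$center[1] + off[1], y_px = o$center[2] + off[2],
                 amplitude = o$amplitude[k, 2] * bl2[fr + 1],
                 proj_weight = w2,
                 phase = o$phase,
                 geom_type = "cap",
                 r1_nm = o$clat_geom$rb, r2_nm = o$clat_geom$h,
                 is_subthreshold = o$is_subthreshold, is_hotspot = hot[i])
    )
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$object_id, truth$frame, truth$channel), ]
  rownames(truth) <- NULL

  list(
    channel1 = ccp_movie(out1, ps, optics$frame_interval, n_raw),
    channel2 = ccp_movie(out2, ps, optics$frame_interval, n_raw),
    truth = truth
  )
}

apply_noise <- function(frame, noise, seed) {
  if (noise[1] <= 0 && noise[2] <= 0) return(frame)
  with_seed(seed, {
    out <- frame
    if (noise[1] > 0) {
      out <- matrix(stats::rpois(length(frame), pmax(frame, 0) * noise[1]),
                    nrow(frame)) / noise[1]
    }
    if (noise[2] > 0) {
      out <- out + matrix(stats::rnorm(length(frame), sd = noise[2]),
                          nrow(frame))
    }
    out
  })
}
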