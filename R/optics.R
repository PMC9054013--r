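#' Optical parameters of an acquisition
#'
#' Bundles the imaging parameters the detection model and the simulator share:
#' the lateral PSF full width at half maximum, the evanescent-field
#' penetration depth `d` (excitation weight `w(z) = exp(-z/d)` at height `z`
#' above the coverslip), the pixel size, the frame interval, and the number of
#' raw sub-frames acquired per time point.
#'
#' @param psf_fwhm Lateral PSF FWHM, nm.
#' @param penetration_depth Evanescent decay constant, nm.
#' @param pixel_size Pixel size, nm per pixel.
#' @param frame_interval Frame interval, s.
#' @param n_raw_per_timepoint Raw sub-frames per time point (>= 1).
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(psf_fwhm, penetration_depth, pixel_size,
                          frame_interval, n_raw_per_timepoint = 1L) {
  vals <- c(psf_fwhm = psf_fwhm, penetration_depth = penetration_depth,
            pixel_size = pixel_size, frame_interval = frame_interval)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all optical parameters must be finite and strictly positive")
  }
  if (psf_fwhm < pixel_size) {
    stop("psf_fwhm must be at least one pixel (psf_fwhm >= pixel_size)")
  }
  n_raw_per_timepoint <- as.integer(n_raw_per_timepoint)
  if (n_raw_per_timepoint < 1) stop("n_raw_per_timepoint must be >= 1")
  structure(
    list(psf_fwhm = psf_fwhm, penetration_depth = penetration_depth,
         pixel_size = pixel_size, frame_interval = frame_interval,
         n_raw_per_timepoint = n_raw_per_timepoint),
    class = "optics_params"
  )
}

#' @export
print.optics_params <- function(x, ...) {
  cat(sprintf(paste0("<optics_params> PSF FWHM %.3g nm (sigma %.3g px), ",
                     "depth %.3g nm, %.3g nm/px, %.3g s/frame, n_raw %d\n"),
              x$psf_fwhm, psf_sigma_px(x), x$penetration_depth,
              x$pixel_size, x$frame_interval, x$n_raw_per_timepoint))
  invisible(x)
}

#' PSF standard deviation in pixels
#' @param optics An [optics_params()].
#' @return Gaussian sigma of the PSF, pixels.
#' @export
psf_sigma_px <- function(optics) {
  fwhm_to_sigma(optics$psf_fwhm) / optics$pixel_size
}

#' Default SIM-like optics
#'
#' TIRF-SIM doubles the lateral resolution of TIRF to about 90 nm; nine raw
#' images (three pattern angles times three phases) are acquired per
#' reconstructed time point at 10 Hz. The reconstructed pixel size of 32.5 nm
#' is a documented assumption chosen so that a 21 x 21 pixel region of
#' interest spans about 680 nm, enough to contain a 260-nm-FWHM coated pit
#' image with margin.
#'
#' @param ... Overrides passed to [optics_params()].
#' @return An [optics_params()].
#' @export
sim_optics <- function(...) {
  args <- utils::modifyList(
    list(psf_fwhm = 90, penetration_depth = 100, pixel_size = 32.5,
         frame_interval = 0.1, n_raw_per_timepoint = 9L),
    list(...)
  )
  do.call(optics_params, args)
}

#' Default TIRF-like optics
#'
#' Conventional TIRF at 0.5 Hz with a diffraction-limited PSF of about
#' 250 nm FWHM and a 110 nm camera pixel.
#'
#' @param ... Overrides passed to [optics_params()].
#' @return An [optics_params()].
#' @export
tirf_optics <- function(...) {
  args <- utils::modifyList(
    list(psf_fwhm = 250, penetration_depth = 100, pixel_size = 110,
         frame_interval = 2, n_raw_per_timepoint = 1L),
    list(...)
  )
  do.call(optics_params, args)
}
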