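#' Single-channel fluorescence movie
#'
#' A `ccp_movie` holds one channel of a time-lapse acquisition as a numeric
#' 3D array `[row (y), column (x), frame]` together with the acquisition
#' metadata the downstream analysis needs: the pixel size in nm and the frame
#' interval in seconds. Positions everywhere in the package are 0-based,
#' pixel-centre, with `x` indexing columns and `y` indexing rows.
#'
#' @param frames Numeric 3D array `[ny, nx, nt]`, or a list of equally sized
#'   matrices (one per frame).
#' @param pixel_size Pixel size, nm per pixel.
#' @param frame_interval Time between consecutive time points, seconds.
#' @param n_raw Number of raw sub-frames per time point stored in `frames`
#'   (SIM acquisitions store 9 raw images per reconstructed time point).
#' @return An object of class `ccp_movie`.
#' @export
ccp_movie <- function(frames, pixel_size, frame_interval, n_raw = 1L) {
  if (is.list(frames)) {
    frames <- array(unlist(frames),
                    dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  n_raw <- as.integer(n_raw)
  if (n_raw < 1) stop("n_raw must be >= 1")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, n_raw = n_raw),
    class = "ccp_movie"
  )
}

#' @export
print.ccp_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ccp_movie> %d x %d px, %d frame(s), %.3g nm/px, %.3g s/frame, n_raw = %d\n",
              d[2], d[1], d[3], x$pixel_size, x$frame_interval, x$n_raw))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A [ccp_movie()].
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Extract one frame of a movie as a matrix
#' @param movie A [ccp_movie()].
#' @param i Frame index (1-based).
#' @return Numeric matrix `[ny, nx]`.
#' @export
movie_frame <- function(movie, i) movie$frames[, , i]

#' Write a movie to a multi-page 16-bit TIFF with a metadata sidecar
#'
#' Intensities are scaled linearly onto the 16-bit range; the scale factor,
#' pixel size, frame interval and raw sub-frame count are stored in a YAML
#' sidecar next to the TIFF so that [read_movie_tiff()] round-trips the data
#' up to 16-bit quantisation.
#'
#' @param movie A [ccp_movie()].
#' @param path Output TIFF path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  mx <- max(movie$frames)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(n_frames(movie)), function(i) {
    pmax(movie$frames[, , i], 0) / scale   # 16-bit output clamps at zero
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(
    list(pixel_size_nm = movie$pixel_size,
         frame_interval_s = movie$frame_interval,
         n_raw = movie$n_raw,
         intensity_scale = scale),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path with a `<path>.yaml` sidecar.
#' @return A [ccp_movie()].
#' @export
read_movie_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(unlist(pages),
                  dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  ccp_movie(frames * meta$intensity_scale,
            pixel_size = meta$pixel_size_nm,
            frame_interval = meta$frame_interval_s,
            n_raw = meta$n_raw %||% 1L)
}
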