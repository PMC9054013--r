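#' Estimate the chromatic transform between two channels from bead images
#'
#' Localises fiducial beads in both frames by 2D Gaussian fitting (via
#' [detect_spots()]), matches them by mutual nearest neighbour, and fits the
#' requested transform by least squares. The transform maps target-channel
#' coordinates into reference-channel coordinates,
#' `x_ref = M %*% c(x_tgt, y_tgt, 1)`.
#'
#' @param beads_ref,beads_target Single bead frames (matrices).
#' @param kind `"translation"`, `"rigid"` or `"affine"`.
#' @param optics An [optics_params()] describing the bead images.
#' @param max_match_dist Maximum bead pairing distance, pixels.
#' @return An object of class `channel_transform`: list with `kind`, `matrix`
#'   (2 x 3, pixel units), `residual` (RMS bead distance after correction,
#'   pixels) and `n_beads`.
#' @export
estimate_transform <- function(beads_ref, beads_target,
                               kind = c("translation", "rigid", "affine"),
                               optics, max_match_dist = 5) {
  kind <- match.arg(kind)
  d_ref <- detect_spots(beads_ref, optics)
  d_tgt <- detect_spots(beads_target, optics)
  need <- c(translation = 1L, rigid = 2L, affine = 3L)[[kind]]
  # mutual nearest neighbour matching
  if (nrow(d_ref) && nrow(d_tgt)) {
    dmat <- sqrt(outer(d_ref$x, d_tgt$x, `-`)^2 +
                   outer(d_ref$y, d_tgt$y, `-`)^2)
    nn_rt <- apply(dmat, 1, which.min)
    nn_tr <- apply(dmat, 2, which.min)
    i <- which(nn_tr[nn_rt] == seq_len(nrow(d_ref)))
    j <- nn_rt[i]
    ok <- dmat[cbind(i, j)] <= max_match_dist
    i <- i[ok]; j <- j[ok]
  } else {
    i <- j <- integer(0)
  }
  if (length(i) < need) {
    stop(sprintf("only %d matched bead(s); %s transform needs >= %d (detected %d ref, %d target)",
                 length(i), kind, need, nrow(d_ref), nrow(d_tgt)))
  }
  P_t <- cbind(d_tgt$x[j], d_tgt$y[j])
  P_r <- cbind(d_ref$x[i], d_ref$y[i])

  M <- switch(kind,
    translation = {
      sh <- colMeans(P_r - P_t)
      cbind(diag(2), sh)
    },
    rigid = {
      ct <- colMeans(P_t); cr <- colMeans(P_r)
      A <- sweep(P_t, 2, ct); B <- sweep(P_r, 2, cr)
      s <- svd(crossprod(A, B))
      R <- s$v %*% diag(c(1, det(s$v %*% t(s$u)))) %*% t(s$u)
      cbind(R, cr - as.numeric(R %*% ct))
    },
    affine = {
      X <- cbind(P_t, 1)
      cf <- qr.solve(X, P_r)       # 3 x 2
      t(cf)
    }
  )
  pred <- t(M %*% t(cbind(P_t, 1)))
  residual <- sqrt(mean(rowSums((pred - P_r)^2)))
  structure(list(kind = kind, matrix = M, residual = residual,
                 n_beads = length(i)),
            class = "channel_transform")
}

#' @export
print.channel_transform <- function(x, ...) {
  cat(sprintf("<channel_transform> %s, %d bead(s), residual %.4g px\n",
              x$kind, x$n_beads, x$residual))
  print(round(x$matrix, 5))
  invisible(x)
}

transform_invert <- function(t) {
  A <- t$matrix[, 1:2]; b <- t$matrix[, 3]
  Ai <- solve(A)
  structure(list(kind = t$kind, matrix = cbind(Ai, -Ai %*% b),
                 residual = t$residual, n_beads = t$n_beads),
            class = "channel_transform")
}

#' Apply a chromatic transform to a movie
#'
#' Resamples every frame with bicubic (Catmull-Rom) interpolation so that the corrected
#' movie lives in reference-channel coordinates. Pixels that map outside the
#' original field are filled with the frame's median (the background level),
#' which avoids creating spurious bright edges for the spot detector.
#'
#' @param movie A [ccp_movie()] (or a single matrix).
#' @param transform A `channel_transform` mapping target to reference
#'   coordinates.
#' @return The resampled movie (same class and shape as the input).
#' @export
apply_transform <- function(movie, transform) {
  is_mat <- is.matrix(movie)
  frames <- if (is_mat) array(movie, c(dim(movie), 1)) else movie$frames
  ny <- dim(frames)[1]; nx <- dim(frames)[2]
  inv <- transform_invert(transform)$matrix
  grid_x <- rep(0:(nx - 1), each = ny)
  grid_y <- rep(0:(ny - 1), times = nx)
  src_x <- inv[1, 1] * grid_x + inv[1, 2] * grid_y + inv[1, 3]
  src_y <- inv[2, 1] * grid_x + inv[2, 2] * grid_y + inv[2, 3]
  out <- frames
  for (t in seq_len(dim(frames)[3])) {
    fr <- frames[, , t]
    fill <- stats::median(fr)
    vals <- bicubic_sample(fr, src_x, src_y, fill = NA_real_)
    vals[is.na(vals)] <- fill
    out[, , t] <- matrix(vals, ny, nx)
  }
  if (is_mat) out[, , 1] else { movie$frames <- out; movie }
}

#' Save a channel transform as JSON
#' @param transform A `channel_transform`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(kind = transform$kind,
         matrix = transform$matrix,
         residual = transform$residual,
         n_beads = transform$n_beads),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' Load a channel transform saved by [write_transform_json()]
#' @param path JSON path.
#' @return A `channel_transform`.
#' @export
read_transform_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = o$kind, matrix = matrix(o$matrix, 2, 3, byrow = FALSE),
                 residual = o$residual, n_beads = o$n_beads),
            class = "channel_transform")
}

#' Render a synthetic fiducial-bead field in two channels
#'
#' Places `n_beads` point-like emitters at random well-separated positions
#' and renders them in a reference channel and in a target channel whose
#' coordinates are transformed by `offset` (translation) or a full 2 x 3
#' matrix. Used to exercise and test the registration step; real bead stacks
#' can be read with [read_movie_tiff()].
#'
#' @param n_beads Number of beads.
#' @param field_size `(nx, ny)`, pixels.
#' @param optics An [optics_params()].
#' @param offset Length-2 translation (pixels) applied to bead positions in
#'   the target channel, or a 2 x 3 matrix for a general affine map.
#' @param amplitude Bead amplitude (photons).
#' @param noise_sd Gaussian noise sd added to both frames.
#' @param seed Integer seed.
#' @return List with matrices `ref` and `target` and the true bead positions.
#' @export
render_bead_field <- function(n_beads = 12, field_size = c(128, 128),
                              optics = sim_optics(), offset = c(0, 0),
                              amplitude = 5000, noise_sd = 2, seed = 1L) {
  nx <- field_size[1]; ny <- field_size[2]
  sig <- psf_sigma_px(optics)
  margin <- ceiling(8 * sig) + 2
  pos <- with_seed(derive_seed(seed, 77), {
    p <- matrix(NA_real_, n_beads, 2)
    for (i in seq_len(n_beads)) {
      repeat {
        cand <- c(stats::runif(1, margin, nx - 1 - margin),
                  stats::runif(1, margin, ny - 1 - margin))
        prev <- p[seq_len(i - 1), , drop = FALSE]
        if (!nrow(prev) || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) > 12) break
      }
      p[i, ] <- cand
    }
    p
  })
  M <- if (is.matrix(offset)) offset else cbind(diag(2), offset)
  pos_t <- t(M %*% t(cbind(pos, 1)))
  paint_beads <- function(p) {
    f <- matrix(0, ny, nx)
    xs <- 0:(nx - 1); ys <- 0:(ny - 1)
    for (i in seq_len(nrow(p))) {
      gx <- exp(-(xs - p[i, 1])^2 / (2 * sig^2))
      gy <- exp(-(ys - p[i, 2])^2 / (2 * sig^2))
      f <- f + amplitude / (2 * pi * sig^2) * outer(gy, gx)
    }
    f
  }
  ref <- paint_beads(pos)
  tgt <- paint_beads(pos_t)
  if (noise_sd > 0) {
    ref <- ref + with_seed(derive_seed(seed, 78),
                           matrix(stats::rnorm(ny * nx, sd = noise_sd), ny, nx))
    tgt <- tgt + with_seed(derive_seed(seed, 79),
                           matrix(stats::rnorm(ny * nx, sd = noise_sd), ny, nx))
  }
  list(ref = ref, target = tgt, positions_ref = pos, positions_target = pos_t)
}
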