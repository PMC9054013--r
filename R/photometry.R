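#' Fit a double-exponential photobleaching model to frame means
#'
#' Fits `Y(x) = a * exp(b * x) + c * exp(d * x)` (x in frames, 0-based) to a
#' per-frame mean-intensity trace by Levenberg-Marquardt nonlinear least
#' squares. The fit is deterministic: starting values come from a single
#' exponential fitted to the log-means, split into two terms with a 10:1
#' rate ratio, and the rates are bounded above by zero so the fitted curve
#' decays. Constant traces short-circuit to the exact degenerate solution
#' `a = mean, b = c = d = 0`.
#'
#' @param frame_means Numeric vector of per-frame mean intensities
#'   (length >= 8, strictly positive).
#' @return An object of class `bleach_model`: list with `a`, `b`, `c`, `d`,
#'   `fit_rmse`, `decaying` (TRUE when both rates are <= 0), and `n_frames`.
#' @export
fit_bleach <- function(frame_means) {
  y <- as.numeric(frame_means)
  if (length(y) < 8) stop("need at least 8 frames to fit the bleach model")
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("frame means must be finite and strictly positive")
  }
  x <- seq_along(y) - 1

  if (stats::sd(y) < 1e-12 * mean(y)) {
    return(new_bleach_model(mean(y), 0, 0, 0, 0, length(y)))
  }

  # deterministic initialisation: single exponential on log-means,
  # split into a fast and a 10x slower term
  lf <- stats::lm(log(y) ~ x)
  a0 <- unname(exp(stats::coef(lf)[1]))
  b0 <- unname(min(stats::coef(lf)[2], -1e-6))
  start <- list(a = 0.5 * a0, b = b0, c = 0.5 * a0, d = b0 / 10)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(b * x) + c * exp(d * x),
      start = start,
      lower = c(a = 0, b = -Inf, c = 0, d = -Inf),
      upper = c(a = Inf, b = 0, c = Inf, d = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit) && !fit$convInfo$isConv) {
    stop(sprintf("bleach fit did not converge after %d iterations (start: a=%g b=%g c=%g d=%g)",
                 fit$convInfo$finIter, start$a, start$b, start$c, start$d))
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    rmse <- sqrt(mean(stats::resid(fit)^2))
    return(new_bleach_model(cf[["a"]], cf[["b"]], cf[["c"]], cf[["d"]], rmse,
                            length(y)))
  }
  # nearly flat or single-rate traces make the two exponential terms
  # collinear; fall back to the nested single-exponential model
  fit1 <- minpack.lm::nlsLM(
    y ~ a * exp(b * x), start = list(a = a0, b = b0),
    lower = c(a = 0, b = -Inf), upper = c(a = Inf, b = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit1)
  rmse <- sqrt(mean(stats::resid(fit1)^2))
  new_bleach_model(cf[["a"]], cf[["b"]], 0, 0, rmse, length(y))
}

new_bleach_model <- function(a, b, c, d, rmse, n) {
  structure(
    list(a = a, b = b, c = c, d = d, fit_rmse = rmse,
         decaying = b <= 0 && d <= 0, n_frames = n),
    class = "bleach_model"
  )
}

#' @export
print.bleach_model <- function(x, ...) {
  cat(sprintf("<bleach_model> Y(x) = %.4g*exp(%.4g x) + %.4g*exp(%.4g x), rmse %.3g%s\n",
              x$a, x$b, x$c, x$d, x$fit_rmse,
              if (x$decaying) "" else " [non-decaying]"))
  invisible(x)
}

#' Evaluate a fitted bleach model
#' @param model A `bleach_model`.
#' @param x Frame indices (0-based).
#' @return `Y(x)`.
#' @export
predict_bleach <- function(model, x) {
  bleach_curve(c(model$a, model$b, model$c, model$d), x)
}

#' Compensate a movie for photobleaching
#'
#' Multiplies frame `x` by the compensation coefficient `Y(0) / Y(x)`, so the
#' first frame is unchanged and later frames are scaled up to its level.
#'
#' @param movie A [ccp_movie()].
#' @param model A `bleach_model` from [fit_bleach()].
#' @return The corrected [ccp_movie()].
#' @export
correct_bleach <- function(movie, model) {
  nt <- n_frames(movie)
  yv <- predict_bleach(model, seq_len(nt) - 1)
  if (any(yv <= 0)) stop("bleach model is non-positive over the movie")
  coefs <- yv[1] / yv
  out <- movie$frames
  for (i in seq_len(nt)) out[, , i] <- out[, , i] * coefs[i]
  movie$frames <- out
  movie
}

#' Estimate the cross-channel intensity scale
#'
#' Estimates the multiplicative coefficient `s` applied to the second channel
#' that minimises the squared difference between the channels' average
#' intensity histograms. The default `"quantile"` mode matches the channels'
#' intensity quantiles (0-100% in 1% steps), for which the least-squares
#' solution is closed form: `s = sum(Q1 * Q2) / sum(Q2^2)`. The `"histogram"`
#' mode instead minimises the squared difference of binned counts between
#' channel 1 and channel 2 rescaled by `s`, via 1D optimisation.
#'
#' @param movie1,movie2 [ccp_movie()]s (or numeric arrays).
#' @param mode `"quantile"` (default) or `"histogram"`.
#' @param n_quantiles Number of quantile knots for the default mode.
#' @return An object of class `channel_scale`: list with `s` and `objective`
#'   (residual sum of squares of the matched histograms/quantiles).
#' @export
estimate_channel_scale <- function(movie1, movie2, mode = c("quantile", "histogram"),
                                   n_quantiles = 101) {
  mode <- match.arg(mode)
  v1 <- as.numeric(if (inherits(movie1, "ccp_movie")) movie1$frames else movie1)
  v2 <- as.numeric(if (inherits(movie2, "ccp_movie")) movie2$frames else movie2)
  if (!length(v1) || !length(v2)) stop("movies must be nonempty")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("degenerate (constant) channel: intensity scale is unidentifiable")
  }
  if (mode == "quantile") {
    p <- seq(0, 1, length.out = n_quantiles)
    q1 <- stats::quantile(v1, p, names = FALSE, type = 7)
    q2 <- stats::quantile(v2, p, names = FALSE, type = 7)
    s <- sum(q1 * q2) / sum(q2^2)
    obj <- sum((q1 - s * q2)^2)
  } else {
    br <- seq(min(v1, v2 * stats::median(v1) / stats::median(v2)),
              max(v1, v2 * stats::median(v1) / stats::median(v2)),
              length.out = 65)
    h1 <- graphics::hist(pmin(pmax(v1, br[1]), br[length(br)]),
                         breaks = br, plot = FALSE)$density
    f <- function(s) {
      h2 <- graphics::hist(pmin(pmax(v2 * s, br[1]), br[length(br)]),
                           breaks = br, plot = FALSE)$density
      sum((h1 - h2)^2)
    }
    s0 <- stats::median(v1) / stats::median(v2)
    op <- stats::optimize(f, interval = c(s0 / 10, s0 * 10))
    s <- op$minimum
    obj <- op$objective
  }
  if (s <= 0) stop("estimated scale is non-positive")
  structure(list(s = s, objective = obj, mode = mode),
            class = "channel_scale")
}

#' @export
print.channel_scale <- function(x, ...) {
  cat(sprintf("<channel_scale> s = %.6g (%s mode, objective %.3g)\n",
              x$s, x$mode, x$objective))
  invisible(x)
}

#' Per-frame mean intensity trace of a movie
#' @param movie A [ccp_movie()].
#' @return Numeric vector of frame means.
#' @export
frame_means <- function(movie) {
  apply(movie$frames, 3, mean)
}
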