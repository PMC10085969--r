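#' Single-gamma hemodynamic response function parameters
#'
#' Bundles the three parameters of the single-gamma HRF
#' \deqn{h(t) = \theta_1 \Gamma(\theta_2)^{-1} \theta_3^{\theta_2}
#'       t^{\theta_2 - 1} e^{-\theta_3 t},}
#' where `theta1` scales the response height, `theta2` (shape) controls the
#' delay and `theta3` (rate, 1/s) the dispersion. Cerebral-blood-volume
#' responses measured with functional ultrasound lack the post-stimulus
#' undershoot of the canonical BOLD double-gamma, so a single gamma is used.
#'
#' @param theta1,theta2,theta3 Strictly positive reals.
#' @return An object of class `hrf_params`.
#' @examples
#' p <- hrf_params(1, 6, 2)
#' peak_latency(evaluate_hrf(p, dt = 0.1, L = 100))
#' @export
hrf_params <- function(theta1, theta2, theta3) {
  th <- c(theta1 = theta1, theta2 = theta2, theta3 = theta3)
  if (length(th) != 3 || any(!is.finite(th)) || any(th <= 0)) {
    stop("HRF parameters must be three finite, strictly positive numbers",
         call. = FALSE)
  }
  structure(as.list(th), class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf("<hrf_params> theta1 = %.4g, theta2 = %.4g, theta3 = %.4g /s\n",
              x$theta1, x$theta2, x$theta3))
  invisible(x)
}

#' Sample a gamma HRF on a regular time grid
#'
#' Evaluates the single-gamma HRF at `t = k * dt`, `k = 0..L`, producing the
#' `L + 1` taps of the causal convolution filter used throughout the
#' deconvolution model.
#'
#' @param params An [hrf_params()] object.
#' @param dt Seconds per sample (`1 / fs`); must be positive.
#' @param L Filter order: the filter has `L + 1` taps; `L >= 1`.
#' @return An object of class `sampled_hrf`: list with `values` (length
#'   `L + 1`), `dt`, and `params`.
#' @export
evaluate_hrf <- function(params, dt, L) {
  if (!inherits(params, "hrf_params")) params <- do.call(hrf_params, as.list(params))
  stopifnot(dt > 0, L >= 1)
  t <- (0:L) * dt
  values <- gamma_hrf(t, params$theta1, params$theta2, params$theta3)
  structure(list(values = values, dt = dt, params = params),
            class = "sampled_hrf")
}

# theta2 < 1 gives a non-integrable spike at t = 0 (0^negative); the raw
# formula value (Inf) is returned there so callers can reject such curves.
gamma_hrf <- function(t, theta1, theta2, theta3) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- theta1 * exp(theta2 * log(theta3) - lgamma(theta2) +
                             (theta2 - 1) * log(t[pos]) - theta3 * t[pos])
  # t = 0: t^(theta2-1) is 1 when theta2 == 1, 0 when theta2 > 1, Inf below 1
  z <- !pos
  if (any(z)) {
    out[z] <- if (theta2 == 1) theta1 * theta3 else if (theta2 > 1) 0 else Inf
  }
  out
}

#' @export
print.sampled_hrf <- function(x, ...) {
  cat(sprintf("<sampled_hrf> %d taps at dt = %g s (%.4g s span)\n",
              length(x$values), x$dt, (length(x$values) - 1) * x$dt))
  invisible(x)
}

#' @describeIn evaluate_hrf Tidy a sampled HRF into a `(time, value)` tibble.
#' @param x A `sampled_hrf`.
#' @param ... Unused.
#' @export
tidy.sampled_hrf <- function(x, ...) {
  tibble(time = (seq_along(x$values) - 1) * x$dt, value = x$values)
}

#' Peak latency (time-to-peak) of a sampled HRF
#'
#' Returns the time of the maximum tap. Ties are broken in favour of the
#' earliest sample, matching the usual time-to-peak reading.
#'
#' @param hrf A `sampled_hrf` (or bare numeric vector with `dt` supplied).
#' @param dt Seconds per sample, only when `hrf` is a bare vector.
#' @return Peak latency in seconds.
#' @export
peak_latency <- function(hrf, dt = NULL) {
  v <- if (inherits(hrf, "sampled_hrf")) hrf$values else hrf
  dt <- if (inherits(hrf, "sampled_hrf")) hrf$dt else dt
  if (is.null(dt)) stop("dt required for a bare numeric vector", call. = FALSE)
  if (all(v == 0)) stop("peak latency undefined for an all-zero curve", call. = FALSE)
  dt * (which.max(v) - 1)
}

#' Full width at half maximum of a sampled HRF
#'
#' Width between the first up-crossing and the last down-crossing of half the
#' curve maximum, with linear interpolation between taps to reduce grid bias
#' at the coarse sampling rates (2-4 Hz) typical of power-Doppler streams. If
#' the curve never drops below half-maximum inside the filter window the
#' window-clipped width is returned with a warning.
#'
#' @inheritParams peak_latency
#' @return FWHM in seconds.
#' @export
hrf_fwhm <- function(hrf, dt = NULL) {
  v <- if (inherits(hrf, "sampled_hrf")) hrf$values else hrf
  dt <- if (inherits(hrf, "sampled_hrf")) hrf$dt else dt
  if (is.null(dt)) stop("dt required for a bare numeric vector", call. = FALSE)
  m <- max(v)
  if (!is.finite(m) || m <= 0) stop("FWHM requires a positive finite maximum", call. = FALSE)
  half <- m / 2
  n <- length(v)
  above <- v >= half
  i1 <- which(above)[1]
  i2 <- which(above)[sum(above)]
  # left crossing (interpolate between i1-1 and i1 when possible)
  t_left <- if (i1 == 1) 0 else
    (i1 - 2 + (half - v[i1 - 1]) / (v[i1] - v[i1 - 1])) * dt
  clipped <- FALSE
  if (i2 == n) {
    t_right <- (n - 1) * dt
    clipped <- i1 > 1 || all(above)
    if (all(above)) t_left <- 0
  } else {
    t_right <- (i2 - 1 + (v[i2] - half) / (v[i2] - v[i2 + 1])) * dt
  }
  if (clipped) warning("curve does not fall below half-maximum within the filter window; ",
                       "returning window-clipped width", call. = FALSE)
  t_right - t_left
}

#' Draw random gamma HRF parameters with prescribed shape ranges
#'
#' Rejection-samples `(theta2, theta3)` from log-uniform proposals until the
#' sampled curve's peak latency and FWHM fall in the requested ranges, then
#' rescales `theta1` so the peak amplitude is uniform in `amp_range`. The
#' FWHM of a gamma density has no closed form, hence rejection rather than
#' inversion. Shape ranges default to the physiologically generous mouse CBV
#' ranges used by the simulator.
#'
#' @param pl_range Peak-latency interval in seconds (default `c(0.25, 4.5)`).
#' @param fwhm_range FWHM interval in seconds (default `c(0.5, 4.5)`).
#' @param amp_range Peak-amplitude interval (default `c(0, 1)`).
#' @param dt Seconds per sample used when measuring PL/FWHM.
#' @param L Filter order used when measuring.
#' @param max_tries Rejection budget.
#' @return An [hrf_params()] object.
#' @export
sample_random_hrf <- function(pl_range = c(0.25, 4.5), fwhm_range = c(0.5, 4.5),
                              amp_range = c(0, 1), dt = 0.5, L = 16,
                              max_tries = 20000L) {
  stopifnot(length(pl_range) == 2, diff(pl_range) >= 0, all(pl_range >= 0),
            length(fwhm_range) == 2, diff(fwhm_range) >= 0, all(fwhm_range > 0),
            length(amp_range) == 2, diff(amp_range) >= 0, all(amp_range >= 0))
  for (i in seq_len(max_tries)) {
    theta2 <- exp(runif(1, log(1), log(30)))
    theta3 <- exp(runif(1, log(0.5), log(8)))
    h <- evaluate_hrf(hrf_params(1, theta2, theta3), dt, L)
    pl <- peak_latency(h)
    fw <- suppressWarnings(hrf_fwhm(h))
    tol <- 1e-9
    if (pl >= pl_range[1] - tol && pl <= pl_range[2] + tol &&
        fw >= fwhm_range[1] - tol && fw <= fwhm_range[2] + tol) {
      amp <- runif(1, amp_range[1], amp_range[2])
      theta1 <- amp / max(h$values)
      if (!is.finite(theta1) || theta1 < 0) next
      if (theta1 == 0) theta1 <- .Machine$double.xmin  # amp_range includes 0
      return(hrf_params(theta1, theta2, theta3))
    }
  }
  stop(sprintf(paste0("rejection budget (%d draws) exhausted sampling an HRF with ",
                      "PL in [%g, %g] s and FWHM in [%g, %g] s at dt = %g"),
               max_tries, pl_range[1], pl_range[2],
               fwhm_range[1], fwhm_range[2], dt), call. = FALSE)
}
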