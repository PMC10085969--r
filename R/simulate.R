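#' Generate a binary experimental paradigm (EP)
#'
#' Builds the stimulus on/off vector used as the task source: `n_reps`
#' stimulus blocks of `stim_dur` seconds, each preceded by a rest drawn
#' uniformly from `rest_range` seconds. The default settings reproduce the
#' visual-stimulation paradigm used in the evaluated study conditions:
#' 20 repetitions of a 4 s stimulus interleaved with random 10-15 s rests at
#' 2 Hz.
#'
#' @param n_reps Number of stimulus repetitions (`>= 1`).
#' @param stim_dur Stimulus duration, seconds.
#' @param rest_range Interval (seconds) from which each rest duration is drawn
#'   uniformly; rest durations are rounded to whole samples.
#' @param fs Sampling rate, Hz.
#' @return An object of class `ep`: list with binary `vector`, `fs`,
#'   integer `onsets`/`offsets` (1-based first/last stimulus sample of each
#'   block) and `n_reps`.
#' @examples
#' ep <- generate_ep()
#' sum(ep$vector)  # 20 reps x 4 s x 2 Hz = 160 on-samples
#' @export
generate_ep <- function(n_reps = 20L, stim_dur = 4, rest_range = c(10, 15),
                        fs = 2) {
  stopifnot(n_reps >= 1, stim_dur > 0, fs > 0, length(rest_range) == 2,
            diff(rest_range) >= 0)
  if (rest_range[1] < 1 / fs) {
    stop("rest_range lower bound must be at least one sample (1/fs)", call. = FALSE)
  }
  n_on <- stim_dur * fs
  if (abs(n_on - round(n_on)) > 1e-9) {
    message(sprintf("stim_dur * fs = %.3f is not integer; rounding to %d samples",
                    n_on, round(n_on)))
  }
  n_on <- as.integer(round(n_on))
  rests <- pmax(1L, as.integer(round(runif(n_reps, rest_range[1], rest_range[2]) * fs)))
  pieces <- vector("list", 2L * n_reps)
  onsets <- integer(n_reps)
  pos <- 0L
  for (r in seq_len(n_reps)) {
    pieces[[2L * r - 1L]] <- rep(0L, rests[r])
    pieces[[2L * r]] <- rep(1L, n_on)
    onsets[r] <- pos + rests[r] + 1L
    pos <- pos + rests[r] + n_on
  }
  structure(list(vector = unlist(pieces), fs = fs, onsets = onsets,
                 offsets = onsets + n_on - 1L, n_reps = n_reps,
                 stim_dur = stim_dur),
            class = "ep")
}

#' @export
print.ep <- function(x, ...) {
  cat(sprintf("<ep> %d reps, %d samples at %g Hz (%.0f s)\n",
              x$n_reps, length(x$vector), x$fs, length(x$vector) / x$fs))
  invisible(x)
}

#' Generate an artifact source: Gaussian process with changing mean
#'
#' Piecewise-constant mean levels (segment lengths uniform in
#' `segment_len_range` samples, levels `Normal(0, mean_scale^2)`) plus white
#' Gaussian noise of standard deviation `noise_sd`. This emulates slow
#' non-neural signal drifts (motion, physiology) superimposed with broadband
#' instrumentation noise.
#'
#' @param n Length in samples.
#' @param segment_len_range Integer interval of segment lengths (samples).
#' @param mean_scale SD of the per-segment mean levels.
#' @param noise_sd SD of the additive white noise.
#' @return Numeric vector of length `n`.
#' @export
generate_artifact <- function(n, segment_len_range = c(20, 60), mean_scale = 1,
                              noise_sd = 1) {
  stopifnot(n >= 1, length(segment_len_range) == 2,
            segment_len_range[1] >= 1, diff(segment_len_range) >= 0)
  mu <- numeric(0)
  while (length(mu) < n) {
    len <- as.integer(round(runif(1, segment_len_range[1], segment_len_range[2])))
    mu <- c(mu, rep(rnorm(1, 0, mean_scale), max(1L, len)))
  }
  mu[seq_len(n)] + rnorm(n, 0, noise_sd)
}

#' Causal convolution of a filter with a source series
#'
#' `y(t) = sum_l h(l) s(t - l)` with zero initial history, truncated to the
#' source length.
#' @param taps Filter taps `h(0..L)`.
#' @param s Source series.
#' @return Numeric vector, same length as `s`.
#' @export
causal_conv <- function(taps, s) {
  n <- length(s)
  convolve(s, rev(taps), type = "open")[seq_len(n)]
}

#' Simulate a multi-ROI functional-ultrasound dataset
#'
#' Generates the synthetic study conditions: `M` region time series at `fs`
#' Hz, each the causal convolution of a region-specific random gamma HRF with
#' a shared binary paradigm, plus a shared additive artifact source scaled
#' per region so that the clean-to-artifact power ratio equals `snr_db`
#' decibels. Rows are finally z-scored (zero mean, unit variance), matching
#' the normalization applied before decomposition.
#'
#' @param M Number of regions.
#' @param snr_db Signal-to-noise ratio in dB (clean convolved signal power
#'   over scaled artifact power, per region). `Inf` disables the artifact.
#' @param fs Sampling rate, Hz.
#' @param L HRF filter order (filter length `L + 1` samples).
#' @param ep Optional pre-built [generate_ep()] paradigm; generated with the
#'   default protocol when `NULL`.
#' @param hrfs Optional list of `M` [hrf_params()] (or `sampled_hrf` objects,
#'   e.g. [plateau_hrf()], whose taps are used verbatim); drawn with
#'   [sample_random_hrf()] when `NULL`.
#' @param pl_range,fwhm_range,amp_range Ranges forwarded to
#'   [sample_random_hrf()].
#' @param artifact_args List of arguments forwarded to [generate_artifact()].
#' @return An object of class `fus_sim`: list with z-scored `Y` (`M x N`),
#'   `Y_raw`, `hrfs`, `ep`, `artifact`, `artifact_gains`, `snr_db`, `fs`, `L`.
#' @examples
#' sim <- simulate_dataset(M = 3, snr_db = 0)
#' dim(sim$Y)
#' @export
simulate_dataset <- function(M = 3L, snr_db = 0, fs = 2, L = 16L, ep = NULL,
                             hrfs = NULL, pl_range = c(0.25, 4.5),
                             fwhm_range = c(0.5, 4.5), amp_range = c(0, 1),
                             artifact_args = list()) {
  stopifnot(M >= 1, is.finite(snr_db) || snr_db == Inf)
  dt <- 1 / fs
  if (is.null(ep)) ep <- generate_ep(fs = fs)
  if (is.null(hrfs)) {
    hrfs <- replicate(M, sample_random_hrf(pl_range, fwhm_range, amp_range,
                                           dt = dt, L = L),
                      simplify = FALSE)
  }
  stopifnot(length(hrfs) == M)
  N <- length(ep$vector)
  clean <- t(vapply(hrfs, function(p) {
    h <- if (inherits(p, "sampled_hrf")) p else evaluate_hrf(p, dt, L)
    stopifnot(length(h$values) == L + 1)
    causal_conv(h$values, as.numeric(ep$vector))
  }, numeric(N)))
  artifact <- do.call(generate_artifact, c(list(n = N), artifact_args))
  p_art <- mean(artifact^2)
  gains <- vapply(seq_len(M), function(m) {
    p_clean <- mean(clean[m, ]^2)
    if (p_clean == 0) stop("zero-power clean signal: SNR undefined", call. = FALSE)
    if (is.infinite(snr_db)) 0 else sqrt(p_clean / (p_art * 10^(snr_db / 10)))
  }, numeric(1))
  Y_raw <- clean + outer(gains, artifact)
  Y <- t(apply(Y_raw, 1, function(x) (x - mean(x)) / sd(x)))
  dimnames(Y) <- list(paste0("ROI", seq_len(M)), NULL)
  structure(list(Y = Y, Y_raw = Y_raw, clean = clean, hrfs = hrfs, ep = ep,
                 artifact = artifact, artifact_gains = gains, snr_db = snr_db,
                 fs = fs, L = L),
            class = "fus_sim")
}

#' @export
print.fus_sim <- function(x, ...) {
  cat(sprintf("<fus_sim> %d regions x %d samples at %g Hz, SNR %g dB\n",
              nrow(x$Y), ncol(x$Y), x$fs, x$snr_db))
  invisible(x)
}

#' @describeIn simulate_dataset Long-format tibble `(region, time, value)` of
#'   the z-scored series.
#' @param x A `fus_sim`.
#' @param ... Unused.
#' @export
tidy.fus_sim <- function(x, ...) {
  M <- nrow(x$Y); N <- ncol(x$Y)
  tibble(region = rep(rownames(x$Y), each = N),
         time = rep((seq_len(N) - 1) / x$fs, M),
         value = as.numeric(t(x$Y)))
}

#' @export
autoplot.fus_sim <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$region)) +
    ggplot2::labs(x = "time (s)", y = "z-scored power-Doppler signal")
}

#' Plateau (sustained-peak) HRF outside the gamma family
#'
#' Builds a sampled response with a gamma-shaped rise, a flat top of
#' `plateau_dur` seconds, and a gamma-shaped decay. Used to probe how the
#' gamma-constrained decomposition degrades when a region's true response is
#' not representable by the single-gamma model.
#'
#' @param rise An [hrf_params()] controlling the rising edge (its curve up to
#'   the mode is used).
#' @param plateau_dur Flat-top duration, seconds.
#' @param amp Peak amplitude.
#' @param dt Seconds per sample.
#' @param L Filter order of the returned `sampled_hrf`.
#' @return A `sampled_hrf` (with `params = NULL`).
#' @export
plateau_hrf <- function(rise = hrf_params(1, 5, 4), plateau_dur = 2, amp = 1,
                        dt = 0.5, L = 16L) {
  fine <- evaluate_hrf(rise, dt, L)$values
  mode_i <- which.max(fine)
  up <- fine[seq_len(mode_i)] / fine[mode_i]
  flat <- rep(1, round(plateau_dur / dt))
  down <- rev(up)[-1]
  v <- amp * c(up, flat, down)
  v <- if (length(v) >= L + 1) v[seq_len(L + 1)] else c(v, numeric(L + 1 - length(v)))
  structure(list(values = v, dt = dt, params = NULL), class = "sampled_hrf")
}
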