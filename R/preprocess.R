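#' SVD clutter filtering of a compound-frame ensemble
#'
#' Removes tissue clutter and noise from a `pixels x frames` ensemble by
#' zeroing the largest `low_frac` and smallest `high_frac` fractions of the
#' singular values (counts rounded up) and reconstructing. Slow, high-energy
#' tissue motion concentrates in the top singular components while the
#' lowest ones carry broadband noise; the blood signal lives in between.
#'
#' @param ensemble `pixels x frames` numeric matrix.
#' @param low_frac Fraction of the largest singular values to zero
#'   (default 0.30).
#' @param high_frac Fraction of the smallest singular values to zero
#'   (default 0.01).
#' @return Filtered matrix of the same dimensions.
#' @export
svd_clutter_filter <- function(ensemble, low_frac = 0.30, high_frac = 0.01) {
  if (low_frac + high_frac >= 1) {
    stop("low_frac + high_frac must be < 1", call. = FALSE)
  }
  stopifnot(low_frac >= 0, high_frac >= 0)
  s <- svd(ensemble)
  nsv <- length(s$d)
  if (nsv < 3) stop("ensemble must have at least 3 singular values", call. = FALSE)
  drop_low <- ceiling(low_frac * nsv)   # indices 1..drop_low (largest)
  drop_high <- ceiling(high_frac * nsv) # trailing (smallest)
  d <- s$d
  if (drop_low > 0) d[seq_len(drop_low)] <- 0
  if (drop_high > 0) d[seq.int(nsv - drop_high + 1L, nsv)] <- 0
  s$u %*% (d * t(s$v))
}

#' Power-Doppler value per pixel
#'
#' Mean squared magnitude over the ensemble frames, per pixel.
#'
#' @param ensemble `pixels x frames` matrix (typically SVD-filtered).
#' @return Numeric vector, one power value per pixel.
#' @export
power_doppler <- function(ensemble) {
  stopifnot(length(ensemble) > 0)
  rowMeans(ensemble^2)
}

#' Power-Doppler stream from a frame sequence
#'
#' Partitions frames into non-overlapping ensembles of `ensemble_len`
#' consecutive frames, clutter-filters each, and computes per-pixel power,
#' yielding a `pixels x n_ensembles` power-Doppler stream at rate
#' `frame_rate / ensemble_len`. A trailing remainder shorter than one
#' ensemble is dropped with a message.
#'
#' @param frames `pixels x n_frames` matrix.
#' @param ensemble_len Frames per ensemble (default 200).
#' @param frame_rate Compound-frame rate, Hz (default 800).
#' @param low_frac,high_frac Passed to [svd_clutter_filter()].
#' @return List with `pdi` (`pixels x n_ensembles`) and `fs` (stream rate, Hz).
#' @export
pdi_stream <- function(frames, ensemble_len = 200L, frame_rate = 800,
                       low_frac = 0.30, high_frac = 0.01) {
  n <- ncol(frames)
  n_ens <- n %/% ensemble_len
  if (n_ens < 1) stop("fewer frames than one ensemble", call. = FALSE)
  if (n %% ensemble_len != 0) {
    message(sprintf("dropping trailing remainder of %d frames", n %% ensemble_len))
  }
  pdi <- vapply(seq_len(n_ens), function(e) {
    cols <- (e - 1L) * ensemble_len + seq_len(ensemble_len)
    power_doppler(svd_clutter_filter(frames[, cols, drop = FALSE],
                                     low_frac, high_frac))
  }, numeric(nrow(frames)))
  list(pdi = matrix(pdi, nrow = nrow(frames)), fs = frame_rate / ensemble_len)
}

#' ROI-averaged, z-scored region time series
#'
#' Averages the power-Doppler stream over the pixels of each binary ROI mask
#' (unweighted mean), then z-scores each region series to zero mean and unit
#' variance -- the normalization applied before decomposition.
#'
#' @param pdi_stream `pixels x N` matrix.
#' @param masks List of logical/0-1 vectors (or matrices flattened to the
#'   pixel grid), one per region; names become region names.
#' @param fs Sampling rate of the stream, Hz.
#' @return A list of class `roi_series`: `Y` (`M x N` z-scored), `fs`,
#'   `regions`.
#' @export
roi_average <- function(pdi_stream, masks, fs) {
  stopifnot(length(masks) >= 1)
  nm <- names(masks)
  if (is.null(nm)) nm <- paste0("ROI", seq_along(masks))
  Y <- t(vapply(seq_along(masks), function(i) {
    m <- as.logical(as.vector(masks[[i]]))
    if (length(m) != nrow(pdi_stream)) {
      stop(sprintf("mask '%s' does not match the pixel grid", nm[i]), call. = FALSE)
    }
    if (!any(m)) stop(sprintf("mask '%s' is empty", nm[i]), call. = FALSE)
    x <- colMeans(pdi_stream[m, , drop = FALSE])
    (x - mean(x)) / sd(x)
  }, numeric(ncol(pdi_stream))))
  dimnames(Y) <- list(nm, NULL)
  structure(list(Y = Y, fs = fs, regions = nm), class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> %d regions x %d samples at %g Hz\n",
              nrow(x$Y), ncol(x$Y), x$fs))
  invisible(x)
}

#' Read a multi-frame TIFF into a pixels-by-frames matrix
#'
#' Thin wrapper around `tiff::readTIFF(all = TRUE)`; frames are flattened
#' column-major into pixel vectors.
#'
#' @param path Path to a multi-frame TIFF.
#' @return `pixels x frames` matrix with attribute `dim_px` (frame height,
#'   width).
#' @export
read_frame_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF stacks", call. = FALSE)
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  out <- vapply(frames, as.numeric, numeric(length(frames[[1]])))
  attr(out, "dim_px") <- dim(frames[[1]])
  out
}
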