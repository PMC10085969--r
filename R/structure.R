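#' Block-Hankel rearrangement of multichannel time series
#'
#' Stacks `Lp` lagged copies of each region's series: column `j` holds
#' `[y_m(n), y_m(n-1), ..., y_m(n-Lp+1)]` for every region `m` (region-major
#' row blocks), with `n = Lp, ..., N` (1-based). Every anti-diagonal within a
#' region block is therefore constant. This is the data-side rearrangement
#' that turns a convolutive mixture into the matrix product `Y = H S`.
#'
#' @param Y `M x N` matrix, rows = regions.
#' @param Lp Lag-window depth `L'` (rows per region block), `1 <= Lp < N`.
#' @return `M*Lp x (N - Lp + 1)` matrix with attributes `M`, `Lp`.
#' @examples
#' hankelize(matrix(1:4, 1), Lp = 2)  # rbind(c(2,3,4), c(1,2,3))
#' @export
hankelize <- function(Y, Lp) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  M <- nrow(Y); N <- ncol(Y)
  if (Lp >= N) stop("Lp must be smaller than the series length", call. = FALSE)
  stopifnot(Lp >= 1)
  ncols <- N - Lp + 1L
  out <- matrix(0, M * Lp, ncols)
  cols <- Lp:N
  for (m in seq_len(M)) {
    for (i in seq_len(Lp)) {
      out[(m - 1L) * Lp + i, ] <- Y[m, cols - (i - 1L)]
    }
  }
  attr(out, "M") <- M
  attr(out, "Lp") <- as.integer(Lp)
  out
}

#' Toeplitz block column of a convolutive mixing matrix
#'
#' For one source, stacks the `M` banded Toeplitz blocks `H_m` whose row `i`
#' carries the filter taps `h_m(0..L)` starting at column `i`:
#' `H_m[i, i + l] = h_m(l)`. Multiplying a depth-`L + Lp` Hankelized source
#' by this block column reproduces the convolved observations.
#'
#' @param filters `M x (L+1)` matrix of filter taps (one region per row), or
#'   a single tap vector for `M = 1`.
#' @param Lp Lag-window depth `L'` (rows per block).
#' @return `M*Lp x (L + Lp)` matrix.
#' @examples
#' toeplitz_block(c(1, 2), Lp = 2)  # rbind(c(1,2,0), c(0,1,2))
#' @export
toeplitz_block <- function(filters, Lp) {
  if (is.vector(filters)) filters <- matrix(filters, nrow = 1)
  M <- nrow(filters)
  L <- ncol(filters) - 1L
  stopifnot(Lp >= 1)
  P <- L + Lp
  out <- matrix(0, M * Lp, P)
  for (m in seq_len(M)) {
    for (i in seq_len(Lp)) {
      out[(m - 1L) * Lp + i, i:(i + L)] <- filters[m, ]
    }
  }
  out
}

#' Full mixing matrix from per-source filters
#'
#' Column-binds one [toeplitz_block()] per source. Task sources contribute
#' their HRF taps; artifact sources contribute scaled unit impulses
#' `(a_m, 0, ..., 0)` so their convolution is a direct, region-weighted
#' addition of the artifact series.
#'
#' @param task_filters List (one per task source) of `M x (L+1)` tap matrices.
#' @param artifact_gains List (one per artifact source) of length-`M` gain
#'   vectors, or `NULL`.
#' @param L Filter order (needed to pad artifact impulses).
#' @param Lp Lag-window depth.
#' @return `M*Lp x R*(L+Lp)` matrix, task block columns first.
#' @export
mixing_matrix <- function(task_filters, artifact_gains = NULL, L, Lp) {
  blocks <- lapply(task_filters, function(f) {
    f <- if (is.vector(f)) matrix(f, nrow = 1) else f
    stopifnot(ncol(f) == L + 1)
    toeplitz_block(f, Lp)
  })
  for (a in artifact_gains) {
    taps <- cbind(matrix(a, ncol = 1), matrix(0, length(a), L))
    blocks <- c(blocks, list(toeplitz_block(taps, Lp)))
  }
  do.call(cbind, blocks)
}

#' Lagged autocorrelation tensor of a block-Hankel matrix
#'
#' Stacks the empirical lagged autocorrelation matrices
#' `R_y(tau) = E[y(n) y(n + tau)^T]` for `tau = 0, ..., K-1` into a
#' 3-way array. The estimator is biased with a common divisor
#' `n_valid = ncol(Yh) - K`, summing over every column pair available at each
#' lag; the shared divisor keeps the slices jointly consistent across lags.
#'
#' @param Yh Block-Hankel matrix from [hankelize()] (any numeric matrix).
#' @param K Number of lags (tensor slices), `1 <= K < ncol(Yh)`.
#' @return `nrow(Yh) x nrow(Yh) x K` array; slice `k` is lag `k - 1`.
#' @export
autocorr_tensor <- function(Yh, K) {
  n <- ncol(Yh)
  if (K < 1 || K >= n) stop("K must satisfy 1 <= K < ncol(Yh)", call. = FALSE)
  nv <- n - K
  out <- array(0, c(nrow(Yh), nrow(Yh), K))
  for (k in seq_len(K)) {
    tau <- k - 1L
    idx <- seq_len(n - tau)
    out[, , k] <- tcrossprod(Yh[, idx, drop = FALSE],
                             Yh[, idx + tau, drop = FALSE]) / nv
  }
  out
}

#' Structured core tensor from a generating autocorrelation vector
#'
#' The lambda operator: maps a vector `z` of source autocorrelation values at
#' nonnegative lags `0..(P + K - 2)` to the `P x P x K` core tensor whose
#' frontal slice `k` has entries `C_k[i, j] = z[|k - 1 + i - j|]` (1-based).
#' Every slice is Toeplitz, slice 1 is symmetric, and each slice is the
#' one-lag shift of its predecessor along the generating sequence; negative
#' lags mirror positive ones (source stationarity).
#'
#' @param z Generating vector, `length(z) >= P + K - 1`.
#' @param P Slice dimension (`L + Lp`).
#' @param K Number of frontal slices.
#' @return `P x P x K` array.
#' @export
lambda_op <- function(z, P, K) {
  if (length(z) < P + K - 1) {
    stop(sprintf("z too short: need at least P + K - 1 = %d lags, got %d",
                 P + K - 1, length(z)), call. = FALSE)
  }
  out <- array(0, c(P, P, K))
  ij <- outer(seq_len(P), seq_len(P), "-")  # i - j
  for (k in seq_len(K)) {
    out[, , k] <- z[abs(k - 1L + ij) + 1L]
  }
  out
}

#' Empirical scalar autocorrelation at nonnegative lags
#'
#' Companion estimator to [lambda_op()]: returns the generating vector of a
#' single source series under the same biased common-divisor convention used
#' by [autocorr_tensor()], so cores built from it are comparable to the data
#' tensor.
#'
#' @param s Source series.
#' @param n_lags Number of lags (including lag 0).
#' @param divisor Common divisor; defaults to `length(s) - n_lags`.
#' @return Numeric vector of length `n_lags`.
#' @export
empirical_autocorr <- function(s, n_lags, divisor = length(s) - n_lags) {
  n <- length(s)
  stopifnot(n_lags >= 1, n_lags < n)
  vapply(0:(n_lags - 1L), function(tau) {
    sum(s[seq_len(n - tau)] * s[seq_len(n - tau) + tau]) / divisor
  }, numeric(1))
}
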