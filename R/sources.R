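#' Truncated-SVD Moore-Penrose pseudo-inverse
#'
#' Pseudo-inverse with the smallest singular values discarded, either below a
#' relative threshold `eps * sigma_max` (default 0.01) or by an explicit discard count. The
#' block columns of the estimated mixing matrix are near rank-deficient
#' (Toeplitz bands of smooth filters), so plain pseudo-inversion amplifies
#' noise; truncation regularizes the inversion.
#'
#' @param A Numeric matrix.
#' @param eps Relative singular-value threshold.
#' @param discard Explicit number of trailing singular values to zero
#'   (overrides `eps` when non-`NULL`).
#' @return The truncated pseudo-inverse, with attribute `rank` (number of
#'   singular values kept).
#' @export
truncated_pinv <- function(A, eps = 0.01, discard = NULL) {
  stopifnot(length(A) > 0)
  s <- svd(A)
  keep <- if (!is.null(discard)) {
    stopifnot(discard >= 0, discard < length(s$d))
    seq_len(length(s$d) - discard)
  } else {
    which(s$d > eps * s$d[1] & s$d > 0)
  }
  if (length(keep) == 0) stop("all singular values discarded", call. = FALSE)
  out <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  attr(out, "rank") <- length(keep)
  out
}

#' Collapse a (noisy) Hankel-structured block to a single series
#'
#' Each column of a depth-`P` Hankel block holds estimates of
#' `s(n), ..., s(n - P + 1)`; the anti-diagonal mean is the least-squares
#' projection onto exact Hankel structure and yields one estimate per time
#' point.
#'
#' @param S `P x nc` matrix.
#' @return Numeric vector of length `nc + P - 1` (times `n0 - P + 1 .. n0 + nc - 1`
#'   relative to the first column's anchor `n0`).
#' @export
dehankelize <- function(S) {
  P <- nrow(S); nc <- ncol(S)
  n_t <- nc + P - 1L
  acc <- numeric(n_t)
  cnt <- numeric(n_t)
  for (i in seq_len(P)) {
    # row i of column j estimates time (P - i) + j  (1-based output index)
    idx <- (P - i) + seq_len(nc)
    acc[idx] <- acc[idx] + S[i, ]
    cnt[idx] <- cnt[idx] + 1
  }
  acc / cnt
}

#' Recover source time courses from final HRF estimates
#'
#' Rebuilds the mixing matrix from the final HRF curves (task block columns)
#' and artifact gains (scaled-impulse block columns), Hankelizes the
#' observations, and inverts the convolutive mixture in one step with the
#' truncated pseudo-inverse: `S_hat = pinv(H_hat) %*% Y_hankel`. Inverting
#' all sources jointly projects the artifact out of the task-source estimate
#' instead of letting it leak through. Each source's Hankel-structured block
#' of `S_hat` is collapsed to a single series by anti-diagonal averaging.
#'
#' @param final An object with per-region HRF `curves` (e.g. [finalize_hrfs()]
#'   output), a bare `M x (L+1)` matrix of filter taps, or a list of such
#'   matrices (one per task source).
#' @param Y `M x N` observation matrix (rows z-scored).
#' @param cfg A [btd_config()].
#' @param artifact_gains List of length-`M` gain vectors, one per artifact
#'   source (e.g. the selection's averaged gains), or `NULL` to invert the
#'   task block alone.
#' @param eps,discard Passed to [truncated_pinv()].
#' @return A list of `source_estimate`s (task sources first): each has
#'   `series` (length `N`, time-aligned to the input; samples before `Lp`
#'   rest on partial windows), `hankel_block`, `trunc_rank`.
#' @export
estimate_sources <- function(final, Y, cfg, artifact_gains = NULL, eps = cfg$eps,
                             discard = NULL) {
  curves <- if (inherits(final, "final_hrfs")) list(final$curves)
            else if (is.list(final)) lapply(final, as.matrix)
            else list(as.matrix(final))
  for (cv in curves) {
    if (ncol(cv) != cfg$L + 1) stop("HRF curves must have L + 1 taps", call. = FALSE)
    if (nrow(Y) != nrow(cv)) stop("Y and HRF curves disagree on the region count",
                                  call. = FALSE)
  }
  Yh <- hankelize(Y, cfg$Lp)
  H <- mixing_matrix(curves, artifact_gains, L = cfg$L, Lp = cfg$Lp)
  Hinv <- truncated_pinv(H, eps = eps, discard = discard)
  Sh_all <- Hinv %*% Yh
  P <- cfg$L + cfg$Lp
  N <- ncol(Y)
  n_src <- length(curves) + length(artifact_gains)
  lapply(seq_len(n_src), function(r) {
    Sh <- Sh_all[(r - 1L) * P + seq_len(P), , drop = FALSE]
    series_full <- dehankelize(Sh)
    # columns anchor times Lp..N; de-Hankelized support is Lp-P+1..N.
    # Keep times 1..N (clip any pre-history).
    t0 <- cfg$Lp - P + 1L  # time of first output sample (can be <= 0)
    series <- numeric(N)
    src <- seq_along(series_full) + t0 - 1L
    okk <- src >= 1 & src <= N
    series[src[okk]] <- series_full[okk]
    structure(list(series = series, hankel_block = Sh,
                   trunc_rank = attr(Hinv, "rank")),
              class = "source_estimate")
  })
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %d samples, truncation rank %d\n",
              length(x$series), x$trunc_rank))
  invisible(x)
}

#' Canonicalize the sign of an estimated source
#'
#' The decomposition leaves each source's sign undetermined. With a known
#' paradigm the source is flipped so its mean inside stimulus windows is
#' positive; blindly, so its skewness is positive (hemodynamic responses are
#' upward-going transients).
#'
#' @param series Estimated source series.
#' @param ep Optional [generate_ep()] paradigm (or binary vector).
#' @return The series, possibly negated.
#' @export
canonicalize_sign <- function(series, ep = NULL) {
  flip <- if (!is.null(ep)) {
    v <- if (inherits(ep, "ep")) ep$vector else ep
    n <- min(length(v), length(series))
    mean(series[seq_len(n)][v[seq_len(n)] == 1]) < 0
  } else {
    m <- mean(series)
    mean((series - m)^3) < 0
  }
  if (flip) -series else series
}

#' Binarize an estimated source into a paradigm estimate
#'
#' Detects local maxima with a minimum prominence and minimum separation,
#' then walks outward from each peak to the first crossing of
#' `rise_drop_frac` of the peak height, marking the enclosed interval as
#' stimulus-on. Overlapping intervals are merged.
#'
#' @param series Estimated (sign-canonicalized) source series.
#' @param fs Sampling rate, Hz.
#' @param min_separation Minimum peak separation, seconds.
#' @param rise_drop_frac Fraction of peak height defining the significant
#'   rise/drop (default 0.5).
#' @param min_prominence Minimum peak prominence; default half the series SD.
#' @return A list of class `estimated_ep`: binary `vector`, `peaks` (sample
#'   indices), and tibble `intervals` (`start_s`, `end_s`).
#' @export
binarize_source <- function(series, fs, min_separation = 5,
                            rise_drop_frac = 0.5, min_prominence = NULL) {
  n <- length(series)
  if (sd(series) == 0) stop("cannot binarize a constant series", call. = FALSE)
  if (is.null(min_prominence)) min_prominence <- 0.5 * sd(series)
  x <- series
  # local maxima (plateau-safe): strictly above the previous sample, at
  # least as high as the next; series endpoints count when the series is
  # still rising into them (responses clipped by the recording boundary)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (x[1] > x[2]) cand <- c(1L, cand)
  if (x[n] > x[n - 1]) cand <- c(cand, n)
  if (length(cand) == 0) cand <- which.max(x)
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- cand[prom >= min_prominence]
  # enforce minimum separation, keeping the larger peak
  keep <- keep[order(-x[keep])]
  sel <- integer(0)
  gap <- round(min_separation * fs)
  for (i in keep) if (all(abs(i - sel) >= gap)) sel <- c(sel, i)
  sel <- sort(sel)
  if (length(sel) == 0) {
    warning("no peaks found; returning an empty paradigm", call. = FALSE)
    return(structure(list(vector = integer(n), peaks = integer(0),
                          intervals = tibble(start_s = numeric(0),
                                             end_s = numeric(0))),
                     class = "estimated_ep"))
  }
  vec <- integer(n)
  ivs <- lapply(sel, function(i) {
    thr <- rise_drop_frac * x[i]
    a <- i; while (a > 1 && x[a - 1] >= thr) a <- a - 1L
    b <- i; while (b < n && x[b + 1] >= thr) b <- b + 1L
    vec[a:b] <<- 1L
    c(a, b)
  })
  iv <- do.call(rbind, ivs)
  structure(list(vector = vec, peaks = sel,
                 intervals = tibble(start_s = (iv[, 1] - 1) / fs,
                                    end_s = (iv[, 2] - 1) / fs)),
            class = "estimated_ep")
}

# prominence: drop from the peak to the higher of the two key saddles
# (lowest point between the peak and the nearest higher terrain on each side)
peak_prominence <- function(x, i) {
  n <- length(x)
  left <- if (i == 1) -Inf else {
    seg <- x[seq_len(i - 1)]
    higher <- which(seg > x[i])
    from <- if (length(higher)) max(higher) + 1L else 1L
    min(seg[from:(i - 1L)])
  }
  right <- if (i == n) -Inf else {
    seg <- x[(i + 1):n]
    higher <- which(seg > x[i])
    to <- if (length(higher)) min(higher) - 1L else length(seg)
    if (to < 1) x[i] else min(seg[seq_len(to)])
  }
  if (!is.finite(max(left, right))) x[i] - min(x) else x[i] - max(left, right)
}

#' @export
print.estimated_ep <- function(x, ...) {
  cat(sprintf("<estimated_ep> %d detected repetitions over %d samples\n",
              length(x$peaks), length(x$vector)))
  invisible(x)
}
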