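test_that("truncated pseudo-inverse keeps Moore-Penrose behaviour", {
  expect_equal(truncated_pinv(diag(3), eps = 0.5), diag(3),
               ignore_attr = TRUE)
  # small singular values are zeroed, not inverted
  A <- diag(c(1, 1e-6))
  expect_equal(truncated_pinv(A, eps = 0.05), diag(c(1, 0)),
               ignore_attr = TRUE)
  # full-rank well-conditioned matrix at eps = 0: true pseudo-inverse
  set.seed(41)
  B <- matrix(rnorm(40), 8, 5)
  expect_lt(max(abs(truncated_pinv(B, eps = 0) %*% B - diag(5))), 1e-8)
  # rank used never increases with eps
  C <- matrix(rnorm(100), 10, 10)
  ranks <- vapply(c(0, 0.01, 0.1, 0.5, 0.9),
                  function(e) attr(truncated_pinv(C, eps = e), "rank"),
                  numeric(1))
  expect_true(all(diff(ranks) <= 0))
  expect_error(truncated_pinv(diag(2), discard = 2), "discard")
})

test_that("anti-diagonal averaging inverts exact Hankel structure", {
  s <- sin(seq(0, 6, length.out = 40))
  Sh <- hankelize(matrix(s, 1), Lp = 7)
  # hankelize column n holds s(n)..s(n-6); dehankelize must return s exactly
  expect_equal(dehankelize(Sh), s, tolerance = 1e-12)
})

test_that("true filters recover the paradigm from noiseless mixtures", {
  cfg <- tiny_cfg(M = 2, L = 8, Lp = 18, K = 9, R_artifact = 0)
  sim <- tiny_sim(seed = 42, M = 2, snr_db = Inf, L = 8)
  taps <- taps_of(sim$hrfs, 0.5, 8)
  sds <- apply(sim$Y_raw, 1, sd)
  est <- estimate_sources(taps / sds, sim$Y, cfg)
  s <- canonicalize_sign(est[[1]]$series, sim$ep)
  expect_gt(ep_correlation(s, sim$ep, trim = cfg$L), 0.99)

  # linearity: scaling the data scales the estimate
  est2 <- estimate_sources(taps / sds, 3 * sim$Y, cfg)
  expect_equal(est2[[1]]$series, 3 * est[[1]]$series, tolerance = 1e-9)

  # Hankel-domain consistency at eps = 0, on the raw (un-normalized) mixture
  # and on columns with full source history: the first P - Lp columns reach
  # back before the recording starts
  P <- cfg$L + cfg$Lp
  Yh <- hankelize(sim$Y_raw, cfg$Lp)[, (P - cfg$Lp + 1):(ncol(sim$Y) - cfg$Lp + 1)]
  H <- mixing_matrix(list(taps), NULL, L = cfg$L, Lp = cfg$Lp)
  Sh <- truncated_pinv(H, eps = 0) %*% Yh
  expect_lt(norm(H %*% Sh - Yh, "F") / norm(Yh, "F"), 1e-6)
})

test_that("two sources with distinct filters separate cleanly", {
  set.seed(43)
  cfg <- tiny_cfg(M = 3, L = 8, Lp = 18, K = 9, R_artifact = 0)
  # two paradigms active on disjoint blocks (near-orthogonal sources)
  n <- 400
  s1 <- rep(0, n); s2 <- rep(0, n)
  s1[as.vector(outer(0:7, seq(10, 350, by = 80), "+"))] <- 1
  s2[as.vector(outer(0:7, seq(50, 390, by = 80), "+"))] <- 1
  taps1 <- taps_of(list(hrf_params(1, 3, 2), hrf_params(1, 6, 2.5),
                        hrf_params(1, 4, 1.5)), 0.5, 8)
  taps2 <- taps_of(list(hrf_params(1, 8, 3), hrf_params(1, 2, 1.2),
                        hrf_params(1, 10, 4)), 0.5, 8)
  Y <- t(sapply(1:3, function(m) causal_conv(taps1[m, ], s1) +
                                 causal_conv(taps2[m, ], s2)))
  est <- estimate_sources(list(taps1, taps2), Y, cfg)
  trim <- 30
  idx <- seq(trim, n)
  e1 <- est[[1]]$series[idx]; e2 <- est[[2]]$series[idx]
  expect_gt(cor(e1, s1[idx]), 0.95)
  expect_gt(cor(e2, s2[idx]), 0.95)
  expect_lt(abs(cor(e1, s2[idx])), 0.2)
  expect_lt(abs(cor(e2, s1[idx])), 0.2)
})

test_that("sign canonicalization orients sources upward", {
  sim <- tiny_sim(seed = 44, snr_db = Inf)
  clean <- sim$Y[1, ]
  expect_equal(canonicalize_sign(-clean, sim$ep), clean)
  expect_equal(canonicalize_sign(clean, sim$ep), clean)
  # blind path: positive skewness
  expect_equal(canonicalize_sign(-clean), clean)
})

test_that("paradigm binarization finds stimulus blocks from clean sources", {
  set.seed(45)
  ep <- generate_ep(n_reps = 6, stim_dur = 4, rest_range = c(10, 15), fs = 2)
  # fast, narrow response: detected half-height intervals then track the
  # stimulus blocks closely
  h <- evaluate_hrf(hrf_params(1, 2.2, 3), 0.5, 16)
  y <- causal_conv(h$values, as.numeric(ep$vector))
  best <- binarize_source(y, fs = 2)
  expect_length(best$peaks, 6)
  # every true block overlaps its detected interval (Jaccard > 0.5)
  for (r in seq_len(ep$n_reps)) {
    blk <- ep$onsets[r]:ep$offsets[r]
    jac <- vapply(seq_len(nrow(best$intervals)), function(i) {
      iv <- round(best$intervals$start_s[i] * 2 + 1):round(best$intervals$end_s[i] * 2 + 1)
      length(intersect(blk, iv)) / length(union(blk, iv))
    }, numeric(1))
    expect_gt(max(jac), 0.5)
  }
  expect_error(binarize_source(rep(1, 50), fs = 2), "constant")
  # two peaks closer than the separation: keep the larger
  x <- rep(0, 60); x[20] <- 1; x[24] <- 2
  bp <- binarize_source(x, fs = 2, min_separation = 5, min_prominence = 0.1)
  expect_equal(bp$peaks, 24)
})
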