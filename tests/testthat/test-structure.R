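test_that("block-Hankel layout stacks lagged copies region-major", {
  expect_equal(hankelize(matrix(1:4, 1), Lp = 2),
               rbind(c(2, 3, 4), c(1, 2, 3)), ignore_attr = TRUE)
  # two regions: region-1 rows first, then region-2 rows
  Y <- rbind(1:5, 11:15)
  Yh <- hankelize(Y, Lp = 2)
  expect_equal(unname(Yh[1:2, ]), rbind(c(2:5), c(1:4)))
  expect_equal(unname(Yh[3:4, ]), rbind(c(12:15), c(11:14)))
  # anti-diagonal constancy inside each region block
  set.seed(1)
  Yh2 <- hankelize(matrix(rnorm(30), 1), Lp = 5)
  for (j in 1:(ncol(Yh2) - 1)) {
    expect_equal(Yh2[1:4, j], Yh2[2:5, j + 1])
  }
  expect_error(hankelize(matrix(1:4, 1), Lp = 4), "smaller")
})

test_that("Toeplitz blocks carry the filter taps along shifted bands", {
  expect_equal(unname(toeplitz_block(c(1, 2), Lp = 2)),
               rbind(c(1, 2, 0), c(0, 1, 2)))
  # artifact block: scaled banded identity
  A <- toeplitz_block(c(3, 0, 0), Lp = 2)
  expect_equal(unname(A), rbind(c(3, 0, 0, 0), c(0, 3, 0, 0)))
})

test_that("the convolutive mixture factorizes as Y = H S exactly", {
  set.seed(7)
  cfg <- tiny_cfg(M = 3, L = 8, Lp = 12, K = 9)
  sim <- tiny_sim(seed = 7, M = 3, snr_db = 0, L = 8)
  P <- cfg$L + cfg$Lp
  taps <- taps_of(sim$hrfs, 0.5, 8)
  S <- rbind(as.numeric(sim$ep$vector), sim$artifact)
  Yh <- hankelize(sim$Y_raw, cfg$Lp)
  Sh <- hankelize(S, P)
  Yh_t <- Yh[, (P - cfg$Lp + 1):ncol(Yh)]
  H <- mixing_matrix(list(taps), list(sim$artifact_gains), L = cfg$L, Lp = cfg$Lp)
  expect_lt(max(abs(Yh_t - H %*% Sh)), 1e-10)

  # ... and so does the autocorrelation tensor, slice by slice
  Tt <- autocorr_tensor(Yh_t, cfg$K)
  Ts <- autocorr_tensor(Sh, cfg$K)
  model <- array(0, dim(Tt))
  for (k in seq_len(cfg$K)) model[, , k] <- H %*% Ts[, , k] %*% t(H)
  expect_lt(sqrt(sum((Tt - model)^2) / sum(Tt^2)), 1e-6)
})

test_that("autocorrelation estimator has the stated normalization and symmetry", {
  set.seed(2)
  # unit-variance scalar series: lag-0 slice is ~1 (z-scored, K = 1)
  x <- rnorm(5000); x <- (x - mean(x)) / sd(x)
  T1 <- autocorr_tensor(hankelize(matrix(x, 1), 1), K = 1)
  expect_equal(as.numeric(T1[, , 1]), 1, tolerance = 1e-3)

  # white noise: lag-0 slice near identity, higher-lag slices near zero
  Yh <- hankelize(matrix(rnorm(1e5), 1), Lp = 3)
  Tw <- autocorr_tensor(Yh, K = 3)
  expect_lt(max(abs(Tw[, , 1] - diag(3))), 0.02)
  expect_lt(max(abs(Tw[2, 2, 2:3])), 0.02)

  # lag-0 slice is exactly symmetric
  Yh2 <- hankelize(matrix(rnorm(500), 2), Lp = 4)
  T2 <- autocorr_tensor(Yh2, K = 3)
  expect_identical(T2[, , 1], t(T2[, , 1]))

  # duplicated regions: cross-blocks equal auto-blocks
  y <- rnorm(300)
  Td <- autocorr_tensor(hankelize(rbind(y, y), Lp = 3), K = 2)
  expect_equal(Td[1:3, 4:6, ], Td[1:3, 1:3, ])

  expect_error(autocorr_tensor(hankelize(matrix(1:10, 1), 2), K = 20), "K must")
})

test_that("lambda operator produces lag-shifted Toeplitz slices", {
  P <- 5; K <- 3
  # unit impulse generator: identity first slice, shifted bands after
  C <- lambda_op(c(1, rep(0, P + K - 2)), P, K)
  expect_equal(C[, , 1], diag(P))
  expect_equal(C[, , 2], rbind(cbind(rep(0, P - 1), diag(P - 1)), 0))

  set.seed(3)
  z <- rnorm(P + K - 1)
  Cz <- lambda_op(z, P, K)
  # every slice is Toeplitz: constant along diagonals
  for (k in 1:K) {
    for (d in -(P - 2):(P - 2)) {
      dg <- Cz[, , k][col(Cz[, , k]) - row(Cz[, , k]) == d]
      expect_equal(diff(dg), rep(0, length(dg) - 1))
    }
  }
  # slice k+1 is the one-step lag shift of slice k
  for (k in 1:(K - 1)) {
    expect_equal(Cz[, 2:P, k + 1], Cz[, 1:(P - 1), k])
  }
  expect_error(lambda_op(rnorm(3), P = 5, K = 3), "too short")
})

test_that("cores built from sample autocorrelations match the tensor estimator", {
  set.seed(4)
  # an AR(1) source: Hankelize, and compare the empirical tensor with the
  # lambda core generated from the scalar sample autocorrelation
  n <- 2e4
  s <- as.numeric(stats::arima.sim(list(ar = 0.6), n))
  P <- 4; K <- 3
  Sh <- hankelize(matrix(s, 1), P)
  Ts <- autocorr_tensor(Sh, K)
  z <- empirical_autocorr(s, P + K - 1, divisor = length(s))
  Cz <- lambda_op(z, P, K)
  expect_lt(max(abs(Ts - Cz)), 0.05)
})

test_that("uncorrelated sources leave vanishing cross-blocks", {
  set.seed(5)
  err_at <- function(n) {
    s1 <- rnorm(n); s2 <- rnorm(n)
    Sh <- hankelize(rbind(s1, s2), 3)
    Ts <- autocorr_tensor(Sh, 2)
    max(abs(Ts[1:3, 4:6, ]))
  }
  e1 <- mean(replicate(5, err_at(1000)))
  e2 <- mean(replicate(5, err_at(16000)))
  # 16x more data should shrink the cross-blocks about 4-fold
  expect_lt(e2, e1 / 2)
})
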