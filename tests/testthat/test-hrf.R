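test_that("gamma HRF evaluates to its closed form on the sampling grid", {
  # theta2 = 1 collapses the gamma to a pure exponential decay
  h <- evaluate_hrf(hrf_params(1, 1, 1), dt = 1, L = 2)
  expect_equal(h$values, c(1, exp(-1), exp(-2)))

  # theta1 is a pure scale
  h2 <- evaluate_hrf(hrf_params(2, 3, 1), dt = 0.5, L = 16)
  h1 <- evaluate_hrf(hrf_params(1, 3, 1), dt = 0.5, L = 16)
  expect_identical(h2$values, 2 * h1$values)

  # shape parameters above 1 start the curve at zero
  expect_identical(evaluate_hrf(hrf_params(1, 5, 2), dt = 0.5, L = 4)$values[1], 0)

  expect_error(hrf_params(1, 0, 1), "positive")
  expect_error(hrf_params(-1, 2, 1), "positive")
})

test_that("peak latency matches the analytic gamma mode and breaks ties early", {
  expect_equal(peak_latency(evaluate_hrf(hrf_params(1, 15, 5), dt = 0.1, L = 100)),
               2.8)
  expect_equal(peak_latency(evaluate_hrf(hrf_params(0.7, 9, 4), dt = 0.25, L = 40)),
               2.0)
  # monotone decreasing curve peaks at the first tap
  expect_equal(peak_latency(evaluate_hrf(hrf_params(1, 1, 1), dt = 0.5, L = 10)), 0)
  # ties break to the earliest sample
  expect_equal(peak_latency(c(0, 1, 1, 0), dt = 1), 1)
  expect_error(peak_latency(rep(0, 5), dt = 1), "all-zero")
})

test_that("analytic mode property: PL converges to (theta2 - 1)/theta3", {
  set.seed(41)
  for (i in 1:20) {
    th2 <- runif(1, 1.5, 20); th3 <- runif(1, 0.5, 6)
    mode <- (th2 - 1) / th3
    dt <- 0.01
    L <- ceiling((mode + 5) / dt)
    expect_lt(abs(peak_latency(evaluate_hrf(hrf_params(1, th2, th3), dt, L)) - mode),
              dt)
  }
})

test_that("FWHM interpolates half-max crossings and flags truncation", {
  # box of height 1 over [1, 3] s: width 2 s in the fine-grid limit
  dt <- 0.01
  t <- seq(0, 5, by = dt)
  box <- as.numeric(t >= 1 & t <= 3)
  expect_lt(abs(hrf_fwhm(box, dt = dt) - 2), 2.5 * dt)

  # dense numerical oracle: scan the continuous gamma curve for half-max
  # crossings at very fine resolution
  th <- c(1, 15, 5)
  tt <- seq(0, 12, by = 1e-4)
  curve <- th[1] * exp(th[2] * log(th[3]) - lgamma(th[2]) +
                         (th[2] - 1) * log(pmax(tt, 1e-300)) - th[3] * tt)
  curve[1] <- 0
  above <- which(curve >= max(curve) / 2)
  oracle <- (max(above) - min(above)) * 1e-4
  got <- hrf_fwhm(evaluate_hrf(hrf_params(th[1], th[2], th[3]), dt = 0.01, L = 1200))
  expect_lt(abs(got - oracle), 0.02)

  # degenerate flat curve: window-clipped width with a warning
  expect_warning(w <- hrf_fwhm(rep(1, 11), dt = 0.5), "window")
  expect_equal(w, 5)
})

test_that("random HRF draws satisfy their PL/FWHM/amplitude constraints", {
  set.seed(7)
  dt <- 0.5; L <- 16
  for (i in 1:200) {
    p <- sample_random_hrf(c(0.25, 4.5), c(0.5, 4.5), c(0.2, 1), dt = dt, L = L)
    h <- evaluate_hrf(p, dt, L)
    pl <- peak_latency(h)
    expect_gte(pl, 0.25); expect_lte(pl, 4.5)
    fw <- suppressWarnings(hrf_fwhm(h))
    expect_gte(fw, 0.5); expect_lte(fw, 4.5)
    expect_lte(max(h$values), 1 + 1e-12)
  }
})

test_that("random HRF draws hit point constraints exactly", {
  set.seed(8)
  # pinned amplitude is met exactly by the theta1 rescaling
  p <- sample_random_hrf(amp_range = c(0.5, 0.5), dt = 0.5, L = 16)
  expect_equal(max(evaluate_hrf(p, 0.5, 16)$values), 0.5)
  # pinned peak latency is met on the sampling grid
  p2 <- sample_random_hrf(pl_range = c(2.8, 2.8), fwhm_range = c(0.5, 6),
                          dt = 0.1, L = 100)
  expect_lt(abs(peak_latency(evaluate_hrf(p2, 0.1, 100)) - 2.8), 0.05 + 1e-9)
  # an unsatisfiable request exhausts the rejection budget
  expect_error(sample_random_hrf(pl_range = c(40, 41), dt = 0.5, L = 16,
                                 max_tries = 50), "budget")
})
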