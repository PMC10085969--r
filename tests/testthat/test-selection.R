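test_that("cost filtering separates outlier restarts like an exhaustive Otsu", {
  expect_equal(filter_by_cost(c(1, 1, 1, 100)), 1:3)
  expect_equal(filter_by_cost(c(5, 5, 5, 5)), 1:4)

  # exhaustive threshold-sweep oracle maximizing between-class variance
  otsu_oracle <- function(x) {
    cand <- sort(unique(x))
    best <- -Inf; thr <- cand[1]
    for (t in cand[-length(cand)]) {
      lo <- x[x <= t]; hi <- x[x > t]
      w <- length(lo) / length(x)
      bc <- w * (1 - w) * (mean(lo) - mean(hi))^2
      if (bc > best) { best <- bc; thr <- t }
    }
    which(x <= thr)
  }
  set.seed(21)
  for (i in 1:20) {
    x <- c(rnorm(12, 10, 0.5), rnorm(5, 100, 3))[sample(17)]
    expect_equal(filter_by_cost(x), otsu_oracle(x))
  }

  # non-finite costs (failed runs) are always dropped
  expect_equal(filter_by_cost(c(1, 1.1, Inf, 0.9, 100)), c(1, 2, 4))
})

test_that("intracluster distance follows the diameter-over-size rule", {
  # single member: zero numerator
  rep1 <- cluster_solutions(matrix(c(1, 2), 1), t_cut = 0.5)
  expect_equal(rep1$clusters$d_c, 0)
  # two members at distance d: d_C = d / 2
  pl <- rbind(c(1, 2), c(1.3, 2.4))
  d <- sqrt(0.09 + 0.16)
  rep2 <- cluster_solutions(pl, t_cut = 1)
  expect_equal(rep2$clusters$d_c, d / 2)

  # 8 near-identical + 2 scattered: the tight frequent cluster wins
  set.seed(22)
  pl8 <- rbind(matrix(rep(c(1, 2, 3), each = 8), 8) + rnorm(24, 0, 0.02),
               c(4, 1, 0.5), c(0.2, 4.4, 2))
  rep3 <- cluster_solutions(pl8, t_cut = 0.5)
  expect_equal(sort(which(rep3$labels == rep3$winner)), 1:8)

  # among equal diameters, the larger cluster wins
  plt <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0), c(10.5, 0))
  rept <- cluster_solutions(plt, t_cut = 2)
  expect_equal(sum(rept$labels == rept$winner), 3)
})

test_that("winner averaging and idempotence of the selection", {
  set.seed(23)
  cfg <- tiny_cfg(maxit = 40)
  sim <- tiny_sim(seed = 23, snr_db = 10)
  T <- autocorr_tensor(hankelize(sim$Y, cfg$Lp), cfg$K)
  sols <- run_btd_multi(T, cfg, n_runs = 6, seed = 2)

  sel <- select_stable(sols, t_cut = 0.5)
  f <- sel$final_hrfs
  # identical members average to any member; here: mean curve PL lies inside
  # the members' PL range per region
  pls <- t(vapply(sel$members, function(i) solution_pl(sols[[i]]),
                  numeric(cfg$M)))
  expect_true(all(f$pl >= apply(pls, 2, min) - 1e-9))
  expect_true(all(f$pl <= apply(pls, 2, max) + 1e-9))

  # re-running the selection on the winner's members reproduces the curves
  sel2 <- select_stable(sols[sel$members], t_cut = 0.5)
  expect_equal(sel2$final_hrfs$curves, f$curves, tolerance = 1e-12)

  # an injected high-cost outlier run never changes the winner
  out <- sols[[1]]
  out$cost <- 10 * max(vapply(sols, `[[`, numeric(1), "cost"))
  out$thetas[[1]][, 2] <- 20
  sel3 <- select_stable(c(sols, list(out)), t_cut = 0.5)
  expect_equal(sel3$final_hrfs$curves, f$curves, tolerance = 1e-12)
})

test_that("explicit averaging identities hold", {
  cfg <- tiny_cfg()
  mk_sol <- function(th) {
    structure(list(thetas = list(th), gains = list(c(1, 1)),
                   Z = NULL, cost = 1, failed = FALSE, cfg = cfg),
              class = "btd_solution")
  }
  th_a <- rbind(c(1, 3, 2), c(1, 5, 2))
  th_b <- rbind(c(1, 4, 2), c(1, 6, 2))
  f_same <- finalize_hrfs(list(mk_sol(th_a), mk_sol(th_a)), 1:2)
  expect_equal(f_same$curves[1, ], theta_curve(th_a[1, ], cfg))
  f_mid <- finalize_hrfs(list(mk_sol(th_a), mk_sol(th_b)), 1:2)
  expect_equal(f_mid$curves[2, ],
               (theta_curve(th_a[2, ], cfg) + theta_curve(th_b[2, ], cfg)) / 2)
  expect_equal(f_mid$theta_mean, (th_a + th_b) / 2)
})
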