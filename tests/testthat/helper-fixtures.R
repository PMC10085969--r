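# Shared fixtures: everything is generated in code at test time.

# small, fast solver configuration for unit tests
tiny_cfg <- function(M = 2, L = 4, Lp = 6, K = 5, ...) {
  btd_config(M = M, fs = 2, L = L, Lp = Lp, K = K, ...)
}

# deterministic tiny dataset: known HRFs, short paradigm
tiny_sim <- function(seed = 1, M = 2, snr_db = Inf, L = 4, n_reps = 8) {
  set.seed(seed)
  ep <- generate_ep(n_reps = n_reps, stim_dur = 4, rest_range = c(10, 15), fs = 2)
  hrfs <- list(hrf_params(1, 3, 2), hrf_params(0.7, 6, 2.5),
               hrf_params(0.9, 4, 1.5))[seq_len(M)]
  simulate_dataset(M = M, snr_db = snr_db, fs = 2, L = L, ep = ep, hrfs = hrfs)
}

# exact model tensor built from given factors (for solver oracles)
exact_tensor <- function(taps, gains, z_task, z_art, cfg) {
  P <- cfg$L + cfg$Lp
  H <- mixing_matrix(list(taps), if (is.null(gains)) NULL else list(gains),
                     L = cfg$L, Lp = cfg$Lp)
  Ct <- lambda_op(z_task, P, cfg$K)
  T <- array(0, c(cfg$M * cfg$Lp, cfg$M * cfg$Lp, cfg$K))
  H1 <- H[, seq_len(P), drop = FALSE]
  for (k in seq_len(cfg$K)) T[, , k] <- H1 %*% Ct[, , k] %*% t(H1)
  if (!is.null(gains)) {
    Ca <- lambda_op(z_art, P, cfg$K)
    H2 <- H[, P + seq_len(P), drop = FALSE]
    for (k in seq_len(cfg$K)) T[, , k] <- T[, , k] + H2 %*% Ca[, , k] %*% t(H2)
  }
  T
}

theta_curve <- function(theta, cfg) {
  evaluate_hrf(hrf_params(theta[1], theta[2], theta[3]), cfg$dt, cfg$L)$values
}

taps_of <- function(hrfs, dt, L) {
  t(vapply(hrfs, function(p) evaluate_hrf(p, dt, L)$values, numeric(L + 1)))
}
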