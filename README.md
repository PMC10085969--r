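# fusdeconv

Blind deconvolution of multivariate hemodynamic time series — as measured by
functional ultrasound (fUS) power-Doppler imaging — into region-specific
hemodynamic response functions (HRFs) and latent source signals.

## The problem

An fUS recording gives one cerebral-blood-volume time series per region of
interest (ROI), sampled at a few hertz. Each series is modelled as a
convolutive mixture

    y_m(t) = Σ_{r∈T} Σ_l h_mr(l) s_r(t−l)  +  Σ_{r∈A} a_mr s_r(t),

where task sources (`T`, e.g. the stimulus paradigm) drive every region
through a region-specific single-gamma HRF

    h(t;θ) = θ1 Γ(θ2)^{-1} θ3^{θ2} t^{θ2−1} e^{−θ3 t},

and artifact sources (`A`, motion/physiology/instrumentation) add in
directly with per-region gains. Neither the sources nor the filters are
known: the package recovers both from second-order statistics alone, so the
stimulus timing is *not* required — it is an output.

## The method

1. Stack lagged copies of the data into a block-Hankel matrix; convolution
   becomes `Y = H S` with a Toeplitz-block mixing matrix `H`.
2. Stack lagged autocorrelation matrices `R_y(τ), τ = 0..K−1` into a tensor
   and fit a structured block-term decomposition (BTD): one
   `(L+L', L+L', ·)` term per source, with gamma-parametrized task blocks,
   impulse artifact blocks, and shift-structured Toeplitz core tensors
   (`λ(z_r)`), by quasi-Newton descent on

   `J = ‖T − Σ_r λ(z_r) ×₁ H_r ×₂ H_r‖²_F`.

3. Run many random restarts, drop the high-cost ones (Otsu threshold), and
   cluster the rest on their HRF peak latencies; the tightest,
   most-revisited cluster wins and its members are averaged (an
   Icasso-style stability selection).
4. Recover the sources by truncated-SVD pseudo-inversion of the rebuilt
   mixing matrix, and optionally binarize the task source back into an
   estimated stimulus paradigm.

A simulator reproducing the evaluated study conditions (20 × 4 s stimuli
with random 10–15 s rests at 2 Hz, gamma HRFs with peak latency in
[0.25, 4.5] s and FWHM in [0.5, 4.5] s, additive artifact at controlled
SNR), the evaluation metrics (paradigm correlation, peak-latency error,
Fano factor, thresholded correlation images) and power-Doppler
preprocessing utilities (SVD clutter filtering, ROI averaging) are
included.

## Worked example

Simulate three ROIs at 0 dB SNR and deconvolve them blindly:

```r
library(fusdeconv)

set.seed(101)
sim <- simulate_dataset(M = 3, snr_db = 0, fs = 2, L = 16)
cfg <- btd_config(M = 3, fs = 2, L = 16)      # 8 s filter, L' = 34, K = 17
fit <- fus_deconvolve(sim, cfg = cfg, seed = 1)

tidy(fit)        # per-region HRF parameters, peak latency, FWHM
glance(fit)      # restart/selection bookkeeping
```

```
#> # A tibble: 3 x 6
#>   region theta1 theta2 theta3 peak_latency  fwhm
#>   <chr>   <dbl>  <dbl>  <dbl>        <dbl> <dbl>
#> 1 ROI1    0.530   4.99   3.56          1   1.34
#> 2 ROI2    0.532   4.57   3.32          1   1.35
#> 3 ROI3    0.717   1.04   1.07          0.5 0.963
#>
#> # A tibble: 1 x 5
#>   n_runs n_retained n_winner best_cost winner_mean_cost
#>    <int>      <int>    <int>     <dbl>            <dbl>
#> 1     20         19        4      4.90             18.4
```

`peak_latency` is each region's time-to-peak in seconds — the ground truth
in this draw is 1.5, 1.5 and 0.5 s, so two regions land one 0.5 s sample
early at 0 dB SNR — and `fwhm` its width. 4 of 20 restarts formed the
winning stability cluster. Compare the recovered source with the
(withheld) paradigm and reconstruct the stimulus timing:

```r
ep_correlation(fit$source, sim$ep, trim = cfg$L)
#> [1] 0.7930832

# stimuli repeat every >= 14 s; at 0 dB a full-SD prominence is appropriate
binarize_source(fit$source, fs = 2, min_separation = 10,
                min_prominence = sd(fit$source))
#> <estimated_ep> 20 detected repetitions over 660 samples
```

The detected intervals overlap 19 of the 20 true stimulus repetitions.

`autoplot(fit)` draws the recovered HRFs, `autoplot(sim)` the simulated
series; `run_monte_carlo()` / `summarize_monte_carlo()` repeat the whole
cycle across seeds and SNRs.

For real acquisitions, build ROI series with `pdi_stream()` (SVD clutter
filtering + per-pixel power over 200-frame ensembles) and `roi_average()`,
then call `fus_deconvolve()` on the resulting matrix with
`btd_config(M, fs = 4, L = 32)`.

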