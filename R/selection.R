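#' Otsu threshold of a numeric sample
#'
#' Histogram-based Otsu threshold (256 bins over the min-max range),
#' maximizing between-class variance, as used for grey-level image
#' binarization. Returns the threshold on the original scale.
#'
#' @param x Numeric vector (`length >= 2`).
#' @param n_bins Histogram resolution.
#' @return Threshold value, or `NA` when `x` is constant.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  stopifnot(length(x) >= 2)
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  u <- (x - rng[1]) / diff(rng)
  counts <- tabulate(pmin(n_bins, floor(u * n_bins) + 1L), nbins = n_bins)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5) / n_bins)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  rng[1] + diff(rng) * k / n_bins
}

#' Drop high-cost restarts by Otsu thresholding
#'
#' Separates the restart costs into a low- and a high-cost class with an Otsu
#' threshold on the min-max-scaled costs, keeping the low class: the stable
#' solution is expected among the low-cost restarts, while runs stuck in poor
#' local minima show clearly elevated costs. Failed runs (non-finite cost)
#' are always dropped. If the threshold degenerates (all costs equal) every
#' run is retained.
#'
#' @param solutions List of `btd_solution` from [run_btd_multi()], or a bare
#'   numeric vector of costs.
#' @return Integer indices of the retained runs.
#' @export
filter_by_cost <- function(solutions) {
  costs <- if (is.numeric(solutions)) solutions
           else vapply(solutions, `[[`, numeric(1), "cost")
  stopifnot(length(costs) >= 2)
  ok <- which(is.finite(costs))
  if (length(ok) < 2) stop("fewer than two usable restarts", call. = FALSE)
  # a run is eliminated only when its cost is *significantly* higher: with a
  # homogeneous cost set (relative spread below 10%) there are no outliers
  # and thresholding noise would arbitrarily split near-ties
  spread <- diff(range(costs[ok])) / max(abs(costs[ok]))
  if (!is.finite(spread) || spread < 0.1) return(ok)
  thr <- otsu_threshold(costs[ok])
  retained <- if (is.na(thr)) ok else ok[costs[ok] <= thr]
  if (length(retained) < 2) {
    stop("cost filtering retained fewer than two runs", call. = FALSE)
  }
  retained
}

#' Cluster retained restarts on their HRF peak latencies
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance) of the restarts' per-region peak-latency vectors, cut at height
#' `t_cut` seconds. Each cluster is scored by its complete diameter (largest
#' intra-cluster pairwise distance) divided by its size, so the winning
#' cluster is simultaneously tight and frequently revisited; ties prefer the
#' larger cluster, then the lower mean cost.
#'
#' @param pl Matrix of peak latencies, retained runs in rows, regions in
#'   columns.
#' @param t_cut Cut height in seconds.
#' @param costs Optional per-run costs (tie-breaking).
#' @param d_floor Resolution floor on the diameter of multi-member clusters
#'   (seconds). Peak latencies measured on a sampling grid cannot separate
#'   solutions more finely than one grid step, so restarts that converge to
#'   the same grid point would otherwise form zero-diameter clusters that
#'   beat any larger, slightly jittered cluster. The pipeline sets this to
#'   the sampling interval; the default 0 reproduces the raw
#'   diameter-over-size values.
#' @return A list of class `cluster_report`: `labels`, tibble `clusters`
#'   (`cluster`, `n`, `diameter`, `d_c`, `mean_cost`), and `winner`.
#' @export
cluster_solutions <- function(pl, t_cut = 0.5, costs = NULL, d_floor = 0) {
  pl <- as.matrix(pl)
  n <- nrow(pl)
  if (is.null(costs)) costs <- rep(NA_real_, n)
  if (n == 1) {
    labels <- 1L
  } else {
    labels <- cutree(hclust(dist(pl), method = "complete"), h = t_cut)
  }
  D <- as.matrix(dist(pl))
  info <- lapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    diam <- if (length(idx) == 1) 0 else max(max(D[idx, idx]), d_floor)
    tibble(cluster = cl, n = length(idx), diameter = diam,
           d_c = diam / length(idx), mean_cost = mean(costs[idx]))
  })
  clusters <- dplyr::bind_rows(info)
  # a run that lands in no multi-member cluster is an unreliable stray, so
  # singletons are only eligible when every cluster is a singleton
  eligible <- if (any(clusters$n >= 2)) clusters$n >= 2 else rep(TRUE, nrow(clusters))
  ord <- order(!eligible, clusters$d_c, -clusters$n, clusters$mean_cost)
  winner <- clusters$cluster[ord[1]]
  structure(list(labels = labels, clusters = clusters, winner = winner),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d runs in %d clusters; winner: cluster %d (n = %d)\n",
              length(x$labels), nrow(x$clusters), x$winner,
              x$clusters$n[x$clusters$cluster == x$winner]))
  invisible(x)
}

#' @export
tidy.cluster_report <- function(x, ...) x$clusters

#' Average the winning cluster's HRF estimates
#'
#' Pointwise mean of the member restarts' sampled HRF curves per region
#' (the final estimate), together with the mean of the member gamma
#' parameters and their dispersion.
#'
#' @param solutions Full solution list.
#' @param members Indices (into `solutions`) of the winning cluster's runs.
#' @param source Task-source index to summarize.
#' @return A list of class `final_hrfs`: `curves` (`M x (L+1)` matrix),
#'   `dt`, `pl` (per-region peak latency of the mean curves), `fwhm`,
#'   `theta_mean`, `theta_sd`, `members`.
#' @export
finalize_hrfs <- function(solutions, members, source = 1L) {
  stopifnot(length(members) >= 1)
  cfg <- solutions[[members[1]]]$cfg
  curves_by_run <- lapply(members, function(i) {
    th <- solutions[[i]]$thetas[[source]]
    t(apply(th, 1, theta_taps, dt = cfg$dt, L = cfg$L))
  })
  curves <- Reduce(`+`, curves_by_run) / length(members)
  thetas <- lapply(members, function(i) solutions[[i]]$thetas[[source]])
  theta_mean <- Reduce(`+`, thetas) / length(thetas)
  theta_sd <- sqrt(Reduce(`+`, lapply(thetas, function(x) (x - theta_mean)^2)) /
                     max(1, length(thetas) - 1))
  pl <- apply(curves, 1, function(v) cfg$dt * (which.max(v) - 1))
  fw <- apply(curves, 1, function(v) {
    tryCatch(suppressWarnings(hrf_fwhm(v, dt = cfg$dt)),
             error = function(e) NA_real_)
  })
  # artifact gains: each run determines them up to sign (a, s) -> (-a, -s);
  # orient each run's gain vector by its largest-magnitude entry, then average
  gains <- if (cfg$R_artifact > 0) {
    lapply(seq_len(cfg$R_artifact), function(r) {
      gs <- lapply(members, function(i) {
        a <- solutions[[i]]$gains[[r]]
        if (a[which.max(abs(a))] < 0) -a else a
      })
      Reduce(`+`, gs) / length(gs)
    })
  } else NULL
  structure(list(curves = curves, dt = cfg$dt, pl = pl, fwhm = fw,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 gains = gains, members = members, cfg = cfg),
            class = "final_hrfs")
}

#' @export
print.final_hrfs <- function(x, ...) {
  cat(sprintf("<final_hrfs> %d regions, mean over %d runs; PL = %s s\n",
              nrow(x$curves), length(x$members),
              paste(signif(x$pl, 3), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.final_hrfs <- function(x, ...) {
  M <- nrow(x$curves)
  tibble(region = rep(paste0("ROI", seq_len(M)), each = ncol(x$curves)),
         time = rep((seq_len(ncol(x$curves)) - 1) * x$dt, M),
         value = as.numeric(t(x$curves)))
}

#' @export
autoplot.final_hrfs <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$value,
                                 colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "HRF amplitude", colour = NULL)
}

#' Stable estimate from a set of restarts
#'
#' Runs the full selection procedure: cost filtering ([filter_by_cost()]),
#' peak-latency clustering ([cluster_solutions()]), and averaging of the
#' winning cluster ([finalize_hrfs()]).
#'
#' @param solutions List of `btd_solution`.
#' @param t_cut Dendrogram cut height (seconds).
#' @param source Task-source index used for the peak-latency features.
#' @return A list of class `stable_estimate`: `final_hrfs`, `report`
#'   (`cluster_report`), `retained`, `members` (indices into `solutions`).
#' @export
select_stable <- function(solutions, t_cut = 0.5, source = 1L) {
  retained <- filter_by_cost(solutions)
  pl <- t(vapply(solutions[retained], solution_pl,
                 numeric(solutions[[retained[1]]]$cfg$M), source = source))
  costs <- vapply(solutions[retained], `[[`, numeric(1), "cost")
  report <- cluster_solutions(pl, t_cut = t_cut, costs = costs,
                              d_floor = solutions[[retained[1]]]$cfg$dt)
  members <- retained[report$labels == report$winner]
  structure(list(final_hrfs = finalize_hrfs(solutions, members, source),
                 report = report, retained = retained, members = members),
            class = "stable_estimate")
}

#' @export
print.stable_estimate <- function(x, ...) {
  cat(sprintf("<stable_estimate> %d/%d runs retained; winner cluster n = %d\n",
              length(x$retained), length(x$retained), length(x$members)))
  print(x$final_hrfs)
  invisible(x)
}
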