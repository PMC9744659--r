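#' Time-rescaling transform of a spike train
#'
#' Maps spike times through the cumulative fitted intensity
#' `Lambda(t) = integral_0^t lambda(s) ds` (trapezoid rule on the bin grid).
#' Under a correctly specified model the rescaled inter-spike intervals
#' `u_i = Lambda(s_i) - Lambda(s_{i-1})` are unit-exponential, truncated by
#' the per-trial total `Lambda(T)`.
#'
#' @param times spike times (ms) within `[0, T]`, one trial.
#' @param intensity fitted rate (spikes/s for the train being rescaled) on
#'   the bin-midpoint grid; must be strictly positive.
#' @param T,bin_width window and bin width in ms.
#' @return list with `u` (rescaled intervals) and `Lambda_T` (total rescaled
#'   trial length).
#' @export
time_rescale <- function(times, intensity, T = 500, bin_width = 2) {
  if (any(intensity <= 0)) stop("intensity must be strictly positive")
  mid <- seq(bin_width / 2, T - bin_width / 2, by = bin_width)
  grid_t <- c(0, mid, T)
  grid_v <- c(intensity[1], intensity, intensity[length(intensity)]) / 1000  # per ms
  Lam <- c(0, cumsum(diff(grid_t) * (utils::head(grid_v, -1) + utils::tail(grid_v, -1)) / 2))
  Lam_at <- function(t) stats::approx(grid_t, Lam, xout = t, rule = 2)$y
  s <- sort(times)
  list(u = diff(c(0, Lam_at(s))), Lambda_T = Lam[length(Lam)])
}

#' KS test of rescaled intervals against a truncation-corrected null
#'
#' Because inter-spike intervals cannot exceed the rescaled trial length,
#' the unit-exponential null is biased for short trials. The corrected null
#' is the mixture, over trials, of unit exponentials truncated at the
#' per-trial `Lambda(T)` (weighted by each trial's interval count); the 95%
#' acceptance band is obtained by Monte Carlo from that corrected null.
#'
#' @param intervals list (one element per trial) of rescaled intervals.
#' @param Lambda_T numeric vector of per-trial rescaled lengths.
#' @param n_mc Monte-Carlo replicates for the band.
#' @param level band level.
#' @param seed RNG seed for the band simulation.
#' @return list with `statistic` (KS distance of the pooled empirical CDF
#'   from the corrected null CDF), `band` (Monte-Carlo critical value),
#'   `within_band`, `n_intervals`, and the `null_cdf` function.
#' @export
ks_test_corrected <- function(intervals, Lambda_T, n_mc = 500, level = 0.95,
                              seed = 1L) {
  n_r <- vapply(intervals, length, integer(1))
  keep <- n_r > 0
  intervals <- intervals[keep]; Lambda_T <- Lambda_T[keep]; n_r <- n_r[keep]
  u <- unlist(intervals)
  if (length(u) < 10) warning("fewer than 10 intervals; KS test has low power")
  wt <- n_r / sum(n_r)
  null_cdf <- function(x) {
    sapply(x, function(xi) {
      sum(wt * (1 - exp(-pmin(xi, Lambda_T))) / (1 - exp(-Lambda_T)))
    })
  }
  ks_of <- function(v) {
    v <- sort(v); n <- length(v)
    Fv <- null_cdf(v)
    max(abs(Fv - seq_len(n) / n), abs(Fv - (seq_len(n) - 1) / n))
  }
  stat <- ks_of(u)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_stats <- replicate(n_mc, {
    sim <- unlist(lapply(seq_along(n_r), function(r) {
      # inverse-CDF draw from Exp(1) truncated at Lambda_T[r]
      -log(1 - stats::runif(n_r[r]) * (1 - exp(-Lambda_T[r])))
    }))
    ks_of(sim)
  })
  band <- unname(stats::quantile(null_stats, level))
  list(statistic = stat, band = band, within_band = stat <= band,
       n_intervals = length(u), null_cdf = null_cdf)
}

# posterior-median pop intensity per trial (spikes/s for the merged group)
.fitted_pop_intensity <- function(chain, ai, ci, n_pop) {
  basis <- chain$basis
  beta <- apply(chain$draws$beta_pop[, , ai, ci, drop = FALSE], 2, stats::median)
  q_med <- apply(chain$draws$q[, ci, , , drop = FALSE], c(3, 4), stats::median)
  spec <- chain$specs[[ai]][[ci]]
  f <- drop(basis$B %*% beta)
  lapply(seq_len(chain$R), function(rr) {
    qi <- 3 * (ai - 1) + 1:3
    w <- build_warp(spec, .clip_dom(q_med[rr, qi[2]], spec, 1),
                    .clip_dom(q_med[rr, qi[3]], spec, 2))
    tw <- warp_time(w, basis$times, inverse = TRUE)
    fw <- stats::approx(basis$times, f, xout = tw, rule = 2)$y
    n_pop * exp(fw + q_med[rr, qi[1]])
  })
}

.clip_dom <- function(x, spec, peak) {
  dom <- shift_domain(spec, margin = 2)
  min(max(x, dom[peak, 1]), dom[peak, 2])
}

#' Fitted-versus-empirical PSTH discrepancy
#'
#' Averages the fitted population intensity over trials (posterior medians)
#' and compares it with the PSTH of the inferred interacting-population
#' neurons, reporting the integrated absolute discrepancy per area.
#'
#' @param dataset the fitted [spike_dataset()].
#' @param chain an `iprf_chain` from [iprf_gibbs()].
#' @param condition condition id.
#' @param pop_threshold posterior pop-membership frequency above which a
#'   neuron counts as a population member.
#' @return data frame per area: `area`, `n_pop`, `discrepancy` (integral of
#'   the absolute difference of the two per-neuron rate curves, in spikes),
#'   plus the two curves as list columns `fitted` and `empirical`.
#' @export
psth_overlay <- function(dataset, chain, condition, pop_threshold = 0.5) {
  ci <- match(as.character(condition), chain$conditions)
  basis <- chain$basis
  out <- lapply(seq_along(chain$areas), function(ai) {
    a <- chain$areas[ai]
    pop_ids <- dataset$neurons[[a]][chain$z_pop_freq[[a]][, ci] >= pop_threshold]
    if (length(pop_ids) == 0)
      return(data.frame(area = a, n_pop = 0L, discrepancy = NA_real_))
    emp <- psth(dataset, pop_ids, condition, basis$bin_width)
    lam <- .fitted_pop_intensity(chain, ai, ci, length(pop_ids))
    fitted <- Reduce(`+`, lam) / length(lam) / length(pop_ids)
    d <- data.frame(area = a, n_pop = length(pop_ids),
                    discrepancy = sum(abs(fitted - emp)) * basis$dt_s)
    d$fitted <- list(fitted); d$empirical <- list(emp)
    d
  })
  do.call(rbind, out)
}

#' Spike-count correlations: data versus model
#'
#' Empirical: the Pearson correlation of per-trial window spike counts for
#' every cross-area pair of interacting-population neurons, computed within
#' condition and pooled across conditions. Model: the same statistic on spike
#' counts simulated from posterior draws of the fitted model.
#'
#' @param dataset the fitted [spike_dataset()].
#' @param chain an `iprf_chain`.
#' @param area_pair character vector of two area labels.
#' @param n_draws posterior draws used for the model curve.
#' @param pop_threshold as in [psth_overlay()].
#' @param seed RNG seed for the simulated counts.
#' @return list with numeric vectors `empirical` and `simulated` of pairwise
#'   correlations.
#' @export
spike_count_corr_fit <- function(dataset, chain, area_pair, n_draws = 20,
                                 pop_threshold = 0.5, seed = 1L) {
  stopifnot(length(area_pair) == 2)
  ai <- match(area_pair, chain$areas)
  basis <- chain$basis
  emp <- c(); simv <- c()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  kk <- unique(round(seq(1, chain$n_kept, length.out = n_draws)))
  for (ci in seq_along(chain$conditions)) {
    cc <- chain$conditions[ci]
    ids <- lapply(ai, function(x)
      dataset$neurons[[chain$areas[x]]][chain$z_pop_freq[[chain$areas[x]]][, ci] >= pop_threshold])
    if (any(lengths(ids) < 2)) next
    counts <- lapply(seq_len(2), function(s) {
      a <- chain$areas[ai[s]]
      idx <- match(ids[[s]], dataset$neurons[[a]])
      t(vapply(dataset$trials, function(rr) {
        tr <- dataset$spikes[[a]][[cc]][[as.character(rr)]]
        tabulate(tr$neuron[tr$neuron %in% idx], length(dataset$neurons[[a]]))[idx]
      }, numeric(length(idx))))  # trials x neurons
    })
    emp <- c(emp, as.vector(stats::cor(counts[[1]], counts[[2]])))
    # model counts: Poisson around per-draw expected counts + shared gain/warp
    for (k in kk) {
      mu <- lapply(seq_len(2), function(s) {
        aix <- ai[s]
        beta <- chain$draws$beta_pop[k, , aix, ci]
        f <- drop(basis$B %*% beta)
        spec <- chain$specs[[aix]][[ci]]
        vapply(seq_len(chain$R), function(rr) {
          q3 <- chain$draws$q[k, ci, rr, 3 * (aix - 1) + 1:3]
          w <- build_warp(spec, .clip_dom(q3[2], spec, 1), .clip_dom(q3[3], spec, 2))
          tw <- warp_time(w, basis$times, inverse = TRUE)
          sum(exp(stats::approx(basis$times, f, xout = tw, rule = 2)$y + q3[1])) * basis$dt_s
        }, numeric(1))
      })
      sim_counts <- lapply(seq_len(2), function(s)
        matrix(stats::rpois(chain$R * length(ids[[s]]), mu[[s]]),
               chain$R, length(ids[[s]])))
      simv <- c(simv, as.vector(stats::cor(sim_counts[[1]], sim_counts[[2]])))
    }
  }
  list(empirical = emp, simulated = simv)
}

#' Cross-correlogram of two binned trains
#'
#' Count-normalized cross-correlation at integer bin lags: at lag `l` the sum
#' over overlapping bins of `x_t * y_(t+l)`, divided by
#' `sqrt(sum(x) * sum(y))`.
#'
#' @param x,y equal-length count vectors (or `binned_train`s).
#' @param max_lag maximum lag in bins.
#' @return data frame with columns `lag` (bins) and `value`.
#' @export
cross_correlogram <- function(x, y, max_lag = 25) {
  if (inherits(x, "binned_train")) x <- x$counts
  if (inherits(y, "binned_train")) y <- y$counts
  stopifnot(length(x) == length(y))
  n <- length(x)
  lags <- -max_lag:max_lag
  norm <- sqrt(max(sum(x), 1) * max(sum(y), 1))
  val <- vapply(lags, function(l) {
    if (l >= 0) sum(x[seq_len(n - l)] * y[seq_len(n - l) + l])
    else sum(x[seq_len(n + l) - l] * y[seq_len(n + l)])
  }, numeric(1)) / norm
  data.frame(lag = lags, value = val)
}
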