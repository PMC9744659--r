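#' Pairwise correlations from a covariance matrix
#'
#' @param Sigma positive definite covariance matrix.
#' @return data frame with one row per unordered pair (upper triangle):
#'   columns `i`, `j` (names if available), `rho`.
#' @export
corr_from_sigma <- function(Sigma) {
  if (any(diag(Sigma) <= 0)) stop("zero or negative variance")
  R <- stats::cov2cor(Sigma)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  nm <- colnames(Sigma)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(Sigma)))
  data.frame(i = nm[idx[, 1]], j = nm[idx[, 2]], rho = R[idx])
}

#' Partial correlation
#'
#' Correlation of components `i` and `j` after linearly removing the
#' conditioning components `k`. For a single conditioning variable this is
#' `(rho_ij - rho_ik rho_jk) / sqrt((1 - rho_ik^2)(1 - rho_jk^2))`; for a
#' vector `k` the general inverse-covariance (Schur complement) formula is
#' used.
#'
#' @param Sigma positive definite covariance matrix.
#' @param i,j indices (or names) of the two variables.
#' @param k index/indices of the conditioning variable(s).
#' @return scalar partial correlation.
#' @export
partial_corr <- function(Sigma, i, j, k) {
  nm <- colnames(Sigma)
  if (is.character(i)) i <- match(i, nm)
  if (is.character(j)) j <- match(j, nm)
  if (is.character(k)) k <- match(k, nm)
  R <- stats::cov2cor(Sigma)
  if (any(abs(R[c(i, j), k]) >= 1 - 1e-12))
    stop("conditioning variable perfectly correlated with i or j")
  S <- Sigma[c(i, j), c(i, j)] -
    Sigma[c(i, j), k, drop = FALSE] %*%
    solve(Sigma[k, k, drop = FALSE], Sigma[k, c(i, j), drop = FALSE])
  S[1, 2] / sqrt(S[1, 1] * S[2, 2])
}

#' Posterior summaries of a functional of the chain
#'
#' Applies a functional to every kept draw and reports the median, a
#' kernel-density mode, and the (0.025, 0.975) quantile interval.
#'
#' @param chain an `iprf_chain`.
#' @param functional a function of a single draw. It receives a list with
#'   elements `Sigma` (9x9) and `q` (C x R x 9) for that draw and must return
#'   a scalar.
#' @return list with `samples`, `median`, `mode`, `q025`, `q975`.
#' @export
posterior_functionals <- function(chain, functional) {
  nk <- chain$n_kept
  if (nk < 100) warning("fewer than 100 kept draws; summaries will be noisy")
  samples <- vapply(seq_len(nk), function(k) {
    functional(list(Sigma = chain$draws$Sigma[k, , ],
                    q = chain$draws$q[k, , , , drop = TRUE]))
  }, numeric(1))
  list(samples = samples, median = stats::median(samples),
       mode = .kde_mode(samples),
       q025 = unname(stats::quantile(samples, 0.025, type = 7)),
       q975 = unname(stats::quantile(samples, 0.975, type = 7)))
}

# kernel-density argmax with the rule-of-thumb bandwidth
.kde_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Posterior summaries of all pairwise feature correlations
#'
#' @param chain an `iprf_chain`.
#' @return data frame with one row per pair: `pair`, `i`, `j`, `median`,
#'   `mode`, `q025`, `q975`.
#' @export
correlation_summaries <- function(chain) {
  d <- dim(chain$draws$Sigma)[2]
  idx <- which(upper.tri(diag(d)), arr.ind = TRUE)
  nm <- chain$feature_names
  nk <- chain$n_kept
  samp <- matrix(NA_real_, nk, nrow(idx))
  for (k in seq_len(nk)) {
    R <- stats::cov2cor(chain$draws$Sigma[k, , ])
    samp[k, ] <- R[idx]
  }
  data.frame(
    pair = paste(nm[idx[, 1]], nm[idx[, 2]], sep = ":"),
    i = nm[idx[, 1]], j = nm[idx[, 2]],
    median = apply(samp, 2, stats::median),
    mode = apply(samp, 2, .kde_mode),
    q025 = apply(samp, 2, stats::quantile, probs = 0.025),
    q975 = apply(samp, 2, stats::quantile, probs = 0.975))
}

#' Per-trial peak times and cross-area lags
#'
#' The peak-k time of area `a` on trial `r` (condition `c`) is the template
#' landmark `tpeak_k(a, c)` plus the posterior median of the trial's peak-k
#' shift. Lags are per-trial differences of peak times between areas;
#' summaries are the median and (0.025, 0.975) quantiles across trials.
#'
#' @param chain an `iprf_chain`.
#' @return list with `peak_times` (data frame: area, condition, trial,
#'   peak1, peak2) and `lags` (data frame: area_from, area_to, peak,
#'   median, q025, q975 of the per-trial lag `t_from - t_to`).
#' @export
peak_times_and_lags <- function(chain) {
  A <- length(chain$areas); C <- length(chain$conditions); R <- chain$R
  q_med <- apply(chain$draws$q, c(2, 3, 4), stats::median)
  rows <- list()
  for (ai in seq_len(A)) for (ci in seq_len(C)) {
    spec <- chain$specs[[ai]][[ci]]
    rows[[length(rows) + 1L]] <- data.frame(
      area = chain$areas[ai], condition = chain$conditions[ci],
      trial = seq_len(R),
      peak1 = spec$tpeak1 + q_med[ci, , 3 * (ai - 1) + 2],
      peak2 = spec$tpeak2 + q_med[ci, , 3 * (ai - 1) + 3])
  }
  pt <- do.call(rbind, rows)
  lag_rows <- list()
  for (ai in seq_len(A)) for (bi in seq_len(A)) {
    if (ai == bi) next
    for (pk in c("peak1", "peak2")) {
      d <- pt[[pk]][pt$area == chain$areas[ai]] -
        pt[[pk]][pt$area == chain$areas[bi]]
      lag_rows[[length(lag_rows) + 1L]] <- data.frame(
        area_from = chain$areas[ai], area_to = chain$areas[bi], peak = pk,
        median = stats::median(d),
        q025 = unname(stats::quantile(d, 0.025)),
        q975 = unname(stats::quantile(d, 0.975)))
    }
  }
  list(peak_times = pt, lags = do.call(rbind, lag_rows))
}

#' Naive single-trial peak times
#'
#' The baseline estimator: smooth each single-trial population PSTH by a
#' penalized spline regression and take the argmax within a search window
#' (earliest bin on ties). This is the method whose trial-to-trial peak-time
#' estimates are strongly attenuated by noise compared with the model-based
#' estimates.
#'
#' @param dataset a [spike_dataset()].
#' @param member_ids neuron ids forming the population (one area).
#' @param window search window `c(lo, hi)` in ms (e.g. the peak-2 domain).
#' @param conditions conditions to include (default all).
#' @param bin_width bin width in ms.
#' @param eta smoothing weight for the single-trial spline fit; `NULL`
#'   selects it once per (area, condition) by cross-validation over trials.
#' @param n_knots spline knots.
#' @return data frame: condition, trial, peak_time (NA for empty trials).
#' @export
naive_peak_times <- function(dataset, member_ids, window,
                             conditions = dataset$conditions,
                             bin_width = 2, eta = NULL, n_knots = 100) {
  m <- .resolve_members(dataset, member_ids)
  basis <- bspline_basis(dataset$T, n_knots, bin_width)
  Omega <- roughness_penalty(basis)
  sel <- basis$times >= window[1] & basis$times <= window[2]
  rows <- list()
  for (cc in conditions) {
    counts <- vapply(dataset$trials, function(rr) {
      sp <- .member_spikes(dataset, m$area, m$idx, cc, rr)
      as.numeric(bin_spikes(sp$times, dataset$T, bin_width)$counts)
    }, numeric(basis$n_bins))
    eta_c <- if (is.null(eta)) {
      cv_select_eta(counts, basis, Omega, exposure = length(m$idx))$eta
    } else eta
    for (ri in seq_along(dataset$trials)) {
      if (sum(counts[, ri]) == 0) {
        pk <- NA_real_
      } else {
        fit <- fit_penalized_poisson(counts[, ri], basis, Omega, eta_c,
                                     exposure = length(m$idx))
        pk <- basis$times[sel][which.max(fit$f[sel])]
      }
      rows[[length(rows) + 1L]] <- data.frame(condition = cc,
                                              trial = dataset$trials[ri],
                                              peak_time = pk)
    }
  }
  do.call(rbind, rows)
}

#' Fisher-z confidence interval for a correlation
#'
#' @param r sample correlation, `|r| < 1` (at `|r| = 1` the interval
#'   degenerates to the point `r`).
#' @param n sample size (> 3).
#' @param level confidence level.
#' @return numeric `c(lower, upper)`, strictly inside (-1, 1) for `|r| < 1`.
#' @export
fisher_z_ci <- function(r, n, level = 0.95) {
  if (n <= 3) stop("need n > 3")
  if (abs(r) >= 1) return(c(r, r))
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}
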