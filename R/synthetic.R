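#' Template shape library
#'
#' Builds smooth log firing-rate curves with well-defined landmarks, used by
#' the simulator and by the template-matching robustness checks. The default
#' two-peak shape mimics the evoked visual response (peaks near 57 and 216 ms,
#' peak rates of tens of spikes/s per neuron). For `rise-to-asymptote` the
#' landmark is the half-rise point of the incline.
#'
#' @param shape one of `"two-peak"`, `"sharp-peak"`, `"broad-peak"`,
#'   `"inverted-peak"`, `"rise-to-asymptote"`.
#' @param T,bin_width grid geometry in ms.
#' @param params optional overrides: `base` (baseline rate, spikes/s),
#'   `peak_rate` (peak or asymptote rate; length 2 for `two-peak`),
#'   `center` (landmark position(s), ms), `width` (Gaussian SD or logistic
#'   scale, ms).
#' @return object of class `iprf_shape`: list with `log_rate` (function of
#'   ms), `f` (log rate on the bin-midpoint grid), `times`, `center` (the true
#'   landmark position(s)), `shape`.
#' @export
make_template <- function(shape = "two-peak", T = 500, bin_width = 2,
                          params = list()) {
  defaults <- switch(shape,
    "two-peak" = list(base = 5, peak_rate = c(120, 80), center = c(57, 216),
                      width = c(13, 18), plateau_rate = 28,
                      plateau_rise = 140, plateau_fall = 430,
                      landmark_frac = 0.25),
    "sharp-peak" = list(base = 5, peak_rate = 40, center = 216, width = 10),
    "broad-peak" = list(base = 5, peak_rate = 40, center = 216, width = 60),
    "inverted-peak" = list(base = 25, peak_rate = 4, center = 216, width = 25),
    "rise-to-asymptote" = list(base = 5, peak_rate = 40, center = 216, width = 20),
    stop("unknown template shape: ", shape))
  p <- utils::modifyList(defaults, params)
  spec <- NULL
  log_rate <- switch(shape,
    "two-peak" = {
      # sharp onset peak; then a sustained plateau (the continuing stimulus
      # response) carrying a narrow second peak. The narrow top is what moves
      # trial to trial; the broad above-half-height plateau is what makes the
      # peak-2 landmark domain wide, as in evoked-response recordings.
      a1 <- log(p$peak_rate[1] / p$base)
      ap <- log(p$plateau_rate / p$base)
      a2 <- log(p$peak_rate[2] / p$plateau_rate)
      function(t)
        log(p$base) +
          a1 * exp(-(t - p$center[1])^2 / (2 * p$width[1]^2)) +
          ap * stats::plogis((t - p$plateau_rise) / 15) *
               stats::plogis((p$plateau_fall - t) / 20) +
          a2 * exp(-(t - p$center[2])^2 / (2 * p$width[2]^2))
    },
    "rise-to-asymptote" = function(t)
      log(p$base) + log(p$peak_rate / p$base) / (1 + exp(-(t - p$center) / p$width)),
    function(t)  # single Gaussian bump (possibly inverted)
      log(p$base) + log(p$peak_rate / p$base) *
        exp(-(t - p$center)^2 / (2 * p$width^2)))
  times <- seq(bin_width / 2, T - bin_width / 2, by = bin_width)
  f <- log_rate(times)
  if (shape == "two-peak")
    spec <- find_landmarks(f, times, frac = p$landmark_frac, T = T)
  structure(list(shape = shape, log_rate = log_rate, f = f,
                 times = times, center = p$center, params = p, T = T,
                 bin_width = bin_width, spec = spec),
            class = "iprf_shape")
}

#' Default ground-truth feature covariance
#'
#' 9x9 covariance of the stacked per-area feature triples
#' `(gain, peak1, peak2)`, with cross-area correlations applied within each
#' feature. Defaults are calibrated to the variability and coupling reported
#' for the mouse visual data (peak-1 SD ~5 ms, peak-2 SD ~30 ms, strong
#' cross-area peak-2 coupling).
#'
#' @param A number of areas.
#' @param sds feature SDs `c(gain, peak1, peak2)` (gain dimensionless, peaks
#'   in ms).
#' @param rhos cross-area correlations `c(gain, peak1, peak2)`.
#' @return positive definite `3A` x `3A` matrix, feature order
#'   `(gain, peak1, peak2)` within area-major blocks.
#' @export
default_sigma <- function(A = 3, sds = c(0.1, 5, 30), rhos = c(0.3, 0.6, 0.85)) {
  S <- matrix(0, 3 * A, 3 * A)
  for (i in 1:3) {
    idx <- 3 * (seq_len(A) - 1) + i
    blk <- matrix(rhos[i], A, A); diag(blk) <- 1
    S[idx, idx] <- blk * sds[i]^2
  }
  dimnames(S) <- rep(list(feature_names(A)), 2)
  S
}

#' Names of the stacked features
#' @param A number of areas.
#' @return character vector like `"a1.gain", "a1.peak1", ...`.
#' @export
feature_names <- function(A = 3)
  as.vector(t(outer(paste0("a", seq_len(A)), c("gain", "peak1", "peak2"),
                    paste, sep = ".")))

#' Smooth per-neuron intensity noise
#'
#' Perturbs each neuron's log intensity by an independent smooth random curve
#' (a coarse spline with zero-mean normal coefficients), emulating
#' neuron-to-neuron intensity-shape variation that the population model does
#' not capture. At `scale = 1` the coefficient SD is 0.1 on the log scale
#' (count dispersion comparable to the unperturbed simulation); `scale`
#' multiplies the coefficient variance, so `scale = 20` is the stress setting.
#'
#' @param log_rates matrix (`n_bins` x `n_neurons`) of per-neuron log rates.
#' @param times bin midpoints (ms).
#' @param scale variance scale (0 leaves the rates unchanged).
#' @param n_coef number of spline coefficients of the perturbation curve.
#' @param base_sd coefficient SD at `scale = 1`.
#' @return perturbed matrix, same shape.
#' @export
inject_neuron_noise <- function(log_rates, times, scale = 1, n_coef = 10,
                                base_sd = 0.1) {
  if (scale == 0) return(log_rates)
  log_rates <- as.matrix(log_rates)
  T <- max(times) + min(times)
  kn <- c(rep(0, 3), seq(0, T, length.out = n_coef - 2), rep(T, 3))
  Bn <- splines::splineDesign(kn, times, ord = 4L)
  coefs <- matrix(stats::rnorm(ncol(Bn) * ncol(log_rates),
                               sd = base_sd * sqrt(scale)),
                  ncol(Bn), ncol(log_rates))
  log_rates + Bn %*% coefs
}

#' Simulate an interacting-population dataset
#'
#' Draws from the generative model: per (neuron, area, condition) membership
#' `z ~ categorical(p)`; per (condition, trial) stacked features
#' `q ~ N(0, Sigma)` (resampled if a peak shift falls outside its warp
#' domain); spikes per neuron from an inhomogeneous Poisson process via
#' per-bin Poisson counts at the analysis bin width, with spike times placed
#' uniformly within their bin.
#'
#' @param A,C,R,N areas, conditions, trials per condition, neurons per area.
#' @param p membership probabilities `(pop, local-1, local-2)`.
#' @param Sigma feature covariance (default [default_sigma()]).
#' @param shape template shape passed to [make_template()] for the `pop` and
#'   `local-1` templates (`local-1` uses a damped copy of the same shape,
#'   `local-2` a constant at the baseline rate).
#' @param noise_scale per-neuron intensity noise variance scale
#'   (see [inject_neuron_noise()]); 0 disables it.
#' @param T,bin_width window and bin width in ms.
#' @param n_knots template spline knots (used to encode the true templates).
#' @param seed RNG seed (same seed, identical dataset).
#' @return list with `dataset` (a [spike_dataset()]) and `truth`: the
#'   template set, `Sigma`, `p`, membership matrix `z[area, condition, neuron]`,
#'   feature array `q[condition, trial, 9]`, and the true correlation matrix.
#' @export
simulate_iprf <- function(A = 3, C = 3, R = 15, N = 30,
                          p = c(0.25, 0.50, 0.25),
                          Sigma = default_sigma(A),
                          shape = "two-peak", noise_scale = 0,
                          T = 500, bin_width = 2, n_knots = 100,
                          seed = 1L) {
  set.seed(seed)
  stopifnot(abs(sum(p) - 1) < 1e-8, nrow(Sigma) == 3 * A)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  basis <- bspline_basis(T, n_knots, bin_width)
  areas <- paste0("area", seq_len(A))
  conditions <- seq_len(C)
  sh <- make_template(shape, T, bin_width)
  f_pop <- sh$f
  # local-1: slow stimulus modulation without sharp population bursts
  f_loc1 <- log(8) + 0.8 * exp(-(sh$times - 150)^2 / (2 * 80^2))
  f_loc2 <- log(sh$params$base)
  spec <- if (!is.null(sh$spec)) sh$spec else find_landmarks(f_pop, basis$times, T = T)
  beta_pop <- .project_spline(basis, f_pop)
  beta_loc1 <- .project_spline(basis, f_loc1)
  templates <- template_set(basis, areas, conditions)
  for (a in areas) for (cc in as.character(conditions))
    templates$tmpl[[a]][[cc]] <- list(beta_pop = beta_pop, beta_loc1 = beta_loc1,
                                      beta_loc2 = f_loc2, spec = spec)
  dom <- shift_domain(spec, margin = 2)
  chol_S <- chol(Sigma)
  # features per (condition, trial), rejection-resampled into the warp domains
  q <- array(0, dim = c(C, R, 3 * A))
  p1_idx <- 3 * (seq_len(A) - 1) + 2
  p2_idx <- 3 * (seq_len(A) - 1) + 3
  for (cc in seq_len(C)) for (rr in seq_len(R)) {
    for (try in 1:1000) {
      qq <- drop(stats::rnorm(3 * A) %*% chol_S)
      ok <- all(qq[p1_idx] > dom[1, 1] & qq[p1_idx] < dom[1, 2]) &&
        all(qq[p2_idx] > dom[2, 1] & qq[p2_idx] < dom[2, 2])
      if (ok) break
    }
    if (!ok) stop("could not draw features inside the warp domains")
    q[cc, rr, ] <- qq
  }
  z <- array(0L, dim = c(A, C, N),
             dimnames = list(areas, as.character(conditions), NULL))
  z[] <- sample.int(3, A * C * N, replace = TRUE, prob = p)
  # per-neuron spike generation
  rows <- vector("list", A * C * R)
  k <- 0L
  width <- max(nchar(as.character(N)))
  for (ai in seq_len(A)) {
    nid <- sprintf("%s.n%0*d", areas[ai], width, seq_len(N))
    base_logr <- cbind(f_pop, f_loc1, rep(f_loc2, basis$n_bins))
    for (cc in seq_len(C)) {
      zz <- z[ai, cc, ]
      # per-neuron unwarped log rates, with optional smooth noise
      logr <- base_logr[, zz, drop = FALSE]
      if (noise_scale > 0)
        logr <- inject_neuron_noise(logr, basis$times, noise_scale)
      for (rr in seq_len(R)) {
        gain <- q[cc, rr, 3 * (ai - 1) + 1]
        w <- build_warp(spec, q[cc, rr, 3 * (ai - 1) + 2], q[cc, rr, 3 * (ai - 1) + 3])
        tw <- warp_time(w, basis$times, inverse = TRUE)
        # warped pop log-rate per bin via linear interpolation of the template
        fw <- stats::approx(basis$times, f_pop, xout = tw, rule = 2)$y
        lam <- exp(logr) * basis$dt_s
        if (any(zz == 1L)) {
          fw_n <- if (noise_scale > 0) {
            # warp each noisy pop neuron's own curve
            apply(logr[, zz == 1L, drop = FALSE] - f_pop, 2, function(d)
              fw + stats::approx(basis$times, d, xout = tw, rule = 2)$y)
          } else matrix(fw, basis$n_bins, sum(zz == 1L))
          lam[, zz == 1L] <- exp(fw_n + gain) * basis$dt_s
        }
        cnt <- matrix(stats::rpois(length(lam), lam), basis$n_bins)
        nz <- which(cnt > 0, arr.ind = TRUE)
        if (nrow(nz)) {
          reps <- cnt[nz]
          bin_i <- rep(nz[, 1], reps)
          neu_i <- rep(nz[, 2], reps)
          tms <- (bin_i - 1) * bin_width + stats::runif(length(bin_i)) * bin_width
          k <- k + 1L
          rows[[k]] <- data.frame(neuron_id = nid[neu_i], area = areas[ai],
                                  condition_id = cc, trial_id = rr,
                                  time_ms = tms)
        }
      }
    }
  }
  tab <- do.call(rbind, rows[seq_len(k)])
  all_ids <- unlist(lapply(areas, function(a)
    sprintf("%s.n%0*d", a, width, seq_len(N))))
  na_map <- stats::setNames(rep(areas, each = N), all_ids)
  ds <- spike_dataset(tab, T = T, neuron_area = na_map)
  dimnames(z)[[3]] <- sprintf("n%0*d", width, seq_len(N))
  list(dataset = ds,
       truth = list(templates = templates, Sigma = Sigma,
                    corr = stats::cov2cor(Sigma), p = p, z = z, q = q,
                    spec = spec, f_pop = f_pop, f_loc1 = f_loc1,
                    f_loc2 = f_loc2, noise_scale = noise_scale))
}

# least-squares projection of a grid curve onto the spline basis
.project_spline <- function(basis, f)
  drop(solve(crossprod(basis$B) + 1e-9 * diag(basis$n_basis),
             crossprod(basis$B, f)))

#' Summarize a recovery table
#'
#' Per correlation pair: signed bias (mean of estimate minus truth), RMSE,
#' 95% interval coverage, and Monte-Carlo standard errors.
#'
#' @param per_replicate data frame with columns `pair`, `truth`, `estimate`,
#'   `lower`, `upper` (one row per replicate and pair).
#' @return data frame with one row per pair: `pair`, `truth`, `bias`,
#'   `rmse`, `coverage`, `bias_se`, `ci_halfwidth_se`, `n`.
#' @export
summarize_recovery <- function(per_replicate) {
  per <- per_replicate
  if (is.null(per$covered))
    per$covered <- per$truth >= per$lower & per$truth <= per$upper
  do.call(rbind, lapply(split(per, per$pair), function(d) {
    err <- d$estimate - d$truth
    nn <- nrow(d)
    data.frame(pair = d$pair[1], truth = d$truth[1],
               bias = mean(err), rmse = sqrt(mean(err^2)),
               coverage = mean(d$covered),
               bias_se = stats::sd(err) / sqrt(nn),
               ci_halfwidth_se = stats::sd((d$upper - d$lower) / 2) / sqrt(nn),
               n = nn)
  }))
}

#' Parameter-recovery experiment
#'
#' Runs the full closed loop: simulate from the generative model, fit by
#' hard-EM initialization plus Gibbs sampling, summarize the posterior of all
#' pairwise feature correlations, and tabulate bias, RMSE, and 95% interval
#' coverage against the simulation truth for each of the 36 pairs.
#'
#' @param n_replicates number of simulated replicates.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param A,C,R,N,p,Sigma,shape,noise_scale simulator settings
#'   (see [simulate_iprf()]).
#' @param n_iter,burn_in,thin Gibbs chain settings.
#' @param em_max_iter,em_tol hard-EM settings.
#' @param peak_frac prominence fraction used to locate the warp landmark
#'   boundaries when fitting; 0.25 places the peak-2 boundaries on the
#'   plateau's rise and fall so the domain covers the realistic spread of
#'   trial-to-trial peak shifts.
#' @param verbose print per-replicate progress.
#' @return list with `per_replicate` (long data frame: replicate, pair,
#'   truth, estimate, lower, upper, covered), `summary` (per pair: truth,
#'   bias, rmse, coverage, and Monte-Carlo standard errors `bias_se`,
#'   `ci_halfwidth_se`), `failed` (replicate indices that errored, with
#'   messages), and the configuration.
#' @export
recovery_experiment <- function(n_replicates = 20, seed = 1L,
                                A = 3, C = 3, R = 15, N = 30,
                                p = c(0.25, 0.50, 0.25),
                                Sigma = default_sigma(A),
                                shape = "two-peak", noise_scale = 0,
                                n_iter = 600, burn_in = 200, thin = 1,
                                em_max_iter = 12, em_tol = 1e-4,
                                peak_frac = 0.25, verbose = FALSE) {
  truth_corr <- stats::cov2cor(Sigma)
  pair_idx <- which(upper.tri(truth_corr), arr.ind = TRUE)
  pair_names <- paste(feature_names(A)[pair_idx[, 1]],
                      feature_names(A)[pair_idx[, 2]], sep = ":")
  rows <- list(); failed <- list()
  for (i in seq_len(n_replicates)) {
    res <- tryCatch({
      sim <- simulate_iprf(A = A, C = C, R = R, N = N, p = p, Sigma = Sigma,
                           shape = shape, noise_scale = noise_scale,
                           seed = seed + i)
      fit <- iprf_fit(sim$dataset, n_iter = n_iter, burn_in = burn_in,
                      thin = thin, em_max_iter = em_max_iter, em_tol = em_tol,
                      seed = seed + 100000L + i, peak_frac = peak_frac,
                      verbose = FALSE)
      cs <- correlation_summaries(fit$chain)
      data.frame(replicate = i, pair = cs$pair,
                 truth = truth_corr[pair_idx],
                 estimate = cs$median, lower = cs$q025, upper = cs$q975)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1L]] <- list(replicate = i,
                                            message = conditionMessage(res))
      if (verbose) message("replicate ", i, " failed: ", conditionMessage(res))
      next
    }
    res$covered <- res$truth >= res$lower & res$truth <= res$upper
    rows[[length(rows) + 1L]] <- res
    if (verbose) message("replicate ", i, " done")
  }
  if (!length(rows)) stop("all replicates failed")
  per <- do.call(rbind, rows)
  summ <- summarize_recovery(per)
  summ <- summ[match(pair_names, summ$pair), , drop = FALSE]
  rownames(summ) <- NULL
  list(per_replicate = per, summary = summ, failed = failed,
       config = list(n_replicates = n_replicates, seed = seed, A = A, C = C,
                     R = R, N = N, p = p, Sigma = Sigma, shape = shape,
                     noise_scale = noise_scale, n_iter = n_iter,
                     burn_in = burn_in, thin = thin))
}
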