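#' Prior hyperparameters
#'
#' Inverse-Wishart prior `IW(Psi0, nu0)` on the feature covariance and a
#' symmetric Dirichlet prior on the membership probabilities. Following the
#' diffuse-prior construction, `nu0 = 3A + 1` and `Psi0 = 2 * Phi0` with
#' `Phi0` diagonal; the square roots of the diagonal of `Phi0` are set to the
#' approximate scale of each feature.
#'
#' @param A number of areas.
#' @param phi0_scale per-feature scales `c(gain, peak1, peak2)` whose squares
#'   form the diagonal of `Phi0` (gain dimensionless, peaks in ms).
#' @param alpha Dirichlet concentration (scalar, replicated to the 3 groups).
#' @return list with `Psi0`, `nu0`, `alpha`, `Phi0`.
#' @export
iprf_prior <- function(A = 3, phi0_scale = c(0.3, 6, 30), alpha = 5) {
  Phi0 <- diag(rep(phi0_scale^2, A))
  list(Psi0 = 2 * Phi0, nu0 = 3 * A + 1, alpha = alpha, Phi0 = Phi0)
}

#' Locate warp landmarks from an initial template
#'
#' Grid search for the two largest local maxima of the template rate (in time
#' order) gives the peak positions; each peak's boundaries are set where the
#' rate falls to a configured fraction of its local prominence (peak height
#' above the flanking minimum), bounded so the two peak domains do not
#' overlap.
#'
#' @param f template log rate on the bin grid.
#' @param times bin midpoints (ms).
#' @param frac prominence fraction at which the boundaries are placed.
#' @param T window length (ms).
#' @return a [warp_spec()].
#' @export
find_landmarks <- function(f, times, frac = 0.5, T = 500) {
  v <- exp(f)
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2)
    stop("screening failure: template does not show two local maxima")
  top2 <- peaks[order(-v[peaks])][1:2]
  m1 <- min(top2); m2 <- max(top2)
  valley <- m1 - 1 + which.min(v[m1:m2])
  side_bound <- function(m, lo, hi, left) {
    base <- min(v[lo:hi])
    thr <- base + frac * (v[m] - base)
    if (left) {
      j <- which(v[lo:(m - 1)] <= thr)
      if (length(j)) times[lo + max(j) - 1] else times[lo]
    } else {
      j <- which(v[(m + 1):hi] <= thr)
      if (length(j)) times[m + min(j)] else times[hi]
    }
  }
  t1L <- side_bound(m1, 1, m1 - 1, TRUE)
  t1R <- side_bound(m1, m1 + 1, valley, FALSE)
  t2L <- side_bound(m2, valley, m2 - 1, TRUE)
  t2R <- side_bound(m2, m2 + 1, n, FALSE)
  if (t1R > t2L) t1R <- t2L <- times[valley]
  t1L <- max(t1L, times[1])
  t2R <- min(t2R, times[n])
  warp_spec(t1L, times[m1], t1R, t2L, times[m2], t2R, T = T)
}

# ---- internal state -------------------------------------------------------
# The fitting state is an environment holding the dataset in indexed form,
# the current parameter values, cached template grids, and the (fixed)
# proposal curvatures. Mutated in place by the EM and Gibbs updates.

.new_state <- function(dataset, bin_width, n_knots, prior) {
  st <- new.env(parent = emptyenv())
  st$areas <- dataset$areas
  st$conditions <- as.character(dataset$conditions)
  st$A <- length(st$areas); st$C <- length(st$conditions)
  st$R <- length(dataset$trials)
  st$T <- dataset$T
  st$neurons <- dataset$neurons
  st$N <- vapply(dataset$neurons, length, integer(1))
  st$basis <- bspline_basis(dataset$T, n_knots, bin_width)
  st$Omega <- roughness_penalty(st$basis)
  st$prior <- prior
  st$dim_q <- 3 * st$A
  st$sp <- dataset$spikes
  st$id_knots <- c(0, dataset$T)
  # raw (unwarped) binned group-independent counts per (a, c): bins x R per neuron
  st
}

.set_f_cache <- function(st, a, cc) {
  tm <- st$templates$tmpl[[a]][[cc]]
  st$fcache[[a]][[cc]] <- list(
    f_pop = drop(st$basis$B %*% tm$beta_pop),
    f_l1 = drop(st$basis$B %*% tm$beta_loc1),
    f_l2 = rep(tm$beta_loc2, st$basis$n_bins))
}

# spike times and binned counts of the current pop members, merged,
# per (a, c, r)
.refresh_pop_cache <- function(st, a, cc) {
  zz <- st$z[[a]][, cc]
  members <- which(zz == 1L)
  st$npop[[a]][[cc]] <- length(members)
  st$pop_times[[a]][[cc]] <- lapply(st$sp[[a]][[cc]], function(tr) {
    tr$times[tr$neuron %in% members]
  })
  nb <- st$basis$n_bins
  CM <- st$cnt2[[a]][[cc]]   # (nb * R) x N flattened count matrix
  st$pop_counts[[a]][[cc]] <- if (length(members)) {
    v <- as.integer(rowSums(CM[, members, drop = FALSE]))
    lapply(seq_len(st$R), function(rr) v[(rr - 1L) * nb + seq_len(nb)])
  } else {
    rep(list(integer(nb)), st$R)
  }
  m1 <- which(zz == 2L); m2 <- which(zz == 3L)
  v1 <- if (length(m1)) rowSums(CM[, m1, drop = FALSE]) else numeric(nb * st$R)
  st$loc_stats[[a]][[cc]] <- list(
    n1 = length(m1),
    Y1 = rowSums(matrix(v1, nb, st$R)),
    n2 = length(m2),
    tot2 = if (length(m2)) sum(CM[, m2]) else 0)
}

.q_idx <- function(st, a) 3 * (match(a, st$areas) - 1) + 1:3

# log N(x; 0, Sigma) with Sigma's upper-triangular Cholesky factor
.ldmvnorm0 <- function(x, cholS) {
  z <- backsolve(cholS, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(cholS))) - 0.5 * sum(z * z)
}

# cached warp join-points per (a, c): building a classed warp object in the
# samplers' inner loops is too slow, so the knot vectors are precomputed and
# only the two peak ordinates are patched per evaluation
.make_warp_cache <- function(st, a, cc) {
  sp <- st$templates$tmpl[[a]][[cc]]$spec
  x <- c(0, sp$t1L, sp$tpeak1, sp$t1R, sp$t2L, sp$tpeak2, sp$t2R, sp$T)
  keep <- c(TRUE, diff(x) > 0)
  st$wk[[a]][[cc]] <- list(x = x[keep], i1 = sum(keep[1:3]), i2 = sum(keep[1:6]),
                           tp1 = sp$tpeak1, tp2 = sp$tpeak2)
}

# trial-time ordinates of the warp with peak shifts (p1, p2)
.wk_y <- function(wk, p1, p2) {
  y <- wk$x
  y[wk$i1] <- wk$tp1 + p1
  y[wk$i2] <- wk$tp2 + p2
  y
}

# pop-group log-likelihood of trial (cc, rr) in area a at feature triple q3
.pop_ll <- function(st, a, cc, rr, q3) {
  npop <- st$npop[[a]][[cc]]
  if (npop == 0L) return(0)
  wk <- st$wk[[a]][[cc]]
  group_loglik_cpp(st$pop_counts[[a]][[cc]][[rr]], .wk_y(wk, q3[2], q3[3]),
                   wk$x, st$fcache[[a]][[cc]]$f_pop, q3[1], npop,
                   st$basis$bin_width)
}

# full conditional log posterior of the 9-dim feature block of trial (cc, rr);
# -Inf outside the warp domains (the warp is undefined there)
.q_logpost <- function(st, cc, rr, q9, cholS) {
  for (a in st$areas) {
    qi <- st$dom_idx[[a]]
    dom <- st$dom[[a]][[cc]]
    if (q9[qi[2]] <= dom[1, 1] || q9[qi[2]] >= dom[1, 2] ||
        q9[qi[3]] <= dom[2, 1] || q9[qi[3]] >= dom[2, 2]) return(-Inf)
  }
  ll <- .ldmvnorm0(q9, cholS)
  for (a in st$areas)
    ll <- ll + .pop_ll(st, a, cc, rr, q9[st$dom_idx[[a]]])
  ll
}

# per-neuron log-likelihood triples for (a, cc): N_a x 3 matrix
.neuron_group_ll <- function(st, a, cc) {
  fc <- st$fcache[[a]][[cc]]
  spec <- st$templates$tmpl[[a]][[cc]]$spec
  qi <- st$dom_idx[[a]]
  n <- st$N[[a]]
  out <- matrix(0, n, 3)
  wk <- st$wk[[a]][[cc]]
  l2 <- st$templates$tmpl[[a]][[cc]]$beta_loc2
  for (rr in seq_len(st$R)) {
    tr <- st$sp[[a]][[cc]][[rr]]
    q3 <- st$q[cc, rr, qi]
    out <- out + neuron_logliks3_cpp(tr$times, tr$neuron, n,
                                     .wk_y(wk, q3[2], q3[3]), wk$x,
                                     fc$f_pop, q3[1], fc$f_l1, l2,
                                     st$basis$bin_width)
  }
  out
}

# warped sufficient statistics of the merged pop trains: counts yw and
# occupancy weights u per trial (bins x R each)
.pop_warp_stats <- function(st, a, cc) {
  qi <- st$dom_idx[[a]]
  spec <- st$templates$tmpl[[a]][[cc]]$spec
  nb <- st$basis$n_bins
  Y <- U <- matrix(0, nb, st$R)
  wk <- st$wk[[a]][[cc]]
  for (rr in seq_len(st$R)) {
    ss <- warp_suffstats_cpp(st$pop_times[[a]][[cc]][[rr]],
                             .wk_y(wk, st$q[cc, rr, qi[2]], st$q[cc, rr, qi[3]]),
                             wk$x, nb, st$basis$bin_width)
    Y[, rr] <- ss$yw
    U[, rr] <- ss$u
  }
  list(Y = Y, U = U)
}

.group_counts <- function(st, a, cc, group) {
  members <- which(st$z[[a]][, cc] == group)
  if (!length(members)) return(matrix(0, st$basis$n_bins, st$R))
  M <- st$cnt[[a]][[cc]][, members, , drop = FALSE]
  apply(M, 3, rowSums)
}

# per-neuron binned counts, built once per (a, c): bins x neurons x trials
.make_count_cache <- function(st, a, cc) {
  nb <- st$basis$n_bins
  bw <- st$basis$bin_width
  n <- st$N[[a]]
  arr <- array(0L, c(nb, n, st$R))
  for (rr in seq_len(st$R)) {
    tr <- st$sp[[a]][[cc]][[rr]]
    if (length(tr$times)) {
      b <- floor(tr$times / bw)
      keep <- b < nb
      idx <- b[keep] + 1L + (tr$neuron[keep] - 1L) * nb
      arr[, , rr] <- tabulate(idx, nb * n)
    }
  }
  st$cnt[[a]][[cc]] <- arr
  # flattened (bins * trials) x neurons view for fast member sums
  st$cnt2[[a]][[cc]] <- matrix(aperm(arr, c(1, 3, 2)), nb * st$R, n)
}

# ---- initialization -------------------------------------------------------

#' Initialize the model state
#'
#' Ranks neurons in each area by their total in-window spike count (merged
#' over conditions and trials) and assigns the top 25% to the interacting
#' population, the middle 50% to the time-varying local group, and the bottom
#' 25% to the constant group. Templates are fitted by penalized splines from
#' the high and medium groups (smoothing weight by fivefold cross-validation
#' on one representative area/condition, then shared); the constant rates come
#' from the low group; warp landmarks are located on each initial population
#' template; all trial features start at zero. An initial population template
#' without two detectable peaks raises a screening failure.
#'
#' @param dataset a [spike_dataset()].
#' @param bin_width,n_knots grid settings (ms / knot count).
#' @param prior an [iprf_prior()]; defaults to the diffuse prior for
#'   `A = length(dataset$areas)`.
#' @param eta_grid smoothing-weight grid for cross-validation.
#' @param eta optional fixed smoothing weights `c(pop, local1)`, skipping CV.
#' @param peak_frac prominence fraction for [find_landmarks()].
#' @param cv_seed seed for the CV fold shuffle.
#' @return an opaque state object (environment) of class `iprf_state`,
#'   consumed by [iprf_hard_em()] and [iprf_gibbs()].
#' @export
iprf_init <- function(dataset, bin_width = 2, n_knots = 100,
                      prior = iprf_prior(length(dataset$areas)),
                      eta_grid = 10^seq(-3, 3, length.out = 7),
                      eta = NULL, peak_frac = 0.5, cv_seed = 1L) {
  st <- .new_state(dataset, bin_width, n_knots, prior)
  st$dom_idx <- stats::setNames(lapply(st$areas, function(a) .q_idx(st, a)), st$areas)
  # activity split 25 / 50 / 25
  st$z <- stats::setNames(lapply(st$areas, function(a) {
    tot <- .neuron_totals(dataset, a)
    ord <- order(-tot, names(tot))
    n <- length(tot)
    n_hi <- round(0.25 * n); n_lo <- round(0.25 * n)
    g <- integer(n)
    g[ord[seq_len(n_hi)]] <- 1L
    g[ord[(n_hi + 1):(n - n_lo)]] <- 2L
    g[ord[seq.int(n - n_lo + 1, n)]] <- 3L
    matrix(g, n, st$C, dimnames = list(names(tot), st$conditions))
  }), st$areas)
  st$q <- array(0, dim = c(st$C, st$R, st$dim_q),
                dimnames = list(st$conditions, NULL, feature_names(st$A)))
  st$p <- array(1 / 3, dim = c(st$A, st$C, 3),
                dimnames = list(st$areas, st$conditions, c("pop", "local-1", "local-2")))
  st$peak_frac <- peak_frac
  st$templates <- template_set(st$basis, st$areas, st$conditions)
  st$fcache <- st$dom <- st$npop <- st$pop_times <- st$wk <- st$cnt <-
    st$cnt2 <- st$loc_stats <-
    stats::setNames(lapply(st$areas, function(a)
      stats::setNames(vector("list", st$C), st$conditions)), st$areas)
  for (a in st$areas) for (cc in st$conditions) .make_count_cache(st, a, cc)
  for (a in st$areas) {
    frac <- table(factor(st$z[[a]][, 1], levels = 1:3)) / st$N[[a]]
    for (cc in st$conditions) st$p[a, cc, ] <- as.numeric(frac)
  }
  # smoothing weights by CV on the first (area, condition), then shared
  a1 <- st$areas[1]; c1 <- st$conditions[1]
  cnt_hi <- .group_counts_init(st, a1, c1, 1L)
  cnt_md <- .group_counts_init(st, a1, c1, 2L)
  if (is.null(eta)) {
    st$eta_pop <- cv_select_eta(cnt_hi$counts, st$basis, st$Omega, eta_grid,
                                exposure = cnt_hi$n, seed = cv_seed)$eta
    st$eta_loc1 <- cv_select_eta(cnt_md$counts, st$basis, st$Omega, eta_grid,
                                 exposure = max(cnt_md$n, 1), seed = cv_seed)$eta
  } else {
    st$eta_pop <- eta[1]; st$eta_loc1 <- eta[length(eta)]
  }
  for (a in st$areas) for (cc in st$conditions) {
    hi <- .group_counts_init(st, a, cc, 1L)
    md <- .group_counts_init(st, a, cc, 2L)
    lo <- .group_counts_init(st, a, cc, 3L)
    fit_pop <- fit_penalized_poisson(hi$counts, st$basis, st$Omega, st$eta_pop,
                                     exposure = hi$n)
    fit_l1 <- fit_penalized_poisson(md$counts, st$basis, st$Omega, st$eta_loc1,
                                    exposure = max(md$n, 1))
    beta_l2 <- log(max(sum(lo$counts), 0.5) /
                     (max(lo$n, 1) * st$R * st$basis$n_bins * st$basis$dt_s))
    spec <- find_landmarks(fit_pop$f, st$basis$times, frac = peak_frac, T = st$T)
    st$templates$tmpl[[a]][[cc]] <- list(beta_pop = fit_pop$beta,
                                         beta_loc1 = fit_l1$beta,
                                         beta_loc2 = beta_l2, spec = spec)
    st$dom[[a]][[cc]] <- shift_domain(spec, margin = 2)
    .make_warp_cache(st, a, cc)
    .set_f_cache(st, a, cc)
    .refresh_pop_cache(st, a, cc)
  }
  st$Sigma <- prior$Phi0
  st$cholS <- chol(st$Sigma)
  class(st) <- "iprf_state"
  st
}

# counts of an initial activity group (z is condition-independent at init)
.group_counts_init <- function(st, a, cc, group) {
  members <- which(st$z[[a]][, cc] == group)
  counts <- vapply(seq_len(st$R), function(rr) {
    tr <- st$sp[[a]][[cc]][[rr]]
    as.numeric(bin_counts_cpp(tr$times[tr$neuron %in% members],
                              st$basis$n_bins, st$basis$bin_width))
  }, numeric(st$basis$n_bins))
  list(counts = counts, n = length(members))
}

# ---- penalized log posterior (monitoring) ---------------------------------

.log_posterior <- function(st) {
  lp <- 0
  for (a in st$areas) for (cc in st$conditions) {
    fc <- st$fcache[[a]][[cc]]
    tm <- st$templates$tmpl[[a]][[cc]]
    npop <- st$npop[[a]][[cc]]
    qi <- st$dom_idx[[a]]
    for (rr in seq_len(st$R))
      lp <- lp + .pop_ll(st, a, cc, rr, st$q[cc, rr, qi])
    n1 <- sum(st$z[[a]][, cc] == 2L); n2 <- sum(st$z[[a]][, cc] == 3L)
    c1 <- .group_counts(st, a, cc, 2L); c2 <- .group_counts(st, a, cc, 3L)
    if (n1 > 0)
      lp <- lp + sum(vapply(seq_len(st$R), function(rr)
        pp_loglik_cpp(as.integer(c1[, rr]), n1 * exp(fc$f_l1) * st$basis$dt_s),
        numeric(1)))
    if (n2 > 0)
      lp <- lp + sum(vapply(seq_len(st$R), function(rr)
        pp_loglik_cpp(as.integer(c2[, rr]), n2 * exp(fc$f_l2) * st$basis$dt_s),
        numeric(1)))
    lp <- lp - st$eta_pop * npop * st$R *
      drop(crossprod(tm$beta_pop, st$Omega %*% tm$beta_pop))
    lp <- lp - st$eta_loc1 * max(n1, 1) * st$R *
      drop(crossprod(tm$beta_loc1, st$Omega %*% tm$beta_loc1))
    cnt <- tabulate(st$z[[a]][, cc], 3)
    lp <- lp + sum(cnt * log(pmax(st$p[a, cc, ], 1e-300))) +
      sum((st$prior$alpha - 1) * log(pmax(st$p[a, cc, ], 1e-300)))
  }
  for (cc in seq_len(st$C)) for (rr in seq_len(st$R))
    lp <- lp + .ldmvnorm0(st$q[cc, rr, ], st$cholS)
  # inverse-Wishart log prior on Sigma (up to a constant)
  Sinv_Psi0 <- backsolve(st$cholS, backsolve(st$cholS, st$prior$Psi0, transpose = TRUE))
  lp <- lp - (st$prior$nu0 + st$dim_q + 1) * sum(log(diag(st$cholS))) -
    0.5 * sum(diag(Sinv_Psi0))
  lp
}

# ---- hard EM --------------------------------------------------------------

#' Hard expectation-maximization
#'
#' Alternates conditional-posterior-mode updates: templates by penalized
#' Poisson fits on the (warped) group trains, trial features by numerical
#' optimization of the 9-dimensional block posterior, memberships by
#' conditional argmax, membership probabilities by the Dirichlet posterior
#' mode, and the feature covariance by the inverse-Wishart posterior mode.
#' Stops when the relative change of the penalized log posterior falls below
#' `tol`, or after `max_iter` iterations, or (with a warning) after the
#' objective fails to increase three times in a row.
#'
#' @param state an [iprf_init()] state; modified in place and returned.
#' @param max_iter,tol stopping rule.
#' @param optim_maxit iterations for the per-trial feature optimizer.
#' @param relocate_landmarks_at iteration at which the warp landmarks are
#'   re-located once on the partially sharpened templates (the initial
#'   templates are blurred by trial-to-trial shifts, which biases the
#'   landmark domains narrow); 0 disables. Landmarks are frozen afterwards,
#'   in particular throughout Gibbs sampling.
#' @param verbose print the objective trace.
#' @return the state, with an `em_trace` attribute of objective values.
#' @export
iprf_hard_em <- function(state, max_iter = 50, tol = 1e-6,
                         optim_maxit = 300, relocate_landmarks_at = 2L,
                         verbose = FALSE) {
  st <- state
  trace <- .log_posterior(st)
  bad <- 0L
  for (it in seq_len(max_iter)) {
    .em_update_templates(st)
    if (it == relocate_landmarks_at) .relocate_landmarks(st)
    .em_update_q(st, if (it <= 3) optim_maxit else ceiling(optim_maxit / 2),
                 seed_grid = it <= 3)
    .em_update_z(st)
    .em_update_p(st)
    .em_update_sigma(st)
    obj <- .log_posterior(st)
    if (verbose) message("EM iter ", it, ": ", format(obj, digits = 10))
    if (obj < utils::tail(trace, 1) - 1e-8 * abs(obj)) bad <- bad + 1L else bad <- 0L
    rel <- abs(obj - utils::tail(trace, 1)) / (abs(obj) + 1e-10)
    trace <- c(trace, obj)
    if (rel < tol) break
    if (bad > 3L) { warning("hard EM objective non-increasing; stopping"); break }
  }
  attr(st, "em_trace") <- trace
  st
}

# re-locate the warp landmarks on the current templates and re-express the
# peak shifts relative to the new peak positions (the observed trial peak
# tpeak_old + q_old must stay put)
.relocate_landmarks <- function(st) {
  for (a in st$areas) for (cc in st$conditions) {
    tm <- st$templates$tmpl[[a]][[cc]]
    fc <- st$fcache[[a]][[cc]]
    new_spec <- tryCatch(
      find_landmarks(fc$f_pop, st$basis$times, frac = st$peak_frac, T = st$T),
      error = function(e) NULL)
    if (is.null(new_spec)) next
    old_spec <- tm$spec
    dom <- shift_domain(new_spec, margin = 2)
    qi <- st$dom_idx[[a]]
    for (rr in seq_len(st$R)) {
      q1 <- st$q[cc, rr, qi[2]] + old_spec$tpeak1 - new_spec$tpeak1
      q2 <- st$q[cc, rr, qi[3]] + old_spec$tpeak2 - new_spec$tpeak2
      st$q[cc, rr, qi[2]] <- min(max(q1, dom[1, 1] + 0.5), dom[1, 2] - 0.5)
      st$q[cc, rr, qi[3]] <- min(max(q2, dom[2, 1] + 0.5), dom[2, 2] - 0.5)
    }
    tm$spec <- new_spec
    st$templates$tmpl[[a]][[cc]] <- tm
    st$dom[[a]][[cc]] <- dom
    .make_warp_cache(st, a, cc)
  }
}

.em_update_templates <- function(st) {
  for (a in st$areas) for (cc in st$conditions) {
    tm <- st$templates$tmpl[[a]][[cc]]
    npop <- st$npop[[a]][[cc]]
    qi <- st$dom_idx[[a]]
    if (npop > 0) {
      ws <- .pop_warp_stats(st, a, cc)
      fit <- fit_penalized_poisson(ws$Y, st$basis, st$Omega, st$eta_pop,
                                   offsets = st$q[cc, , qi[1]], exposure = npop,
                                   exposure_weights = ws$U)
      tm$beta_pop <- fit$beta
      st$Q_beta_pop[[a]][[cc]] <- fit$neg_hessian
    }
    n1 <- sum(st$z[[a]][, cc] == 2L)
    if (n1 > 0) {
      fit1 <- fit_penalized_poisson(.group_counts(st, a, cc, 2L), st$basis,
                                    st$Omega, st$eta_loc1, exposure = n1)
      tm$beta_loc1 <- fit1$beta
      st$Q_beta_loc1[[a]][[cc]] <- fit1$neg_hessian
    }
    n2 <- sum(st$z[[a]][, cc] == 3L)
    if (n2 > 0) {
      tot <- sum(.group_counts(st, a, cc, 3L))
      tm$beta_loc2 <- log(max(tot, 0.5) / (n2 * st$R * st$basis$n_bins * st$basis$dt_s))
    }
    st$templates$tmpl[[a]][[cc]] <- tm
    .set_f_cache(st, a, cc)
  }
}

.em_update_q <- function(st, optim_maxit, seed_grid = TRUE) {
  # scale the simplex to the current feature SDs (gains ~0.1, shifts ~ms)
  parscale <- pmax(sqrt(diag(st$Sigma)), 1e-3)
  # seeding penalty never narrower than the prior hyperscale: the mode
  # update must be able to find distant likelihood optima even while the
  # covariance estimate is still small
  sd_q <- pmax(sqrt(diag(st$Sigma)), sqrt(diag(st$prior$Phi0)))
  for (cc in seq_len(st$C)) for (rr in seq_len(st$R)) {
    cur <- st$q[cc, rr, ]
    # per-area 1-D grid seeding of the peak shifts: the blockwise posterior
    # can be nearly flat near zero early on (trial-blurred template), where
    # a simplex started at the origin stalls
    seed <- cur
    if (seed_grid) for (a in st$areas) {
      qi <- st$dom_idx[[a]]
      dom <- st$dom[[a]][[cc]]
      for (pk in 1:2) {
        grid <- seq(dom[pk, 1] + 0.5, dom[pk, 2] - 0.5, by = 4)
        vals <- vapply(grid, function(g) {
          q3 <- seed[qi]; q3[pk + 1] <- g
          .pop_ll(st, a, cc, rr, q3) - 0.5 * (g / sd_q[qi[pk + 1]])^2
        }, numeric(1))
        seed[qi[pk + 1]] <- grid[which.max(vals)]
      }
    }
    negll <- function(x) {
      v <- .q_logpost(st, cc, rr, x, st$cholS)
      if (is.finite(v)) -v else 1e10
    }
    start <- if (negll(seed) < negll(cur)) seed else cur
    opt <- stats::optim(start, negll, method = "Nelder-Mead",
                        control = list(maxit = optim_maxit, reltol = 1e-7,
                                       parscale = parscale))
    if (opt$value < negll(cur)) st$q[cc, rr, ] <- opt$par
  }
}

.em_update_z <- function(st) {
  for (a in st$areas) for (cc in st$conditions) {
    ll <- .neuron_group_ll(st, a, cc)
    lw <- sweep(ll, 2, log(pmax(st$p[a, cc, ], 1e-300)), "+")
    st$z[[a]][, cc] <- max.col(lw, ties.method = "first")
    .refresh_pop_cache(st, a, cc)
  }
}

.em_update_p <- function(st) {
  al <- st$prior$alpha
  for (a in st$areas) for (cc in st$conditions) {
    cnt <- tabulate(st$z[[a]][, cc], 3)
    st$p[a, cc, ] <- (cnt + al - 1) / (sum(cnt) + 3 * al - 3)
  }
}

.em_update_sigma <- function(st) {
  qmat <- .q_matrix(st)
  S <- crossprod(qmat)
  # Laplace E-step correction: the modal features q-hat are shrunk relative
  # to the latent features, and a purely modal covariance update compounds
  # that shrinkage across iterations (collapsing Sigma in moderate-
  # information regimes). Adding each trial block's conditional covariance
  # (inverse curvature at the mode) restores E[q q'] to first order.
  for (cc in seq_len(st$C)) for (rr in seq_len(st$R)) {
    Cv <- .q_block_cov(st, cc, rr)
    if (!is.null(Cv)) S <- S + Cv
  }
  Psi <- st$prior$Psi0 + S
  st$Sigma <- Psi / (st$prior$nu0 + nrow(qmat) + st$dim_q + 1)
  st$Sigma <- (st$Sigma + t(st$Sigma)) / 2
  st$cholS <- chol(st$Sigma)
}

.q_matrix <- function(st)
  matrix(aperm(st$q, c(2, 1, 3)), st$C * st$R, st$dim_q)

# ---- Gibbs sampling -------------------------------------------------------

# fixed proposal curvature: inverse Hessians at the hard-EM mode, regularized
# to positive definite by eigenvalue flooring
.prep_proposals <- function(st, scale = 0.05, q_scale = scale,
                            recenter_prob = 0.2) {
  st$prop <- list(scale = scale, q_scale = q_scale,
                  recenter_prob = recenter_prob)
  st$prop$beta_pop <- st$prop$beta_loc1 <-
    stats::setNames(lapply(st$areas, function(a)
      stats::setNames(vector("list", st$C), st$conditions)), st$areas)
  for (a in st$areas) for (cc in st$conditions) {
    for (nm in c("beta_pop", "beta_loc1")) {
      H <- if (nm == "beta_pop") st$Q_beta_pop[[a]][[cc]] else st$Q_beta_loc1[[a]][[cc]]
      if (is.null(H)) H <- diag(st$basis$n_basis)
      Q <- .safe_inverse(H)
      # upper Cholesky of scale * Q for proposal draws
      st$prop[[nm]][[a]][[cc]] <- chol(scale * Q)
    }
  }
  # q blocks: finite-difference Hessian of the block posterior at the mode,
  # shared across trials within a condition (curvature is trial-similar)
  st$prop$q <- vector("list", st$C)
  for (cc in seq_len(st$C)) {
    Q <- .q_block_cov(st, cc, 1L)
    if (is.null(Q)) Q <- st$Sigma  # prior curvature as fallback
    st$prop$q[[cc]] <- list(chol_prop = chol(q_scale * Q))
  }
  st$acc <- list(beta_pop = c(0, 0), beta_loc1 = c(0, 0),
                 beta_loc2 = c(0, 0), q = c(0, 0))
  invisible(st)
}

.safe_inverse <- function(H, floor = 1e-8) {
  H <- (H + t(H)) / 2
  e <- eigen(H, symmetric = TRUE)
  vals <- pmax(e$values, max(max(e$values), 1) * floor)
  e$vectors %*% (t(e$vectors) / vals)
}

# conditional covariance of a trial's feature block at the current values:
# blockwise likelihood curvature (per-area finite differences) plus the
# exact prior precision
.q_block_cov <- function(st, cc, rr) {
  d <- st$dim_q
  H <- matrix(0, d, d)
  for (a in st$areas) {
    qi <- st$dom_idx[[a]]
    Ha <- tryCatch({
      hh <- .fd_hessian(function(x3) .pop_ll(st, a, cc, rr, x3),
                        st$q[cc, rr, qi], hh = c(0.05, 2, 3))
      if (!all(is.finite(hh))) stop("non-finite")
      hh
    }, error = function(e) matrix(0, 3, 3))
    H[qi, qi] <- Ha
  }
  Sinv <- chol2inv(st$cholS)
  tryCatch(.safe_inverse(Sinv - H), error = function(e) NULL)
}

.fd_hessian <- function(fn, x, h = 1e-3, hh = NULL) {
  d <- length(x)
  H <- matrix(0, d, d)
  if (is.null(hh)) hh <- pmax(abs(x), 1) * h
  hh <- rep_len(hh, d)
  f0 <- fn(x)
  for (i in seq_len(d)) for (j in i:d) {
    ei <- ej <- numeric(d); ei[i] <- hh[i]; ej[j] <- hh[j]
    if (i == j) {
      H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / hh[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  H
}

# collapsed template target for the MH step (unwarped groups): counts
# merged over trials; W is the per-bin exposure (scalar or vector)
.beta_target <- function(beta, B, Y, W, pen_mat) {
  f <- drop(B %*% beta)
  sum(Y * f) - sum(W * exp(pmin(f, 50))) -
    drop(crossprod(beta, pen_mat %*% beta))
}

# warped-trial template target for the MH step on beta_pop: the sum over
# trials of the smooth warped-data likelihood, minus the roughness prior
.pop_beta_target <- function(st, a, cc, beta, warps, gains, npop, pen_mat) {
  f <- drop(st$basis$B %*% beta)
  s <- -drop(crossprod(beta, pen_mat %*% beta))
  for (rr in seq_len(st$R))
    s <- s + group_loglik_cpp(st$pop_counts[[a]][[cc]][[rr]],
                              warps[[rr]]$y, warps[[rr]]$x, f, gains[rr],
                              npop, st$basis$bin_width)
  s
}

.gibbs_step_templates <- function(st) {
  dt_s <- st$basis$dt_s
  for (a in st$areas) for (cc in st$conditions) {
    tm <- st$templates$tmpl[[a]][[cc]]
    qi <- st$dom_idx[[a]]
    npop <- st$npop[[a]][[cc]]
    if (npop > 0) {
      wk <- st$wk[[a]][[cc]]
      warps <- lapply(seq_len(st$R), function(rr)
        list(y = .wk_y(wk, st$q[cc, rr, qi[2]], st$q[cc, rr, qi[3]]), x = wk$x))
      gains <- st$q[cc, , qi[1]]
      pen <- st$eta_pop * npop * st$R * st$Omega
      cur <- .pop_beta_target(st, a, cc, tm$beta_pop, warps, gains, npop, pen)
      prop <- tm$beta_pop + drop(crossprod(st$prop$beta_pop[[a]][[cc]],
                                           stats::rnorm(st$basis$n_basis)))
      new <- .pop_beta_target(st, a, cc, prop, warps, gains, npop, pen)
      st$acc$beta_pop[2] <- st$acc$beta_pop[2] + 1
      if (log(stats::runif(1)) < new - cur) {
        tm$beta_pop <- prop
        st$acc$beta_pop[1] <- st$acc$beta_pop[1] + 1
      }
    }
    ls <- st$loc_stats[[a]][[cc]]
    n1 <- ls$n1
    if (n1 > 0) {
      Y1 <- ls$Y1
      wexp <- n1 * dt_s * st$R
      pen <- st$eta_loc1 * n1 * st$R * st$Omega
      cur <- .beta_target(tm$beta_loc1, st$basis$B, Y1, wexp, pen)
      prop <- tm$beta_loc1 + drop(crossprod(st$prop$beta_loc1[[a]][[cc]],
                                            stats::rnorm(st$basis$n_basis)))
      new <- .beta_target(prop, st$basis$B, Y1, wexp, pen)
      st$acc$beta_loc1[2] <- st$acc$beta_loc1[2] + 1
      if (log(stats::runif(1)) < new - cur) {
        tm$beta_loc1 <- prop
        st$acc$beta_loc1[1] <- st$acc$beta_loc1[1] + 1
      }
    }
    n2 <- ls$n2
    if (n2 > 0) {
      tot <- ls$tot2
      expo <- n2 * st$R * st$basis$n_bins * dt_s
      tgt <- function(b) tot * b - expo * exp(b)
      # 1-dim block: optimal random-walk scale 5.76/d with d = 1
      sd_prop <- sqrt(5.76 / max(tot, 1))
      bp <- tm$beta_loc2 + stats::rnorm(1, sd = sd_prop)
      st$acc$beta_loc2[2] <- st$acc$beta_loc2[2] + 1
      if (log(stats::runif(1)) < tgt(bp) - tgt(tm$beta_loc2)) {
        tm$beta_loc2 <- bp
        st$acc$beta_loc2[1] <- st$acc$beta_loc2[1] + 1
      }
    }
    st$templates$tmpl[[a]][[cc]] <- tm
    .set_f_cache(st, a, cc)
  }
}

.gibbs_step_q <- function(st) {
  d <- st$dim_q
  p_rec <- st$prop$recenter_prob
  for (cc in seq_len(st$C)) {
    Lp <- st$prop$q[[cc]]$chol_prop   # upper chol of scale * Q
    qbar <- colMeans(st$q[cc, , , drop = FALSE][1, , ])
    for (rr in seq_len(st$R)) {
      cur <- st$q[cc, rr, ]
      # mixture kernel: mostly a symmetric random walk; with probability
      # p_rec the mean-recentred proposal that pulls the across-trial
      # feature mean toward zero (identifiability of template position
      # versus shared shifts), with its exact Hastings correction
      recenter <- stats::runif(1) < p_rec
      mean_f <- if (recenter) cur - 0.5 * qbar else cur
      prop <- mean_f + drop(crossprod(Lp, stats::rnorm(d)))
      st$acc$q[2] <- st$acc$q[2] + 1
      lp_new <- .q_logpost(st, cc, rr, prop, st$cholS)
      if (!is.finite(lp_new)) next
      lp_cur <- .q_logpost(st, cc, rr, cur, st$cholS)
      lhast <- 0
      if (recenter) {
        # reverse-move proposal mean uses the trial mean with q_rr replaced
        qbar_new <- qbar + (prop - cur) / st$R
        mean_r <- prop - 0.5 * qbar_new
        lhast <- .ldmvnorm0(cur - mean_r, Lp) - .ldmvnorm0(prop - mean_f, Lp)
      }
      if (log(stats::runif(1)) < lp_new - lp_cur + lhast) {
        st$q[cc, rr, ] <- prop
        qbar <- qbar + (prop - cur) / st$R
        st$acc$q[1] <- st$acc$q[1] + 1
      }
    }
  }
}

.gibbs_step_z <- function(st) {
  for (a in st$areas) for (cc in st$conditions) {
    ll <- .neuron_group_ll(st, a, cc)
    lw <- sweep(ll, 2, log(pmax(st$p[a, cc, ], 1e-300)), "+")
    lw <- lw - apply(lw, 1, max)
    pr <- exp(lw); pr <- pr / rowSums(pr)
    u <- stats::runif(nrow(pr))
    st$z[[a]][, cc] <- 1L + (u > pr[, 1]) + (u > pr[, 1] + pr[, 2])
    .refresh_pop_cache(st, a, cc)
  }
}

.gibbs_step_p <- function(st) {
  al <- st$prior$alpha
  for (a in st$areas) for (cc in st$conditions) {
    cnt <- tabulate(st$z[[a]][, cc], 3)
    g <- stats::rgamma(3, shape = cnt + al)
    st$p[a, cc, ] <- g / sum(g)
  }
}

.gibbs_step_sigma <- function(st) {
  qmat <- .q_matrix(st)
  Psi <- st$prior$Psi0 + crossprod(qmat)
  nu <- st$prior$nu0 + nrow(qmat)
  if (min(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("posterior inverse-Wishart scale matrix is not positive definite")
  W <- stats::rWishart(1, nu, solve(Psi))[, , 1]
  st$Sigma <- solve(W)
  st$Sigma <- (st$Sigma + t(st$Sigma)) / 2
  st$cholS <- chol(st$Sigma)
}

#' Metropolis-within-Gibbs sampler
#'
#' Cycles template, feature, membership, probability, and covariance updates.
#' Template coefficients and trial features use Metropolis-Hastings with
#' fixed proposal curvature (scaled inverse Hessians estimated at the hard-EM
#' mode); memberships, probabilities, and the covariance are exact conjugate
#' draws (categorical, Dirichlet, inverse-Wishart). The feature proposal mean
#' is recentred by half the across-trial feature mean, which keeps the
#' otherwise weakly identified template-position/shift decomposition from
#' drifting.
#'
#' @param state state after [iprf_hard_em()]; modified in place.
#' @param n_iter total iterations.
#' @param burn_in iterations discarded before storing.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed RNG seed (same seed, identical chain).
#' @param proposal_scale scale multiplying the template-coefficient proposal
#'   covariance (5.76/d for the d = 102 coefficient block).
#' @param q_proposal_scale scale for the 9-dimensional feature-block
#'   proposals; the default applies the same 5.76/d rule at d = 9.
#' @param recenter_prob probability that a feature-block proposal uses the
#'   mean-recentred form (identifiability control) instead of the symmetric
#'   random walk.
#' @param verbose print progress every 100 iterations.
#' @return object of class `iprf_chain`: kept draws of `Sigma`
#'   (`n_kept` x 9 x 9), `q` (`n_kept` x C x R x 9), `p`, membership
#'   pop-probability running sums, template coefficient draws, acceptance
#'   rates per block, landmark specs, and metadata.
#' @export
iprf_gibbs <- function(state, n_iter = 2000, burn_in = 500, thin = 3,
                       seed = 1L, proposal_scale = 0.05,
                       q_proposal_scale = 5.76 / 9, recenter_prob = 0.2,
                       verbose = FALSE) {
  st <- state
  set.seed(seed)
  .prep_proposals(st, scale = proposal_scale, q_scale = q_proposal_scale,
                  recenter_prob = recenter_prob)
  keep_at <- seq.int(burn_in + 1L, n_iter)
  keep_at <- keep_at[(seq_along(keep_at) - 1L) %% thin == 0L]
  nk <- length(keep_at)
  nb <- st$basis$n_basis
  draws <- list(
    Sigma = array(NA_real_, c(nk, st$dim_q, st$dim_q)),
    q = array(NA_real_, c(nk, st$C, st$R, st$dim_q)),
    p = array(NA_real_, c(nk, st$A, st$C, 3)),
    beta_pop = array(NA_real_, c(nk, nb, st$A, st$C)),
    beta_loc2 = array(NA_real_, c(nk, st$A, st$C)))
  z_pop_sum <- stats::setNames(lapply(st$areas, function(a)
    matrix(0, st$N[[a]], st$C)), st$areas)
  ki <- 0L
  for (it in seq_len(n_iter)) {
    .gibbs_step_templates(st)
    .gibbs_step_q(st)
    .gibbs_step_z(st)
    .gibbs_step_p(st)
    .gibbs_step_sigma(st)
    if (ki < nk && it == keep_at[ki + 1L]) {
      ki <- ki + 1L
      draws$Sigma[ki, , ] <- st$Sigma
      draws$q[ki, , , ] <- st$q
      draws$p[ki, , , ] <- st$p
      for (ai in seq_len(st$A)) {
        a <- st$areas[ai]
        for (ci in seq_len(st$C)) {
          cc <- st$conditions[ci]
          draws$beta_pop[ki, , ai, ci] <- st$templates$tmpl[[a]][[cc]]$beta_pop
          draws$beta_loc2[ki, ai, ci] <- st$templates$tmpl[[a]][[cc]]$beta_loc2
          z_pop_sum[[a]][, ci] <- z_pop_sum[[a]][, ci] + (st$z[[a]][, cc] == 1L)
        }
      }
    }
    if (verbose && it %% 100 == 0) message("Gibbs iter ", it)
  }
  acc_rate <- vapply(st$acc, function(x) if (x[2] > 0) x[1] / x[2] else NA_real_,
                     numeric(1))
  low <- acc_rate < 0.2 | acc_rate > 0.8
  if (any(low, na.rm = TRUE))
    message("MH acceptance rate outside [0.2, 0.8] for block(s): ",
            paste(names(acc_rate)[which(low)], collapse = ", "))
  structure(list(
    draws = draws, n_kept = nk, keep_at = keep_at,
    z_pop_freq = lapply(z_pop_sum, function(m) m / max(ki, 1)),
    acceptance = acc_rate,
    specs = lapply(st$areas, function(a) lapply(st$templates$tmpl[[a]], `[[`, "spec")),
    areas = st$areas, conditions = st$conditions,
    R = st$R, basis = st$basis,
    feature_names = feature_names(st$A),
    settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    seed = seed, proposal_scale = proposal_scale)),
    class = "iprf_chain")
}

#' Fit the full model
#'
#' Convenience wrapper: [iprf_init()], [iprf_hard_em()], then [iprf_gibbs()].
#'
#' @param dataset a [spike_dataset()].
#' @param n_iter,burn_in,thin,seed Gibbs settings.
#' @param em_max_iter,em_tol hard-EM settings.
#' @param ... passed to [iprf_init()].
#' @param verbose progress messages.
#' @return list with the `state` (post-EM), the `chain`, and the EM trace.
#' @export
iprf_fit <- function(dataset, n_iter = 2000, burn_in = 500, thin = 3,
                     seed = 1L, em_max_iter = 50, em_tol = 1e-6, ...,
                     verbose = FALSE) {
  st <- iprf_init(dataset, ...)
  st <- iprf_hard_em(st, max_iter = em_max_iter, tol = em_tol, verbose = verbose)
  ch <- iprf_gibbs(st, n_iter = n_iter, burn_in = burn_in, thin = thin,
                   seed = seed, verbose = verbose)
  list(state = st, chain = ch, em_trace = attr(st, "em_trace"))
}

#' @export
print.iprf_chain <- function(x, ...) {
  cat("iprf_chain:", x$n_kept, "kept draws (",
      x$settings$n_iter, "iterations, burn-in", x$settings$burn_in,
      ", thin", x$settings$thin, ")\n")
  cat("MH acceptance rates:\n")
  print(round(x$acceptance, 3))
  invisible(x)
}
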