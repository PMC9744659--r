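#' Cubic B-spline basis on an equally spaced knot grid
#'
#' Builds the cubic B-spline basis used for all log firing-rate templates.
#' Knots are equally spaced over `[0, T]` (boundary knots included), and the
#' basis is evaluated at the midpoints of the analysis bins. With the default
#' 100 knots over a 500 ms window there are 102 basis functions.
#'
#' @param T analysis window length in ms.
#' @param n_knots number of equally spaced knots spanning `[0, T]`
#'   (boundaries included); must be at least 4.
#' @param bin_width bin width in ms; must divide `T`.
#' @return An object of class `iprf_basis`: a list with the basis matrix `B`
#'   (`n_bins` x `n_basis`), the evaluation times `times` (bin midpoints, ms),
#'   the knot sequence, and the grid geometry (`T`, `bin_width`, `n_bins`,
#'   `n_basis`, `dt_s` = bin width in seconds).
#' @examples
#' b <- bspline_basis(500, 100, 2)
#' dim(b$B)   # 250 x 102
#' @export
bspline_basis <- function(T = 500, n_knots = 100, bin_width = 2) {
  if (n_knots < 4) stop("n_knots must be >= 4")
  if (T <= 0 || bin_width <= 0) stop("T and bin_width must be positive")
  n_bins <- T / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8) stop("bin_width must divide T")
  n_bins <- as.integer(round(n_bins))
  knots <- seq(0, T, length.out = n_knots)
  all_knots <- c(rep(0, 3), knots, rep(T, 3))
  times <- (seq_len(n_bins) - 0.5) * bin_width
  B <- splines::splineDesign(all_knots, times, ord = 4L)
  structure(list(
    B = B, times = times, knots = knots, all_knots = all_knots,
    T = T, bin_width = bin_width, n_bins = n_bins,
    n_basis = ncol(B), dt_s = bin_width / 1000
  ), class = "iprf_basis")
}

#' Evaluate the spline on arbitrary times
#'
#' @param basis an [bspline_basis()] object.
#' @param beta coefficient vector of length `basis$n_basis`.
#' @param t times in ms within `[0, T]`.
#' @return the spline values at `t`.
#' @export
eval_spline <- function(basis, beta, t) {
  t <- pmin(pmax(t, 0), basis$T)
  drop(splines::splineDesign(basis$all_knots, t, ord = 4L) %*% beta)
}

#' Second-derivative roughness penalty matrix
#'
#' Computes `Omega[i, j] = integral of B_i''(x) B_j''(x) dx` over the window by
#' exact Gauss-Legendre quadrature: second derivatives of cubic B-splines are
#' piecewise linear, so their products are piecewise quadratic and a 2-point
#' rule on each inter-knot interval integrates them exactly.
#'
#' @param basis an [bspline_basis()] object.
#' @return symmetric positive semidefinite matrix `n_basis` x `n_basis`;
#'   coefficient vectors representing straight lines have zero penalty.
#' @export
roughness_penalty <- function(basis) {
  k <- basis$knots
  # 2-point Gauss-Legendre nodes on each interval [k[i], k[i+1]]
  g <- 1 / sqrt(3)
  lo <- k[-length(k)]
  hi <- k[-1]
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  nodes <- c(mid - half * g, mid + half * g)
  w <- rep(half, 2L)  # weights: half-length per node for the 2-point rule
  D2 <- splines::splineDesign(basis$all_knots, nodes, ord = 4L, derivs = 2L)
  Omega <- crossprod(D2 * sqrt(w))
  (Omega + t(Omega)) / 2
}

# Penalized Poisson log-likelihood pieces, collapsed over trials.
# counts: n_bins x n_trials matrix; offsets: length n_trials; exposure: N;
# exposure_weights: optional n_bins x n_trials bin-time weights (warp
# occupancy), 1 everywhere when NULL.
# Objective: sum_r l(y_r, N exp{B beta + off_r}) - eta * N * R * beta' Omega beta
# where l is the discretized point-process log-likelihood (bin width dt_s).
.collapse_trains <- function(counts, offsets, exposure, dt_s,
                             exposure_weights = NULL) {
  counts <- as.matrix(counts)
  R <- ncol(counts)
  if (length(offsets) == 1L) offsets <- rep(offsets, R)
  stopifnot(length(offsets) == R)
  W <- if (is.null(exposure_weights)) {
    rep(exposure * dt_s * sum(exp(offsets)), nrow(counts))
  } else {
    exposure * dt_s * drop(as.matrix(exposure_weights) %*% exp(offsets))
  }
  list(
    Y = rowSums(counts),
    W = W,
    off_dot = sum(colSums(counts) * offsets),
    lfact = sum(lgamma(counts + 1)),
    total = sum(counts),
    R = R
  )
}

#' Penalized Poisson template fit
#'
#' Maximizes the penalized discretized point-process log-likelihood
#' `sum_r l(y_r, N exp(B beta + offset_r)) - eta * N * R * beta' Omega beta`
#' over the spline coefficients `beta` by damped Newton iteration
#' (iteratively reweighted least squares with step halving).
#'
#' @param counts matrix of spike counts (`n_bins` x `n_trials`), or a vector
#'   for a single train.
#' @param basis an [bspline_basis()] object.
#' @param penalty the [roughness_penalty()] matrix.
#' @param eta smoothing weight (>= 0).
#' @param offsets per-trial additive offset on the log rate (e.g. trial gains);
#'   scalar or length `n_trials`.
#' @param exposure number of merged neurons `N` (exposure multiplier).
#' @param exposure_weights optional `n_bins` x `n_trials` matrix of bin-time
#'   weights (warp occupancy for time-warped trains); 1 everywhere if `NULL`.
#' @param tol relative change in the penalized objective at which to stop.
#' @param max_iter maximum Newton iterations.
#' @return list with `beta`, the fitted log rate `f` (spikes/s, on the bin
#'   grid), the penalized objective `objective`, `converged`, `n_iter`, and
#'   `neg_hessian` (the penalized observed information at the optimum).
#' @export
fit_penalized_poisson <- function(counts, basis, penalty, eta,
                                  offsets = 0, exposure = 1,
                                  exposure_weights = NULL,
                                  tol = 1e-8, max_iter = 100L) {
  if (eta < 0) stop("eta must be >= 0")
  if (any(counts < 0)) stop("counts must be nonnegative")
  cl <- .collapse_trains(counts, offsets, exposure, basis$dt_s, exposure_weights)
  B <- basis$B
  pen <- 2 * eta * exposure * cl$R * penalty
  # initial value: ridge least squares on smoothed log counts
  rate0 <- (cl$Y + 0.5) / pmax(cl$W, .Machine$double.eps)
  z0 <- log(rate0)
  beta <- solve(crossprod(B) + pen + 1e-8 * diag(ncol(B)), crossprod(B, z0))
  obj_fun <- function(beta) {
    f <- drop(B %*% beta)
    sum(cl$Y * f) - sum(cl$W * exp(pmin(f, 50))) -
      drop(crossprod(beta, pen %*% beta)) / 2
  }
  obj <- obj_fun(beta)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    f <- drop(B %*% beta)
    mu <- cl$W * exp(pmin(f, 50))
    grad <- crossprod(B, cl$Y - mu) - pen %*% beta
    H <- crossprod(B * sqrt(mu)) + pen
    step <- tryCatch(solve(H + 1e-10 * diag(ncol(B)), grad),
                     error = function(e) grad / max(diag(H)))
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      obj_new <- obj_fun(beta_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { beta_new <- beta; obj_new <- obj; break }
    }
    done <- abs(obj_new - obj) < tol * (abs(obj) + 1e-10)
    beta <- drop(beta_new)
    obj <- obj_new
    if (done) { converged <- TRUE; break }
  }
  f <- drop(B %*% beta)
  mu <- cl$W * exp(pmin(f, 50))
  # full log-likelihood value (with constants) + penalty
  loglik <- sum(cl$Y * f) - sum(mu) +
    cl$off_dot + cl$total * log(exposure * basis$dt_s) - cl$lfact
  list(beta = beta, f = f, objective = obj, loglik = loglik,
       converged = converged, n_iter = it,
       neg_hessian = crossprod(B * sqrt(mu)) + 2 * eta * exposure * cl$R * penalty)
}

#' Select the smoothing weight by fivefold cross-validation
#'
#' Trials are split into five folds by a deterministic seeded shuffle; for each
#' `eta` on the grid the template is fitted on the training folds and scored by
#' the held-out discretized Poisson log-likelihood. Returns the `eta`
#' maximizing the mean held-out score.
#'
#' @param counts matrix of spike counts (`n_bins` x `n_trials`).
#' @param basis,penalty as in [fit_penalized_poisson()].
#' @param grid candidate `eta` values; default 7 values spanning 6 orders of
#'   magnitude.
#' @param offsets,exposure as in [fit_penalized_poisson()].
#' @param n_folds number of folds (trials are split across folds).
#' @param seed seed for the fold shuffle.
#' @return list with `eta` (the selected value), `score` (mean held-out
#'   log-likelihood per grid point) and `grid`.
#' @export
cv_select_eta <- function(counts, basis, penalty,
                          grid = 10^seq(-3, 3, length.out = 7),
                          offsets = 0, exposure = 1,
                          n_folds = 5L, seed = 1L) {
  if (length(grid) == 0L) stop("empty eta grid")
  counts <- as.matrix(counts)
  R <- ncol(counts)
  if (length(grid) == 1L) return(list(eta = grid, score = NA_real_, grid = grid))
  if (R < n_folds) stop("need at least ", n_folds, " trials for CV")
  if (length(offsets) == 1L) offsets <- rep(offsets, R)
  perm <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sample.int(R)
  })
  fold <- rep_len(seq_len(n_folds), R)[order(perm)]
  scores <- vapply(grid, function(eta) {
    s <- 0
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      fit <- fit_penalized_poisson(counts[, tr, drop = FALSE], basis, penalty,
                                   eta, offsets[tr], exposure)
      for (r in which(!tr)) {
        mu <- exposure * exp(fit$f + offsets[r]) * basis$dt_s
        s <- s + pp_loglik(counts[, r], mu)
      }
    }
    s / R
  }, numeric(1))
  list(eta = grid[which.max(scores)], score = scores, grid = grid)
}

# save/restore the RNG state so seeded internals do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
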