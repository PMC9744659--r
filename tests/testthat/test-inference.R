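test_that("correlations from a covariance follow the standard formula", {
  expect_true(all(corr_from_sigma(diag(3))$rho == 0))
  S <- matrix(c(4, 3, 3, 9), 2)
  expect_equal(corr_from_sigma(S)$rho, 0.5)
  # idempotence on the induced correlation matrix
  S2 <- default_sigma()
  r1 <- corr_from_sigma(S2)$rho
  expect_equal(corr_from_sigma(stats::cov2cor(S2))$rho, r1, tolerance = 1e-12)
  expect_error(corr_from_sigma(matrix(c(0, 0, 0, 1), 2)), "variance")
})

test_that("partial correlation matches closed form and residual oracle", {
  R <- matrix(0.9, 3, 3); diag(R) <- 1
  expect_equal(partial_corr(R, 1, 2, 3), 0.09 / 0.19, tolerance = 1e-12)
  R2 <- diag(3); R2[1, 2] <- R2[2, 1] <- 0.4
  expect_equal(partial_corr(R2, 1, 2, 3), 0.4, tolerance = 1e-12)
  # residual oracle: correlation of exact least-squares residuals
  set.seed(14)
  X <- matrix(rnorm(5000 * 3), ncol = 3) %*% chol(R)
  S <- cov(X)
  res1 <- resid(lm(X[, 1] ~ X[, 3]))
  res2 <- resid(lm(X[, 2] ~ X[, 3]))
  expect_equal(partial_corr(S, 1, 2, 3), cor(res1, res2), tolerance = 1e-10)
})

test_that("posterior functionals report quantiles consistent with sorting", {
  chain <- structure(list(
    n_kept = 200,
    draws = list(Sigma = array(rep(diag(2), each = 200), c(200, 2, 2)),
                 q = array(rnorm(200 * 1 * 2 * 2), c(200, 1, 2, 2)))),
    class = "iprf_chain")
  set.seed(15)
  vals <- rnorm(200)
  pf <- posterior_functionals(chain, local({
    i <- 0
    function(draw) { i <<- i + 1; vals[i] }
  }))
  expect_equal(pf$median, median(vals))
  expect_equal(pf$q025, unname(quantile(vals, 0.025)))
  expect_equal(pf$q975, unname(quantile(vals, 0.975)))
  # constant chain: zero-width interval
  pf0 <- posterior_functionals(chain, function(draw) 1.5)
  expect_equal(pf0$q025, 1.5)
  expect_equal(pf0$q975, 1.5)
  expect_equal(pf0$mode, 1.5)
})

test_that("Fisher-z intervals match the closed form", {
  ci <- fisher_z_ci(0.5, 195)
  expect_equal(ci, c(0.387, 0.598), tolerance = 2e-3)
  ci0 <- fisher_z_ci(0, 195)
  expect_equal(ci0[2], tanh(1.96 / sqrt(192)), tolerance = 1e-3)
  expect_equal(ci0[1], -ci0[2])
  expect_true(all(abs(fisher_z_ci(0.999, 20)) < 1))
  expect_equal(fisher_z_ci(1, 20), c(1, 1))
  expect_error(fisher_z_ci(0.5, 3), "n > 3")
})

test_that("peak times combine landmarks with posterior median shifts", {
  sim <- small_sim()
  spec <- sim$truth$spec
  nk <- 120
  qd <- array(0, c(nk, 2, 15, 9))
  qd[, , , 3] <- 5   # constant peak-2 shift of +5 in area 1
  chain <- structure(list(
    n_kept = nk, R = 15,
    draws = list(Sigma = array(rep(diag(9), each = nk), c(nk, 9, 9)), q = qd,
                 p = NULL),
    specs = rep(list(rep(list(spec), 2)), 3),
    areas = paste0("area", 1:3), conditions = c("1", "2"),
    feature_names = feature_names(3)), class = "iprf_chain")
  pl <- peak_times_and_lags(chain)
  a1 <- pl$peak_times[pl$peak_times$area == "area1", ]
  expect_true(all(a1$peak2 == spec$tpeak2 + 5))
  expect_true(all(a1$peak1 == spec$tpeak1))
  lag <- pl$lags[pl$lags$area_from == "area1" & pl$lags$area_to == "area2" &
                   pl$lags$peak == "peak2", ]
  expect_equal(lag$median, 5)
})

test_that("naive single-trial peak estimates locate clean and shifted bumps", {
  set.seed(16)
  mk_trial <- function(cc, r, center, n_neur = 8, amp = 80) {
    tt <- seq(1, 499, 2)
    rate <- 10 + amp * exp(-(tt - center)^2 / (2 * 15^2))
    k <- rpois(250, n_neur * rate * 0.002)
    nz <- which(k > 0)
    data.frame(neuron_id = paste0("n", sprintf("%02d", 1:n_neur))[1 + (seq_len(sum(k[nz])) %% n_neur)],
               area = "A", condition_id = cc, trial_id = r,
               time_ms = rep((nz - 1) * 2, k[nz]) + runif(sum(k[nz])) * 2)
  }
  tab <- rbind(mk_trial(1, 1, 216), mk_trial(1, 2, 206), mk_trial(1, 3, 226))
  ds <- spike_dataset(tab, T = 500)
  pk <- naive_peak_times(ds, unique(tab$neuron_id), window = c(150, 300),
                         eta = 10)
  expect_lt(abs(pk$peak_time[1] - 216), 10)
  expect_lt(abs((pk$peak_time[3] - pk$peak_time[2]) - 20), 10)
})
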