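# Unit tests for initialization, landmarks, and the conjugate Gibbs blocks.
# MH-vs-grid checks live in test-acceptance.R.

test_that("landmark search locates two-peak structure", {
  tt <- seq(1, 499, 2)
  f <- log(5 + 60 * exp(-(tt - 57)^2 / 200) + 40 * exp(-(tt - 216)^2 / 800))
  sp <- find_landmarks(f, tt)
  expect_lt(abs(sp$tpeak1 - 57), 2.5)
  expect_lt(abs(sp$tpeak2 - 216), 2.5)
  # symmetric peak: boundaries symmetric about the peak within one bin
  expect_lt(abs((sp$tpeak1 - sp$t1L) - (sp$t1R - sp$tpeak1)), 2.5)
  # monotone template: screening failure
  expect_error(find_landmarks(0.01 * tt, tt), "screening failure")
})

test_that("initial activity split follows the 25/50/25 rule", {
  sim <- small_sim()
  st <- iprf_init(sim$dataset, eta = c(100, 100))
  z1 <- st$z[["area1"]][, 1]
  expect_equal(sum(z1 == 1L), round(0.25 * 30))
  expect_equal(sum(z1 == 2L), 30 - 2 * round(0.25 * 30))
  expect_equal(sum(z1 == 3L), round(0.25 * 30))
  # the split is by total activity: every pop neuron out-spikes every local-2
  tot <- iprf:::.neuron_totals(sim$dataset, "area1")
  expect_gt(min(tot[z1 == 1L]), max(tot[z1 == 3L]) - 1e-9)
  # all features start at zero and probabilities match the split
  expect_true(all(st$q == 0))
  expect_equal(unname(st$p["area1", "1", ]), c(8, 14, 8) / 30, tolerance = 1e-9)
})

test_that("quantile split matches the documented example", {
  # counts [12, 9, 7, 5, 3, 1, 0, 0] -> high {12, 9}, low {0, 0}
  counts <- c(12, 9, 7, 5, 3, 1, 0, 0)
  ord <- order(-counts)
  n_hi <- round(0.25 * 8); n_lo <- round(0.25 * 8)
  expect_equal(sort(counts[ord[seq_len(n_hi)]]), c(9, 12))
  expect_equal(counts[ord[seq.int(8 - n_lo + 1, 8)]], c(0, 0))
})

test_that("membership probabilities draw from the documented Dirichlet", {
  sim <- small_sim()
  st <- iprf_init(sim$dataset, eta = c(100, 100))
  # force known counts: 10 / 40 / ... scaled to 30 neurons: use real z counts
  st$z[["area1"]][, 1] <- rep(1:3, c(5, 20, 5))
  set.seed(20)
  draws <- replicate(4000, {
    iprf:::.gibbs_step_p(st)
    st$p["area1", "1", ]
  })
  m <- unname(rowMeans(draws))
  expect_equal(m, (c(5, 20, 5) + 5) / (30 + 15), tolerance = 0.02)
  v <- unname(apply(draws, 1, var))
  a0 <- 45
  expect_equal(v, m * (1 - m) / (a0 + 1), tolerance = 0.1)
})

test_that("covariance draws follow the inverse-Wishart posterior", {
  sim <- small_sim(C = 2)
  st <- iprf_init(sim$dataset, eta = c(100, 100))
  # nu arithmetic: nu0 = 3A + 1, nu_tilde = nu0 + RC
  expect_equal(st$prior$nu0, 10)
  # with q = 0 the posterior scale is exactly Psi0
  st$q[] <- 0
  set.seed(21)
  n_draw <- 3000
  acc <- matrix(0, n_draw, 2)
  for (i in seq_len(n_draw)) {
    iprf:::.gibbs_step_sigma(st)
    acc[i, ] <- c(st$Sigma[1, 1], st$Sigma[2, 2])
  }
  nu_t <- 10 + 30
  # IW marginal mean of a diagonal entry: Psi_ii / (nu - p - 1)
  expect_equal(mean(acc[, 1]), st$prior$Psi0[1, 1] / (nu_t - 9 - 1),
               tolerance = 0.05)
  expect_equal(mean(acc[, 2]), st$prior$Psi0[2, 2] / (nu_t - 9 - 1),
               tolerance = 0.05)
})

test_that("membership draws match enumerated categorical probabilities", {
  sim <- small_sim()
  st <- iprf_init(sim$dataset, eta = c(100, 100))
  # equal group likelihoods: make all three templates identical constants
  for (a in st$areas) for (cc in st$conditions) {
    tm <- st$templates$tmpl[[a]][[cc]]
    flat <- iprf:::.project_spline(st$basis, rep(log(10), st$basis$n_bins))
    tm$beta_pop <- tm$beta_loc1 <- flat
    tm$beta_loc2 <- log(10)
    st$templates$tmpl[[a]][[cc]] <- tm
    iprf:::.set_f_cache(st, a, cc)
  }
  st$q[] <- 0
  st$p["area1", "1", ] <- c(0.5, 0.3, 0.2)
  ll <- iprf:::.neuron_group_ll(st, "area1", "1")
  expect_lt(max(abs(ll[, 1] - ll[, 2])), 1e-6)
  expect_lt(max(abs(ll[, 1] - ll[, 3])), 1e-6)
  # with equal likelihoods the draw frequencies must match p (chi-squared)
  set.seed(22)
  n_draw <- 600
  freq <- matrix(0, 3, 1)
  counts <- c(0, 0, 0)
  for (i in seq_len(n_draw)) {
    st$p["area1", "1", ] <- c(0.5, 0.3, 0.2)   # keep the prior fixed
    iprf:::.gibbs_step_z(st)
    counts <- counts + tabulate(st$z[["area1"]][, 1], 3)
  }
  n_tot <- n_draw * 30
  pv <- chisq.test(counts, p = c(0.5, 0.3, 0.2))$p.value
  expect_gt(pv, 1e-4)
  # saturation: a 100-nat likelihood gap forces the favored group
  lw <- matrix(c(100, 0, 0), 1, 3)
  pr <- exp(lw - max(lw)); pr <- pr / sum(pr)
  expect_lt(pr[2] + pr[3], 1e-40)
})

test_that("hard EM increases the penalized posterior and keeps z stable at truth", {
  sim <- small_sim()
  st <- iprf_init(sim$dataset, eta = c(100, 100))
  st <- iprf_hard_em(st, max_iter = 4, tol = 1e-6, optim_maxit = 60)
  tr <- attr(st, "em_trace")
  # ascent up to small numerical slack
  expect_true(all(diff(tr) > -abs(tr[1]) * 1e-3))
})

test_that("the sampler is reproducible given a seed", {
  sim <- small_sim()
  st1 <- iprf_init(sim$dataset, eta = c(100, 100))
  st1 <- iprf_hard_em(st1, max_iter = 2, tol = 1e-4, optim_maxit = 40)
  ch1 <- iprf_gibbs(st1, n_iter = 30, burn_in = 10, thin = 1, seed = 99)
  st2 <- iprf_init(sim$dataset, eta = c(100, 100))
  st2 <- iprf_hard_em(st2, max_iter = 2, tol = 1e-4, optim_maxit = 40)
  ch2 <- iprf_gibbs(st2, n_iter = 30, burn_in = 10, thin = 1, seed = 99)
  expect_identical(ch1$draws$Sigma, ch2$draws$Sigma)
  expect_identical(ch1$draws$q, ch2$draws$q)
  # acceptance logs present for every MH block
  expect_true(all(c("beta_pop", "beta_loc1", "beta_loc2", "q") %in%
                    names(ch1$acceptance)))
})
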