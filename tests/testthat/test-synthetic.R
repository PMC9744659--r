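test_that("template shapes place their landmarks as documented", {
  sh <- make_template("sharp-peak")
  expect_lt(abs(sh$times[which.max(sh$f)] - 216), 2.5)
  inv <- make_template("inverted-peak")
  expect_lt(abs(inv$times[which.min(inv$f)] - 216), 2.5)
  rta <- make_template("rise-to-asymptote")
  # half-rise point of the log-rate incline equals the analytic midpoint
  half <- (log(rta$params$base) + log(rta$params$peak_rate)) / 2
  expect_lt(abs(rta$times[which.min(abs(rta$f - half))] - rta$params$center), 3)
  two <- make_template("two-peak")
  expect_lt(abs(two$spec$tpeak1 - 57), 3)
  expect_lt(abs(two$spec$tpeak2 - 216), 3)
  expect_error(make_template("zigzag"), "unknown template shape")
})

test_that("default covariance has the documented block structure", {
  S <- default_sigma()
  expect_equal(dim(S), c(9L, 9L))
  expect_equal(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0, TRUE)
  R <- cov2cor(S)
  expect_equal(R[3, 6], 0.85)
  expect_equal(R[2, 5], 0.6)
  expect_equal(R[1, 4], 0.3)
  expect_equal(R[1, 2], 0)           # no cross-feature coupling
  expect_equal(sqrt(diag(S))[1:3], c(0.1, 5, 30), ignore_attr = TRUE)
})

test_that("the simulator is seed-reproducible and respects the gain", {
  s1 <- simulate_iprf(A = 2, C = 1, R = 4, N = 8, Sigma = default_sigma(2), seed = 5)
  s2 <- simulate_iprf(A = 2, C = 1, R = 4, N = 8, Sigma = default_sigma(2), seed = 5)
  expect_identical(s1$truth$q, s2$truth$q)
  t1 <- s1$dataset$spikes[["area1"]][["1"]][["2"]]
  t2 <- s2$dataset$spikes[["area1"]][["1"]][["2"]]
  expect_identical(t1$times, t2$times)
  # gain = log 2 doubles expected pop counts: check via the generative law
  set.seed(6)
  sh <- make_template("two-peak")
  lam <- exp(sh$f) * 0.002
  n_rep <- 400
  c0 <- colSums(matrix(rpois(250 * n_rep, lam), 250))
  c2 <- colSums(matrix(rpois(250 * n_rep, 2 * lam), 250))
  expect_equal(mean(c2) / mean(c0), 2, tolerance = 0.05)
})

test_that("with near-zero feature variance counts are Poisson from the template", {
  sim <- simulate_iprf(A = 1, C = 1, R = 30, N = 12,
                       Sigma = diag(c(1e-6, 1e-6, 1e-6)), seed = 9)
  # all pop neurons share the unwarped template rate; chi-squared GOF of
  # per-trial counts in a fixed window against Poisson
  ds <- sim$dataset
  pop <- which(sim$truth$z[1, 1, ] == 1L)
  lam_bin <- exp(sim$truth$f_pop) * 0.002
  # counts of one pop neuron across trials in bins 100-150 (one block)
  blk <- 100:150
  expected <- sum(lam_bin[blk])
  obs <- sapply(1:30, function(rr) {
    tr <- ds$spikes[["area1"]][["1"]][[as.character(rr)]]
    sum(tr$neuron %in% pop & tr$times >= (min(blk) - 1) * 2 &
          tr$times < max(blk) * 2)
  })
  expect_equal(mean(obs), length(pop) * expected, tolerance = 0.25 * length(pop) * expected)
  # dispersion consistent with Poisson
  expect_lt(var(obs) / mean(obs), 2)
  expect_gt(var(obs) / mean(obs), 0.4)
})

test_that("simulator rejects invalid covariance", {
  S <- default_sigma(2); S[1, 1] <- -1
  expect_error(simulate_iprf(A = 2, Sigma = S, seed = 1), "positive definite")
})

test_that("neuron noise injection preserves means and inflates dispersion", {
  times <- seq(1, 499, 2)
  base <- matrix(log(20), 250, 40)
  expect_identical(inject_neuron_noise(base, times, scale = 0), base)
  set.seed(33)
  pert <- inject_neuron_noise(base, times, scale = 1)
  expect_equal(mean(pert - base), 0, tolerance = 0.05)
  # count dispersion: Fano factor of per-neuron totals grows with the scale
  totals <- function(lr) {
    apply(lr, 2, function(f) sum(rpois(250, exp(f) * 0.002)))
  }
  set.seed(34)
  f0 <- var(totals(base)) / mean(totals(base))
  p20 <- inject_neuron_noise(base, times, scale = 20)
  f20 <- var(totals(p20)) / mean(totals(p20))
  expect_gt(f20, f0)
})

test_that("recovery summaries reduce to the stated arithmetic", {
  per <- data.frame(
    replicate = c(1, 2), pair = "x:y", truth = 0.9,
    estimate = c(0.8, 1.0), lower = c(0.7, 0.85), upper = c(0.95, 1.0))
  s <- summarize_recovery(per)
  expect_equal(s$bias, 0)
  expect_equal(s$rmse, 0.1)
  expect_equal(s$coverage, 1)
  # estimates identical to truth: all zero
  per2 <- transform(per, estimate = truth)
  s2 <- summarize_recovery(per2)
  expect_equal(s2$bias, 0)
  expect_equal(s2$rmse, 0)
  # brute-force recomputation from the per-replicate table
  set.seed(35)
  per3 <- data.frame(replicate = 1:10,
                     pair = rep(c("a", "b"), each = 5),
                     truth = 0.5, estimate = runif(10),
                     lower = 0, upper = 1)
  s3 <- summarize_recovery(per3)
  for (pp in c("a", "b")) {
    e <- per3$estimate[per3$pair == pp]
    expect_equal(s3$bias[s3$pair == pp], mean(e - 0.5))
    expect_equal(s3$rmse[s3$pair == pp], sqrt(mean((e - 0.5)^2)))
  }
})
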