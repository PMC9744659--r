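test_that("basis has the documented dimensions and partition of unity", {
  b <- bspline_basis(500, 100, 2)
  expect_equal(dim(b$B), c(250L, 102L))
  expect_equal(rowSums(b$B), rep(1, 250), tolerance = 1e-10)
  expect_true(all(b$B >= 0))
  expect_error(bspline_basis(500, 3, 2), "n_knots")
  expect_error(bspline_basis(500, 100, 3), "divide")
})

test_that("basis reproduces cubic polynomials exactly", {
  b <- bspline_basis(500, 20, 2)
  y <- 1 + 0.02 * b$times - 1e-5 * b$times^2 + 3e-8 * b$times^3
  beta <- qr.solve(b$B, y)
  expect_equal(drop(b$B %*% beta), y, tolerance = 1e-8)
  # and eval_spline agrees off the grid
  t_off <- c(0.3, 123.45, 499.9)
  expect_equal(eval_spline(b, beta, t_off),
               1 + 0.02 * t_off - 1e-5 * t_off^2 + 3e-8 * t_off^3,
               tolerance = 1e-6)
})

test_that("roughness penalty annihilates straight lines and is PSD", {
  b <- bspline_basis(500, 30, 2)
  Om <- roughness_penalty(b)
  beta_lin <- qr.solve(b$B, 2 + 0.01 * b$times)
  expect_lt(drop(crossprod(beta_lin, Om %*% beta_lin)), 1e-10)
  ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("roughness penalty matches dense numerical quadrature", {
  b <- bspline_basis(500, 12, 2)
  Om <- roughness_penalty(b)
  # brute-force quadrature of products of second derivatives
  xs <- seq(0, 500, length.out = 20001)
  D2 <- splines::splineDesign(b$all_knots, xs, ord = 4L, derivs = 2L)
  h <- diff(xs)[1]
  w <- rep(h, length(xs)); w[c(1, length(xs))] <- h / 2
  Om_num <- crossprod(D2 * sqrt(w))
  expect_equal(Om, Om_num, tolerance = 1e-6)
})

test_that("penalized Poisson fit recovers a constant rate", {
  b <- bspline_basis(500, 100, 2)
  Om <- roughness_penalty(b)
  set.seed(3)
  counts <- matrix(rpois(250 * 20, 10 * 0.002 * 5), 250, 20)  # 5 neurons, 10 Hz
  fit <- fit_penalized_poisson(counts, b, Om, eta = 1e5, exposure = 5)
  expect_true(fit$converged)
  expect_equal(mean(exp(fit$f)), 10, tolerance = 0.1)
  # in the stiff limit the log rate is in the penalty nullspace (a line)
  expect_lt(max(abs(diff(fit$f, differences = 2))), 1e-3)
})

test_that("very stiff penalty drives the log rate to a straight line", {
  b <- bspline_basis(500, 50, 2)
  Om <- roughness_penalty(b)
  set.seed(4)
  lam <- exp(1 + 0.004 * b$times) * 0.002
  counts <- matrix(rpois(250 * 30, lam), 250, 30)
  fit <- fit_penalized_poisson(counts, b, Om, eta = 1e8)
  # second differences of the fitted log rate vanish
  expect_lt(max(abs(diff(fit$f, differences = 2))), 1e-4)
})

test_that("tiny-instance fit matches a generic optimizer", {
  b <- bspline_basis(20, 6, 2)   # 10 bins, 8 basis functions
  Om <- roughness_penalty(b)
  set.seed(5)
  y <- rpois(10, 3)
  eta <- 0.5
  fit <- fit_penalized_poisson(y, b, Om, eta)
  obj <- function(beta) {
    f <- drop(b$B %*% beta)
    -(sum(y * f) - sum(exp(f) * b$dt_s) - eta * drop(crossprod(beta, Om %*% beta)))
  }
  # likelihood term scale: fit uses mu = exposure * exp(f) * dt_s
  obj_fit <- function(beta) {
    f <- drop(b$B %*% beta)
    -(sum(y * f) - b$dt_s * sum(exp(f)) - eta * drop(crossprod(beta, Om %*% beta)))
  }
  o <- optim(fit$beta + 0.1, obj_fit, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-12))
  expect_lt(abs(obj_fit(fit$beta) - o$value), 1e-4)
  expect_equal(drop(b$B %*% fit$beta), drop(b$B %*% o$par), tolerance = 1e-2)
})

test_that("exposure scales expected counts, not the fitted log rate", {
  b <- bspline_basis(500, 100, 2)
  Om <- roughness_penalty(b)
  set.seed(6)
  counts1 <- matrix(rpois(250 * 10, 20 * 0.002), 250, 10)
  counts2 <- counts1 * 2L
  f1 <- fit_penalized_poisson(counts1, b, Om, 10, exposure = 1)$f
  f2 <- fit_penalized_poisson(counts2, b, Om, 10, exposure = 2)$f
  expect_equal(f1, f2, tolerance = 1e-5)
})

test_that("cross-validation selects sensible smoothing weights", {
  b <- bspline_basis(500, 100, 2)
  Om <- roughness_penalty(b)
  expect_equal(cv_select_eta(matrix(0, 250, 6), b, Om, grid = 7)$eta, 7)
  expect_error(cv_select_eta(matrix(0, 250, 6), b, Om, grid = numeric(0)),
               "empty")
  set.seed(7)
  # smooth two-peak rate: selected eta beats both grid endpoints on held-out
  rate <- 5 + 30 * exp(-(b$times - 100)^2 / 200) + 20 * exp(-(b$times - 300)^2 / 800)
  counts <- matrix(rpois(250 * 10, rate * 0.002), 250, 10)
  grid <- 10^seq(-3, 3, length.out = 7)
  sel <- cv_select_eta(counts, b, Om, grid)
  expect_gte(sel$score[match(sel$eta, grid)], sel$score[1])
  expect_gte(sel$score[match(sel$eta, grid)], sel$score[7])
  # pure-noise constant data: stiff end preferred
  flat <- matrix(rpois(250 * 10, 10 * 0.002), 250, 10)
  sel2 <- cv_select_eta(flat, b, Om, grid)
  expect_gte(sel2$eta, grid[5])
})
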