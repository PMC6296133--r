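# Maximum-likelihood machinery: numerical derivatives, standard errors,
# optimizer agreement, boundary handling, and the likelihood ratio test.

test_that("numerical Hessian is exact on a quadratic", {
  A <- matrix(c(4, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 2), 3)
  f <- function(x) 0.5 * drop(t(x) %*% A %*% x) + sum(x)
  H <- screenmsm:::.num_hess(f, c(0.3, -0.2, 1), h = 1e-4)
  expect_equal(H, A, tolerance = 1e-6)
  g <- screenmsm:::.num_grad(f, c(0.3, -0.2, 1), h = 1e-6)
  expect_equal(g, drop(A %*% c(0.3, -0.2, 1)) + 1, tolerance = 1e-6)
})

test_that("standard errors delta-map and truncate correctly", {
  # craft a fit object with a known covariance
  fit <- structure(list(
    model = "homogeneous",
    natural = c(lambda12 = 0.003, lambda23 = 0.4, r = 0.00182, S = 0.88),
    cov_natural = diag(c(1e-8, 4e-4, 3.03e-6, 2.25e-4))
  ), class = "nh_fit")
  dimnames(fit$cov_natural) <- list(names(fit$natural), names(fit$natural))
  se <- standard_errors(fit)
  expect_equal(se$se, c(1e-4, 0.02, sqrt(3.03e-6), 0.015), tolerance = 1e-10)
  # the r interval is truncated at zero, never negative
  expect_equal(se$lower[se$parameter == "r"], 0)
  expect_gt(se$upper[se$parameter == "r"], 0.00182)
  expect_lte(se$upper[se$parameter == "S"], 1)
  fit$cov_natural <- NULL
  expect_error(standard_errors(fit), "singular|covariance")
})

test_that("likelihood ratio test reproduces deviance arithmetic", {
  lrt <- likelihood_ratio_test(198878, 198024, df = 3)
  expect_equal(unname(lrt$statistic), 854)
  expect_equal(unname(lrt$parameter), 3)
  expect_lt(lrt$p.value, 0.001)
  same <- likelihood_ratio_test(1234.5, 1234.5, df = 3)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(likelihood_ratio_test(100, 110, df = 3), "negative")
  expect_error(likelihood_ratio_test(110, 100), "df")
})

# Shared moderate fixture for the optimizer-level checks.
fit_fixture <- local({
  co <- NULL
  function() {
    if (is.null(co))
      co <<- simulate_cohort(simulation_config(n_women = 5000), seed = 23)
    co
  }
})

test_that("BFGS and Nelder-Mead agree on the optimum deviance", {
  co <- fit_fixture()
  f <- fit_natural_history(co)
  # independent Nelder-Mead maximisation of the same objective
  A <- f$partition
  negll <- function(theta) {
    l12 <- c(f$lambda12_fixed, exp(theta[1:2]))
    prm <- model_parameters(l12, exp(theta[3:5]), exp(theta[6]),
                            stats::plogis(theta[7]))
    v <- -cohort_loglik(co, prm, A, condition_entry = TRUE) / f$n_women
    if (!is.finite(v)) 1e10 else v
  }
  nm <- list(par = f$theta, value = Inf)
  for (rs in 1:4) {   # restart until the simplex truly settles
    nm2 <- stats::optim(nm$par, negll, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    done <- nm$value - nm2$value < 1e-9
    nm <- nm2
    if (done) break
  }
  expect_lt(abs(2 * nm$value * f$n_women - f$minus2loglik), 1e-3)
})

test_that("reported deviance is reproducible from the stored estimates", {
  co <- fit_fixture()
  f <- fit_natural_history(co)
  m2 <- -2 * cohort_loglik(co, f$estimates, f$partition,
                           condition_entry = TRUE)
  expect_identical(f$minus2loglik, m2)
})

test_that("the optimum beats random local perturbations", {
  co <- fit_fixture()
  f <- fit_natural_history(co)
  A <- f$partition
  negll <- function(theta) {
    l12 <- c(f$lambda12_fixed, exp(theta[1:2]))
    prm <- model_parameters(l12, exp(theta[3:5]), exp(theta[6]),
                            stats::plogis(theta[7]))
    -cohort_loglik(co, prm, A, condition_entry = TRUE)
  }
  v0 <- negll(f$theta)
  set.seed(77)
  for (i in 1:100) {
    expect_gte(negll(f$theta + stats::rnorm(7, sd = 0.05)), v0 - 1e-6)
  }
})

test_that("a cohort without non-progressive cases pushes r to the boundary", {
  p <- nh_params()
  p0 <- model_parameters(p$lambda12, p$lambda23, r = 0, S = p$S)
  co <- simulate_cohort(simulation_config(n_women = 15000, params = p0),
                        seed = 31)
  f <- fit_natural_history(co)
  expect_lt(f$natural["r"], 0.05)
  se <- standard_errors(f)
  expect_equal(se$lower[se$parameter == "r"], 0)
  if (f$natural["r"] < 1e-7) expect_true(f$boundary$r)
})

test_that("non-finite starting values are rejected with guidance", {
  co <- toy_cohort()
  bad <- model_parameters(c(0, 0, 0), c(0, 0, 0), r = 0, S = 0.5)
  expect_error(fit_natural_history(co, init = bad, lambda12_fixed = 0),
               "init")
})

test_that("estimation error shrinks with the cohort size", {
  # seed-averaged error on the well-identified homogeneous parameters; the
  # seven-parameter model's r ridge makes single draws too noisy for a
  # consistency comparison at this scale
  hp <- hom_params()
  truth <- c(lambda12 = 0.00306, lambda23 = 0.418, S = 0.924)
  err <- vapply(c(3000, 27000), function(n) {
    mean(vapply(1:3, function(s) {
      co <- simulate_cohort(simulation_config(n_women = n, params = hp),
                            seed = 400 + n + s)
      f <- fit_natural_history(co, model = "homogeneous")
      mean(abs(f$natural[names(truth)] - truth) / truth)
    }, numeric(1)))
  }, numeric(1))
  expect_true(err[2] < err[1] || err[2] < 0.03)
})
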