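# Latent four-state transition machinery: generator layout, closed-form
# piece solution against a matrix-exponential oracle, multi-interval
# composition against an ODE oracle, and structural invariants.

test_that("rate matrix has the four-state generator layout", {
  p <- nh_params()
  A <- default_partition()
  Q <- rate_matrix_at_age(p, A, 55)
  expect_equal(unname(rowSums(Q)), rep(0, 4))
  expect_equal(Q[1, 2], 0.00276)
  expect_equal(Q[1, 4], 0.00182 * 0.00276, tolerance = 1e-12)
  expect_equal(Q[1, 3], 0)
  expect_equal(Q[2, 3], 0.464)
  expect_true(all(Q[3:4, ] == 0))
  # r = 0 removes the non-progressive pathway
  p0 <- model_parameters(p$lambda12, p$lambda23, r = 0, S = p$S)
  expect_equal(rate_matrix_at_age(p0, A, 45)[, 4], rep(0, 4),
               ignore_attr = TRUE)
  expect_error(rate_matrix_at_age(p, A, 39), "t0")
})

test_that("piece solution matches direct exponentials and is identity at dt = 0", {
  A <- default_partition()
  p <- model_parameters(c(0, 0, 0.00381), c(0, 0, 0.284), r = 0, S = 1)
  M <- piece_transition_matrix(p, A, 3, 2)
  expect_equal(M[2, 2], exp(-0.568), tolerance = 1e-10)
  expect_equal(M[1, 1], exp(-0.00762), tolerance = 1e-10)
  expect_equal(piece_transition_matrix(nh_params(), A, 2, 0),
               diag(4), ignore_attr = TRUE)
  expect_error(piece_transition_matrix(nh_params(), A, 2, -1), "non-negative")
})

test_that("piece solution agrees with a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  A <- default_partition()
  set.seed(42)
  for (i in 1:30) {
    p <- random_params()
    dt <- runif(1, 0, 40)
    l <- sample(3, 1)
    Q <- rate_matrix_at_age(p, A, c(45, 55, 65)[l])
    oracle <- as.matrix(Matrix::expm(Q * dt))
    expect_equal(unname(piece_transition_matrix(p, A, l, dt)),
                 unname(oracle), tolerance = 1e-10)
  }
  # near-degenerate lambda23 = lambda12 (1 + r): limit form stays continuous
  for (eps in c(-1e-9, 0, 1e-9)) {
    l12 <- 0.3; r <- 0.1
    p <- model_parameters(rep(l12, 3), rep(l12 * (1 + r) + eps, 3),
                          r = r, S = 1)
    Q <- rate_matrix_at_age(p, A, 45)
    oracle <- as.matrix(Matrix::expm(Q * 5))
    expect_equal(unname(piece_transition_matrix(p, A, 1, 5)),
                 unname(oracle), tolerance = 1e-10)
  }
})

test_that("multi-interval composition satisfies Chapman-Kolmogorov", {
  A <- default_partition()
  set.seed(7)
  for (i in 1:20) {
    p <- random_params()
    ages <- sort(40 + 40 * runif(3))
    M_direct <- transition_matrix(p, A, ages[1], ages[3])
    M_split <- transition_matrix(p, A, ages[1], ages[2]) %*%
      transition_matrix(p, A, ages[2], ages[3])
    expect_equal(M_direct, M_split, tolerance = 1e-10)
  }
  expect_equal(transition_matrix(nh_params(), A, 55, 55), diag(4),
               ignore_attr = TRUE)
  expect_error(transition_matrix(nh_params(), A, 56, 55), "exceed")
})

test_that("composition across cutpoints matches an ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- nh_params()
  A <- default_partition()
  rhs <- function(t, y, parms) {
    Q <- rate_matrix_at_age(p, A, t)
    list(as.vector(matrix(y, 4) %*% Q))
  }
  sol <- deSolve::ode(y = as.vector(diag(4)), times = c(45, 65), func = rhs,
                      parms = NULL, rtol = 1e-11, atol = 1e-13)
  oracle <- matrix(sol[2, -1], 4)
  expect_lt(max(abs(transition_matrix(p, A, 45, 65) - oracle)), 1e-8)
})

test_that("transition matrices are row-stochastic with bounded entries", {
  A <- default_partition()
  set.seed(11)
  for (i in 1:50) {
    p <- random_params()
    s <- 40 + 35 * runif(1)
    M <- transition_matrix(p, A, s, s + 40 * runif(1))
    expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(M[2, 1], 0)
    expect_equal(M[2, 4], 0)
    expect_equal(M[3, ], c(0, 0, 1, 0), ignore_attr = TRUE)
    expect_equal(M[4, ], c(0, 0, 0, 1), ignore_attr = TRUE)
  }
})

test_that("P13 is non-decreasing in the horizon", {
  p <- nh_params()
  A <- default_partition()
  ts <- seq(45, 90, by = 0.5)
  p13 <- vapply(ts, function(t) transition_matrix(p, A, 43, t)[1, 3],
                numeric(1))
  expect_true(all(diff(p13) >= -1e-14))
})

test_that("compiled kernel agrees with the plain-R transition code", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_params()
    par <- screenmsm:::.par_engine(p, default_partition())
    s <- 40 + 30 * runif(200)
    t <- s + 40 * runif(200)
    r_ref <- screenmsm:::.trans_probs(s, t, par)
    dtl <- screenmsm:::.trans_durations(s, t, par$cuts)
    nz <- lapply(dtl, function(d) which(d > 0))
    cpp <- screenmsm:::.trans_probs_cpp(
      length(s), nz, lapply(seq_along(dtl), function(l) dtl[[l]][nz[[l]]]),
      par$l12, par$l23, par$r)
    for (nm in names(r_ref))
      expect_equal(cpp[[nm]], r_ref[[nm]], tolerance = 1e-12)
  }
})

test_that("mean sojourn time is the reciprocal progression rate", {
  expect_equal(round(mean_sojourn_time(c(0.385, 0.464, 0.284, 0.418)), 2),
               c(2.60, 2.16, 3.52, 2.39))
  expect_equal(mean_sojourn_time(1), 1)
  expect_error(mean_sojourn_time(0), "positive")
  expect_error(mean_sojourn_time(-0.1), "positive")
})
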