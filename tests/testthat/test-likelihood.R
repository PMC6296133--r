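# Observed-data likelihood: misclassification structure, onset densities,
# per-history closed forms, the exhaustive outcome partition, and agreement
# with model-faithful simulation.

test_that("misclassification matrix has the stated structure", {
  E <- misclassification_matrix(0.880)
  expect_equal(unname(rowSums(E)), rep(1, 4))
  expect_equal(E[1, ], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(E[2, 1], 0.12)      # Pr(negative | progressive PCDP)
  expect_equal(E[4, 2], 0.88)
  expect_equal(E[3, ], c(0, 0, 1), ignore_attr = TRUE)
  expect_equal(E[1, 2], 0)         # assessment rules out false positives
  E1 <- misclassification_matrix(1)
  expect_equal(E1[2, 2], 1)
  expect_equal(E1[4, 2], 1)
  expect_error(misclassification_matrix(1.2), "probability")
})

test_that("clinical onset density integrates and differentiates consistently", {
  p <- nh_params()
  A <- default_partition()
  # total clinical mass from state 1 is the progressive share 1/(1+r)
  total <- integrate(function(u) clinical_onset_density(p, A, 45, u),
                     45, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1 / (1 + p$r), tolerance = 1e-6)
  # r = 0, constant rates: textbook two-stage convolution
  pc <- model_parameters(rep(0.003, 3), rep(0.4, 3), r = 0, S = 1)
  u <- seq(46, 80, by = 2.5)
  d <- 0.003 * 0.4 * (exp(-0.003 * (u - 45)) - exp(-0.4 * (u - 45))) /
    (0.4 - 0.003)
  expect_equal(clinical_onset_density(pc, A, 45, u), d, tolerance = 1e-12)
  # finite difference of P13 recovers the density
  h <- 1e-5
  # (away from the cutpoints, where the rate jump makes the density
  # one-sidedly discontinuous)
  for (u0 in c(48, 55.5, 61, 71)) {
    fd <- (transition_matrix(p, A, 45, u0 + h)[1, 3] -
             transition_matrix(p, A, 45, u0 - h)[1, 3]) / (2 * h)
    expect_equal(clinical_onset_density(p, A, 45, u0), fd, tolerance = 1e-6)
  }
  expect_error(clinical_onset_density(p, A, 50, 50), "greater")
})

test_that("history likelihood reproduces its closed forms", {
  p <- nh_params()
  A <- default_partition()
  S <- p$S
  # a perfect test: one negative screen anchors state 1
  p1 <- model_parameters(p$lambda12, p$lambda23, r = p$r, S = 1)
  h <- screening_history(1, invited_ages = 50, screen_ages = 50,
                         outcome = "censored", censor_age = 50)
  expect_equal(history_loglik(h, p1, A),
               log(transition_matrix(p1, A, 40, 50)[1, 1]), tolerance = 1e-12)
  # detection at the second-ever screen: fresh mass times S plus carried
  # missed mass
  h2 <- screening_history(1, invited_ages = c(50, 52),
                          screen_ages = c(50, 52),
                          outcome = "screen_detected", outcome_age = 52)
  P1 <- transition_matrix(p, A, 40, 50)
  P2 <- transition_matrix(p, A, 50, 52)
  manual <- P1[1, 1] * (P2[1, 2] + P2[1, 4]) * S +
    (P1[1, 4] + P1[1, 2] * P2[2, 2]) * (1 - S)
  expect_equal(history_loglik(h2, p, A), log(manual), tolerance = 1e-12)
  # inconsistent history is rejected
  expect_error(screening_history(1, invited_ages = c(50, 52),
                                 screen_ages = 50,
                                 outcome = "screen_detected",
                                 outcome_age = 52), "last attended")
})

test_that("likelihood of the exhaustive outcome partition sums to one", {
  A <- default_partition()
  expect_equal(partition_total(nh_params(), A, c(50, 52), 54), 1,
               tolerance = 1e-6)
  set.seed(31)
  for (i in 1:5) {
    p <- random_params()
    screens <- sort(41 + 35 * runif(sample(1:3, 1)))
    expect_equal(partition_total(p, A, screens, max(screens) + 3 * runif(1)),
                 1, tolerance = 1e-6)
  }
})

test_that("cohort likelihood sums per-woman contributions", {
  p <- nh_params()
  A <- default_partition()
  co <- toy_cohort()
  ll_women <- cohort_loglik(co, p, A, per_woman = TRUE)
  expect_equal(sum(ll_women), cohort_loglik(co, p, A))
  expect_true(all(is.finite(ll_women)))
  h <- cohort_history(co, 2)
  expect_equal(history_loglik(h, p, A), ll_women[2], tolerance = 1e-12)
  # duplicated cohort doubles the log-likelihood exactly
  ev <- co$events
  ev2 <- ev; ev2$woman_id <- paste0(ev2$woman_id, "_dup")
  co2 <- screening_cohort(rbind(ev, ev2))
  expect_equal(cohort_loglik(co2, p, A), 2 * cohort_loglik(co, p, A))
  expect_error(screening_cohort(data.frame(woman_id = character(),
                                           event = character(),
                                           age = numeric())),
               "terminal|empty|woman", ignore.case = TRUE)
})

test_that("compiled likelihood matches the plain-R recursion", {
  p <- nh_params()
  A <- default_partition()
  co <- simulate_cohort(simulation_config(n_women = 2000, params = p),
                        seed = 12)
  par <- screenmsm:::.par_engine(p, A)
  for (cond in c(FALSE, TRUE)) {
    ll_cpp <- screenmsm:::.loglik_engine(co$cc, par, cond)
    ll_r <- screenmsm:::.loglik_engine_r(co$cc, par, cond)
    expect_equal(ll_cpp, ll_r, tolerance = 1e-12)
  }
})

test_that("r = 0 reduces to the progressive three-state likelihood", {
  A <- default_partition()
  p0 <- model_parameters(c(0.002, 0.003, 0.004), c(0.3, 0.45, 0.25),
                         r = 0, S = 0.85)
  # clinical case in a never-attender: two-stage convolution density,
  # integrated piecewise over the age partition by independent quadrature
  h <- screening_history(1, invited_ages = c(50, 52),
                         outcome = "clinical", outcome_age = 56.3)
  f_onset <- function(x) {  # onset density at age x from state 1 at 40
    l12 <- c(0.002, 0.003, 0.004)[findInterval(x, c(40, 50, 60))]
    H <- 0.002 * pmin(pmax(x - 40, 0), 10) + 0.003 * pmin(pmax(x - 50, 0), 10) +
      0.004 * pmax(x - 60, 0)
    l12 * exp(-H)
  }
  surv23 <- function(a, b) {  # stay in PCDP from a to b
    H <- 0.3 * pmax(pmin(b, 50) - pmin(a, 50), 0) +
      0.45 * pmax(pmin(b, 60) - pmax(pmin(a, 60), 50), 0) +
      0.25 * pmax(b - pmax(a, 60), 0)
    exp(-H)
  }
  l23_at <- function(x) c(0.3, 0.45, 0.25)[findInterval(x, c(40, 50, 60))]
  oracle <- integrate(function(x)
    f_onset(x) * surv23(x, 56.3) * l23_at(56.3),
    40, 56.3, rel.tol = 1e-10)$value
  expect_equal(exp(history_loglik(h, p0, A)), oracle, tolerance = 1e-8)
})

test_that("outcome frequencies in model-faithful simulation match the likelihood", {
  p <- nh_params()
  A <- default_partition()
  n_target <- 150000
  cfg <- simulation_config(n_women = n_target, params = p, entry_jitter = 0,
                           participation = 1, recall_fp = 0,
                           last_invite_age = 53, study_end_age = 54)
  co <- simulate_cohort(cfg, seed = 42)
  cc <- co$cc
  n <- cc$n
  cond <- 1 - transition_matrix(p, A, 40, 50)[1, 3]
  prob <- function(h) exp(history_loglik(h, p, A)) / cond
  mod <- c(
    det1 = prob(screening_history(1, c(50, 52), 50, "screen_detected", 50)),
    det2 = prob(screening_history(1, c(50, 52), c(50, 52), "screen_detected",
                                  52)),
    cens = prob(screening_history(1, c(50, 52), c(50, 52), "censored",
                                  censor_age = 54)))
  emp <- c(det1 = sum(cc$outcome == "screen_detected" & cc$n_screens == 1),
           det2 = sum(cc$outcome == "screen_detected" & cc$n_screens == 2),
           cens = sum(cc$outcome == "censored")) / n
  se <- sqrt(mod * (1 - mod) / n)
  expect_true(all(abs(emp - mod) < 3 * se))
  # remaining mass is clinical surfacing
  p_cl <- 1 - sum(mod)
  se_cl <- sqrt(p_cl * (1 - p_cl) / n)
  expect_lt(abs(sum(cc$outcome == "clinical") / n - p_cl), 3 * se_cl)
})
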