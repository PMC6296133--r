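# Observed versus expected cumulative incidence among ever-attenders.

test_that("a cancer-free cohort yields a flat zero observed curve", {
  co <- screening_cohort(list(
    screening_history(1, invited_ages = c(50, 52), screen_ages = c(50, 52),
                      outcome = "censored", censor_age = 54),
    screening_history(2, invited_ages = c(50, 52), screen_ages = 50,
                      outcome = "censored", censor_age = 54)))
  curve <- observed_cumulative_incidence(co, c(50, 60))
  expect_true(all(curve$observed_events == 0))
  expect_true(all(curve$observed_cumulative == 0))
})

test_that("a single cancer produces a single step", {
  co <- screening_cohort(list(
    screening_history(1, invited_ages = c(50, 52), screen_ages = 50,
                      outcome = "clinical", outcome_age = 53.5),
    screening_history(2, invited_ages = seq(50, 58, 2),
                      screen_ages = seq(50, 58, 2),
                      outcome = "censored", censor_age = 60)))
  curve <- observed_cumulative_incidence(co, c(50, 60))
  expect_equal(sum(curve$observed_events), 1)
  expect_equal(curve$observed_events[curve$age == 53], 1)
  steps <- diff(c(0, curve$observed_cumulative))
  expect_true(all(steps[curve$age != 53] == 0))
})

test_that("never-attenders are excluded from the curves", {
  co <- screening_cohort(list(
    screening_history(1, invited_ages = c(50, 52), screen_ages = 50,
                      outcome = "censored", censor_age = 54),
    screening_history(2, invited_ages = c(50, 52),
                      outcome = "clinical", outcome_age = 53)))
  curve <- observed_cumulative_incidence(co, c(50, 60))
  expect_equal(sum(curve$observed_events), 0)   # the NP case never attended
  expect_equal(sum(curve$person_years), 4)
})

test_that("expected events telescope to the per-woman outcome probabilities", {
  # independent recount: for each woman walk her schedule with
  # transition_matrix calls, conditioning at each negative screen, and
  # accumulate P(detected at screen k) + P(clinical before window end)
  p <- nh_params()
  A <- default_partition()
  co <- simulate_cohort(simulation_config(n_women = 120, params = p),
                        seed = 61)
  curve <- incidence_curves(co, p)
  cc <- co$cc
  win <- screenmsm:::.diag_windows(cc)
  total <- 0
  for (i in seq_len(cc$n)) {
    if (cc$n_screens[i] == 0L) next
    screens <- cc$screens[i, seq_len(cc$n_screens[i])]
    if (cc$outcome[i] == "screen_detected")
      screens <- screens[-length(screens)]
    wend <- win$exp_end[i]
    b <- c(1, 0, 0); v <- 40; S <- p$S
    pos <- cc$entry_age[i]   # at risk only from entry
    seg <- function(v, from, to, b) {
      Pa <- transition_matrix(p, A, v, from)
      Pb <- transition_matrix(p, A, v, to)
      b[1] * (Pb[1, 3] - Pa[1, 3]) + b[2] * (Pa[2, 2] - Pb[2, 2])
    }
    for (u in screens) {
      P <- transition_matrix(p, A, v, u)
      total <- total + seg(v, pos, u, b) +
        b[1] * (P[1, 2] + P[1, 4]) * S + b[2] * P[2, 2] + b[3]
      nb <- c(b[1] * P[1, 1], b[1] * P[1, 2] * (1 - S),
              b[1] * P[1, 4] * (1 - S))
      b <- nb / sum(nb); v <- u; pos <- u
    }
    if (cc$outcome[i] == "screen_detected") {
      u <- cc$outcome_age[i]
      P <- transition_matrix(p, A, v, u)
      total <- total + seg(v, pos, u, b) +
        b[1] * (P[1, 2] + P[1, 4]) * S + b[2] * P[2, 2] + b[3]
    } else {
      total <- total + seg(v, pos, wend, b)
    }
  }
  expect_equal(sum(curve$expected_events), total, tolerance = 1e-6)
})

test_that("expected tracks observed when the model is true", {
  p <- nh_params()
  co <- simulate_cohort(simulation_config(n_women = 30000, params = p),
                        seed = 62)
  for (band in list(c(50, 60), c(60, Inf))) {
    oc <- observed_cumulative_incidence(co, band)
    ec <- expected_cumulative_incidence(co, p, band)
    obs <- tail(oc$observed_cumulative, 1)
    exq <- tail(ec$expected_cumulative, 1)
    n_ev <- sum(oc$observed_events)
    expect_gt(n_ev, 50)
    expect_lt(abs(obs - exq) / exq, max(3 / sqrt(n_ev), 0.1) + 0.05)
  }
})

test_that("age-homogeneous rates overshoot the risk before age 60", {
  # data generated under the age-varying truth, expected curve evaluated at
  # the age-constant parameter set
  co <- simulate_cohort(simulation_config(n_women = 30000, params = nh_params()),
                        seed = 62)
  oc <- observed_cumulative_incidence(co, c(50, 60))
  ec_hom <- expected_cumulative_incidence(co, hom_params(), c(50, 60))
  expect_gt(tail(ec_hom$expected_cumulative, 1),
            tail(oc$observed_cumulative, 1))
  # while the age-varying parameters stay close (checked above); direction:
  ec_nh <- expected_cumulative_incidence(co, nh_params(), c(50, 60))
  expect_gt(tail(ec_hom$expected_cumulative, 1),
            tail(ec_nh$expected_cumulative, 1))
})
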