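# Shared fixtures: published-scale parameter sets and small cohort builders.

# Non-homogeneous estimates at the scale of a large organised biennial
# programme (onset per woman-year on [40,50)/[50,60)/[60,Inf), progression
# rates, non-progressive ratio, test sensitivity).
nh_params <- function() {
  model_parameters(lambda12 = c(0.0015, 0.00276, 0.00381),
                   lambda23 = c(0.385, 0.464, 0.284),
                   r = 0.00182, S = 0.880)
}

# Homogeneous (age-constant) counterpart.
hom_params <- function() {
  model_parameters(lambda12 = 0.00306, lambda23 = 0.418,
                   r = 9.999e-4, S = 0.924)
}

default_partition <- function() age_partition(c(40, 50, 60))

# A tiny deterministic cohort built from explicit histories.
toy_cohort <- function() {
  screening_cohort(list(
    screening_history(1, invited_ages = c(50, 52, 54),
                      screen_ages = c(50, 52, 54),
                      outcome = "censored", censor_age = 56),
    screening_history(2, invited_ages = c(50, 52),
                      screen_ages = 50,
                      outcome = "clinical", outcome_age = 51.5),
    screening_history(3, invited_ages = c(50, 52, 54),
                      screen_ages = c(52, 54),
                      outcome = "screen_detected", outcome_age = 54),
    screening_history(4, invited_ages = c(50, 52),
                      outcome = "clinical", outcome_age = 53.1),
    screening_history(5, invited_ages = c(50, 52, 54, 56),
                      screen_ages = c(50, 56),
                      outcome = "censored", censor_age = 58)
  ))
}

# Random valid rate sets for property-style fuzzing.
random_params <- function() {
  model_parameters(lambda12 = runif(3, 0, 1), lambda23 = runif(3, 0, 1),
                   r = runif(1, 0, 0.5), S = runif(1, 0.05, 1))
}
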