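# Observed versus expected cumulative incidence among ever-attenders.
#
# The observed annual incidence rate is detected cases (screen + clinical)
# over at-risk person-years in annual age bins. The expected count per bin
# sums, over all at-risk women, the probability of an observable detection
# event in that bin given the woman's actual screening schedule and her
# previously observed (negative) screen results: the same three-component
# belief as the likelihood, re-anchored and conditioned at each attended
# screen, with unconditional probability increments between screens so that
# per-woman expected events telescope to the likelihood's outcome
# probabilities. Follow-up of clinically detected cases is extended to the
# next supposed examination time (two years after the latest scheduled
# invitation at or before diagnosis).

# Per-woman observed and expected follow-up window ends.
.diag_windows <- function(cc, extension = 2) {
  obs_end <- ifelse(cc$outcome == "censored", cc$censor_age, cc$outcome_age)
  exp_end <- obs_end
  cl <- which(cc$outcome == "clinical")
  if (length(cl)) {
    dx <- cc$outcome_age[cl]
    last_sched <- vapply(seq_along(cl), function(i) {
      z <- cc$invited[cl[i], ]
      z <- z[!is.na(z) & z <= dx[i] + 1e-9]
      if (length(z)) max(z) else cc$entry_age[cl[i]]
    }, numeric(1))
    exp_end[cl] <- pmax(last_sched + extension, dx)
  }
  list(obs_end = obs_end, exp_end = exp_end)
}

#' Observed and expected cumulative incidence curves
#'
#' Computes annual observed and model-expected detection counts, rates and
#' cumulative incidence among ever-attenders (women with at least one
#' attended screen) on a common annual age grid.
#'
#' @param cohort A [screening_cohort].
#' @param fit An \code{nh_fit} or [model_parameters] providing the rates.
#' @param partition Used when `fit` is a bare parameter set.
#' @param extension Years of expected follow-up granted to clinically
#'   detected cases after their latest scheduled invitation.
#' @return A data.frame with one row per annual age bin: \code{age} (lower
#'   bound), observed and expected event counts, person-years, annual rates
#'   and cumulative rates.
#' @export
incidence_curves <- function(cohort, fit, partition = NULL, extension = 2) {
  stopifnot(inherits(cohort, "screening_cohort"))
  if (is.null(partition))
    partition <- if (inherits(fit, "nh_fit")) fit$partition else age_partition()
  par <- .par_engine(.fit_to_params(fit), partition)
  cc <- cohort$cc

  keep <- which(cc$n_screens > 0L)
  if (!length(keep)) stop("no ever-attenders in the cohort")
  n <- length(keep)
  entry <- cc$entry_age[keep]
  win <- .diag_windows(cc, extension)
  obs_end <- win$obs_end[keep]
  exp_end <- win$exp_end[keep]
  screens <- cc$screens[keep, , drop = FALSE]
  n_screens <- cc$n_screens[keep]
  outcome <- cc$outcome[keep]
  out_age <- cc$outcome_age[keep]

  a0 <- floor(min(entry))
  a1 <- ceiling(max(pmax(obs_end, exp_end)) + 1e-9)
  grid <- seq(a0, a1 - 1L)

  S <- par$S
  v <- rep(par$t0, n)          # anchor: last conditioned screen (or t0)
  B1 <- rep(1, n); B2 <- numeric(n); B4 <- numeric(n)
  scr_ptr <- rep(1L, n)
  done <- rep(FALSE, n)        # detection screen processed

  obs_events <- numeric(length(grid))
  exp_events <- numeric(length(grid))
  py <- numeric(length(grid))
  eps <- 1e-9

  for (bi in seq_along(grid)) {
    a <- grid[bi]; b <- a + 1
    lo <- pmax(entry, a)
    py[bi] <- sum(pmax(pmin(obs_end, b) - lo, 0))
    obs_events[bi] <- sum(outcome != "censored" & !is.na(out_age) &
                            out_age >= a & out_age < b)

    hi <- pmin(exp_end, b)
    pos <- lo
    e <- numeric(n)
    repeat {
      u <- rep(NA_real_, n)
      has <- which(!done & scr_ptr <= n_screens)
      if (length(has)) u[has] <- screens[cbind(has, scr_ptr[has])]
      wsel <- which(!is.na(u) & u >= a - eps & u < b - eps &
                      u <= hi + eps & u >= pos - eps)
      if (!length(wsel)) break
      uu <- pmax(u[wsel], pos[wsel])
      tp_pos <- .trans_probs(v[wsel], pos[wsel], par)
      tp_u <- .trans_probs(v[wsel], uu, par)
      e[wsel] <- e[wsel] +
        B1[wsel] * (tp_u$p13 - tp_pos$p13) +
        B2[wsel] * (tp_pos$p22 - tp_u$p22) +
        B1[wsel] * (tp_u$p12 + tp_u$p14) * S +
        B2[wsel] * tp_u$p22 + B4[wsel]
      term <- outcome[wsel] == "screen_detected" & scr_ptr[wsel] == n_screens[wsel]
      cont <- wsel[!term]
      if (length(cont)) {
        i <- match(cont, wsel)
        nb1 <- B1[cont] * tp_u$p11[i]
        nb2 <- B1[cont] * tp_u$p12[i] * (1 - S)
        nb4 <- B1[cont] * tp_u$p14[i] * (1 - S)
        norm <- nb1 + nb2 + nb4
        B1[cont] <- nb1 / norm; B2[cont] <- nb2 / norm; B4[cont] <- nb4 / norm
        v[cont] <- uu[i]
      }
      done[wsel[term]] <- TRUE
      pos[wsel] <- uu
      scr_ptr[wsel] <- scr_ptr[wsel] + 1L
    }
    tail_i <- which(!done & hi > pos + eps)
    if (length(tail_i)) {
      tp_pos <- .trans_probs(v[tail_i], pmax(pos[tail_i], v[tail_i]), par)
      tp_hi <- .trans_probs(v[tail_i], hi[tail_i], par)
      e[tail_i] <- e[tail_i] +
        B1[tail_i] * (tp_hi$p13 - tp_pos$p13) +
        B2[tail_i] * (tp_pos$p22 - tp_hi$p22)
    }
    exp_events[bi] <- sum(e)
  }

  obs_rate <- ifelse(py > 0, obs_events / py, 0)
  exp_rate <- ifelse(py > 0, exp_events / py, 0)
  data.frame(age = grid, person_years = py,
             observed_events = obs_events, expected_events = exp_events,
             observed_rate = obs_rate, expected_rate = exp_rate,
             observed_cumulative = cumsum(obs_rate),
             expected_cumulative = cumsum(exp_rate))
}

.band_slice <- function(curve, age_band) {
  sel <- curve$age >= age_band[1L] & curve$age < age_band[2L]
  out <- curve[sel, , drop = FALSE]
  out$observed_cumulative <- cumsum(out$observed_rate)
  out$expected_cumulative <- cumsum(out$expected_rate)
  rownames(out) <- NULL
  out
}

#' Observed cumulative incidence among ever-attenders
#'
#' @inheritParams incidence_curves
#' @param age_band Two ages delimiting the band, e.g. \code{c(50, 60)} or
#'   \code{c(60, Inf)}.
#' @return A data.frame with annual observed events, person-years, rates and
#'   the cumulative rate within the band.
#' @export
observed_cumulative_incidence <- function(cohort, age_band = c(50, 60)) {
  stopifnot(length(age_band) == 2L, age_band[1L] < age_band[2L])
  # observed component needs no parameters; a placeholder set is used
  dummy <- model_parameters(lambda12 = 0, lambda23 = 0, r = 0, S = 1)
  curve <- incidence_curves(cohort, dummy)
  out <- .band_slice(curve, age_band)
  if (!nrow(out)) stop("no person-time in the requested age band")
  out[, c("age", "person_years", "observed_events", "observed_rate",
          "observed_cumulative")]
}

#' Expected cumulative incidence among ever-attenders
#'
#' @inheritParams incidence_curves
#' @param age_band Two ages delimiting the band.
#' @return A data.frame with annual expected events, rates and the cumulative
#'   rate within the band.
#' @export
expected_cumulative_incidence <- function(cohort, fit, age_band = c(50, 60),
                                          partition = NULL, extension = 2) {
  stopifnot(length(age_band) == 2L, age_band[1L] < age_band[2L])
  curve <- incidence_curves(cohort, fit, partition, extension)
  out <- .band_slice(curve, age_band)
  if (!nrow(out)) stop("no person-time in the requested age band")
  out[, c("age", "person_years", "expected_events", "expected_rate",
          "expected_cumulative")]
}
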