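# Overdiagnosis: expected number of screen-detected non-progressive cancers.
#
# A screen-detected case at round k (age t_k) is non-progressive with
# probability (A1 + A2) / ((A1 + B1) + (A2 + B2)) where
#   A1 = P11(t_{k-2}, t_{k-1}) P14(t_{k-1}, t_k) S      (fresh, non-progressive)
#   B1 = P11(t_{k-2}, t_{k-1}) P12(t_{k-1}, t_k) S      (fresh, progressive)
#   A2 = P14(t_{k-2}, t_{k-1}) (1 - S)                  (missed, non-progressive)
#   B2 = P12(t_{k-2}, t_{k-1}) P22(t_{k-1}, t_k) (1 - S)(missed, progressive)
# with the state-4 persistence probability equal to one. At the prevalent
# (first attended) screen there is no missed carry-over term and the belief
# is anchored in state 1 at t0, so the probability reduces to
# P14(t0, t1) / (P14(t0, t1) + P12(t0, t1)) and the sensitivity cancels;
# this first-round form is a model-consistent reconstruction (the source
# formula is only displayed for subsequent rounds).

.prob_np_subsequent <- function(par, t_km2, t_km1, t_k, S) {
  tpA <- .trans_probs(t_km2, t_km1, par)
  tpB <- .trans_probs(t_km1, t_k, par)
  A1 <- tpA$p11 * tpB$p14 * S
  B1 <- tpA$p11 * tpB$p12 * S
  A2 <- tpA$p14 * (1 - S)
  B2 <- tpA$p12 * tpB$p22 * (1 - S)
  num <- A1 + A2
  den <- A1 + B1 + A2 + B2
  ifelse(den > 0, num / den, 0)
}

#' Probability that a prevalent-round screen-detected cancer is non-progressive
#'
#' @inheritParams rate_matrix_at_age
#' @param t_1 Age at the woman's first attended screen (vectorised), above
#'   \code{t0}.
#' @return Probability (vectorised).
#' @export
prob_nonprogressive_prevalent <- function(params, partition = age_partition(),
                                          t_1) {
  par <- .par_engine(params, partition)
  if (any(t_1 <= par$t0)) stop("`t_1` must be above the initiation age t0")
  tp <- .trans_probs(rep(par$t0, length(t_1)), t_1, par)
  den <- tp$p14 + tp$p12
  ifelse(den > 0, tp$p14 / den, 0)
}

#' Probability that a subsequent-round screen-detected cancer is non-progressive
#'
#' Uses the woman's two previous attended-screen ages \code{t_km2 < t_km1}
#' and her detection age \code{t_k}; for a detection at the second attended
#' screen, \code{t_km2} is the initiation age \code{t0}.
#'
#' @inheritParams rate_matrix_at_age
#' @param t_km2,t_km1,t_k Strictly increasing ages (vectorised).
#' @return Probability (vectorised).
#' @export
prob_nonprogressive_subsequent <- function(params, partition = age_partition(),
                                           t_km2, t_km1, t_k) {
  par <- .par_engine(params, partition)
  len <- max(length(t_km2), length(t_km1), length(t_k))
  t_km2 <- rep_len(t_km2, len); t_km1 <- rep_len(t_km1, len)
  t_k <- rep_len(t_k, len)
  if (any(!(t_km2 < t_km1 & t_km1 < t_k)))
    stop("ages must satisfy t_km2 < t_km1 < t_k")
  .prob_np_subsequent(par, t_km2, t_km1, t_k, par$S)
}

#' Overdiagnosis as a percentage of screen-detected cases
#'
#' @param expected_npbc Expected number of detected non-progressive cancers.
#' @param n_detected Number of screen-detected cases (denominator).
#' @return Percentage.
#' @examples
#' overdiagnosis_fraction(35.90, 8305)
#' @export
overdiagnosis_fraction <- function(expected_npbc, n_detected) {
  if (any(n_detected <= 0)) stop("`n_detected` must be positive")
  100 * expected_npbc / n_detected
}

# Gather, per screen-detected case, the ages the round-appropriate formula
# needs. Returns a list of vectors; prevalent cases have is_prev = TRUE.
.detected_case_ages <- function(cc, t0) {
  det <- which(cc$outcome == "screen_detected")
  k <- cc$n_screens[det]
  t_k <- cc$screens[cbind(det, k)]
  is_prev <- k == 1L
  t_km1 <- rep(NA_real_, length(det))
  t_km2 <- rep(NA_real_, length(det))
  s2 <- which(!is_prev)
  if (length(s2)) {
    t_km1[s2] <- cc$screens[cbind(det[s2], k[s2] - 1L)]
    t_km2[s2] <- ifelse(k[s2] >= 3L,
                        cc$screens[cbind(det[s2], pmax(k[s2] - 2L, 1L))], t0)
  }
  list(idx = det, is_prev = is_prev, t_k = t_k, t_km1 = t_km1, t_km2 = t_km2)
}

.np_fractions <- function(ages, par) {
  p <- numeric(length(ages$idx))
  if (any(ages$is_prev)) {
    t1 <- ages$t_k[ages$is_prev]
    tp <- .trans_probs(rep(par$t0, length(t1)), t1, par)
    den <- tp$p14 + tp$p12
    p[ages$is_prev] <- ifelse(den > 0, tp$p14 / den, 0)
  }
  if (any(!ages$is_prev)) {
    s <- !ages$is_prev
    p[s] <- .prob_np_subsequent(par, ages$t_km2[s], ages$t_km1[s],
                                ages$t_k[s], par$S)
  }
  c(prevalent = sum(p[ages$is_prev]), subsequent = sum(p[!ages$is_prev]))
}

.fit_to_params <- function(object) {
  if (inherits(object, "nh_fit")) object$estimates
  else if (inherits(object, "model_parameters")) object
  else stop("expected an `nh_fit` or `model_parameters` object")
}

#' Expected number of detected non-progressive cancers in a cohort
#'
#' Evaluates, for every screen-detected case, the round-appropriate
#' probability of being non-progressive at her own attended-screen ages
#' (irregular inter-screen gaps use the actual previous attended screens, not
#' a nominal spacing) and sums by round class. The overdiagnosis fraction
#' uses the screen-detected counts as denominator.
#'
#' @param cohort A [screening_cohort] (detection modes are implied by each
#'   woman's attended-screen sequence).
#' @param fit An \code{nh_fit} or [model_parameters].
#' @param partition An [age_partition]; defaults to the fit's partition.
#' @return A data.frame with rows prevalent / subsequent / overall and
#'   columns \code{n_detected}, \code{expected_npbc}, \code{fraction_pct}.
#' @export
expected_overdiagnosis <- function(cohort, fit,
                                   partition = NULL) {
  stopifnot(inherits(cohort, "screening_cohort"))
  if (is.null(partition))
    partition <- if (inherits(fit, "nh_fit")) fit$partition else age_partition()
  par <- .par_engine(.fit_to_params(fit), partition)
  cc <- cohort$cc
  ages <- .detected_case_ages(cc, par$t0)
  n_prev <- sum(ages$is_prev)
  n_subs <- sum(!ages$is_prev)
  if (n_prev + n_subs == 0L) {
    warning("no screen-detected cases in the cohort")
    enp <- c(prevalent = 0, subsequent = 0)
  } else {
    enp <- .np_fractions(ages, par)
  }
  n <- c(n_prev, n_subs, n_prev + n_subs)
  e <- c(enp, sum(enp))
  data.frame(
    round = c("prevalent", "subsequent", "overall"),
    n_detected = n,
    expected_npbc = unname(e),
    fraction_pct = ifelse(n > 0, 100 * unname(e) / n, 0),
    row.names = NULL)
}

# Multivariate normal draws via Cholesky, with a symmetric square root as
# the fallback for semi-definite covariances (deterministic given the RNG).
.rmvnorm <- function(n, mu, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) {
    ev <- eigen(Sigma, symmetric = TRUE)
    ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  })
  z <- matrix(stats::rnorm(n * length(mu)), n)
  sweep(z %*% R, 2L, mu, `+`)
}

#' Simulation-based confidence interval for the overdiagnosis fraction
#'
#' Draws parameter vectors from the multivariate normal distribution with
#' mean the MLEs and covariance the estimated covariance matrix, recomputes
#' the expected number of non-progressive cancers for each draw, and reports
#' percentile intervals of the fraction per round class. Draws are taken on
#' the transformed (log/logit) scale by default, which guarantees valid
#' parameters; \code{scale = "natural"} draws on the natural scale and
#' rejects draws with negative rates or a sensitivity outside \eqn{[0,1]}.
#'
#' @param cohort A [screening_cohort].
#' @param fit A converged \code{nh_fit} with a covariance matrix.
#' @param n_draws Number of parameter draws (1000 by default).
#' @param seed Optional integer seed; a fixed seed gives a bit-identical
#'   interval on re-run.
#' @param level Confidence level.
#' @param scale Scale on which to draw.
#' @return A data.frame with rows prevalent / subsequent / overall and the
#'   point estimate plus percentile bounds of the fraction (percent).
#' @export
overdiagnosis_ci <- function(cohort, fit, n_draws = 1000, seed = NULL,
                             level = 0.95,
                             scale = c("transformed", "natural")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "nh_fit"))
  if (is.null(fit$cov_trans))
    stop("the fit has no covariance matrix; cannot simulate the interval")
  if (!is.null(seed)) set.seed(seed)
  partition <- fit$partition
  par0 <- .par_engine(fit$estimates, partition)
  cc <- cohort$cc
  ages <- .detected_case_ages(cc, par0$t0)
  n_prev <- sum(ages$is_prev); n_subs <- sum(!ages$is_prev)
  if (n_prev + n_subs == 0L) stop("no screen-detected cases in the cohort")
  L <- partition$n_intervals

  if (scale == "transformed") {
    draws <- .rmvnorm(n_draws, fit$theta, fit$cov_trans)
    # a near-singular direction (e.g. log r under weak identification) can
    # throw draws to numerically infinite rates; cap the transformed scale
    draws <- pmin(pmax(draws, -300), 30)
  } else {
    if (is.null(fit$cov_natural)) stop("no natural-scale covariance available")
    draws <- matrix(NA_real_, 0, length(fit$natural))
    tries <- 0L
    while (nrow(draws) < n_draws && tries < 50L) {
      cand <- .rmvnorm(n_draws, fit$natural, fit$cov_natural)
      ok <- apply(cand, 1L, function(z)
        all(z[-length(z)] >= 0) && z[length(z)] >= 0 && z[length(z)] <= 1)
      draws <- rbind(draws, cand[ok, , drop = FALSE])
      tries <- tries + 1L
    }
    if (nrow(draws) < n_draws)
      stop("could not obtain enough valid natural-scale draws")
    draws <- draws[seq_len(n_draws), , drop = FALSE]
  }

  fr <- matrix(NA_real_, n_draws, 3L,
               dimnames = list(NULL, c("prevalent", "subsequent", "overall")))
  for (d in seq_len(n_draws)) {
    if (scale == "transformed") {
      p <- .theta_to_params(draws[d, ], fit$model, fit$lambda12_fixed, L)
    } else {
      z <- draws[d, ]
      if (fit$model == "nonhomogeneous") {
        p <- list(l12 = c(fit$lambda12_fixed, z[seq_len(L - 1L)]),
                  l23 = z[L:(2L * L - 1L)], r = z[2L * L], S = z[2L * L + 1L])
      } else {
        p <- list(l12 = rep(z[1L], L), l23 = rep(z[2L], L), r = z[3L],
                  S = z[4L])
      }
    }
    par <- list(l12 = p$l12, l23 = p$l23, r = p$r, S = p$S,
                cuts = partition$cutpoints, t0 = partition$t0)
    enp <- .np_fractions(ages, par)
    fr[d, ] <- 100 * c(enp, sum(enp)) /
      c(max(n_prev, 1L), max(n_subs, 1L), n_prev + n_subs)
  }
  alpha <- (1 - level) / 2
  point <- expected_overdiagnosis(cohort, fit)
  qs <- apply(fr, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  data.frame(round = c("prevalent", "subsequent", "overall"),
             n_detected = point$n_detected,
             expected_npbc = point$expected_npbc,
             fraction_pct = point$fraction_pct,
             lower_pct = qs[1L, ], upper_pct = qs[2L, ],
             row.names = NULL)
}
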