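# Closed-form transition machinery of the latent four-state chain.
#
# Latent states: 1 free of BC, 2 progressive PCDP, 3 clinical phase,
# 4 non-progressive PCDP. The chain is acyclic (1 -> 2 -> 3, 1 -> 4) so the
# piecewise forward Kolmogorov system has an explicit solution; multi-interval
# probabilities are products of piece solutions split at partition cutpoints.

# Internal vectorised kernel. `s`, `t` are equal-length vectors with s <= t;
# `par` is the flat list from .par_engine(). Returns the non-trivial first- and
# second-row entries of P(s, t).
#
# Within a piece with constant rates and a = lambda12 * (1 + r):
#   P11 = exp(-a dt)
#   P14 = (r/(1+r)) (1 - exp(-a dt))
#   P12 = lambda12 exp(-a dt) (1 - exp(-(lambda23 - a) dt)) / (lambda23 - a)
#   P22 = exp(-lambda23 dt)
# with the analytic limit P12 = lambda12 dt exp(-a dt) inside a switch-over
# band |lambda23 - a| < 1e-8 to avoid catastrophic cancellation.
.trans_durations <- function(s, t, cuts) {
  upper <- c(cuts[-1L], Inf)
  lapply(seq_along(cuts), function(l)
    pmax(pmin(t, upper[l]) - pmax(s, cuts[l]), 0))
}

.trans_probs_core <- function(dtl, par) {
  n <- length(dtl[[1L]])
  p11 <- rep(1, n); p12 <- numeric(n); p14 <- numeric(n); p22 <- rep(1, n)
  for (l in seq_along(par$l12)) {
    dt <- dtl[[l]]
    l12 <- par$l12[l]; l23 <- par$l23[l]; r <- par$r
    a <- l12 * (1 + r)
    e_a <- exp(-a * dt)
    q11 <- e_a
    q14 <- if (a > 0) (r / (1 + r)) * (1 - e_a) else 0
    # three regimes around the removable singularity lambda23 = a: plain
    # difference quotient when well-separated, an expm1 form nearby (the
    # plain form cancels catastrophically), and the second-order analytic
    # limit inside the switch-over band
    d <- l23 - a
    q12 <- if (abs(d) < 1e-8) l12 * dt * e_a * (1 - 0.5 * d * dt)
           else if (abs(d) < 1e-4) l12 * e_a * (-expm1(-d * dt)) / d
           else l12 * (e_a - exp(-l23 * dt)) / d
    q22 <- exp(-l23 * dt)
    p12n <- p11 * q12 + p12 * q22
    p14n <- p11 * q14 + p14
    p11 <- p11 * q11
    p22 <- p22 * q22
    p12 <- p12n
    p14 <- p14n
  }
  p13 <- pmax(1 - p11 - p12 - p14, 0)
  list(p11 = p11, p12 = p12, p13 = p13, p14 = p14, p22 = p22)
}

.trans_probs <- function(s, t, par) {
  .trans_probs_core(.trans_durations(s, t, par$cuts), par)
}

.assemble_tpm <- function(tp, i = 1L) {
  m <- matrix(c(tp$p11[i], tp$p12[i],      tp$p13[i],     tp$p14[i],
                0,         tp$p22[i],      1 - tp$p22[i], 0,
                0,         0,              1,             0,
                0,         0,              0,             1),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("state", 1:4), paste0("state", 1:4)))
  m
}

#' Transition rate matrix at a given age
#'
#' Returns the 4x4 generator of the latent process at age \code{age}: row 1
#' carries the onset intensities \code{lambda12} (to progressive PCDP) and
#' \code{lambda14 = r * lambda12} (to non-progressive PCDP), row 2 the
#' progression intensity \code{lambda23} (to the clinical phase); the clinical
#' and non-progressive states are absorbing.
#'
#' @param params A [model_parameters] object.
#' @param partition An [age_partition]; intensities are constant within its
#'   intervals.
#' @param age Age in years, at or above the initiation age \code{t0}.
#' @return A 4x4 numeric matrix with zero row sums.
#' @examples
#' p <- model_parameters(lambda12 = c(0.0015, 0.00276, 0.00381),
#'                       lambda23 = c(0.385, 0.464, 0.284),
#'                       r = 0.00182, S = 0.88)
#' rate_matrix_at_age(p, age_partition(), 55)
#' @export
rate_matrix_at_age <- function(params, partition = age_partition(), age) {
  par <- .par_engine(params, partition)
  if (length(age) != 1L || !is.finite(age)) stop("`age` must be a single finite age")
  l <- interval_index(partition, age)
  l12 <- par$l12[l]; l23 <- par$l23[l]; l14 <- par$r * l12
  matrix(c(-(l12 + l14), l12,  0,   l14,
           0,           -l23,  l23, 0,
           0,            0,    0,   0,
           0,            0,    0,   0),
         nrow = 4, byrow = TRUE,
         dimnames = list(paste0("state", 1:4), paste0("state", 1:4)))
}

#' Transition probability matrix over one constant-rate piece
#'
#' Closed-form solution of the forward Kolmogorov equation for the acyclic
#' four-state chain over a duration \code{dt} with the rates of one age
#' interval held constant.
#'
#' @inheritParams rate_matrix_at_age
#' @param interval Index of the age interval whose rates apply.
#' @param dt Non-negative duration in years.
#' @return A 4x4 row-stochastic matrix; rows 3 and 4 are absorbing.
#' @export
piece_transition_matrix <- function(params, partition = age_partition(),
                                    interval, dt) {
  par <- .par_engine(params, partition)
  if (length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("`dt` must be a single non-negative duration")
  interval <- as.integer(interval)
  if (interval < 1L || interval > partition$n_intervals)
    stop("`interval` out of range")
  one <- list(l12 = par$l12[interval], l23 = par$l23[interval], r = par$r,
              S = par$S, cuts = 0, t0 = 0)
  .assemble_tpm(.trans_probs(0, dt, one))
}

#' Transition probability matrix between two ages
#'
#' Composes the piecewise closed-form solutions across every partition
#' cutpoint lying in \code{(s, t)}, yielding \eqn{P(s, t)} for the latent
#' process. Satisfies the Chapman-Kolmogorov identity.
#'
#' @inheritParams rate_matrix_at_age
#' @param s,t Ages in years with \code{t0 <= s <= t}.
#' @return A 4x4 row-stochastic matrix.
#' @examples
#' p <- model_parameters(c(0.0015, 0.00276, 0.00381), c(0.385, 0.464, 0.284),
#'                       r = 0.00182, S = 0.88)
#' transition_matrix(p, age_partition(), 40, 50)
#' @export
transition_matrix <- function(params, partition = age_partition(), s, t) {
  par <- .par_engine(params, partition)
  if (length(s) != 1L || length(t) != 1L) stop("`s` and `t` must be single ages")
  if (s < partition$t0) stop("`s` below the initiation age t0 = ", partition$t0)
  if (s > t) stop("`s` must not exceed `t`")
  .assemble_tpm(.trans_probs(s, t, par))
}

#' Mean sojourn time in the progressive preclinical phase
#'
#' The mean sojourn time (MST) is the expected duration spent in the
#' progressive preclinical screen-detectable phase before clinical surfacing,
#' \code{1 / lambda23}, in years.
#'
#' @param lambda23 Positive progression rate(s) per woman-year (vectorised).
#' @return Mean sojourn time(s) in years.
#' @examples
#' mean_sojourn_time(c(0.385, 0.464, 0.284))
#' @export
mean_sojourn_time <- function(lambda23) {
  if (!is.numeric(lambda23) || any(!is.finite(lambda23)) || any(lambda23 <= 0))
    stop("`lambda23` must be positive")
  1 / lambda23
}
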