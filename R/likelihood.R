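# Observed-data likelihood for individual screening histories.
#
# The observed process has three states (negative finding, screen-detected
# case, clinical case) linked to the latent four-state chain through the
# misclassification matrix E with test sensitivity S, plus the simplifying
# assumption that a false-negative case is detected at the woman's next
# attended screen unless it surfaces clinically before then.
#
# The per-woman likelihood is a forward recursion over a three-component
# belief anchored at the last attended screen v:
#   b1: in state 1 at v (all screens so far truly negative)
#   b2: in state 2 at v, missed at v
#   b4: in state 4 at v, missed at v
# A negative screen at u multiplies b1 by P11(v,u) and routes newly entered
# preclinical mass through (1 - S); carried missed mass must resolve by the
# next attended screen, so it contributes nothing to a second negative --
# two consecutive negatives anchor state 1 at the earlier screen. Terminal
# factors: screen detection gets S on newly entered preclinical mass and
# probability one on carried missed mass; clinical diagnosis gets the onset
# density at the diagnosis age; censoring gets the probability of no
# clinical event by the censoring age.

#' Misclassification matrix of the screening test
#'
#' Rows are the latent states (1 free of BC, 2 progressive PCDP, 3 clinical
#' phase, 4 non-progressive PCDP), columns the observed states (negative,
#' screen-detected, clinical). A woman free of cancer is never confirmed as a
#' case (assessment resolves false positives), and both preclinical states
#' are detected with the same sensitivity \code{S}.
#'
#' @param S Test sensitivity, a probability.
#' @return A 4x3 matrix with unit row sums.
#' @examples
#' misclassification_matrix(0.88)
#' @export
misclassification_matrix <- function(S) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S < 0 || S > 1)
    stop("`S` must be a probability in [0, 1]")
  matrix(c(1,     0, 0,
           1 - S, S, 0,
           0,     0, 1,
           1 - S, S, 0),
         nrow = 4, byrow = TRUE,
         dimnames = list(paste0("state", 1:4),
                         c("negative", "screen_detected", "clinical")))
}

#' Density of clinical surfacing at a given age
#'
#' Returns the sub-density of entering the clinical phase at age \code{u} for
#' a woman in state 1 (\code{from = "free"}) or in the progressive preclinical
#' phase (\code{from = "progressive"}) at age \code{s}. By the forward
#' Kolmogorov equation these are \code{lambda23(u) * P12(s, u)} and
#' \code{lambda23(u) * P22(s, u)} respectively.
#'
#' @inheritParams rate_matrix_at_age
#' @param s Anchoring age (years).
#' @param u Age of clinical surfacing, strictly greater than \code{s}
#'   (vectorised).
#' @param from Latent state at age \code{s}.
#' @return Density value(s) per year.
#' @export
clinical_onset_density <- function(params, partition = age_partition(), s, u,
                                   from = c("free", "progressive")) {
  from <- match.arg(from)
  par <- .par_engine(params, partition)
  if (length(s) == 1L) s <- rep(s, length(u))
  if (any(u <= s)) stop("`u` must be strictly greater than `s`")
  if (any(s < partition$t0)) stop("`s` below the initiation age t0")
  l23 <- par$l23[findInterval(u, par$cuts)]
  tp <- .trans_probs(s, u, par)
  if (from == "free") l23 * tp$p12 else l23 * tp$p22
}

# Core engine: per-woman log-likelihood over compiled arrays. Every
# transition-probability pair was stacked at compile time (the age pairs are
# data, not parameters), so each call hands one duration matrix and the
# slice structure to the compiled kernel. `cc` is the compiled cohort list,
# `par` the flat parameter list.
.loglik_engine <- function(cc, par, condition_entry = FALSE) {
  n <- cc$n
  t0 <- par$t0
  if (any(cc$entry_age < t0 - 1e-9, na.rm = TRUE))
    stop("entry (first invitation) before the initiation age t0 = ", t0)
  ca <- cc$lik_cache
  if (!identical(ca$dt_cuts, par$cuts)) {
    s_all <- ca$s_all
    s_all[ca$t0_mask] <- t0
    if (isTRUE(any(s_all > ca$t_all + 1e-12, na.rm = TRUE)))
      stop("screen or event ages precede the initiation age t0 = ", t0)
    dtl <- .trans_durations(s_all, ca$t_all, par$cuts)
    ca$n_pairs <- length(s_all)
    ca$nz_idx <- lapply(dtl, function(d) which(d > 0))
    ca$nz_dt <- lapply(seq_along(dtl), function(l) dtl[[l]][ca$nz_idx[[l]]])
    ca$cl_int <- findInterval(cc$outcome_age[ca$cl$idx], par$cuts)
    ca$dt_cuts <- par$cuts
  }
  .loglik_cpp(n, ca$n_pairs, ca$nz_idx, ca$nz_dt,
              par$l12, par$l23, par$r, par$S,
              ca$steps_idx, ca$steps_det,
              ca$cl$idx, ca$cl_int, ca$cs$idx, condition_entry)
}

# Reference implementation of the same recursion in plain R; retained as the
# independent cross-check of the compiled kernel.
.loglik_engine_r <- function(cc, par, condition_entry = FALSE) {
  n <- cc$n
  t0 <- par$t0
  if (any(cc$entry_age < t0 - 1e-9, na.rm = TRUE))
    stop("entry (first invitation) before the initiation age t0 = ", t0)
  ca <- cc$lik_cache
  s_all <- ca$s_all
  s_all[ca$t0_mask] <- t0
  tp <- .trans_probs(s_all, ca$t_all, par)

  S <- par$S
  b1 <- rep(1, n); b2 <- numeric(n); b4 <- numeric(n)
  logw <- numeric(n)
  ll <- rep(NA_real_, n)

  for (k in seq_len(ca$K)) {
    st <- ca$steps[[k]]
    if (is.null(st)) next
    at <- st$at
    p11 <- tp$p11[at]; p12 <- tp$p12[at]; p14 <- tp$p14[at]; p22 <- tp$p22[at]
    det <- st$det
    if (any(det)) {
      i <- st$idx[det]
      lik <- b1[i] * (p12[det] + p14[det]) * S + b2[i] * p22[det] + b4[i]
      ll[i] <- logw[i] + log(lik)
    }
    if (any(!det)) {
      i <- st$idx[!det]
      nb1 <- b1[i] * p11[!det]
      nb2 <- b1[i] * p12[!det] * (1 - S)
      nb4 <- b1[i] * p14[!det] * (1 - S)
      norm <- nb1 + nb2 + nb4
      logw[i] <- logw[i] + log(norm)
      b1[i] <- nb1 / norm; b2[i] <- nb2 / norm; b4[i] <- nb4 / norm
    }
  }

  cl <- ca$cl$idx
  if (length(cl)) {
    at <- ca$cl$at
    l23 <- par$l23[findInterval(cc$outcome_age[cl], par$cuts)]
    lik <- l23 * (b1[cl] * tp$p12[at] + b2[cl] * tp$p22[at])
    ll[cl] <- logw[cl] + log(lik)
  }
  cs <- ca$cs$idx
  if (length(cs)) {
    at <- ca$cs$at
    lik <- b1[cs] * (1 - tp$p13[at]) + b2[cs] * tp$p22[at] + b4[cs]
    ll[cs] <- logw[cs] + log(lik)
  }
  if (condition_entry) {
    if (any(is.na(cc$entry_age)))
      stop("entry conditioning needs an invitation age for every woman; ",
           "the cohort contains women without invitations")
    ll <- ll - log1p(-tp$p13[ca$entry_at])
  }
  ll
}

#' Log-likelihood of one screening history
#'
#' @param history A [screening_history].
#' @inheritParams rate_matrix_at_age
#' @param condition_entry Condition on being free of clinical cancer at entry
#'   (first invitation) by dividing by \code{1 - P13(t0, entry)}. Off by
#'   default: the estimation anchors every woman in state 1 at \code{t0} and
#'   excludes pre-invitation diagnoses without further conditioning.
#' @return The log-likelihood value.
#' @examples
#' p <- model_parameters(c(0.0015, 0.00276, 0.00381), c(0.385, 0.464, 0.284),
#'                       r = 0.00182, S = 0.88)
#' h <- screening_history(1, invited_ages = c(50, 52), screen_ages = c(50, 52),
#'                        outcome = "screen_detected", outcome_age = 52)
#' history_loglik(h, p)
#' @export
history_loglik <- function(history, params, partition = age_partition(),
                           condition_entry = FALSE) {
  stopifnot(inherits(history, "screening_history"))
  co <- screening_cohort(list(history))
  par <- .par_engine(params, partition)
  .loglik_engine(co$cc, par, condition_entry)[1L]
}

#' Total log-likelihood of a screening cohort
#'
#' Sums per-woman contributions. Never-attenders contribute through the
#' clinical-onset density (cancer cases) or the no-clinical-event survival
#' probability (censored), anchored in state 1 at \code{t0}.
#'
#' @param cohort A [screening_cohort].
#' @inheritParams history_loglik
#' @param per_woman Return the vector of per-woman contributions instead of
#'   the sum.
#' @return Total log-likelihood (or per-woman vector).
#' @export
cohort_loglik <- function(cohort, params, partition = age_partition(),
                          condition_entry = FALSE, per_woman = FALSE) {
  stopifnot(inherits(cohort, "screening_cohort"))
  if (cohort$cc$n < 1L) stop("empty cohort")
  par <- .par_engine(params, partition)
  ll <- .loglik_engine(cohort$cc, par, condition_entry)
  if (per_woman) ll else sum(ll)
}
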