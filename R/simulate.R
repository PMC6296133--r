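# Synthetic screening-cohort generator.
#
# Emulates a biennial invitation programme (ages 50-69, ~73% participation,
# ~2% benign recalls) layered over latent four-state disease trajectories, in
# two observation modes:
#   model_faithful -- a case missed at an attended screen is detected with
#     probability one at her next attended screen (unless clinical first),
#     exactly matching the likelihood's carry-forward simplification;
#   natural -- every attended screen is an independent Bernoulli(S) test.

#' Configuration for the cohort simulator
#'
#' Defaults encode the study conditions the model targets: biennial
#' invitations from age 50 to 69, per-invitation participation 0.727, benign
#' recall probability 0.02 per attended screen of a cancer-free woman, and
#' follow-up to two years after the last invitation. The first invitation age
#' is jittered uniformly by +/- `entry_jitter` years to avoid grid artifacts;
#' set it to 0 for exact worked examples.
#'
#' @param n_women Number of women to generate.
#' @param params True [model_parameters].
#' @param partition [age_partition] for the piecewise rates.
#' @param first_invite_age Nominal age at first invitation.
#' @param entry_jitter Half-width (years) of the uniform jitter on the first
#'   invitation age.
#' @param invite_interval Years between invitations.
#' @param last_invite_age No invitations are issued after this age.
#' @param participation Per-invitation attendance probability (independent
#'   across invitations; the likelihood assumes non-informative
#'   participation).
#' @param recall_fp Probability that an attended screen of a cancer-free woman
#'   is recalled for assessment with a benign outcome. Affects descriptives
#'   only; assessment never creates a cancer record.
#' @param study_end_age Administrative end of follow-up (age); default
#'   unbounded, so follow-up ends `invite_interval` years after the last
#'   invitation.
#' @param mode Observation mode, see above.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_women = 20000,
                              params = model_parameters(
                                lambda12 = c(0.0015, 0.00276, 0.00381),
                                lambda23 = c(0.385, 0.464, 0.284),
                                r = 0.00182, S = 0.880),
                              partition = age_partition(),
                              first_invite_age = 50, entry_jitter = 1,
                              invite_interval = 2, last_invite_age = 69,
                              participation = 0.727, recall_fp = 0.02,
                              study_end_age = Inf,
                              mode = c("model_faithful", "natural")) {
  mode <- match.arg(mode)
  stopifnot(n_women >= 1, invite_interval > 0,
            participation >= 0, participation <= 1,
            recall_fp >= 0, recall_fp <= 1,
            first_invite_age - entry_jitter >= partition$t0,
            last_invite_age >= first_invite_age, entry_jitter >= 0)
  structure(list(n_women = as.integer(n_women), params = params,
                 partition = partition, first_invite_age = first_invite_age,
                 entry_jitter = entry_jitter, invite_interval = invite_interval,
                 last_invite_age = last_invite_age,
                 participation = participation, recall_fp = recall_fp,
                 study_end_age = study_end_age, mode = mode),
            class = "simulation_config")
}

# First passage time of a piecewise-exponential hazard, by inversion of the
# cumulative hazard. `rate[l]` applies on [cuts[l], cuts[l+1]); event times
# are measured from the (vector of) start ages; Inf when no event.
.sim_piecewise_exp <- function(start, rate, cuts) {
  n <- length(start)
  E <- stats::rexp(n)
  out <- rep(Inf, n)
  rem <- E
  done <- rep(FALSE, n)
  upper <- c(cuts[-1L], Inf)
  for (l in seq_along(rate)) {
    lo <- pmax(start, cuts[l])
    len <- pmax(upper[l] - lo, 0)
    h <- rate[l]
    Hseg <- if (h > 0) h * len else rep(0, n)
    hit <- !done & h > 0 & rem <= Hseg
    out[hit] <- lo[hit] + rem[hit] / h
    done <- done | hit
    rem <- rem - Hseg
  }
  out
}

#' Simulate latent disease trajectories
#'
#' Draws the latent four-state path for `n` women anchored in state 1 at
#' `t0`: the exit time from state 1 follows the piecewise-exponential hazard
#' \code{lambda12(t) (1 + r)}, the destination is non-progressive with
#' probability \code{r / (1 + r)}, and progressive onsets draw a clinical
#' surfacing time from the piecewise-exponential hazard \code{lambda23(t)}.
#' Uses the current RNG state.
#'
#' @param n Number of trajectories.
#' @inheritParams rate_matrix_at_age
#' @return A data.frame with `onset_age` (Inf if no onset), `destination`
#'   (`"progressive"`, `"non_progressive"` or `"none"`) and `clinical_age`
#'   (Inf unless a progressive case surfaces).
#' @export
simulate_latent_trajectories <- function(n, params,
                                         partition = age_partition()) {
  par <- .par_engine(params, partition)
  onset <- .sim_piecewise_exp(rep(par$t0, n), par$l12 * (1 + par$r), par$cuts)
  dest <- ifelse(is.finite(onset),
                 ifelse(stats::runif(n) < par$r / (1 + par$r),
                        "non_progressive", "progressive"),
                 "none")
  clin <- rep(Inf, n)
  pr <- which(dest == "progressive")
  if (length(pr))
    clin[pr] <- .sim_piecewise_exp(onset[pr], par$l23, par$cuts)
  data.frame(onset_age = onset, destination = dest, clinical_age = clin)
}

#' Simulate a screening cohort
#'
#' Generates individual screening histories with the exact statistical
#' structure the likelihood assumes (see [simulation_config] for the
#' programme design). Women whose clinical surfacing precedes their first
#' invitation are excluded, mirroring the register convention of dropping
#' pre-invitation diagnoses; the number excluded is recorded in the
#' `"n_excluded"` attribute.
#'
#' @param config A [simulation_config].
#' @param seed Optional integer seed; when supplied the cohort is
#'   byte-identical across runs.
#' @return A [screening_cohort] with a ground-truth data.frame in
#'   `$truth` (onset age, destination, clinical age, detection flags).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  par <- .par_engine(config$params, config$partition)
  n <- config$n_women

  entry <- rep(config$first_invite_age, n) +
    if (config$entry_jitter > 0) stats::runif(n, -config$entry_jitter,
                                              config$entry_jitter) else 0
  lat <- simulate_latent_trajectories(n, config$params, config$partition)

  keep <- lat$clinical_age > entry
  entry <- entry[keep]; lat <- lat[keep, , drop = FALSE]
  n_excl <- n - sum(keep)
  n <- sum(keep)
  if (n < 1L) stop("all simulated women excluded; check the configuration")

  J <- floor((config$last_invite_age - min(entry)) / config$invite_interval) + 1L
  invited <- outer(entry, (seq_len(J) - 1L) * config$invite_interval, `+`)
  invited[invited > config$last_invite_age + 1e-9] <- NA_real_
  invited[invited > config$study_end_age] <- NA_real_
  attend <- matrix(stats::runif(n * J) < config$participation, n, J)

  active <- rep(TRUE, n)
  missed <- rep(FALSE, n)
  outcome <- rep("censored", n)
  out_age <- rep(NA_real_, n)
  det_round <- rep(NA_integer_, n)
  n_att <- integer(n)
  # per-screen event codes: 0 none, 1 neg, 2 recall-benign, 3 detected
  scr_code <- matrix(0L, n, J)

  for (j in seq_len(J)) {
    u <- invited[, j]
    has <- active & !is.na(u)
    # clinical surfacing before this invitation
    cl <- has & lat$clinical_age <= u
    outcome[cl] <- "clinical"; out_age[cl] <- lat$clinical_age[cl]
    active[cl] <- FALSE
    att <- active & !is.na(u) & attend[, j]
    n_att[att] <- n_att[att] + 1L
    in_pcdp <- att & lat$onset_age <= u
    if (config$mode == "model_faithful") {
      pdet <- ifelse(missed[in_pcdp], 1, par$S)
    } else {
      pdet <- par$S
    }
    det <- in_pcdp
    det[in_pcdp] <- stats::runif(sum(in_pcdp)) < pdet
    scr_code[det, j] <- 3L
    outcome[det] <- "screen_detected"; out_age[det] <- u[det]
    det_round[det] <- n_att[det]
    active[det] <- FALSE
    fn <- in_pcdp & !det
    scr_code[fn, j] <- 1L
    missed[fn] <- TRUE
    free <- att & lat$onset_age > u
    rec <- free
    rec[free] <- stats::runif(sum(free)) < config$recall_fp
    scr_code[rec, j] <- 2L
    scr_code[free & !rec, j] <- 1L
  }

  last_inv <- apply(invited, 1L, function(z) max(z, na.rm = TRUE))
  censor <- pmin(last_inv + config$invite_interval, config$study_end_age)
  post_cl <- active & lat$clinical_age <= censor
  outcome[post_cl] <- "clinical"; out_age[post_cl] <- lat$clinical_age[post_cl]
  censor_age <- ifelse(outcome == "censored", censor, out_age)

  # assemble the long event table, per woman in age order
  wid <- seq_len(n)
  ev_list <- vector("list", 2L * J + 2L)
  pos <- 0L
  for (j in seq_len(J)) {
    has <- !is.na(invited[, j]) &
      (is.na(out_age) | invited[, j] <= out_age + 1e-12)
    # invitations after the outcome are not part of the history
    has <- has & (outcome == "censored" | invited[, j] <= censor_age + 1e-12)
    if (any(has)) {
      pos <- pos + 1L
      ev_list[[pos]] <- data.frame(woman_id = wid[has], event = "invite",
                                   age = invited[has, j])
    }
    sc <- scr_code[, j]
    scr <- sc > 0L
    if (any(scr)) {
      pos <- pos + 1L
      ev_list[[pos]] <- data.frame(
        woman_id = wid[scr],
        event = c("screen_neg", "screen_pos_recall_benign",
                  "screen_detected")[sc[scr]],
        age = invited[scr, j])
    }
  }
  cl_all <- outcome == "clinical"
  if (any(cl_all)) {
    pos <- pos + 1L
    ev_list[[pos]] <- data.frame(woman_id = wid[cl_all], event = "clinical_dx",
                                 age = out_age[cl_all])
  }
  cs <- outcome == "censored"
  if (any(cs)) {
    pos <- pos + 1L
    ev_list[[pos]] <- data.frame(woman_id = wid[cs], event = "censor",
                                 age = censor_age[cs])
  }
  events <- do.call(rbind, ev_list[seq_len(pos)])

  truth <- data.frame(
    woman_id = wid,
    onset_age = lat$onset_age,
    destination = lat$destination,
    clinical_age = lat$clinical_age,
    detected = outcome == "screen_detected",
    detected_round = det_round,
    nonprogressive_detected = outcome == "screen_detected" &
      lat$destination == "non_progressive"
  )
  co <- screening_cohort(events, truth = truth)
  attr(co, "n_excluded") <- n_excl
  attr(co, "config") <- config
  co
}
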