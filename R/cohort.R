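# Screening histories and cohort containers.
#
# The canonical on-disk form is a long-format CSV, one row per event:
#   woman_id, event, age
# with event one of invite, screen_neg, screen_pos_recall_benign,
# screen_detected, clinical_dx, censor. In memory a cohort keeps the event
# table plus a compiled per-woman representation (NA-padded age matrices) that
# the likelihood and descriptive kernels operate on.

.EVENT_LEVELS <- c("invite", "screen_neg", "screen_pos_recall_benign",
                   "screen_detected", "clinical_dx", "censor")
.SCREEN_EVENTS <- c("screen_neg", "screen_pos_recall_benign", "screen_detected")
.TERMINAL_EVENTS <- c("screen_detected", "clinical_dx", "censor")

#' A single woman's screening history
#'
#' @param woman_id Identifier (scalar).
#' @param invited_ages Ordered ages (years) of all screening invitations.
#' @param screen_ages Ordered ages of attended screens; each must coincide
#'   with an invitation age.
#' @param outcome One of \code{"censored"}, \code{"clinical"},
#'   \code{"screen_detected"}.
#' @param outcome_age Age at diagnosis/detection (required for cancer
#'   outcomes; for \code{"screen_detected"} it must equal the last attended
#'   screen age).
#' @param censor_age End of follow-up; equals \code{outcome_age} for cancers.
#' @return An object of class \code{screening_history}.
#' @examples
#' screening_history(1, invited_ages = c(50, 52), screen_ages = c(50, 52),
#'                   outcome = "screen_detected", outcome_age = 52)
#' @export
screening_history <- function(woman_id, invited_ages = numeric(),
                              screen_ages = numeric(),
                              outcome = c("censored", "clinical",
                                          "screen_detected"),
                              outcome_age = NA_real_, censor_age = NA_real_) {
  outcome <- match.arg(outcome)
  invited_ages <- as.numeric(invited_ages)
  screen_ages <- as.numeric(screen_ages)
  if (length(invited_ages) && is.unsorted(invited_ages, strictly = TRUE))
    stop("`invited_ages` must be strictly increasing")
  if (length(screen_ages) && is.unsorted(screen_ages, strictly = TRUE))
    stop("`screen_ages` must be strictly increasing")
  if (length(screen_ages)) {
    ok <- vapply(screen_ages, function(a)
      any(abs(invited_ages - a) < 1e-8), logical(1))
    if (!all(ok))
      stop("every attended screen must coincide with an invitation age")
  }
  if (outcome == "screen_detected") {
    if (!length(screen_ages)) stop("screen-detected outcome requires screens")
    if (is.na(outcome_age) ||
        abs(outcome_age - screen_ages[length(screen_ages)]) > 1e-8)
      stop("a screen-detected outcome_age must equal the last attended screen age")
  }
  if (outcome == "clinical") {
    if (is.na(outcome_age)) stop("clinical outcome requires `outcome_age`")
    if (length(screen_ages) && outcome_age <= screen_ages[length(screen_ages)])
      stop("clinical diagnosis must fall strictly after the last attended screen")
  }
  if (outcome == "censored") {
    if (is.na(censor_age)) stop("censored history requires `censor_age`")
    outcome_age <- NA_real_
  } else {
    censor_age <- outcome_age
  }
  if (length(screen_ages) && censor_age < screen_ages[length(screen_ages)] - 1e-8)
    stop("`censor_age` must not precede the last attended screen")
  structure(list(woman_id = woman_id, invited_ages = invited_ages,
                 screen_ages = screen_ages, outcome = outcome,
                 outcome_age = outcome_age, censor_age = censor_age),
            class = "screening_history")
}

#' @export
print.screening_history <- function(x, ...) {
  cat("Screening history for woman", format(x$woman_id), "\n")
  cat("  invited:", paste(round(x$invited_ages, 2), collapse = ", "), "\n")
  cat("  attended:", if (length(x$screen_ages))
    paste(round(x$screen_ages, 2), collapse = ", ") else "(never)", "\n")
  cat("  outcome:", x$outcome,
      if (!is.na(x$outcome_age)) paste0("at age ", round(x$outcome_age, 2)),
      "| follow-up ends", round(x$censor_age, 2), "\n")
  invisible(x)
}

# Fill an NA-padded matrix from grouped, ordered values.
.pad_matrix <- function(group, values, n_groups) {
  cnt <- tabulate(group, nbins = n_groups)
  K <- max(cnt, 1L)
  m <- matrix(NA_real_, n_groups, K)
  if (length(values)) m[cbind(group, sequence(cnt))] <- values
  m
}

# Build the compiled per-woman arrays from an ordered event table.
.compile_cohort <- function(events) {
  wid <- factor(events$woman_id, levels = unique(events$woman_id))
  n <- nlevels(wid)
  g <- as.integer(wid)

  inv <- events$event == "invite"
  scr <- events$event %in% .SCREEN_EVENTS
  invited <- .pad_matrix(g[inv], events$age[inv], n)
  screens <- .pad_matrix(g[scr], events$age[scr], n)
  n_invited <- tabulate(g[inv], nbins = n)
  n_screens <- tabulate(g[scr], nbins = n)

  term <- events$event %in% .TERMINAL_EVENTS
  tg <- g[term]
  outcome <- character(n); out_age <- rep(NA_real_, n)
  outcome[tg] <- as.character(events$event[term])
  out_age[tg] <- events$age[term]
  outcome <- c(censor = "censored", clinical_dx = "clinical",
               screen_detected = "screen_detected")[outcome]

  entry <- invited[, 1L]
  last_inv <- invited[cbind(seq_len(n), pmax(n_invited, 1L))]
  last_inv[n_invited == 0L] <- NA_real_
  censor_age <- out_age
  cc <- list(n = n, woman_id = levels(wid), entry_age = entry,
             invited = invited, n_invited = n_invited,
             last_invited_age = last_inv,
             screens = screens, n_screens = n_screens,
             outcome = unname(outcome), outcome_age = out_age,
             censor_age = censor_age)
  cc$lik_cache <- .build_lik_cache(cc)
  cc
}

# Precompute, once per cohort, everything the likelihood recursion needs that
# does not depend on the parameters: the (s, t) age pairs of every transition
# probability evaluation (stacked into one long vector so each likelihood
# evaluation makes a single vectorised kernel call), the women involved at
# each screening step, and the terminal-event slices. Pairs whose start is
# the initiation age t0 (unknown until a partition is supplied) carry NA and
# are filled in at evaluation time.
.build_lik_cache <- function(cc) {
  n <- cc$n
  K <- ncol(cc$screens)
  if (all(is.na(cc$screens))) K <- 0L
  is_det <- cc$outcome == "screen_detected"
  s_all <- numeric(0); t_all <- numeric(0)
  steps <- vector("list", K)
  off <- 0L
  for (k in seq_len(K)) {
    idx <- which(!is.na(cc$screens[, k]))
    if (!length(idx)) { steps[[k]] <- NULL; next }
    s <- if (k == 1L) rep(NA_real_, length(idx)) else cc$screens[idx, k - 1L]
    t <- cc$screens[idx, k]
    det <- is_det[idx] & cc$n_screens[idx] == k
    steps[[k]] <- list(idx = idx, det = det, at = off + seq_along(idx))
    s_all <- c(s_all, s); t_all <- c(t_all, t)
    off <- off + length(idx)
  }
  last_scr <- function(i) {
    k <- cc$n_screens[i]
    out <- rep(NA_real_, length(i))
    pos <- k > 0L
    out[pos] <- cc$screens[cbind(i[pos], k[pos])]
    out
  }
  cl_idx <- which(cc$outcome == "clinical")
  cl_at <- off + seq_along(cl_idx)
  s_all <- c(s_all, last_scr(cl_idx)); t_all <- c(t_all, cc$outcome_age[cl_idx])
  off <- off + length(cl_idx)
  cs_idx <- which(cc$outcome == "censored")
  cs_at <- off + seq_along(cs_idx)
  s_all <- c(s_all, last_scr(cs_idx)); t_all <- c(t_all, cc$censor_age[cs_idx])
  off <- off + length(cs_idx)
  en_at <- off + seq_len(n)
  s_all <- c(s_all, rep(NA_real_, n)); t_all <- c(t_all, cc$entry_age)
  ca <- new.env(parent = emptyenv())
  ca$K <- K; ca$steps <- steps; ca$s_all <- s_all; ca$t_all <- t_all
  ca$t0_mask <- is.na(s_all)
  ca$cl <- list(idx = cl_idx, at = cl_at)
  ca$cs <- list(idx = cs_idx, at = cs_at)
  ca$entry_at <- en_at
  # flat slice layout for the compiled kernel (same order as s_all/t_all)
  ca$steps_idx <- unlist(lapply(steps, `[[`, "idx"), use.names = FALSE)
  ca$steps_det <- as.integer(unlist(lapply(steps, `[[`, "det"),
                                    use.names = FALSE))
  if (is.null(ca$steps_idx)) {
    ca$steps_idx <- integer(0); ca$steps_det <- integer(0)
  }
  ca$dt_cuts <- NULL   # memoised per-interval durations, keyed on cutpoints
  ca$dtm <- NULL
  ca$cl_int <- NULL
  ca
}

.validate_events <- function(events) {
  req <- c("woman_id", "event", "age")
  if (!all(req %in% names(events)))
    stop("cohort events need columns: ", paste(req, collapse = ", "))
  if (nrow(events) == 0L) stop("empty cohort: no events")
  events$age <- as.numeric(events$age)
  bad <- which(!events$event %in% .EVENT_LEVELS)
  if (length(bad))
    stop("unknown event type at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": ", paste(unique(events$event[bad]), collapse = ", "))
  bad <- which(!is.finite(events$age))
  if (length(bad))
    stop("non-finite age at row(s) ", paste(utils::head(bad, 5), collapse = ", "))

  # order by woman (first appearance) then age, events at equal age: invite first
  wid <- factor(events$woman_id, levels = unique(events$woman_id))
  rank_ev <- match(events$event, .EVENT_LEVELS)
  ord <- order(as.integer(wid), events$age, rank_ev)
  events <- events[ord, , drop = FALSE]
  row0 <- attr(events, "source_row")
  if (is.null(row0)) row0 <- seq_len(nrow(events)) else row0 <- row0[ord]

  g <- as.integer(factor(events$woman_id, levels = unique(events$woman_id)))
  # per-woman ordering of like events must be strict
  for (ev in c("invite", "screen")) {
    sel <- if (ev == "invite") events$event == "invite"
           else events$event %in% .SCREEN_EVENTS
    gg <- g[sel]; aa <- events$age[sel]
    dup <- which(duplicated(cbind(gg, aa)))
    if (length(dup))
      stop("duplicated ", ev, " ages within a woman at row(s) ",
           paste(utils::head(row0[sel][dup], 5), collapse = ", "))
  }
  # exactly one terminal event per woman, last by age
  term <- events$event %in% .TERMINAL_EVENTS
  n <- max(g)
  cnt <- tabulate(g[term], nbins = n)
  if (any(cnt != 1L))
    stop("each woman needs exactly one terminal event ",
         "(censor, clinical_dx or screen_detected); offending woman_id(s): ",
         paste(utils::head(unique(events$woman_id)[cnt != 1L], 5), collapse = ", "))
  last_age <- tapply(events$age, g, max)
  term_age <- events$age[term][order(g[term])]
  late <- which(term_age < last_age - 1e-8)
  if (length(late))
    stop("events after the terminal event for woman_id(s): ",
         paste(utils::head(unique(events$woman_id)[late], 5), collapse = ", "))
  events
}

#' Build a screening cohort
#'
#' Constructs a validated cohort either from a long-format event
#' \code{data.frame} (columns \code{woman_id}, \code{event}, \code{age}) or
#' from a list of [screening_history] objects. Recall-for-assessment events
#' with a benign outcome (\code{screen_pos_recall_benign}) are kept for the
#' descriptive summaries but count as negative screens in the likelihood,
#' since assessment rules out cancer.
#'
#' @param x Event \code{data.frame} or list of [screening_history] objects.
#' @param truth Optional ground-truth \code{data.frame} from the simulator.
#' @return An object of class \code{screening_cohort}.
#' @export
screening_cohort <- function(x, truth = NULL) {
  if (is.data.frame(x)) {
    events <- .validate_events(x)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "screening_history"))) {
    events <- do.call(rbind, lapply(x, .history_events))
    events <- .validate_events(events)
  } else {
    stop("`x` must be an event data.frame or a list of screening_history objects")
  }
  cc <- .compile_cohort(events)
  .validate_compiled(cc)
  structure(list(events = events, cc = cc, truth = truth),
            class = "screening_cohort")
}

.history_events <- function(h) {
  inv <- h$invited_ages[h$invited_ages <= h$censor_age + 1e-9]
  ev <- data.frame(woman_id = rep(h$woman_id, length(inv)),
                   event = rep("invite", length(inv)), age = inv)
  if (length(h$screen_ages)) {
    scr_ev <- rep("screen_neg", length(h$screen_ages))
    if (h$outcome == "screen_detected")
      scr_ev[length(scr_ev)] <- "screen_detected"
    ev <- rbind(ev, data.frame(woman_id = h$woman_id, event = scr_ev,
                               age = h$screen_ages))
  }
  if (h$outcome == "clinical")
    ev <- rbind(ev, data.frame(woman_id = h$woman_id, event = "clinical_dx",
                               age = h$outcome_age))
  if (h$outcome == "censored")
    ev <- rbind(ev, data.frame(woman_id = h$woman_id, event = "censor",
                               age = h$censor_age))
  ev
}

.validate_compiled <- function(cc) {
  det <- which(cc$outcome == "screen_detected")
  if (length(det)) {
    k <- cc$n_screens[det]
    if (any(k == 0L))
      stop("screen-detected outcome without any attended screen: woman_id ",
           paste(utils::head(cc$woman_id[det][k == 0L], 5), collapse = ", "))
    last_scr <- cc$screens[cbind(det, k)]
    bad <- abs(last_scr - cc$outcome_age[det]) > 1e-8
    if (any(bad))
      stop("screen_detected age must be the last attended screen age: woman_id ",
           paste(utils::head(cc$woman_id[det][bad], 5), collapse = ", "))
  }
  cl <- which(cc$outcome == "clinical" & cc$n_screens > 0L)
  if (length(cl)) {
    last_scr <- cc$screens[cbind(cl, cc$n_screens[cl])]
    bad <- cc$outcome_age[cl] <= last_scr + 1e-10
    if (any(bad))
      stop("clinical diagnosis must fall strictly after the last attended ",
           "screen: woman_id ",
           paste(utils::head(cc$woman_id[cl][bad], 5), collapse = ", "))
  }
  # attended screens must match invitation ages
  if (any(cc$n_screens > 0L)) {
    for (k in seq_len(ncol(cc$screens))) {
      a <- cc$screens[, k]
      has <- !is.na(a)
      if (!any(has)) next
      match_inv <- rowSums(abs(cc$invited[has, , drop = FALSE] - a[has]) < 1e-8,
                           na.rm = TRUE) > 0
      if (!all(match_inv))
        stop("attended screen without a matching invitation: woman_id ",
             paste(utils::head(cc$woman_id[has][!match_inv], 5), collapse = ", "))
    }
  }
  invisible(cc)
}

#' @export
print.screening_cohort <- function(x, ...) {
  cc <- x$cc
  cat("Screening cohort:", cc$n, "women,",
      sum(cc$n_invited), "invitations,", sum(cc$n_screens), "attended screens\n")
  tab <- table(factor(cc$outcome, levels = c("censored", "clinical",
                                             "screen_detected")))
  cat("  outcomes:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$truth)) cat("  (ground-truth labels attached)\n")
  invisible(x)
}

#' Number of women in a cohort
#' @param cohort A [screening_cohort].
#' @return Integer count.
#' @export
n_women <- function(cohort) {
  stopifnot(inherits(cohort, "screening_cohort"))
  cohort$cc$n
}

#' Extract one woman's history from a cohort
#' @param cohort A [screening_cohort].
#' @param i Row index (position, not id).
#' @return A [screening_history].
#' @export
cohort_history <- function(cohort, i) {
  cc <- cohort$cc
  stopifnot(i >= 1, i <= cc$n)
  screening_history(
    woman_id = cc$woman_id[i],
    invited_ages = cc$invited[i, seq_len(cc$n_invited[i])],
    screen_ages = if (cc$n_screens[i]) cc$screens[i, seq_len(cc$n_screens[i])]
                  else numeric(),
    outcome = cc$outcome[i],
    outcome_age = cc$outcome_age[i],
    censor_age = cc$censor_age[i]
  )
}

#' Read a screening cohort from a long-format CSV file
#'
#' Expects a header with columns \code{woman_id}, \code{event}, \code{age}
#' (decimal years, '.' decimal separator). Malformed rows are reported with
#' their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A [screening_cohort].
#' @export
read_cohort <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(ev, "source_row") <- seq_len(nrow(ev)) + 1L  # header is line 1
  screening_cohort(ev)
}

#' Write a screening cohort to a long-format CSV file
#'
#' @param cohort A [screening_cohort].
#' @param path Output path.
#' @param truth_path Optional path for the ground-truth sidecar CSV (written
#'   only when the cohort carries simulation truth).
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  stopifnot(inherits(cohort, "screening_cohort"))
  ev <- cohort$events[, c("woman_id", "event", "age")]
  # 17 significant digits round-trip doubles exactly
  ev$age <- format(ev$age, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path) && !is.null(cohort$truth))
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
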