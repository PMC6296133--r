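# Programme-level descriptive summaries and EU-guideline case classification.

#' Participation rate (percent)
#' @param screened,invited Counts.
#' @return Percentage, NA when nothing was invited.
#' @examples participation_rate(1695872, 2333153)
#' @export
participation_rate <- function(screened, invited) {
  ifelse(invited > 0, 100 * screened / invited, NA_real_)
}

#' Recall rate (percent)
#' @param recalled,screened Counts; recalls include both benign assessments
#'   and confirmed screen-detected cancers.
#' @return Percentage, NA when nothing was screened.
#' @examples recall_rate(42021, 1695872)
#' @export
recall_rate <- function(recalled, screened) {
  ifelse(screened > 0, 100 * recalled / screened, NA_real_)
}

#' Interval cancer ratio (percent)
#'
#' Number of interval cancers divided by the number of prevalent
#' screen-detected, subsequent screen-detected and interval cancers.
#'
#' @param ic,psd,ssd Case counts.
#' @return Percentage, NA when the denominator is zero.
#' @examples ic_ratio(3538, 1799, 6506)
#' @export
ic_ratio <- function(ic, psd, ssd) {
  den <- ic + psd + ssd
  ifelse(den > 0, 100 * ic / den, NA_real_)
}

#' Classify the detection mode of each cancer case
#'
#' EU-guideline classification from the individual screening history:
#' \describe{
#'   \item{PSD}{screen-detected at the woman's first attended screen
#'     (regardless of how many invitations she had ignored before);}
#'   \item{SSD}{screen-detected at any later attended screen;}
#'   \item{IC}{interval cancer: clinical diagnosis after a negative attended
#'     screen, within 24 months and before any further attended screen;}
#'   \item{NP}{clinical diagnosis in a woman whose most recent invitation was
#'     not attended, including never-attenders.}
#' }
#'
#' @param cohort A [screening_cohort].
#' @return A factor of length [n_women()] with levels PSD, SSD, IC, NP and
#'   \code{NA} for women without a cancer outcome.
#' @export
classify_detection_mode <- function(cohort) {
  stopifnot(inherits(cohort, "screening_cohort"))
  cc <- cohort$cc
  mode <- rep(NA_character_, cc$n)

  det <- cc$outcome == "screen_detected"
  mode[det & cc$n_screens == 1L] <- "PSD"
  mode[det & cc$n_screens > 1L] <- "SSD"

  cl <- which(cc$outcome == "clinical")
  if (length(cl)) {
    dx <- cc$outcome_age[cl]
    # most recent invitation at or before diagnosis
    inv <- cc$invited[cl, , drop = FALSE]
    inv_before <- inv <= dx + 1e-9
    inv[!inv_before | is.na(inv)] <- -Inf
    last_inv <- apply(inv, 1L, max)
    # was that invitation attended?
    scr <- cc$screens[cl, , drop = FALSE]
    attended_last <- rowSums(abs(scr - last_inv) < 1e-8, na.rm = TRUE) > 0
    is_ic <- attended_last & (dx - last_inv) <= 2 + 1e-9
    mode[cl] <- ifelse(is_ic, "IC", "NP")
  }
  factor(mode, levels = c("PSD", "SSD", "IC", "NP"))
}

#' Person-years of follow-up per woman
#'
#' Counted from the first invitation to the cancer diagnosis, two years after
#' the last invitation, or the administrative study end, whichever comes
#' first; floored at zero.
#'
#' @param cohort A [screening_cohort].
#' @param study_end_age Administrative end of follow-up in age years
#'   (default unbounded).
#' @param extension Years of observation granted after the last invitation
#'   (2 by default, the invitation interval).
#' @return Numeric vector of person-years.
#' @export
person_years <- function(cohort, study_end_age = Inf, extension = 2) {
  stopifnot(inherits(cohort, "screening_cohort"))
  cc <- cohort$cc
  end <- pmin(ifelse(cc$outcome == "censored", Inf, cc$outcome_age),
              cc$last_invited_age + extension, study_end_age)
  pmax(end - cc$entry_age, 0)
}

#' Programme participation and recall summary
#'
#' Counts invitations, attended screens and recalls (benign assessments plus
#' screen-detected cancers) with the corresponding rates, overall or by
#' invitation round.
#'
#' @param cohort A [screening_cohort].
#' @param by \code{"overall"} or \code{"round"} (the woman's invitation
#'   number).
#' @return A data.frame with counts and percentage rates; strata with no
#'   invitations get \code{NA} rates.
#' @export
program_summary <- function(cohort, by = c("overall", "round")) {
  by <- match.arg(by)
  stopifnot(inherits(cohort, "screening_cohort"))
  ev <- cohort$events
  g <- as.integer(factor(ev$woman_id, levels = unique(ev$woman_id)))
  if (by == "round") {
    is_inv <- ev$event == "invite"
    rnd <- integer(nrow(ev))
    rnd[is_inv] <- stats::ave(rep(1L, sum(is_inv)), g[is_inv], FUN = cumsum)
    # a screen shares the round of the invitation at the same age
    scr <- which(ev$event %in% .SCREEN_EVENTS)
    key_inv <- paste(g[is_inv], round(ev$age[is_inv], 6))
    rnd[scr] <- rnd[is_inv][match(paste(g[scr], round(ev$age[scr], 6)),
                                  key_inv)]
    strata <- sort(unique(rnd[is_inv]))
    out <- do.call(rbind, lapply(strata, function(s) {
      sel <- rnd == s
      .program_counts(ev[sel, , drop = FALSE], label = as.character(s))
    }))
    rbind(out, .program_counts(ev, label = "total"))
  } else {
    .program_counts(ev, label = "total")
  }
}

.program_counts <- function(ev, label) {
  invited <- sum(ev$event == "invite")
  screened <- sum(ev$event %in% .SCREEN_EVENTS)
  recalled <- sum(ev$event %in% c("screen_pos_recall_benign",
                                  "screen_detected"))
  data.frame(stratum = label, invited = invited, screened = screened,
             participation_pct = participation_rate(screened, invited),
             recalled = recalled,
             recall_pct = recall_rate(recalled, screened),
             row.names = NULL)
}

#' Person-years, cases by detection mode and incidence by age group
#'
#' Person-time is sliced by age at the boundaries of the groups; cases are
#' attributed to the group of their age at diagnosis/detection. The last
#' group is open-ended (person-time and cases at older ages fold into it)
#' and the first absorbs any follow-up before its lower bound.
#'
#' @param cohort A [screening_cohort].
#' @param breaks Lower bounds of the age groups (default
#'   \code{c(50, 55, 60, 65)}).
#' @param study_end_age,extension Passed to [person_years()].
#' @return A data.frame with one row per age group plus a total row:
#'   person-years, PSD/SSD/IC/NP counts, IC ratio (percent) and incidence
#'   per 100,000 woman-years.
#' @export
age_group_summary <- function(cohort, breaks = c(50, 55, 60, 65),
                              study_end_age = Inf, extension = 2) {
  stopifnot(inherits(cohort, "screening_cohort"))
  cc <- cohort$cc
  mode <- classify_detection_mode(cohort)
  end <- cc$entry_age + person_years(cohort, study_end_age, extension)
  G <- length(breaks)
  lo <- c(-Inf, breaks[-1L])
  hi <- c(breaks[-1L], Inf)
  labels <- c(paste0(breaks[-G], "-", breaks[-1L] - 1),
              paste0(breaks[G], "+"))

  rows <- lapply(seq_len(G), function(gi) {
    py <- sum(pmax(pmin(end, hi[gi]) - pmax(cc$entry_age, lo[gi]), 0))
    case_age <- cc$outcome_age
    in_g <- !is.na(mode) & case_age >= lo[gi] & case_age < hi[gi] &
      case_age <= end + 1e-9
    counts <- table(mode[in_g])
    data.frame(age_group = labels[gi], person_years = py,
               PSD = as.integer(counts["PSD"]), SSD = as.integer(counts["SSD"]),
               IC = as.integer(counts["IC"]), NP = as.integer(counts["NP"]),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(age_group = "total",
                    person_years = sum(out$person_years),
                    PSD = sum(out$PSD), SSD = sum(out$SSD),
                    IC = sum(out$IC), NP = sum(out$NP))
  out <- rbind(out, tot)
  out$ic_ratio_pct <- ic_ratio(out$IC, out$PSD, out$SSD)
  cases <- out$PSD + out$SSD + out$IC + out$NP
  out$incidence_per_1e5 <- ifelse(out$person_years > 0,
                                  1e5 * cases / out$person_years, NA_real_)
  out
}
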