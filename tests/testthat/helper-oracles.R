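# Independent oracles shared across test files.

# Total probability of the exhaustive, disjoint outcome set for one woman
# with a fixed attended schedule: detection at each screen, clinical
# surfacing in each inter-screen gap (by quadrature), and censoring. A
# correct likelihood makes this sum to one.
partition_total <- function(p, A, screens, censor) {
  stopifnot(censor >= max(screens))
  invited <- screens
  tot <- 0
  for (k in seq_along(screens)) {
    h <- screening_history(1, invited, screens[seq_len(k)],
                           outcome = "screen_detected",
                           outcome_age = screens[k])
    tot <- tot + exp(history_loglik(h, p, A))
  }
  gaps <- cbind(c(A$t0, screens), c(screens, censor))
  for (g in seq_len(nrow(gaps))) {
    if (gaps[g, 2] <= gaps[g, 1] + 1e-12) next
    att <- screens[screens < gaps[g, 1] + 1e-9]
    f <- function(w) vapply(w, function(wi) {
      h <- screening_history(1, invited, att, outcome = "clinical",
                             outcome_age = wi)
      exp(history_loglik(h, p, A))
    }, numeric(1))
    tot <- tot + integrate(f, gaps[g, 1] + 1e-9, gaps[g, 2],
                           rel.tol = 1e-9)$value
  }
  h <- screening_history(1, invited, screens, outcome = "censored",
                         censor_age = censor)
  tot + exp(history_loglik(h, p, A))
}
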