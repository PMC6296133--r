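---
title: "A non-homogeneous four-state model for mammography screening and overdiagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A non-homogeneous four-state model for mammography screening and overdiagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenmsm)
```

## The model

`screenmsm` estimates the natural history of invasive breast cancer from
individual mammography screening histories with a hidden Markov model on
four latent states:

1. free of breast cancer,
2. progressive preclinical screen-detectable phase (PCDP) — asymptomatic
   disease a mammogram can find that will surface clinically,
3. clinical phase (CP) — symptomatic disease that enters the cancer
   register without screening,
4. non-progressive PCDP — screen-detectable disease that never surfaces
   clinically.

The permitted transitions are 1 → 2 (onset rate $\lambda_{12}(t)$ per
woman-year), 2 → 3 (progression rate $\lambda_{23}(t)$, whose reciprocal is
the mean sojourn time of progressive disease), and 1 → 4 (rate
$\lambda_{14}(t) = r\,\lambda_{12}(t)$, with a single dimensionless ratio
$r$ shared across ages). States 3 and 4 are absorbing. Screen detection of
a state-4 case is the model's operational definition of overdiagnosis.

Intensities are piecewise constant on the left-closed age intervals
$[40,50)$, $[50,60)$, $[60,\infty)$; the first cutpoint is the initiation
age $t_0 = 40$ at which every woman is anchored in state 1. Because the
chain is acyclic, the forward Kolmogorov system has a closed-form solution
on each piece (with $a = \lambda_{12}(1+r)$):

$$P_{11} = e^{-a\,\Delta t},\qquad
  P_{14} = \tfrac{r}{1+r}\,(1 - e^{-a\,\Delta t}),\qquad
  P_{22} = e^{-\lambda_{23}\Delta t},$$
$$P_{12} = \lambda_{12}\,
  \frac{e^{-a\,\Delta t} - e^{-\lambda_{23}\Delta t}}{\lambda_{23} - a},$$

and multi-interval probabilities are products of piece solutions split at
the cutpoints (`transition_matrix()`). At the removable singularity
$\lambda_{23} = a$ the analytic limit
$P_{12} = \lambda_{12}\,\Delta t\, e^{-a \Delta t}$ is used inside a
switch-over band $|\lambda_{23} - a| < 10^{-8}$; between $10^{-8}$ and
$10^{-4}$ an `expm1` form guards against cancellation. The test suite pins
the closed forms to a matrix-exponential oracle at $10^{-10}$.

## Observation scheme and likelihood

A woman is observed only through her screening history: invitations,
attended screens with a negative or positive (assessed, then confirmed or
benign) outcome, clinical diagnoses, and censoring. The test has
sensitivity $S$ for both PCDP states; a cancer-free woman is never
*confirmed* as a case because assessment resolves false positives
(recall-with-benign-outcome events are kept for the descriptive tables but
count as negative screens in the likelihood). A false-negative case is
assumed to be detected at the woman's next **attended** screen if it does
not surface clinically before then — the carry-forward simplification that
keeps the likelihood closed-form.

`history_loglik()` implements the resulting forward recursion over a
three-component belief anchored at the last attended screen: mass in state
1, and missed mass in states 2 and 4. A negative screen multiplies the
state-1 mass by $P_{11}$ and routes newly entered preclinical mass through
$(1-S)$; carried missed mass cannot be negative again, so two consecutive
negative screens anchor state 1 at the earlier screen. Terminal factors are
the detection mass ($S$ on fresh preclinical mass, probability one on
carried mass), the clinical onset density
$\lambda_{23}(w)\,P_{12}(v,w)$ (or $\lambda_{23}(w)\,P_{22}(v,w)$ for
carried mass), and the no-clinical-event probability at censoring.
Never-attenders contribute the last two factors anchored at $t_0$; this is
how non-participant cancers inform the fit. Participation is treated as
non-informative.

Two facts about this construction are verified by independent oracles in
the tests: the exhaustive outcome partition for any fixed schedule carries
unit probability (quadrature), and empirical outcome frequencies in
model-faithful simulation match the per-history probabilities.

### Left truncation at entry

Cohorts assembled from screening registers exclude women diagnosed before
their first invitation, and `simulate_cohort()` reproduces that exclusion.
The data are therefore left-truncated at entry, and
`fit_natural_history()` by default conditions each woman's contribution on
the absence of a clinical diagnosis before her entry age (dividing by
$1 - P_{13}(t_0, \text{entry})$). The package took this as a design
decision after quantifying the alternative: fitting the unconditioned
likelihood to a left-truncated 20,000-woman synthetic cohort displaced the
optimum by the entire truncation mass
($n\,\log 1/(1-P_{13})\approx 263$ deviance units), collapsing the
pre-50 progression rate toward zero and dragging the sensitivity estimate
to 0.51 when the truth was 0.88. The unconditioned likelihood remains
available (`condition_entry = FALSE`, and it is the default in the raw
`cohort_loglik()`/`history_loglik()` functions, which compute the plain
model likelihood).

## Estimation

The free parameters of the non-homogeneous model are $\lambda_{12}$ on
$[50,60)$ and $[60,\infty)$, $\lambda_{23}$ on all three intervals, $r$
and $S$ — seven in total. $\lambda_{12}$ on $[40,50)$ is not identifiable
from histories that start at 50 and must be supplied
(`lambda12_fixed`); its default 0.0015/woman-year is a synthetic stand-in
for a registry-derived background incidence and is flagged in the fit
output and the pipeline run log. The homogeneous comparator estimates one
onset and one progression rate across all ages (four free parameters, no
fixed cell), so the likelihood-ratio test has three degrees of freedom.

Optimization runs on a transformed scale — $\log$ for rates and $r$,
logit for $S$ — so the search is unconstrained and multivariate-normal
draws on this scale always yield valid parameters. The objective is the
mean negative log-likelihood per woman, which keeps tolerances meaningful
across cohort sizes. Gradients are central differences with step
$10^{-6}$; BFGS runs first (relative tolerance $10^{-8}$) and Nelder–Mead
polishes whenever BFGS stops early or leaves a non-stationary gradient.
The Karush–Kuhn–Tucker check at the optimum requires the sup-norm of the
mean per-woman score below $10^{-5}$ and all finite-difference Hessian
eigenvalues above $-10^{-6}$. Default starting values are the crude cancer
incidence of the cohort for the onset rates, $\lambda_{23} = 0.4$ (mean
sojourn time 2.5 years), $r = 0.001$ and $S = 0.9$.

Standard errors come from the inverse Hessian of the total negative
log-likelihood on the transformed scale, delta-mapped to the natural
scale; Wald intervals are truncated at zero for the rates and $r$ and
clipped to $[0,1]$ for $S$. A singular Hessian is reported as such —
no silent pseudo-inverse. Whether the original analysis computed its
Hessian on the transformed or natural scale is not documented; the
transformed scale is this package's default because it respects the
parameter domain, and the natural-scale covariance is also stored.

With roughly 3,000 cancer cases (a 50,000-woman cohort) the likelihood
surface has a pronounced ridge linking $S$, $\lambda_{23}$ and $r$:
deviations of two to three standard errors along it are ordinary, and at a
few thousand women $r$ can wander far from small true values. This is a
property of the model's weak identifiability at small case counts, not of
the optimizer; the package flags $r$ estimates at the zero boundary.

## Overdiagnosis

The probability that a screen-detected case at round $k$ (age $t_k$,
previous attended screens at $t_{k-1}, t_{k-2}$) is non-progressive is
$(A_1+A_2)\,/\,((A_1+B_1)+(A_2+B_2))$ with

$$A_1 = P_{11}(t_{k-2},t_{k-1})\,P_{14}(t_{k-1},t_k)\,S, \quad
  B_1 = P_{11}(t_{k-2},t_{k-1})\,P_{12}(t_{k-1},t_k)\,S,$$
$$A_2 = P_{14}(t_{k-2},t_{k-1})\,(1-S), \quad
  B_2 = P_{12}(t_{k-2},t_{k-1})\,P_{22}(t_{k-1},t_k)\,(1-S),$$

state-4 persistence being one. Two reconstructions were required where the
source analysis leaves the first rounds unstated, and both follow from the
belief recursion: at the **prevalent** (first attended) screen there is no
missed carry-over, the belief is anchored in state 1 at $t_0$, and the
sensitivity cancels, giving $P_{14}(t_0,t_1)/(P_{14}(t_0,t_1) +
P_{12}(t_0,t_1))$; at the **second** attended screen $t_0$ stands in for
$t_{k-2}$. Under the carry-forward observation scheme these expressions
are exact, which the tests confirm against ground-truth labels in
model-faithful simulation — the pipeline's central end-to-end oracle.

`expected_overdiagnosis()` evaluates the round-appropriate probability at
each detected woman's own attended-screen ages (irregular gaps use her
actual schedule) and sums by round class; fractions divide by the
screen-detected counts. `overdiagnosis_ci()` draws parameter vectors from
the multivariate normal with the MLE mean and estimated covariance —
on the transformed scale by default, with natural-scale drawing plus
rejection available behind a flag — recomputes the expected counts per
draw, and reports percentile intervals, matching the simulate-and-summarize
description of the source method (1000 draws by default).

## Model-fit diagnostics

`incidence_curves()` compares annual observed detection rates (screen plus
clinical, over at-risk person-years, among women with at least one
attended screen) with their model expectations given each woman's actual
schedule and previously observed screen results. The expectation uses the
same belief recursion as the likelihood, conditioned (renormalized) only
at attended screens so that per-woman expected events telescope exactly to
the likelihood's outcome probabilities — the conservation property the
tests check on a small fixture. Follow-up of clinically detected cases is
extended to two years after the latest scheduled invitation at or before
diagnosis, so the expected curve is not artificially censored by the
events it predicts. The curves are binned by age (annual bins), and the
two reporting bands are ages 50–59 and 60 and above. Fitting an
age-homogeneous parameter set to data generated under the age-varying
truth overestimates cumulative risk before 60 — the directional check the
tests reproduce.

## The synthetic cohort generator

`simulate_cohort()` generates the study conditions the analysis assumes:
biennial invitations from age 50 to 69, per-invitation participation
0.727, benign recall probability 0.02 per attended screen of a cancer-free
woman, follow-up to two years after the last invitation, and latent
trajectories drawn from the four-state model by piecewise-exponential
inversion. The default true parameters are the published-scale estimates
(onset 0.0015/0.00276/0.00381 per woman-year across the three age
intervals, progression 0.385/0.464/0.284, $r = 0.00182$, $S = 0.880$),
which give participation, recall, interval-cancer ratio and incidence
close to a large organised programme. The first invitation age is
jittered uniformly by ±1 year to avoid grid artifacts; set
`entry_jitter = 0` for exact worked examples. Two observation modes
exist: `model_faithful` applies the carry-forward rule exactly as the
likelihood assumes (missed cases are detected with probability one at the
next attended screen), while `natural` makes every screen an independent
Bernoulli($S$) test, allowing the cost of the simplification to be
quantified.

Deliberately not emulated: calendar-time programme rollout (every woman
enters at ~50, so the prevalent-round age mix of a programme that started
with a standing population of 50–69-year-olds cannot be reproduced),
competing mortality, opportunistic screening outside the programme,
sensitivity drift with technology, HRT-era risk trends, and informative
participation. Passing tests on these cohorts therefore demonstrate
internal consistency of estimator and generator under the stated
assumptions, not robustness to the ways real register data violate them.

## Problem sizes and test design

The test suite and the acceptance script choose sizes that make their
statistical assertions sharp but cheap: 50,000 women (the published
analysis drew on 417,710) for parameter recovery, where the sensitivity is
recovered within about ±3 percentage points; one million latent draws for
Monte-Carlo checks of the overdiagnosis formula at the published
estimates (three Monte-Carlo standard errors); 40 replicates of 1,500
women for the null calibration of the likelihood-ratio statistic against
$\chi^2_3$; and 80 replicates of 3,000 women for Wald-interval coverage
of the homogeneous model. At a few hundred cases per replicate the
coverage check is informative for the well-identified transition rates
(close to nominal); the sensitivity interval under-covers there because
of the $S$–$r$ ridge, which is a property of the quadratic approximation
at small case counts, not of the standard-error code. Property tests
fuzz rates over $[0,1]$ and horizons up to 40 years.

## Known limitations

* $\lambda_{12}$ on $[40,50)$ enters as an assumption; if it misstates the
  true preclinical background incidence, the 40–49 sojourn time absorbs
  the error.
* Overdiagnosis from death before clinical surfacing is outside the model
  (no death state), so the reported fraction is a lower bound on all-cause
  overdiagnosis.
* The carry-forward simplification slightly overstates sensitivity when
  reality allows repeated false negatives; the `natural` simulation mode
  exists to measure that bias.
* Wald intervals and the multivariate-normal draw for the overdiagnosis
  interval both lean on the quadratic approximation at the optimum, which
  the ridge described above degrades at small case counts.
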