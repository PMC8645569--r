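---
title: "Methods: design, simulation and score calibration for the One Card Learning test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, simulation and score calibration for the One Card Learning test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocltools)
```

## The task

The One Card Learning (OCL) test is a continuous visual recognition task:
playing cards are shown one at a time and the respondent answers, for every
card, whether it has been seen earlier in the session. Four **target**
cards — one per suit — recur once per presentation cycle; **lures** are
once-shown distractors sharing a numerical rank with a target; **foils**
are once-shown distractors sharing no rank with any target. Because lures
are highly similar to studied targets, rejecting them loads on pattern
separation — the ability to discriminate novel information from very
similar stored information — and the expected accuracy ordering is
lure < foil < target.

Two forms are implemented. The standard 80-trial form presents each target
8 times with 12 lures and 36 foils; the reduced-difficulty 48-trial form
presents each target 6 times with 6 lures and 18 foils. Both keep the
3:1 foil-to-lure ratio, so the similarity structure of the distractor
stream is preserved while overall difficulty drops.

## Schedule generation

`ocl_schedule()` is a pure function of (configuration, seed): one seeded
stream is consumed in a fixed order — targets, lures, foils, then
per-cycle trial orders — so schedules are bit-reproducible.

Several points of the construction are underdetermined by the test's
verbal description; the package resolves them as follows.

* **Target ranks are pairwise distinct.** One card is drawn per suit,
  uniformly over rank; draws with a repeated rank are rejected and
  redrawn. Distinct ranks guarantee the canonical 12-card lure pool
  (3 same-rank cards per target). Rejection sampling does not distort the
  per-suit rank marginal: the acceptance region is invariant under any
  relabelling of ranks applied simultaneously to all suits, so each
  suit's marginal stays uniform (the test suite checks this by
  chi-square over 10,000 draws).
* **Reduced-form lure subset.** The 48-trial form uses 6 of the 12
  same-rank cards, sampled uniformly without replacement and without
  per-target balancing: 6 lures cannot be spread evenly over 4 targets,
  and an unbalanced-but-uniform draw is the least informative choice.
* **Distractor allocation.** Distractors are shuffled globally and dealt
  to cycles under the single constraint of a fixed count per cycle; the
  lure/foil mix per cycle is left random.
* **Target order across cycles.** Requiring a full pass of the other
  three targets between two presentations of the same target is
  incompatible with independently randomized cycle orders (the target
  closing one cycle may open the next). The package enforces the weaker,
  consistent pair of constraints: each target appears exactly once per
  cycle, and the first target of a cycle differs from the last target of
  the previous cycle (redrawn on violation). Together these guarantee
  that consecutive presentations of a target fall in adjacent cycles
  with at least one intervening trial, and that the same card never
  appears on two consecutive trials.
* **Indexing.** Trials and cycles are 1-based everywhere, including CSV
  output.

`validate_schedule()` re-checks every constraint independently of the
generator and reports violations by name; the test suite fuzzes it over
1,000 seeds per form.

## Administration and scoring

Responses follow a forced-correction flow: an incorrect first press
leaves the card in place until the other (correct) button is pressed.
Only first responses are scored — the forced correction guarantees
eventual correctness, so the follow-up press carries no information; it
is retained in the record as `attempts`.

Accuracy is the proportion of correct first responses, reported after the
arcsine-square-root transform `s = asin(sqrt(p))`: chance (p = 0.5) maps
to pi/4, displayed 0.79, and perfect performance to pi/2, displayed 1.57.
Computation keeps full precision; display rounding is half-up to two
decimals (`format_score()`), which reproduces the published score tables
exactly.

**Answer keying.** Two statements about the key conflict in the test's
verbal description: every target trial keyed "yes", versus the first card
of the test always keyed "no" (the first card has, by definition, not
been seen). The package defaults to truthful *novelty keying*: the first
presentation of any card — every lure, every foil, and each target's
first showing — is keyed "no", and target re-presentations "yes". This
reconciles the first-trial rule with an attainable perfect score. The
literal alternative (`target_keying = "always_yes"`) is available; the
choice only affects scores of biased responders, not of a veridical one.

Floor and ceiling effects use the strict 10% rule: flagged only when
*more than* 10% of a sample scores at or beyond the bound.

## The respondent and cohort generator

No generative model of respondents accompanies the published analyses, so
the package supplies the simplest structure that reproduces the reported
group-level statistics: a two-level model in which each subject carries a
latent ability and each trial is an independent Bernoulli draw.

* `simulate_responder()` works at the trial level: per-trial-type
  accuracies (obtained from published transformed means via
  `calibrate_trial_type_probs()`, i.e. `p = sin(mean)^2`), an optional
  learning increment on target accuracy (default 0, since short-interval
  retesting shows no practice effect), and an optional logit-scale
  subject offset.
* `simulate_cohort()` works at the session level: a latent ability per
  subject on the transformed scale, `a_i ~ N(mu, sigma)` clamped to
  [0, pi/2], then `Binomial(n_trials, sin(a_i)^2)` correct responses.
  Because the transform is variance-stabilizing, session noise adds
  nearly constant variance `1/(4 n_trials)` on the transformed scale;
  `(mu, sigma)` are calibrated by a short Monte-Carlo fixed-point
  iteration (20,000 draws per step, fixed internal seed, memoised) so
  that the observed cohort moments match the requested mean and SD. At
  n = 5,000 the achieved moments sit within ±0.005 of their targets.

Session noise imposes a floor of about `sqrt(1/(4 n_trials))` — 0.072
for 48 trials — on the achievable score SD; a target SD below the floor
collapses the latent dispersion to zero and triggers a warning rather
than silently failing.

`simulate_retest()` splits the latent variance into a stable
between-subject component `r * sd^2` and a session-specific remainder, so
that `retest_r` is the target intraclass correlation of the *observed*
scores, with session noise counted as within-subject variance. The
achievable reliability is therefore capped at `1 - v_noise / sd^2`;
requests beyond the cap are clamped with a warning. At a cohort SD of
0.13 (the upper end of what repeated administrations of the 48-trial form
show) a target reliability of 0.6 is comfortably inside the cap, and the
test suite verifies recovery at 200 subjects by 3 sessions.

**What the generator does not emulate.** Real sessions show
within-subject standard deviations (about 0.06) *below* the independent-
trial noise floor, which means real trial outcomes are positively
dependent within a session (attention and strategy fluctuate slower than
trials). The conditionally independent Bernoulli model cannot reproduce
that combination of small within-subject SD, per-timepoint SD near 0.10
and reliability near 0.6 simultaneously; passing simulation tests
therefore validate the package's statistics, not the fine structure of
human data. Fatigue, dropout, malingering and diffusion-style process
models are out of scope.

## The analysis battery

* **Glass's delta** `(mean_control - mean_patient) / sd_control`:
  impairment positive, control-referenced because patient variance is
  compressed near the scale floor. CIs are seeded nonparametric
  bootstraps (10,000 resamples by default) — assumption-light and
  adequate for reporting. Note the sample statistic is slightly
  biased upward in small samples (E[1/S] > 1/sigma; about +3.7% at
  n = 22), which matters when averaging deltas over simulation
  replicates.
* **Cohen's d** pooled-SD (independent) or difference-SD (paired).
* **Intraclass correlation**: one-way random, single measure by default,
  `(F - 1)/(F + k - 1)` with the F-based CI; two-way consistency and
  agreement variants are selectable. The one-way model is the default
  because the published reliability analysis does not name its ICC form
  and its printed degrees of freedom match no standard balanced layout
  for the sample analysed; the discrepancy is documented rather than
  chased. Per-subject SDs across sessions and their mean accompany every
  fit.
* **Profile analysis**: one-sample Hotelling T-squared on the k - 1
  adjacent-session differences, converted to F by
  `T2 (n - k + 1) / ((n - 1)(k - 1))` on (k - 1, n - k + 1) df.
  Identical columns return the degenerate T2 = 0, p = 1 with a flag;
  a singular difference covariance with a non-zero mean is an error.
* **Mixed ANOVA**: Type III tests with sum-to-zero contrasts, built on a
  multivariate linear model fit. Within effects with 3 or more levels get
  Mauchly's test and the Greenhouse-Geisser epsilon; the corrected
  p-value becomes `p_reported` when Mauchly's p < 0.05. The print method
  marks significance at 0.01, the threshold used throughout the published
  analyses to limit type-I error; both thresholds are configurable.
  Interaction decomposition via `group_contrast()` applies the Welch
  degrees-of-freedom approximation when a variance-ratio pre-test flags
  unequal variances.

## Equipercentile equating

Scores are calibrated between forms on a fixed grid from 0.79 to 1.57 at
0.01 steps — the two-decimal display values of pi/4 and pi/2, matching
the resolution at which scores are reported.

1. **Clamping.** Scores below 0.79 are set to 0.79: below-chance scores
   carry no performance information and clamping avoids deleting those
   records. Each score then bins to the nearest grid point (ties up).
2. **Loglinear presmoothing.** A polynomial exponential-family model fit
   by Poisson maximum likelihood (`glm`, convergence tolerance 1e-10);
   the total count and the first `degree` raw moments are the sufficient
   statistics and are preserved exactly. Degree 3 — matching mean,
   variance and skewness — is the default, standard practice in
   observed-score equating; the degree is exposed.
3. **Continuization and inversion.** Percentile ranks use the half-count
   convention; the rank function is continuized piecewise-linearly over
   each grid cell and inverted. When a rank falls exactly on a cumulative
   plateau (a zero-count run) the inverse is set-valued; the midpoint of
   the plateau interval is returned. Results are clipped to the grid
   range and forced non-decreasing (a no-op except for float jitter).
4. **Bootstrap standard errors.** The design is single-group (every
   subject takes both forms), so the bootstrap resamples *subjects* with
   replacement, preserving the dependence between forms, and repeats the
   whole clamp/smooth/equate pipeline per replicate; the SE at each grid
   point is the SD across replicates. Replicates whose degenerate
   resample cannot be smoothed are skipped and counted. The unweighted
   mean SE averages over the grid; the weighted mean SE weights each
   point by the observed source-form relative frequency, discounting the
   sparse extremes where equating error concentrates.

Equating a distribution to itself returns the identity exactly on all 79
grid points; a constant shift between forms is recovered within one grid
step; forward-backward composition deviates from identity by at most one
grid step on well-populated mid-range points. These are the properties
the acceptance suite asserts — the published equating *table* itself
derives from a 401-subject normative sample that is not distributable, so
its specific entries are not reproduction targets.

## Problem sizes and numerical choices

The checks shipped with the package use desk-scale problem sizes chosen
to keep the whole suite comfortably under a few minutes while leaving
Monte-Carlo error well inside the asserted tolerances: 1,000 replicate
case-control studies per form for the sensitivity comparison; 2,000
replicates for the null error-rate checks of the profile analysis and the
mixed-ANOVA interaction (nominal 0.05, asserted within [0.035, 0.065]);
5,000 subjects for cohort-calibration accuracy (±0.005); 1,000 seeds per
form for schedule fuzzing; 10,000 draws for rank-uniformity. Bootstrap
defaults (10,000 for effect-size CIs, 1,000 for equating SEs) follow
common reporting practice and are all configurable.

Degenerate inputs are handled explicitly rather than by numerical
accident: zero control variance, zero paired-difference SD (including
constant shifts that leave only float jitter), identical repeated
sessions, singular difference covariances, empty score distributions, and
unbalanced within-subject designs all raise typed errors or flagged
degenerate results.

## Known limitations

* The respondent model is statistical, not cognitive: it reproduces
  group moments and orderings, not response-time distributions, serial
  dependence, or strategy shifts.
* Equating supports the single-group design only; anchor-test and IRT
  linking are out of scope, as is kernel continuization.
* The mixed ANOVA requires complete, balanced within-subject data;
  missing cells must be handled upstream.
* `n_targets` is fixed at 4 by the one-per-suit constraint of a standard
  deck; generalizations vary cycle counts and distractor mixes instead.
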