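---
title: "Constructing and aggregating personal utility functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and aggregating personal utility functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufval)
```

## The valuation problem

A value set assigns a utility to every health state an instrument can
describe, on a scale with full health at 1 and dead at 0, so that time spent
in a state can be weighted into quality-adjusted life years. `pufval` works
with a simplified EQ-5D descriptive system: five dimensions (mobility,
self-care, usual activities, pain/discomfort, anxiety/depression) at three
levels each (no / moderate / extreme problems), giving 243 states coded as
five-digit strings such as `"21312"`.

The personal-utility-function (PUF) approach builds each respondent's
*complete* utility function from direct importance judgements rather than
inferring it from valuations of a state subset:

* **Section B** ranks the five dimensions (ties allowed).
* **Section C** swing-rates each dimension's extreme-to-none improvement on
  0–100, with the most valued improvement rated 100.
* **Section D** allocates 100 points between the extreme-to-moderate and the
  moderate-to-none improvement of each dimension.
* **Sections E–G** are adaptive choice tasks generated from the respondent's
  own answers: two validation pairs, a five-task search for the location of
  dead, and two interaction probes.

## The utility model and its assumptions

Ratings are normalised proportionally, `w_d = r_d / sum(r)`, so the weights
sum to 1 regardless of whether exactly one dimension was rated 100 (in
practice some respondents rate none or several at 100; proportional
normalisation treats all of these uniformly because only *relative* weights
enter the model). State utility is additive in per-dimension decrements:

$$u(s) = 1 - \sum_d \delta_{d, l_d(s)}, \qquad
  \delta_{d,1} = 0,\; \delta_{d,3} = w_d,\; 0 \le \delta_{d,2} \le \delta_{d,3}.$$

Because the level-3 decrements sum to 1, `u("33333") = 0` before anchoring.
Additivity is an explicit modelling assumption; the section G tasks exist to
*detect* interactions, but their responses do not enter the utility function
(`tally_interactions()` only tabulates them).

### The level-2 mapping: an open convention made explicit

Section D's instruction makes larger point allocations to the intermediate
(extreme→moderate) improvement mean that improvement is *better*. Two
readings of how the points scale the level-2 decrement are defensible:

* `share_of_swing` (default): $\delta_{d,2} = w_d \, p_d / 100$ — the points
  measure how much of the dimension's full swing is recovered by escaping
  extreme problems, i.e. how bad *remaining at level 2* is relative to
  level 3.
* `remaining_badness`: $\delta_{d,2} = w_d (1 - p_d / 100)$ — the
  literal-instruction reading, under which a large allocation to the
  intermediate improvement implies level 2 is *mild*.

The two coincide at `p = 50`. We default to `share_of_swing` because in the
published pilot tables the ratio of mean level-2 to mean level-3 decrements
(e.g. mobility 0.1133/0.2061 ≈ 0.55) tracks the mean section-D allocation
(mobility 55.2/100) on **all five** dimensions, which is what the
`share_of_swing` algebra predicts. Both conventions are implemented
(`level_decrements(..., level2_mapping = )`) and the choice is recorded in
study metadata; we document rather than silently resolve the ambiguity.

### Ranking and ties

`rank_states()` sorts the 243 states by utility, breaking exact ties by
ascending lexicographic state code. The tie-break is our convention — any
deterministic rule works, but one is needed because coarse inputs (e.g. all
allocations 50) produce many exact ties. Two tie-aware rank statistics for
section B are provided: `ranks_avg()` (tied dimensions share the mean of the
occupied positions; ranks always sum to 15) and `ranks_eq()` (tied
dimensions share the group's starting position, later positions skipped).

## Adaptive tasks

**Validation pairs (section E).** Pair 1 aims at a large utility disparity:
starting targets at ranks ⌈0.25·243⌉ = 61 and ⌈0.75·243⌉ = 183, pushed
outward one rank at a time to the first pair where neither state dominates
the other. Pair 2 aims at a minimal disparity: the non-dominating
adjacent-rank pair with the smallest utility gap, nearest the median rank.
These selection targets are our design choice (made for determinism and to
reproduce the intended easy/hard contrast); the pilot tool's exact rule is
unpublished. One known consequence: with pilot-calibrated preference
heterogeneity the easy pair's level-sum-score gap averages about 2.3 units,
a weaker severity contrast than the pilot reported for its own tool.

**Search for dead (section F).** Each task offers 10 years in a state
versus dying now; the 10-year duration is carried as metadata only and never
enters the arithmetic. The first state is always `"33333"` (rank 243); a
respondent preferring it to death is classified `below_33333` and the search
stops (no PUF can currently be anchored for them). Otherwise five tasks run,
each presenting the **round-half-up midpoint** of the current rank bounds,
with rank 1 as the implicit better bound until a state is preferred to
death. Round-half-up is calibrated against two fixed points of the protocol:
the first midpoint must be 122, and the sequence B,A,A,A,A must terminate at
the bracket (228, 243); floor rounding fails the second (it yields 227).
Every completed search brackets dead within 15–16 ranks — we report the
*rank difference*, one of two defensible readings of "a range of 15 to 16
states". All-B respondents are classified `above_mildest`, with dead assumed
between full health and the mildest presented state.

**Interaction tasks (section G).** Both options of each task improve the
same dimension by one level, differing only in whether a second dimension
sits at level 2. The most/least important dimensions come from the section B
AVG ranks, ties broken by the higher (respectively lower) section C rating,
then by the fixed dimension order — first position for "most", last for
"least", so they always differ. The protocol specifies only "as indicated in
section B"; the tie rule is ours.

## Anchoring, outliers and aggregation

`dead_utility()` is the midpoint of the bracketing states' utilities (or of
1 and the mildest presented state's utility for `above_mildest`);
`anchor_puf()` rescales by $v(s) = (u(s) - u_{dead})/(1 - u_{dead})$, which
is order-preserving and equivalent to dividing every decrement by
$1 - u_{dead}$.

Two aggregation conventions deserve scrutiny because they are normative:

* **Respondents with dead below `"33333"`** (about a quarter of pilot
  respondents) cannot be rescaled. By default they enter the aggregation
  with their unrescaled 0–1 values — equivalent to conservatively anchoring
  dead at `"33333"` — with `include_unrescaled = FALSE` to drop them
  instead. How the pilot handled them is not stated; the default is flagged
  here as an assumption.
* **Outliers.** Anchoring divides by $1 - u_{dead}$, so a respondent who
  locates dead very near full health produces explosive negative values
  (a dead utility of 31/32 sends `"33333"` to −31). The pilot excluded one
  such respondent judgementally; `filter_outliers()` makes the rule explicit
  and reproducible as a threshold on the anchored value of `"33333"`,
  default −10. The default is deliberately far from the values ordinary
  respondents produce (the pilot's value-set minimum is −0.667) while
  catching the pathological regime.

`summarize_decrements()` reports min, quartiles, mean, max, sd (n−1
denominator) and se = sd/√n per dimension-level; quartiles interpolate
linearly between order statistics (`quantile(type = 7)`, the spreadsheet
convention, chosen so summary tables are bit-reproducible from raw data).
The embedded pilot tables (`pilot_table()`) reproduce the published numbers
verbatim; note their printed level-2 standard errors are internally
inconsistent with the stated n = 60 (they imply n ≈ 30), which cannot be
resolved from the publication — the package's own summaries always compute
se = sd/√n. `value_set()` then values every state as 1 minus the sum of the
chosen central (mean or median) decrements, so the value set inherits
monotonicity in dominance.

## The respondent simulator

`simulate_cohort()` generates synthetic respondents with known latent
preferences so the whole pipeline can be tested end to end. Defaults encode
the study conditions the generator is meant to emulate:

| parameter | default | rationale |
|---|---|---|
| `n_respondents` | 76 | pilot sample size |
| `weight_concentration` | 20 | symmetric Dirichlet; gives level-3 decrement dispersion (sd ≈ 0.04) matching the pilot tables |
| `level2_shape` | 1.1 | symmetric Beta: fractions centred at 0.5 with sd ≈ 0.28, matching the pilot's allocation dispersion |
| `p_nothing_worse_than_dead` | 0.24 | the pilot's ~quarter of never-switch respondents |
| `dead_shape1`, `dead_shape2` | 2, 6 | Beta(2,6) dead utility: most respondents place dead among severe states |
| `choice_noise_scale` | 0.05 | logistic noise on utility differences; 0 = deterministic |
| `rating_grid` | 5 | round-number bias: ratings snapped to multiples of 5 (1 = integers; 0 = no rounding) |

All randomness flows from one master seed through per-respondent counter
streams, so enlarging a cohort never perturbs earlier respondents. Sections
B–D restate the latent weights and fractions (after grid rounding); sections
E–G are answered by comparing *latent* utilities under logistic noise, while
the tasks themselves are generated from the *elicited* (rounded) responses,
exactly as the interview tool would. With zero noise and no rounding the
pipeline recovers weights and level-2 fractions to numerical precision, and
recovered dead brackets straddle the latent dead utility; `recovery_report()`
quantifies bias and RMSE under any configuration.

What the simulator does **not** emulate: interaction effects (its latent
utilities are additive, so noise-free section G answers are ties, unlike the
pilot's respondents, most of whom preferred option A), anchoring and framing
effects, interviewer effects, and within-interview preference change.
Passing recovery tests therefore shows the *pipeline arithmetic* is
faithful, not that the elicitation would recover real people's preferences.

## Degenerate inputs and numerical notes

* All swing ratings zero: weights are undefined; constructors refuse the
  record and `validate_record()` flags it as an error.
* A zero rating zeroes the dimension's decrements (it drops out of the PUF).
* `p = 0` or `p = 100` allocations are legal and make one of the two level
  transitions worthless — both occurred in practice.
* Weight sums are checked to 1e-9; utility comparisons in tests use 1e-12
  slack for float noise.
* `bisection_next()` errors when no rank lies strictly between the bounds;
  with 243 states and five tasks this cannot arise in protocol use.

## Problem sizes

The test suite runs cohorts of 20–60 respondents (one 400-respondent cohort
for the classification-rate convergence check) and parameter-recovery runs
at n = 50; the acceptance script fits one simulated respondent and replays
all 32 choice sequences. Everything completes in well under a minute on a
single CPU.

## Known limitations

* No interaction terms in the utility function; section G data are tabulated
  only.
* Respondents who place dead below `"33333"` cannot be anchored; their
  treatment in aggregation is a documented convention, not an estimate.
* The exact section E selection rule and the bisection rounding convention
  of the original interview tool are unpublished; ours are calibrated to the
  protocol's published fixed points and documented as assumptions.
* The value set is a mean (or median) of PUFs; treating personal utilities
  as interpersonally comparable is assumed, and the choice of averaging
  statistic is normative.
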