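---
title: "Goal-framed voting: models, design and simulation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal-framed voting: models, design and simulation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voteframe)
```

## The scientific problem

Election and poll outcomes only reflect the preferences of people who
express one. Two classic accounts of why voters opt out are
*indifference* (the candidates are equally liked, so the withheld vote is
uninformative) and *alienation* (both candidates are disliked, even though
one is disliked less — so the withheld vote hides a real preference). A
goal-congruency account adds a third ingredient: the standard voting goal
is to *select* the better candidate, and selecting among bad options is
goal-incongruent and therefore avoided. If the same decision is framed as
*rejecting* the worse candidate, bad option sets become goal-congruent and
the alienation-driven opt-outs should largely disappear.

`voteframe` implements the computational chain needed to study this
account end to end: personalized candidate desirability, a constrained
ballot design, logistic-model voting agents under either frame,
fixed-effects inference with parameter recovery, deterministic election
scenarios, and the two-proportion test used for framed polls.

## The desirability model

A participant rates 13 political issues on two continuous sliders, stance
and importance, both on $[-3, 3]$. A hypothetical candidate holds stances
on exactly two issues. The candidate's desirability for that participant
is

$$D = \frac{10}{12}\sum_{k=1}^{2} w_k\left[1 -
\frac{|s^{cand}_k - s^{part}_k|}{6}\right], \qquad w_k =
\text{importance}_k + 3 \in [0, 6],$$

an importance-weighted sum of issue alignments scaled to $[0, 10]$: the
maximum 10 requires both issues maximally important and perfectly
aligned; 0 arises when both weights vanish or both alignments are zero.
Sliders are treated as continuous reals; no integer snapping is imposed.

Ballot-level descriptors follow: **overall** desirability is the mean of
the two candidates' scores (how good the option set is), **relative**
desirability their difference (how strong the preference is), signed
(left minus right) for side-choice models and unsigned for opt-out and
decision-time models.

## Ballot design

For each participant the 13 issues are ranked by importance (ties broken
by ascending issue id — the original procedure does not specify a
tie-break, and continuous sliders make ties measure-zero anyway). The top
8 issues enter the main task, issues 9–12 the practice ballots, and the
least important issue is dropped. All $\binom{8}{2} = 28$ issue pairs
crossed with $3\times3$ nominal stance levels (left/neutral/right,
base stances $-3/0/+3$) give 252 candidates. Stance noise is zero-mean
Gaussian with default SD 0.3, clipped to $[-3, 3]$; the original
description says only "with random noise", so the law and magnitude are
package choices, and `noise_sd = 0` recovers exact level stances.

Each of 50 design iterations produces two ballots. A target point in
(overall, unsigned relative) desirability space is drawn uniformly over
the region realizable from the table — operationalized as the convex hull
of the descriptors of all admissible candidate pairs, sampled by
rejection from the bounding box. The admissible pair closest to the
target in Euclidean distance is selected (ties broken lexicographically
by candidate id), under the constraint that the four issues within a
ballot are distinct and, for the second ballot of an iteration, disjoint
from the first ballot's four. Every iteration therefore uses all 8 issues
exactly once, and every issue occurs exactly 50 times per 100-ballot set.
Side assignment is counterbalanced so the more desirable candidate is on
the left on exactly 50 ballots, candidate colors are counterbalanced
50/50, and presentation order is shuffled. All of this is reproducible
from a single seed, down to byte-identical CSV exports.

The original generative law for the targets is unstated; uniform-over-
feasible-region is this package's choice and makes the design-space
coverage maximally even. Infeasible matches trigger fresh target draws
with a 100-resample budget (in practice the second slot always has 243
admissible pairs, so the budget is never approached).

## The voting agents

Agents are fixed-effects logistic models on within-participant
standardized predictors (mean 0, SD 1 per participant, matching the
analysis pipeline):

* **Opt-out**: $\text{logit}\, P(\text{no vote}) = \beta_0 +
  \beta_{ov}\,\text{overall} + \beta_{rel}\,|\text{relative}| +
  \beta_{t}\,\text{order}$.
* **Choice**: $\text{logit}\, P(\text{left chosen}) = \gamma_0 +
  \gamma_{rel}\,\text{relative}_{signed} + \gamma_{ov}\,\text{overall} +
  \gamma_t\,\text{order}$ (under rejection, "choosing" a candidate means
  voting against them).
* **Decision time**: linear on the $\log_{10}$-seconds scale with
  unsigned relative and overall desirability, Gaussian noise (default SD
  0.15).

The documented defaults encode the fixed-effect estimates of the lab
studies: selection opt-out $\beta_{ov} = -2.72$, $\beta_{rel} = -0.92$;
rejection opt-out $\beta_{ov} = +0.71$ (the modest reversal between two
good candidates); selection choice $\gamma_{rel} = +2.75$; rejection
choice $\gamma_{rel} = -1.67$; RT slopes $-0.04/-0.04$ (selection) and
$-0.02/+0.02$ (rejection), encoding the goal-congruency reversal in
speed. Intercepts are set so that marginal opt-out rates approximate the
observed 40.3% (selection) and 33.3% (rejection) via `qlogis`;
trial-order coefficients default to 0 (they are controls). On the
$\pm1$ condition coding the implied goal-by-overall-desirability
interaction is $(0.71 - (-2.72))/2 = 1.715$.

Two task designs are provided and distributionally identical by
construction: a two-stage design (opt-out Bernoulli, then side Bernoulli)
and a trinary design (one categorical draw with the composed masses).
Each trial is independently deadline-censored with default probability
0.001, emulating the rare implicit per-trial deadline; censored trials
count as not abstaining in opt-out analyses and are dropped from choice
and RT analyses. `heterogeneity()` adds Gaussian between-agent variation
around the population coefficients (diagonal covariance; zero SD
reproduces homogeneous agents exactly).

### What the generator does and does not emulate

The generator reproduces the statistical structure the analyses assume:
personalized desirability distributions shaped by the real design
algorithm, logistic dependence of opt-out and choice on the descriptors,
and the frame-dependent sign structure. It does **not** emulate random
participant effects with the original covariance (unprinted), real issue
semantics, sequential/history effects, or the evidence-accumulation
dynamics underlying decision times. Passing recovery tests therefore
show that the fitting pipeline is unbiased for data of the assumed
structure at the study's size — not that the original point estimates
would be re-obtained from new human data; the published quartile opt-out
rates (82.8% etc.) depend on participant random effects and are
deliberately not targets, only their orderings and signs are.

## Inference pipeline

`apply_exclusions()` implements the two participation rules: participants
who never opt out, and participants whose goal-inconsistent share of
voted ballots is $\geq 50\%$ (selection: chose the strictly less
desirable candidate; rejection: rejected the strictly more desirable
one), are dropped with a logged reason. The rules are idempotent.
`standardize_within_participant()` recenters and rescales all predictors
per participant. Fits are fixed-effects logistic (IRLS) and OLS models
with Wald standard errors and $\pm1.96\,SE$ confidence intervals —
matching the reporting style of the lab analyses, whose mixed-effects
structure is reduced to fixed effects here, the same reduction the
election simulator uses. Quasi-separation is flagged via `converged`.
The full mixed-model route can be delegated to `lme4` on the exported
trial CSVs without touching this package's surface.

`recovery_experiment()` simulates, excludes, standardizes and fits
repeatedly. Designs (profiles and ballot sets) are generated once per
experiment from the base seed and held fixed across replicates —
recovery conditional on the design, as in a repeated study with the same
trial lists — while behavior is redrawn every replicate; this keeps a
44-participant, 100-ballot, 50-replicate experiment under half a minute
without changing the estimand. With homogeneous agents at that size,
all generating coefficients are recovered with $|bias| < 0.1$ and CI
coverage at the nominal level.

## Elections

The voting agent is evaluated on a $9\times9$ grid of (blue, red)
candidate desirabilities from 1 to 9. Because grid desirabilities are
given directly, predictors are standardized with fixed reference moments
computed from the design generator's own population (20 profiles, fixed
seed, means and SDs averaged across participants), and trial order is
set to 1. Voter groups off the grid are handled by direct model
evaluation — the logistic agent is defined everywhere; the grid is a
reporting surface.

Elections are deterministic expectations: blue votes accrue as
$count \times P(\text{not opt out}) \times P(\text{vote blue})$, where
under rejection framing $P(\text{vote blue})$ is the probability of
rejecting the red candidate; abstentions are $count \times P(\text{opt
out})$. Votes conserve the electorate to $10^{-9}$. The standard
scenarios cross two archetypes — Blue Voters rating the candidates
(blue 4, red 1), Red Voters (blue 3, red 6): equal 3-point margins,
unequal overall liking — with mixes (500, 9500), (3500, 6500),
(6500, 3500), (9500, 500) of 10,000 voters, each also in a full-turnout
variant with the opt-out pathway disabled. Under selection framing the
alienated Blue-majority electorate at (6500, 3500) is carried by Red;
under rejection framing the majority archetype wins every mix, and full
turnout always follows the majority. These are qualitative claims: the
authors' numeric standardization constants are unpublished, so bar
heights are not numeric targets.

## Polls

`reconstruct_counts()` inverts printed percentages to counts
(round-half-up, warning when the back-computed percentage moves by more
than 0.05 points). `two_proportion_z()` is the pooled two-proportion z
test; with the continuity correction the squared statistic equals the
Yates chi-square of the 2×2 table. The correction is **on by default**:
the published reports do not state it, but only the corrected statistic
reproduces both printed chi-squares (20.3 and 10.6) from the
reconstructed counts — the package documents this match empirically
rather than asserting intent. `poll_framing_test()` wires the printed
group sizes and undecided percentages of the two framed pre-election
surveys through this chain with the preregistered one-sided alternative.

```{r polls}
poll_framing_test(3)
poll_framing_test(4)
```

## Numerical and design choices

* Issue-ranking ties: ascending issue id. Pair-matching ties:
  lexicographic candidate id (pairs are enumerated in id order, so the
  first minimizer wins).
* Convex-hull membership uses `mgcv::in.out`; degenerate single-point
  regions are returned directly.
* Logistic fits: IRLS with relative-deviance tolerance $10^{-10}$, 100
  iterations max; separation flagged, rank deficiency an error.
* Quartile binning is rank-based within participant by default (100
  ballots give exactly 25 per quartile); pooled binning is available by
  flag since the original figure's binning is unstated.
* A single pipeline seed is expanded into per-stage child seeds (32-bit
  safe), so stages are independently reproducible.
* Problem sizes in the test suite mirror the study (44 and 47 agents,
  100 ballots, 50 replicates); the election reference population uses 20
  profiles, enough to stabilize the moments to the second decimal.

## Limitations

Only fixed-effects inference is built in; random-effect covariances are
not estimated. The decision-time model is descriptive, not a process
model. The election simulator propagates expectations, not sampling
variability (a seeded multinomial mode could be layered on top). Survey
weighting and demographic adjustment are out of scope.
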