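---
title: "Sequential basis functions for multi-agent decisions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential basis functions for multi-agent decisions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialbasis)
library(dplyr)
```

## The task and the model

Four players are observed in sequence, each delivering a performance score
between 0 and 6 (aggregated from six binary cues). Two players — self (S) and
a partner (P) — form the decision-maker's own team; two opponents (O1, O2)
form the other. After the observation phase, two decisions follow: compare
oneself with one opponent (*self* decision), the partner with one opponent
(*partner* decision), or team against team (*group* decision), each sweetened
or handicapped by a non-social bonus with fractional part 0.5, so a correct
response always exists. Engaging pays the signed, bonus-inclusive decision
variable; avoiding pays zero.

Because the presentation order of the players is randomised and fully
counterbalanced, decision-relevant information can be held in a *sequential*
frame: the score vector `pos` indexed by position rather than identity. Every
comparison the task can ask for lives in a three-dimensional subspace of the
four-dimensional sequential score space, spanned by three orthogonal weight
vectors

```{r}
basis_matrix()
```

with the all-ones *null vector* (the total performance) orthogonal to all
three and irrelevant to every decision. Projections `b = W pos` compress the
observation phase into three signed performance differences; the six dyadic
(one-against-one) comparisons are exactly the half-sums and half-differences
of pairs of basis functions, so any decision variable is a linear read-out of
`b`.

For a specific trial, the basis functions sort by relevance: the *primary*
basis function is the one whose sign pattern matches the team partition under
the presentation order (sign fixed so the own team is positive); for a dyadic
decision the *secondary* is the unique other basis function whose signed
combination with the primary isolates the two cued players; the *tertiary* is
the remainder. Re-expressed in the identity frame `[S, P, Or, Oi]` the signed
primary is always `(1, 1, -1, -1)` and the signed secondary
`(1, -1, -1, 1)`; their mean `(1, 0, -1, 0)` is the cued comparison, which is
why averaging the two inverted projections (plus the bonus) yields the
agent-centric decision variable. `sort_relevance()`, `inverted_projections()`
and `agent_centric_dv()` implement this algebra, and the test suite verifies
the full circle exhaustively over all 24 orders and all 7^4 score vectors.

A design note: the overall sign of each basis function is arbitrary, and the
package treats the printed `w1`–`w3` as canonical and immutable, carrying
explicit sign fields in the relevance sorting instead of re-signing the
matrix. Identity ordering for agent-centric vectors is fixed as
`[S, P, Or, Oi]` (`[S, P, O1, O2]` for group decisions). Scores are integers
by contract; projections are returned as doubles so they compose with the
half-integer bonus.

## Schedule generation

`generate_schedule()` reproduces the study designs structurally:

* **study1_fmri** — 144 trials, 288 decisions split 96/96/96 across
  self/partner/group, bonuses from ±0.5/±1.5, each opponent relevant equally
  often within self and within partner decisions, each player first in the
  sequence equally often.
* **study2_group** — 108 trials, 72/72/72, bonuses ±0.5; every dyadic
  decision is *matched* (kept identical in the derived no-group condition).
  `derive_nogroup_from_group()` replaces the 72 group decisions by 36 self +
  36 partner decisions with the same bonuses, giving 108 + 108.
* **study4** — 96 trials (64 training + 32 test), one group and one dyadic
  decision per trial; the dyadic comparison is pinned to sequence positions
  2 and `pre` (3 or 4) during training and 1 and `post` during test.

Orders come from `build_order_sequence()`: complete shuffled blocks of all 24
permutations, remainder uniform, with 1,000 candidate sequences generated and
one selected — mirroring the original scheduling procedure. The trial pairing
of decision types uses equal numbers of self+partner, self+group and
partner+group trials, which satisfies the constraint that the two decisions
of a trial never compare the same player pair and that group decisions never
repeat within a trial, while hitting the printed type counts exactly.

Scores emulate the perceptual pre-experiment as per-player binomial(6, 0.5)
pools, oversampled threefold and re-drawn until the players' pool means agree
within 0.25 points ("approximately similar performance"; both the success
probability and the tolerance are configurable). The generator then
resamples the score-to-trial assignment until the three basis projections
share at most `decorrelation_threshold` (default 0.01) of variance with
every *choice-independent* control variable: the four per-player
performances, the social DV (relevant own minus relevant opponent), the
overall team difference and choice difficulty. Choice difficulty is defined
as the inverse of the absolute bonus-inclusive DV, which is never zero by
design; using the bonus-exclusive social DV would divide by zero on tied
scores. Choice-*dependent* variables (the choice itself, the
chosen-minus-unchosen DV) cannot be known at schedule time; they are
re-checked post hoc on simulated choices by `fig_rsq_matrix()` and in the
acceptance suite, pooled over a cohort of synthetic participants with
individual schedules — pooling is what gives the check resolution well below
the 0.01 bound.

Decision relevance (`decision_relevance()`) scores 0.5 per relevant player in
dyadic decisions and 0.25 each in group decisions, normalised by the number
of decisions so the per-player scores sum to one (an even design gives 0.25
per player); per-trial normalisation is available as an option.

## Choice simulation

`simulate_choices()` draws engage/avoid choices from a logistic model on the
inverted primary projection, the inverted secondary projection and the bonus.
Two regimes matter: *balanced* (1.5/1.5/1.5), the ideal-observer weighting
that recovers the agent-centric DV, and *overweighting* (1.7/1.3/1.5), the
behavioural footprint of the primary function's earlier onset. Predictors are
standardised within decision type across the schedule before the weights
apply; the simulator's weights then land on the same scale as the fitted
standardised regression weights (a raw-scale mode exists for analytic
checks). Group decisions, which have no secondary basis function, are
simulated from the primary projection and bonus alone; the default restricts
simulation to self decisions, matching the original simulation analyses.
Each synthetic participant (default 56, the fMRI sample size) has an own
seeded RNG stream with 200 replicates by default.

The signature consequence, reproduced in the acceptance suite: under
overweighting, an agent-centric logistic GLM on self decisions shows a
*positive* effect of the irrelevant teammate and a *negative* effect of the
irrelevant opponent; under the balanced regime both vanish. The effect works
through group membership: the primary projection carries `+P` and `-Oi`
terms that the secondary no longer fully cancels once the weights differ.

## Decision-weight estimation

`agent_centric_glm()` fits, per participant, engage/avoid against the five
standardised regressors S, P, Or, Oi and bonus. The ridge path is an
in-package penalised IRLS (intercept unpenalised, penalty `n * lambda / 2 *
sum(beta^2)`, matching the per-observation convention of elastic-net
software so one grid serves datasets of different sizes); `lambda = 0` is the
maximum-likelihood fit, with complete separation flagged rather than
silently returned. `select_lambda()` implements the shared-penalty
procedure: a log-spaced grid (default 25 points in 1e-3..1e-1; 1e-3..1 for
the small test-phase datasets), three-fold cross-validation repeated twice,
held-out deviance summed over folds, repeats and *all* participants, and a
single winning lambda used for everyone, keeping betas comparable across
participants and conditions.

`sequential_position_glm()` is the sequence-contingency analysis: dyadic
choices on the standardised scores of positions 1–4 plus bonus, with
opponent scores recoded `x -> 6 - x` (the range is symmetric around 3) so
that all predictors point in the engage direction. `accuracy_rt_summary()`
computes percent-correct against the sign of the bonus-inclusive DV and
median RT by decision type and index, with a matched-decision filter for
group/no-group comparisons. `compare_model_accuracy()` cross-validates the
three-regressor basis-function model against the five-regressor
agent-centric model on identical folds and reports per-participant accuracy
and log-loss differences; cross-validated log-loss is the package's concrete
choice for an information-theoretic model-accuracy metric.

## The time-varying drift-diffusion model

The tDDM (`simulate_tddm()`, `fit_tddm()`) has exactly seven free
parameters: drift weights for the inverted primary projection, the inverted
secondary projection and the bonus; the onset asynchrony of the secondary
attribute relative to the primary (negative values mean the secondary enters
first — the bonus always enters at the earlier onset); threshold; starting
bias; and non-decision time. Evidence accumulates by Euler–Maruyama steps
(default `dt` 1 ms, compiled) with the diffusion noise fixed at 0.1 per
root-second — a fixed scale is required for identifiability, and all default
bounds live on that conventional scale (drift weights and thresholds of
order 0.1–0.5). Walks alive at the maximal duration (default 10 s) are
truncated, classified by the nearer boundary and flagged.

The likelihood is simulation-based: for each unique (primary, secondary,
bonus) combination in the data — repeated combinations share one simulation —
the forward model generates the joint choice-by-RT distribution, discretised
into 50-ms bins per choice with add-one smoothing so observed cells are
never impossible. Simulation seeds are derived per combination, making the
surface deterministic given the seed; `fit_tddm()` exploits this by freezing
the random numbers across evaluations of its best/1/bin differential
evolution optimiser (population 10 per free parameter by default, 150
iterations, all configurable). `asynchrony_test()` compares the full model
with a refit constrained to zero asynchrony via `2 * (LL_full - LL_0)`
against chi-squared(1), re-evaluating both parameter sets on a common
simulation seed when data are supplied so the two likelihoods share their
Monte-Carlo noise.

Problem sizes: the parameter-recovery study in the acceptance suite uses 20
synthetic subjects, 16 attribute combinations times 15 repeats (240 trials),
350 simulations per combination, a 5-ms fitting step and 50 optimiser
iterations with population 18 — deliberately smaller than the reference
settings of 3,000 simulations and 150 iterations, chosen as the smallest
design at which the true-versus-recovered asynchrony correlation is reliably
above 0.7. Coarser histograms (0.1-s bins, 4-s cap) accompany the reduced
simulation counts: with few simulations spread over many 50-ms bins, add-one
smoothing would otherwise dominate the distribution estimate.

## fMRI designs and the ROI pipeline

`design_manifest()` is the machine-readable inventory — names, lock events,
durations, constant versus parametric — of the three whole-brain designs and
the two ROI time-course designs; `build_design()` constructs the event
tables against it and the match is test-asserted. GLM1 models each player
RDK as a 2-s constant with a parametric performance score, plus six
decision constants (type by decision index) each carrying its parametric
set. GLM2 time-locks 0.1-s sticks 2 s after the observation offset for the
basis projections and player performances, adds S/P sequence positions at
the offset itself, and models decisions with DV, DV-by-choice, choice,
irrelevant-player DV and its choice interaction. GLM3 carries the
relevance-sorted projections (primary/secondary/tertiary), their inverted
versions, choice interactions, the bonus terms, and a binary indicator for
whether the secondary basis function required sign inversion — the printed
regressor list is ambiguous on that entry, and the binary-flag reading is a
documented reconstruction. Interactions standardise both components and
multiply; every parametric regressor is then standardised to mean 0, sd 1,
and the test suite asserts both to within 1e-12.

Timing uses the task's jitter structure (clipped Poisson: 1–5 s mean 2
between observation and first decision, 2–8 s mean 3.5 between decisions,
1–5 s mean 2 intertrial), a 2.1-s observation event per player and 2-s
modelled decisions. Convolution uses the canonical double-gamma HRF (peak
6 s, undershoot 16 s, ratio 6, 32-s kernel, configurable) on a 0.1-s grid
sampled at TR = 1.2 s, with optional temporal derivatives. `simulate_bold()`
adds Gaussian noise with optional AR(1) (default rho 0.3); since the
synthetic noise is known, estimation uses ordinary least squares — no
pre-whitening stage is emulated. Per-session normalisation is z-scoring.

`roi_timecourse_glm()` z-scores the series, oversamples tenfold by cubic
spline, epochs trials around the observation offset and fits a GLM per time
point, giving one beta time course per regressor. `loo_peak_test()`
implements the leave-one-out read-out: each subject's beta is taken at the
peak latency (maximal absolute deviation from zero, window 4–10 s by
default, 0–6 s for fast position effects) of the *other* subjects' mean
time course, then tested against zero.

One property of this procedure deserves emphasis. The leave-one-out step
makes each individual read-out unbiased — the subject's value is read at a
latency chosen without that subject's data, so its expectation under the
null is exactly zero, and the test suite confirms this. But all subjects are
read at essentially the same selection-driven latency, so under the null
their values share the sign of the group-level extremum; the between-subject
t-test therefore rejects more often than its nominal level, and the more
effective independent peaks the analysis window contains, the stronger the
inflation (the acceptance suite measures this on synthetic null cohorts).
The package implements the procedure as specified and reports this
anticonservatism as a known limitation rather than re-calibrating it;
injected-effect recovery, sign and latency localisation are unaffected.

## What the synthetic data do and do not show

The generator reproduces the *structure* of the study designs — counts,
balance, decorrelation, bonuses, position contingencies — and the generative
models produce choices, reaction times and BOLD with known ground truth. It
does not emulate learning or fatigue across trials, individual differences
beyond independent RNG streams, veridical perceptual performance
distributions (scores are binomial by choice, not empirical), or any
physiological BOLD property beyond HRF-convolved linear effects with AR(1)
noise. Passing tests therefore validate the algebra, the estimators and the
pipelines, not claims about real participants; the printed real-sample
statistics are out of scope throughout.
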