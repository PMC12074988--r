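# socialbasis

Tools for studying how people make decisions about groups of interacting
agents using **sequential basis functions**. In the task family this package
models, four players — self (S) and partner (P) versus two opponents (O1,
O2) — show performance scores (0–6) in a randomised order, and the
decision-maker then compares either two individuals or the two teams,
factoring in a half-integer bonus B. Engaging pays the signed decision
variable; avoiding pays zero.

All decision-relevant comparisons live in a 3-dimensional subspace of the
4-dimensional sequential score space, spanned by three orthogonal weight
vectors over sequence positions,

```
w1 = [-1,  1, -1,  1]
w2 = [ 1,  1, -1, -1]      b = W pos
w3 = [ 1, -1, -1,  1]
```

with the all-ones null axis (total performance) task-irrelevant. Every
dyadic comparison is a signed half-sum of two basis functions, e.g.
`w6 = [0, 1, -1, 0] = (w1 + w2)/2`. Per trial, the basis functions sort by
relevance — the *primary* matches the team partition under the presentation
order, the *secondary* completes the cued dyadic comparison — and invert to
the agent-centric frame `[S, P, Or, Oi]`, where primary is always
`[1, 1, -1, -1]`, secondary `[1, -1, -1, 1]`, and their mean plus bonus is
the decision variable (`DV_self = S - Or + B`, etc.).

The package implements, end to end on synthetic data:

- the basis-function algebra (`basis_matrix()`, `project()`,
  `sort_relevance()`, `inverted_projections()`, `agent_centric_dv()`);
- counterbalanced, decorrelated schedule generation for the fMRI design
  (144 trials), the group/no-group behavioural design (108 trials, matched
  decisions) and the sequence-contingency design (96 trials, pre/post
  position rules) — `generate_schedule()`, `validate_schedule()`,
  `decision_relevance()`;
- logistic choice simulation under balanced (1.5/1.5/1.5) and
  primary-overweighting (1.7/1.3/1.5) regimes — `simulate_choices()`;
- per-participant ridge logistic decision-weight GLMs with a shared
  cross-validated penalty — `agent_centric_glm()`, `select_lambda()`,
  `sequential_position_glm()`, `compare_model_accuracy()`;
- a time-varying drift-diffusion model with attribute onset asynchrony,
  simulation-based likelihood and differential-evolution fitting —
  `simulate_tddm()`, `fit_tddm()`, `asynchrony_test()`;
- fMRI design-matrix construction (GLM1–GLM3, ROI designs), synthetic BOLD
  and the ROI time-course GLM with the leave-one-out peak test —
  `build_design()`, `convolve_hrf()`, `simulate_bold()`,
  `roi_timecourse_glm()`, `loo_peak_test()`.

Fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(socialbasis)
library(dplyr)

sched <- generate_schedule("study1_fmri", seed = 1)
sched
#> <bf_schedule> variant: study1_fmri  seed: 1  trials: 144  decisions: 288

validate_schedule(sched)
#> <bf_balance_report> study1_fmri - 144 trials, 288 decisions
#> decision types: self=96 partner=96 group=96
#> max r^2: 0.00967

decision_relevance(sched)
#> # A tibble: 4 × 2
#>   player relevance
#>   <chr>      <dbl>
#> 1 S           0.25
#> 2 P           0.25
#> 3 O1          0.25
#> 4 O2          0.25

ch <- simulate_choices(sched, choice_regime("overweighting"),
                       n_participants = 8, n_sims = 50, seed = 2)
glance(agent_centric_glm(ch, "self"))
#> # A tibble: 5 × 6
#>   term    mean      se statistic  p.value     n
#>   <chr>  <dbl>   <dbl>     <dbl>    <dbl> <int>
#> 1 Oi    -0.241 0.0128      -18.8 2.97e- 7     8
#> 2 Or    -1.58  0.0151     -105.  1.94e-12     8
#> 3 P      0.194 0.00981      19.8 2.11e- 7     8
#> 4 S      1.39  0.0159       87.3 6.79e-12     8
#> 5 bonus  1.50  0.0268       56.1 1.51e-10     8
```

The mean decision weights show the basis-function signature: large correct
effects of the relevant players (S positive, Or negative) and the bonus,
plus the small but reliable *irrelevant-player* effects — positive for the
irrelevant teammate P, negative for the irrelevant opponent Oi — that
primary-over-secondary overweighting predicts. Under
`choice_regime("balanced")` those two effects vanish.

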