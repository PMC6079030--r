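# vsprl

Trial-by-trial analysis of self-protective social evaluation across
development: reinforcement learning of the **value of self-protection
(VSP)**, logistic feedback-influence models, and brain–age–behavior
mediation — exercised end to end on synthetic cohorts.

## The scientific problem

In reciprocal social-evaluation tasks, people who have just been judged
("your artwork is not creative") turn around and judge their evaluator.
How strongly that counter-evaluation is driven by the *current* piece of
feedback versus feedback *accumulated* over the whole interaction changes
from late childhood to early adulthood: younger participants react to the
most recent evaluation, older ones integrate the history. `vsprl`
implements the full analysis pipeline for such a task — a fixed 75-trial
design crossing 3 feedback valences (positive / neutral / negative) with 5
objective-creativity (OC) levels — together with a synthetic-cohort
generator, so every stage is testable without participant data.

## The models

**Feedback-influence model.** Each participant's binary partner-evaluation
decision (1 = "creative") is fit by logistic regression

```
logit P(D = 1) = β_cFB · cFB + β_accFB · accFB + β_OC · OC + β_0
```

where `cFB ∈ {−1, 0, +1}` codes the current trial's feedback, `accFB` is
the running sum of previous feedback codes rescaled from ±3 to ±1 (0 on
trial 1), and OC is the artwork's creativity level rescaled from 1–5 to
±1.

**Reinforcement-learning model.** A latent value of self-protection is
updated by a delta rule on *reverse-coded* feedback
(`FB = +1` negative, `0` neutral, `−1` positive), starting at `VSP_0 = 0`:

```
VSP_t = VSP_{t−1} + α · (FB_t − VSP_{t−1})
     = Σ_{i≤t} (1−α)^{t−i} α FB_i        (closed form)
```

and decisions follow `P(D = 1) = logistic(β_VSP·VSP_t + β_OC·OC + β_0)`.
The learning rate α is estimated per participant by grid-search maximum
likelihood over [0, 1] (step 0.0001, profile likelihood with the
coefficients re-fit at each α). High α agents behave like cFB-followers;
low α agents like accFB-integrators. Participants whose fitted
`β_VSP > 0` (favorable evaluation under high VSP) violate the
self-protection assumption and are excluded from group analyses.

Downstream analyses: VSP-conditioned partner-derogation/enhancement bias
(Wilcoxon tests of mean decision probabilities in VSP > 0 and VSP < 0
trials against chance), age regressions and the feedback-type × age
ANCOVA interaction, nonparametric bootstrap regression, Spearman
correlations, and case-resampling bootstrap mediation
(age → ROI estimate → behavioral estimate) with single-pass Grubbs
outlier screening.

## Worked example

```r
library(vsprl)

design <- generate_design(design_spec(seed = 1))   # 75 constrained trials
cohort <- simulate_cohort(cohort_spec(n_agents = 20, seed = 8), design)

glm_fits <- fit_influence_cohort(add_predictors(cohort$trials))
rl_fits  <- fit_rl_cohort(cohort$trials, grid_step = 1e-4)

group_analysis(glm_fits, rl_fits, cohort$participants,
               n_boot = 2000, seed = 9)
```

```
  analysis                         estimate statistic  p_value ci_lower ci_upper
1 cfb_on_age                        -0.0752     4.77   0.0424   NA       NA
2 accfb_on_age                       0.0380     1.04   0.322    NA       NA
3 feedback_type_by_age_interaction  -0.113      4.97   0.0321   NA       NA
4 alpha_residual_normality          NA          0.954  0.427    NA       NA
5 alpha_on_age_bootstrap            -0.0348    NA     NA        -0.0607  -0.0143
6 alpha_vs_cfb_influence             0.651    464      0.00187  NA       NA
7 alpha_vs_accfb_influence          -0.120   1490      0.613    NA       NA
```

Even at n = 20 the developmental dissociation built into the generator is
visible: the current-feedback influence falls with age (slope −0.075,
p = 0.042), the accumulated-feedback influence trends upward, the two
trajectories diverge (interaction F = 4.97), the learning rate declines
with age (bootstrap slope −0.035, 95% CI excluding 0), and the learning
rate correlates positively with the cFB influence.

```r
bias <- vsp_bias_analysis(rl_fits, cohort$trials)
bias$tests
```

```
  analysis              median   iqr statistic    p_value
1 high_vsp_vs_chance     0.276 0.212     -3.90 0.00000191
2 low_vsp_vs_chance      0.702 0.193      3.42 0.000168
3 high_minus_low_paired -0.403 0.166     -3.90 0.00000191
```

When VSP is high, the median probability of rating the partner's work
creative drops well below chance (0.276 vs 0.5): partner derogation.

```r
triad <- simulate_mediation_cohort(mediation_cohort_spec(n = 56, seed = 10))
bootstrap_mediation(triad, n_boot = 5000, seed = 11)
```

```
<mediation_fit> n = 56, 5000 bootstrap samples
  a = 0.548, b = 0.482, c' = 0.0788
  indirect a*b = 0.264 (SE 0.0801), 95% CI [0.107, 0.423] *
```

`run_pipeline(run_config(...), out_dir)` chains all stages (design →
cohort → predictors → influence fits → RL fits → group stats → mediation)
and writes byte-reproducible CSVs, JSON reports, and a hash manifest.
Result objects have `tidy()` / `glance()` methods, and
`plot_age_trajectories()`, `plot_vsp_bias()`, `plot_vsp_trajectory()` and
`autoplot()` methods cover the main figures.

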