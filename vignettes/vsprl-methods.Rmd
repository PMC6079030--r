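---
title: "Models and methods behind vsprl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vsprl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsprl)
```

`vsprl` analyses reciprocal social-evaluation behaviour: a participant
submits artwork, receives positive, neutral, or negative feedback from a
partner on each of 75 trials, and then rates that partner's artwork as
creative or not. Two families of models quantify how feedback shapes
these counter-evaluations, and a synthetic-cohort generator makes every
stage testable end to end. This vignette documents the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic data can and cannot establish.

## Task design and its constraints

The design crosses 3 feedback valences with 5 objective-creativity (OC)
levels, 5 trials per cell. `generate_design()` reproduces the design's
structural constraints rather than any one published trial order, which
is not available:

* **Run-length**: no more than 2 consecutive trials of the same
  (valence, OC) condition. "Condition" is the full pair; whether the
  original sequence also limited valence runs alone is unknown, so only
  the pair rule is enforced.
* **Running-sum bound**: the cumulative valence code stays within ±3 at
  every trial. This bound is inferred from the accumulated-feedback
  predictor being rescaled "from −3..+3 to −1..+1", which presupposes the
  sum never leaves ±3; it is enforced at generation and configurable
  (`accfb_bound`).
* Among 25 neutral trials, 20 are labelled "not yet evaluated" and 5 "no
  response" — cover-story texture with no analytic role; both count as
  neutral everywhere.

Generation is randomized sequential construction: each position draws
uniformly among remaining condition instances that violate no constraint
and leave the running sum returnable to zero; dead ends restart the
attempt (budget 10,000, then an infeasibility error — reaching it
signals a contradictory specification such as a one-valence design, not
bad luck). `validate_design()` re-checks every invariant and never
throws; an explicit sequence can be loaded via
`design_spec(sequence_file=)` when a fixed published order should be
used. A 75-trial generation typically succeeds within a handful of
restarts.

## The feedback-influence model

Per participant, decisions are fit by maximum-likelihood logistic
regression

$$\mathrm{logit}\,P(D=1) = \beta_{cFB}\,x_{cFB} + \beta_{accFB}\,x_{accFB}
  + \beta_{OC}\,x_{OC} + \beta_0$$

with raw (not mean-centred) codings: $x_{cFB} \in \{-1,0,+1\}$;
$x_{accFB}(t) = \sum_{i<t} x_{cFB}(i) / 3$ with $x_{accFB}(1)=0$; and
$x_{OC} = (\mathrm{level}-3)/2$. Division by the design bound (3) rather
than a per-participant min–max keeps the rescaling identical across
participants and well-defined for designs that never reach the bound.

**Exclusions.** Uniform or near-uniform responders give the model nothing
to fit. "Near-uniform" has no published operational definition; the
package excludes participants whose minority response class has fewer
than 3 presses (`min_minority = 3`, configurable) — 3 being the smallest
count that offers any leverage on three slopes. This is a stand-in rule,
not a claim about the original criterion.

**Separation.** Deterministic responders (e.g. a young, high-α agent who
perfectly mirrors feedback) produce quasi-complete separation and
divergent ML estimates. The fit detects this (coefficients beyond ±15
with fitted probabilities pinned at 0/1) and falls back to a
Jeffreys-penalized (Firth) fit, flagged via `method = "firth"`, rather
than returning unbounded coefficients. The reported log-likelihood is
always the *unpenalized* likelihood at the reported coefficients, so
likelihood comparisons remain on one scale.

The IRLS convergence tolerance is 1e-8 on the deviance scale with at most
100 iterations.

## The reinforcement-learning model

The value of self-protection is a latent state initialized at 0 and
updated by a delta rule on reverse-coded feedback (negative → +1,
neutral → 0, positive → −1):

$$\mathrm{VSP}_t = \mathrm{VSP}_{t-1} +
  \alpha\,(\mathrm{FB}_t - \mathrm{VSP}_{t-1}),$$

equivalently the exponentially recency-weighted sum
$\sum_{i\le t}(1-\alpha)^{t-i}\alpha\,\mathrm{FB}_i$ (`closed_form_vsp()`
agrees with the recursion to 1e-12 and is property-tested). With
feedback in {−1, 0, +1} and $\mathrm{VSP}_0=0$, $|\mathrm{VSP}_t|\le 1$
for every $\alpha \in [0,1]$. Neutral trials contribute FB = 0, so the
value decays toward 0 by a factor $1-\alpha$; this follows the update
rule literally.

Decisions follow
$P(D=1) = \mathrm{logistic}(\beta_{VSP}\mathrm{VSP}_t +
\beta_{OC}\,x_{OC} + \beta_0)$. Two conventions required a choice:

* **Timing**: the decision on trial *t* uses VSP updated *through* trial
  *t*'s feedback ($\mathrm{VSP}_t$), matching the pairing of
  current-trial VSP with the evaluation event; `vsp_timing = "previous"`
  exposes the $\mathrm{VSP}_{t-1}$ alternative for sensitivity analysis.
* **OC coding**: the rescaled ±1 coding is used, consistent with the
  influence model; this affects only the scale of $\beta_{OC}$.

**Estimation** is profile maximum likelihood on a grid: for each
candidate α in [0, 1] with step 0.0001, the VSP trajectory is rebuilt and
$\beta_{VSP}, \beta_{OC}, \beta_0$ re-estimated by full MLE; the α with
the highest log-likelihood wins, ties broken deterministically toward the
smaller α (deeper integration). By default a coarse scan (step 0.01)
locates the mode and the 0.0001 grid is applied one coarse cell around
it; `refine = FALSE` forces the exhaustive fine grid, and the two agree
to within one coarse cell by construction (tested). A flat profile —
likelihood range below 1e-6, as with an all-neutral feedback sequence
where α has no observable consequence — is flagged non-identifiable and
assigned the tie-break α of 0.

**Violators.** The model assumes high VSP suppresses favorable
evaluation. A fitted $\beta_{VSP} > 0$ contradicts that assumption; such
participants are flagged (`flag_violator()`) and dropped from group
analyses. The sign rule operationalizes the described behaviour
("favorable evaluation when VSP is high"); whether the original exclusion
used exactly this criterion is not stated.

**Identifiability limits.** The α grid is much finer than the data can
resolve: at 75 trials the profile likelihood is nearly flat at the low
end (for small α, $\mathrm{VSP}_t \approx \alpha\sum\mathrm{FB}_i$, and
the scale is absorbed by $\beta_{VSP}$) and at the high end (VSP tracks
current feedback). The design's ±3 running-sum bound further suppresses
the slow component of the feedback series that would separate
deep-integration agents. Consequently single-participant $\hat\alpha$ is
noisy: across agents spanning α ∈ [0.05, 0.95] with $\beta_{VSP}=-3$,
the true-vs-estimated Spearman correlation plateaus around 0.65–0.75,
and that ceiling is a property of the task design, not of the optimizer
(the exhaustive fine grid does no better). Group-level quantities — the
mean of $\hat\alpha$ over replicates, age trends, sign correlations with
the influence estimates — are recovered reliably, and those are the
quantities the analyses consume.

## VSP-conditioned evaluation bias

For each non-violator, fitted decision probabilities are averaged within
high-VSP (VSP > 0) and low-VSP (VSP < 0) trial sets; VSP = 0 trials
belong to neither, and a participant contributes only to sets with at
least one qualifying trial. Group tests are one-sample Wilcoxon
signed-rank tests against chance (0.5) per set plus a paired test between
sets. Below-chance high-VSP probabilities indicate partner derogation;
above-chance low-VSP probabilities partner enhancement. Where the
derogation-only asymmetry appears depends on the intercept: agents with
$\beta_0 = 0$ and symmetric policies show both biases symmetrically, so a
chance-level low-VSP cell in real data reflects intercept calibration,
not a structural property of the model.

## Group statistics

All tests are two-tailed and return one-row tibbles with a common column
set. OLS age regressions report the F test for the age term; the
feedback-type × age ANCOVA fits `estimate ~ type * age` and F-tests the
interaction, treating the two rows per participant as independent — this
replicates the original analysis structure (reported df 1, 56 for 58
participants); a paired alternative would model the within-participant
difference directly and is easy to build from the same table, but is not
the default. The bootstrap regression is case-resampling with percentile
CIs (5000 resamples by default, seed mandatory); significance means the
CI excludes 0. The Wilcoxon implementation reports the z statistic with
continuity and tie corrections, switching to the exact signed-rank
distribution for n ≤ 25 without ties (crossing at 25 keeps the exact
branch cheap while the normal approximation is already accurate above
it); exact ties with the null value are dropped, per convention.
Shapiro–Wilk routes analyses to nonparametric branches; Spearman uses
mid-ranks.

## Mediation

`bootstrap_mediation()` estimates the simple-mediation paths by two OLS
fits (`mediator ~ age`, `outcome ~ mediator + age`); the indirect effect
is the product $a\,b$, the total effect decomposes exactly as
$c = c' + ab$ (an OLS identity, asserted in tests to 1e-12), and
inference is by case-resampling bootstrap of the product. The CI is
percentile by default — the original macro's CI flavour is not
identified, so bias-corrected is available via
`ci_type = "bias_corrected"` without asserting which matches. Variables
are analysed on raw scales (`standardize = TRUE` exists because the
original coefficient scaling is unreported). Percentile CIs for a product
of coefficients undercover slightly at n = 56 (measured coverage ≈
0.91–0.95 at nominal 0.95) and are conservative under the null — both
well-documented properties of this estimator.

Grubbs screening is two-sided, single-pass, removing at most one
maximal-deviation point at α = 0.05, mirroring a single-extreme-outlier
exclusion; the critical value is the standard t-quantile bound, so the
clean-data removal rate sits at the nominal 5%. The screen operates on
the raw mediator values, so a covariate trend in the mediator inflates
the variance it studentizes against — an outlier must be large relative
to the *marginal* spread to be caught.

## The synthetic-cohort generator

No generative model of participants is published, so the simulator uses
the fitted model itself as the generator — the standard
parameter-recovery convention: agents update VSP by the delta rule and
decide by the logistic policy. Defaults, chosen once as plausible study
conditions:

| parameter | default | rationale |
|---|---|---|
| `n_agents` | 60 | study-scale cohort (58 analyzable) |
| `age_range` | 10–25 y | study age span |
| `alpha_age_slope` | −0.029 / y | fitted developmental slope |
| `alpha_intercept` | 0.70 at age 10 | spans α ≈ 0.7 → 0.27 over the age range, high enough for visible current-feedback behaviour in the young |
| `alpha_noise_sd` | 0.1 | individual differences around the trend; clipped to [0, 1] |
| `beta_vsp` | N(−3, 1) | self-protective on average; the positive tail yields occasional violators at roughly the observed few-per-cohort rate |
| `beta_oc` | N(1, 0.5) | creativity matters but does not dominate |
| `beta_0` | N(0, 0.5) | roughly unbiased overall evaluation |

The mediation generator draws age uniformly, then
`mediator = a·age + noise`, `outcome = b·mediator + c'·age + noise`
(defaults a = 0.5, b = 0.4, c′ = 0.1, unit noise SDs, n = 56), with
optional outlier injection scaled in mediator-noise SDs. Exactly zero
mediator noise makes mediator and age collinear and the b path
unidentifiable — the well-posed "noise-free" limit used in tests keeps an
epsilon of mediator noise.

What the synthetic data does **not** emulate: reaction times, trial
timing, BOLD signals, satiation or strategy shifts within the session,
any deviation of real decision noise from the Bernoulli-logistic form,
and measurement error in age. Passing tests therefore establish that the
pipeline recovers what its own model family generates under the study's
design — parameter recovery, calibration, and sign-level structure — not
that real participants obey the model.

## Numerical choices, degenerate inputs, problem sizes

* Logistic fits: IRLS (`glm.fit`), deviance tolerance 1e-8, max 100
  iterations; rank-deficient designs (e.g. all-neutral sequences) return
  NA for inestimable coefficients with a warning.
* Profile grid: step 0.0001 with coarse-scan refinement (exhaustive grid
  available); ties and flat profiles resolve toward smaller α,
  deterministically.
* Bootstrap internals are vectorized closed-form OLS on resample-index
  matrices, so 5000-resample CIs cost milliseconds; all resampling takes
  an explicit seed and is reproducible to the byte.
* The pipeline derives one sub-seed per stage from the master seed, so
  changing one stage's settings does not perturb another's random stream.
* Test and acceptance problem sizes — 200 replicate agents for mean
  recovery, 190 agents spanning the α range, a 60-agent cohort for the
  developmental pattern, 5000 null replicates per calibration check with
  1000 inner bootstrap resamples, 500 mediation replicates at n = 56 —
  were chosen to put Monte-Carlo error well inside each criterion's
  tolerance band while keeping a full run in the minutes range on a
  single core.

## Known limitations

* Single-participant learning-rate estimates are intrinsically noisy at
  75 trials (see above); analyses should treat $\hat\alpha$ as a
  rank-informative, not point-accurate, quantity.
* The ANCOVA treats the two feedback-type rows per participant as
  independent, inheriting the original analysis structure.
* The near-uniform exclusion threshold and the violator sign rule are
  operationalizations of verbal descriptions.
* Percentile bootstrap CIs undercover mildly for products of
  coefficients; the bias-corrected option narrows but does not remove
  this.
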