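---
title: "Dual-error models of implicit sensorimotor recalibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-error models of implicit sensorimotor recalibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualerror)
```

## The scientific problem

When a reach is perturbed, two distinct error signals are available to the
motor system. The *sensory prediction error* (SPE) is the angular difference
between the cursor feedback and the original target -- the mismatch between
what the movement was predicted to produce and what was seen. The *task
error* (TE) is the difference between the cursor feedback and the (possibly
displaced) target -- the miss with respect to the current movement goal.
Error-clamp feedback (a cursor whose angular path is fixed relative to the
target, regardless of the hand) fixes the SPE, and mid-movement target jumps
manipulate the TE independently; a target that flickers off and back on in
place ("jump-in-place") perturbs attention without changing either error.

`dualerror` implements six candidate models of how these signals combine to
drive the trial-to-trial *implicit recalibration* of reach direction,
together with the experiment designs that dissociate them, a synthetic
cohort generator, the model-free trial-pair analysis, and the model-fitting
and comparison machinery.

## The model family

All models predict the motor update `U` (degrees, in a sign-normalized frame
where positive means "away from the clamp") as a function of the clamp
magnitude $\theta_c$ and the relative target jump $\theta_j$ (positive =
toward/past the clamp, negative = away). Writing $U_0(\theta_c)$ for the
baseline no-jump update:

* **Invariant SPE** -- $U_{SPE} = U_0(\theta_c)$: target jumps are ignored.
* **Rewarded SPE** -- $U_{SPE} = U_0 - \gamma_r
  e^{-(\theta_c-\theta_j)^2 / 2\sigma_r^2}$: learning is attenuated by an
  intrinsic reward signal that peaks when the target lands on the cursor
  ($\theta_j = \theta_c$). $\gamma_r$ (degrees) is the attenuation gain,
  $\sigma_r$ (degrees) its scope.
* **Distracted SPE** -- on any trial with a target perturbation event,
  $U_{SPE} = C_J \, U_0 \, e^{-\theta_j^2 / 2\sigma_d^2}$: a fixed
  multiplicative attentional cost $C_J \in (0, 1]$ from the mere occurrence
  of a perturbation (isolated empirically by the jump-in-place condition)
  plus a Gaussian decay of width $\sigma_d$ (degrees) with jump size.
  No-jump trials use $U_0$ unmodified.

Each variant exists with and without an additive TE learning process

$$U_{TE} = \beta_{TE}\,(\theta_c - \theta_j), \qquad
  U_{Total} = U_{SPE} + U_{TE},$$

which is zero exactly when the target jumps onto the cursor, grows with
jump-away, and shrinks with jump-past. Free-parameter counts are 0/1/2/3/2/3
for Invariant/Rewarded/Distracted with and without TE. Both Gaussian terms
use negative exponents: they are decays, which is the only reading
consistent with attenuation.

Signature predictions (`predict_condition_curve()`): Invariant is flat in
$\theta_j$; Rewarded dips only near $\theta_j = \theta_c$; Distracted
SPE-only is an even function of $\theta_j$; adding TE makes the curve
asymmetric, with the jump-away branch exceeding the jump-toward branch by
exactly $2\beta_{TE}|\theta_j|$.

### Composition of the fixed baseline with TE

During fitting, $U_0$ is not free: it is pinned to the empirical no-jump
condition means. The literature leaves open whether that empirical mean *is*
the SPE baseline (so the modelled no-jump total becomes
$U_0 + \beta_{TE}\theta_c$) or whether the SPE baseline should be derived so
the no-jump total reproduces the empirical mean exactly. Both readings are
implemented via `u0_composition = c("literal", "constrained")` in
`model_params()` and `fit_model()`; they differ by a single subtraction
($U_0 - \beta_{TE}\theta_c$) and the switch makes the ambiguity testable.
The pipeline default is `constrained`, under which the fixed baseline equals
the observable quantity it is estimated from, and the TE-fraction worked
examples (below) reproduce their published values from round inputs.

On no-feedback trials there is no cursor, hence no SPE; SPE-only models
predict 0 and SPE+TE models predict the TE term alone. A caveat: in the
TE-only normalized frame (clamp magnitude 0, `jump_rel` = |jump|), the
literal formula $\beta_{TE}(0 - \theta_j)$ points opposite to a
toward-the-target learner. Since the empirical result these conditions exist
to encode is a *null* (TE alone does not drive recalibration), no analysis
in the package depends on that sign, and the generator's null-effect truth
for such designs is an SPE-only model.

## Experiment schedules

`generate_schedule()` reproduces ten perturbation-block designs
(`experiment_ids()`), with the published per-combination trial counts:

| id | trials | structure |
|----|--------|-----------|
| exp1a | 804 | 4 alternating homogeneous mini-blocks of 201 (clamp-only vs jump-only); 40 trials per type + 41 at (0,0) per mini-block; zero-mean every 20 trials |
| exp1b | 200 | fully mixed; clamp trials and *no-feedback* jump trials, 20 per condition |
| exp2a/b | 724 | fully mixed, 80 per combination (84 at (0,0)); zero-mean every 24 trials |
| exp3a/b | 120 | clamp ±3 or ±7 with jump-to, jump-away, no-jump, jump-in-place; 30 per sign-collapsed condition |
| exp4a--d | 252 | clamp ±3 or ±7 with seven relative jumps (narrow set -10...17, wide set 0, ±10, ±17, ±30); 18 per signed combination |

The zero-mean constraint is enforced constructively, not by rejection:
trials with opposite signed errors are paired, zero-error trials are paired
with each other, and pairs are shuffled into window-sized bins (20 or 24
trials) before shuffling within bins. Every disjoint window therefore has a
mean signed perturbation of exactly 0°; designs described only as "zero-mean
overall" are balanced over the whole block. `validate_schedule()` re-checks
counts, windows and mini-block homogeneity and reports (never throws)
violations. Two published counts for the exp1a (0,0) condition are mutually
inconsistent (4 x 41 per mini-block vs 84 in total); the generator follows
the per-mini-block rule and the validator reports counts without enforcing
the other figure.

## The synthetic-cohort generator

No raw behavioral data are deposited for this paradigm, so the generator is
the package's stand-in for a cohort, and its defaults are study conditions,
not tuning knobs. Hand angles follow a latent state-space process

$$x_1 = 0,\quad \text{hand}_n = x_n + \varepsilon_n,\quad
  \varepsilon_n \sim N(0, \sigma^2_{noise}),\quad
  x_{n+1} = \rho\, x_n + s_n\, U_{Total}(\text{cond}_n),$$

with $s_n$ restoring the raw sign convention. Artifact assumptions, chosen
once and documented here:

* **Motor noise** $\sigma_{noise} = 0.15$° per trial. With the designs'
  18--84 trials per condition and cohorts of tens of participants this
  yields group condition SEMs of roughly 0.1--0.2°, the range typical of
  trial-pair analyses in this paradigm.
* **Retention** $\rho = 1$ by default: the trial-pair statistic treats each
  update as persistent over one trial. $\rho < 1$ is available for
  robustness studies.
* **Between-subject variability** is a participant-level multiplicative
  gain on the $U_0$ entries with SD 0.2 (dimensionless), truncated at 0.05.
  Only the mean structure matters for group-averaged fits, so heterogeneity
  in $C_J$, $\sigma_d$ or $\beta_{TE}$ is deliberately not modelled.
* The generative truth used by the acceptance study is the Distracted
  SPE+TE model at its published estimates ($C_J = 0.84$, $\sigma_d = 11.8$,
  $\beta_{TE} = 0.02$) with constrained baselines of 0.5° (3° clamp) and
  0.9° (7° clamp), and a cohort of 210 split 53/53/52/52 across the four
  wide-jump designs (the source reports only the total).

What the generator does *not* emulate: attentional lapses and anticipatory
reaches (the heavy-tailed outliers the exclusion rule exists for), explicit
re-aiming, online corrections, reaction/movement-time structure, and any
drift or autocorrelation in motor noise. Passing tests therefore show that
the pipeline recovers what this generative family produces -- not that real
cohorts contain no structure beyond it.

With zero noise and full retention the pipeline is exactly invertible: the
analysis chain returns the generative update per condition to machine
precision for all six models on all ten designs. That round-trip identity is
the core oracle of the test suite.

## The model-free analysis

Following the paradigm's standard pipeline:

1. **Outlier exclusion** (`flag_outliers()`): a trial is excluded when its
   hand angle deviates more than 3 SDs from the mean of the 5-trial window
   centered on it (window truncated at block edges, the trial itself left
   out of the mean). The SD scale is estimated per participant and block
   over the raw pass. A windowed SD from the remaining four trials was
   considered and rejected: it turns the rule into a 3-df t-criterion that
   discards several percent of perfectly clean trials, an order of magnitude
   above the removal rates this filter is known to produce (~0.1--1%). With
   the block SD, clean Gaussian data loses
   $2\Phi(-3/\sqrt{1.25}) \approx 0.7\%$. Flags are decided in one pass; the
   SD is floored at $10^{-9}$.
2. **Trial-pair deltas** (`compute_deltas()`): for adjacent non-excluded
   trials within a block, $\Delta = \text{hand}_{n+1} - \text{hand}_n$,
   attributed to trial $n$'s condition; pairs spanning exclusions or block
   boundaries are dropped (conditions change regime at boundaries).
3. **Sign normalization** (`normalize_signs()`): clamp trials are flipped so
   positive $\Delta$ means "away from the clamp" and the jump is expressed
   relative to the clamp direction; TE-only trials are flipped along the
   jump.
4. **Condition medians** (`condition_medians()`): per-participant medians
   (robust to residual outliers), then group mean/SEM across participants.
   Conditions a participant lacks are omitted, never zero-filled.
5. **Per-participant regressions** (`participant_slopes()`): OLS of the raw
   delta on signed perturbation size, per perturbation type (or with a
   size-by-type interaction), then one-sample t-tests on the group slopes.
   This replaces the original linear-mixed-model inference, whose
   random-effects structure is not specified; group slope + t-test is the
   matching per-participant formulation.

## Fitting, comparison and uncertainty

`fit_model()` minimizes the (optionally inverse-SEM-weighted; default
unweighted, as the source describes plain least squares) sum of squared
errors between group condition means and model predictions, jointly across
clamp magnitudes, with $U_0$ fixed to the empirical no-jump means. The
optimizer is bounded L-BFGS-B restarted from 10 uniform draws within the
bounds ($\gamma_r \in [0,5]$, $\sigma_r \in (0,30]$, $C_J \in (0,1.5]$,
$\sigma_d \in (0,90]$, $\beta_{TE} \in [-0.5,0.5]$ -- generous boxes around
plausible values); ties break by SSE then start index, and non-convergence
of every start is reported on the result, never silently.

$R^2 = 1 - SSE/SST$ with SST about the grand mean of the fitted points, so
the grand-mean predictor scores exactly 0 and worse-than-mean models score
negative (the Invariant fits on real data famously do).
$AIC = n\ln(SSE/n) + 2k$ over the $n$ fitted condition means, constants
dropped, no small-sample correction; absolute values on synthetic data are
not comparable to published ones (the raw data are not available), so only
orderings and $\Delta AIC$ are meaningful. `compare_models()` ranks by AIC
and flags AIC/$R^2$ disagreements.

`bootstrap_ci()` resamples participants with replacement within groups,
rebuilds group means from the precomputed participant medians, re-derives
$U_0$ from each resample's no-jump means, refits, and reports percentile
CIs; resamples missing a condition are dropped and counted.

`derived_quantities()` turns fits into the headline numbers: the TE share of
the no-jump update $100\,\beta_{TE}\theta_c / U_{nojump}(\theta_c)$ (12.0%
at a 3° clamp with a 0.5° update; 15.6% at 7° with 0.9°), the fixed
attentional cost $100(1 - C_J)$, and the effective jump range $3\sigma_d$
beyond which SPE-driven learning is abolished ($\approx 35$° at
$\sigma_d = 11.8$).

```{r example, eval = FALSE}
res <- run_pipeline(run_config(seed = 11, B = 0), quiet = TRUE)
res$comparison      # distracted_spe_te ranks first by AIC
res$best_fit$free   # c_j ~ 0.84, sigma_d ~ 11.8, beta_te ~ 0.02
res$derived         # TE fractions, fixed cost %, effective jump range
```

## Numerical choices and degenerate inputs

* All randomness flows from one master seed through `derive_seed()`, a
  polynomial string hash modulo $2^{31}-1$ of the stage label, so any stage
  reruns in isolation; R's default Mersenne-Twister stream underlies every
  draw.
* An SSE of exactly 0 yields $AIC = -\infty$; orderings remain valid.
* `u0` lookups match clamp magnitudes with a $10^{-8}$ tolerance and fail
  loudly naming the missing magnitude.
* Schedules whose signed perturbations cannot be paired (unequal +/- counts)
  or whose zero-mean window is odd raise constraint errors at generation;
  `validate_schedule()` itself never throws on content, and handles empty
  schedules.
* Blocks with fewer than 3 trials receive no outlier flags, with a warning.
* Degenerate regressions (a single perturbation size, collinear design
  columns) raise errors naming the offending participant and columns.

## Problem sizes used by the test suite

The replicated acceptance study uses 50 synthetic cohorts of 210
participants each on the four wide-jump designs -- the full published cohort
size per replicate -- which suffices to bound recovery bias well below the
published uncertainty half-widths (0.13 for $C_J$, 2.3 for $\sigma_d$,
0.003 for $\beta_{TE}$) and to measure the AIC model-recovery rate. The
null-reproduction check uses one 87-participant no-feedback cohort, matching
the published sample. Bootstrap unit tests use small B; the default B = 1000
is exercised through `run_config(B = ...)` at the user's choice.

## Known limitations

* The models are descriptive single-trial update rules; no multi-trial
  state estimation, forgetting asymmetries, or explicit/implicit
  interaction is modelled.
* Group-averaged fitting ignores between-subject parameter heterogeneity by
  design; hierarchical fitting is out of scope.
* The generator's Gaussian motor noise cannot produce the attentional-lapse
  outliers the exclusion rule targets on real data, so exclusion rates on
  synthetic cohorts sit at or below the published ones.
* Absolute $R^2$/AIC values from the original dataset are not reproducible
  without that dataset; only model orderings are testable.
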