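# dualerror

Dual-error models of implicit sensorimotor recalibration.

When a reach is perturbed, two error signals are available to the motor
system: the **sensory prediction error** (SPE, the angle between the cursor
feedback and the original target) and the **task error** (TE, the angle
between the cursor feedback and the — possibly displaced — target).
Error-clamp feedback fixes the SPE; mid-movement target jumps manipulate the
TE; a target flickered in place perturbs attention without changing either.
`dualerror` is for researchers in motor learning who want to model, simulate
and analyse how these two signals combine to drive trial-by-trial implicit
recalibration in such experiments.

## What it implements

Six candidate models of the trial-to-trial update *U* as a function of clamp
magnitude θ<sub>c</sub> and relative target jump θ<sub>j</sub>, each with and
without an additive TE process:

| family | U<sub>SPE</sub> |
|---|---|
| Invariant SPE | U₀(θ<sub>c</sub>) |
| Rewarded SPE | U₀ − γ<sub>r</sub> exp(−(θ<sub>c</sub>−θ<sub>j</sub>)² / 2σ<sub>r</sub>²) |
| Distracted SPE | C<sub>J</sub> U₀ exp(−θ<sub>j</sub>² / 2σ<sub>d</sub>²) on perturbation-event trials |

with U<sub>TE</sub> = β<sub>TE</sub>(θ<sub>c</sub> − θ<sub>j</sub>) and
U<sub>Total</sub> = U<sub>SPE</sub> + U<sub>TE</sub>.

Around the models: generators for the ten error-clamp/target-jump experiment
designs (exact per-combination counts and zero-mean perturbation windows), a
state-space synthetic-cohort simulator, the model-free trial-pair analysis
(outlier exclusion, Δ hand angle, sign normalization, condition medians,
per-participant regressions), multi-start bounded least-squares fitting with
R²/AIC model comparison, participant-level bootstrap CIs, and derived
summary quantities. See the vignette (`vignettes/dual-error-models.Rmd`) for
the full methods account.

## Worked example

Model predictions for a 3° clamp across target jumps, at the published
best-fit parameters (C<sub>J</sub> = 0.84, σ<sub>d</sub> = 11.8°,
β<sub>TE</sub> = 0.02, no-jump updates 0.5°/0.9°):

```r
library(dualerror)
spec <- model_spec("distracted_spe_te")
params <- model_params(u0 = c("3" = 0.5, "7" = 0.9), c_j = 0.84,
                       sigma_d = 11.8, beta_te = 0.02,
                       u0_composition = "constrained")
predict_condition_curve(spec, params, clamp_mag = 3,
                        jump_grid = c(-10, -3, 0, 3, 7, 10, 17))
#>   jump_rel     update
#> 1      -10  0.5180954
#> 2       -3  0.4778461
#> 3        0  0.5000000
#> 4        3  0.3578461
#> 5        7  0.2299671
#> 6       10  0.1180954
#> 7       17 -0.1490724
```

The curve is asymmetric: jumps *away* from the clamp (negative) barely
change the update, while jumps toward and past it suppress recalibration —
the signature that separates the Distracted SPE+TE model from its
competitors.

An end-to-end run — simulate a 210-participant cohort on the four wide-jump
designs from that generative truth, analyse it, and fit all six models:

```r
res <- run_pipeline(run_config(seed = 11, B = 0), quiet = TRUE)
res$comparison
#>            model_id k    sse      r2    aic delta_aic rank
#> 1 distracted_spe_te 3 0.0031  0.9990 -169.5         0    1
#> 2   rewarded_spe_te 3 1.1950  0.6165  -50.4       119    2
#> 3    distracted_spe 2 2.1197  0.3199  -40.9       129    3
#> 4  invariant_spe_te 1 2.5026  0.1970  -39.6       130    4
#> 5      rewarded_spe 2 2.9992  0.0376  -33.9       136    5
#> 6     invariant_spe 0 4.7128 -0.5122  -28.9       141    6
round(res$best_fit$free, 4)
#>     c_j sigma_d beta_te
#>  0.8377 11.9649  0.0200
res$derived
#> $te_fraction_pct
#>        3        7
#> 11.92444 15.76505
#> $fixed_cost_pct
#> [1] 16.23121
#> $effective_jump_range_deg
#> [1] 35.89474
```

The generating model wins by a wide AIC margin and its parameters are
recovered: a ~16% fixed attentional cost from merely perturbing the target,
a Gaussian attentional decay putting the effective jump range near 36°, and
a TE process contributing ~12% (3° clamp) and ~16% (7° clamp) of the
no-jump update.

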