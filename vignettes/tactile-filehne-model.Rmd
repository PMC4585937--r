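---
title: "A stationarity-prior observer model of tactile motion perception during pursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stationarity-prior observer model of tactile motion perception during pursuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filehne)
```

## The perceptual problem

When a finger slides over a moving surface, the skin only senses *relative*
motion (cutaneous slip, $v_\mathrm{tact}$), while proprioception senses the
finger's own velocity ($v_\mathrm{prop}$). A veridical observer recovers the
world-centred surface velocity by summation,
$v_\mathrm{surf} = v_\mathrm{tact} + v_\mathrm{prop}$. Human observers do not
sum veridically: during manual pursuit a world-stationary surface is
perceived as moving opposite to the hand — a tactile analog of the visual
Filehne illusion. This package implements a Bayesian observer that explains
the bias, the psychometric machinery used to measure it, and synthetic
experiments that exercise the whole analysis.

## The observer model

Each sensory channel delivers a noisy, unbiased velocity measurement:
proprioception measures the initial (pursuit) velocity with variance
$\sigma^2_p$, and touch measures the velocity change with variance
$\sigma^2_t$ (all variances in mm²/s²). Each measurement is combined with a
zero-mean Gaussian *stationarity prior* of variance $\sigma^2_S$ — the belief
that surfaces are usually at rest. The conjugate-Gaussian update shrinks a
measurement $m$ towards zero by the weight

$$w = \frac{\sigma^2_S}{\sigma^2_S + \sigma^2}, \qquad
  \tau^2 = w\,\sigma^2,$$

so the noisier channel is shrunk harder. The observer's surface-velocity
estimate is the *sum of one sample from each posterior*. Propagating the
measurement noise through the shrinkage and adding the posterior sampling
variance gives a Gaussian fused estimate with

$$\mu = w_p v_\mathrm{prop} + w_t (v_\mathrm{surf} - v_\mathrm{prop}),
\qquad
\sigma^2 = w_p^2\sigma_p^2 + w_t^2\sigma_t^2 + \tau_p^2 + \tau_t^2 .$$

The response "the surface moved away" occurs when the fused estimate exceeds
zero, so the predicted psychometric function is a probit in
$v_\mathrm{surf}$ with slope $w_t/\sigma$ and PSE

$$\mathrm{PSE}_\mathrm{main} = v_\mathrm{prop}\left(1 - \frac{w_p}{w_t}\right).$$

Because proprioception is noisier than touch ($w_p < w_t$), the PSE is
positive: a surface must physically move away for the observer to judge it
stationary — the illusion. With the finger stationary the proprioceptive
channel is discarded entirely, which makes the control-task prediction
structurally unbiased (PSE $=0$ for *any* variances) and its slope equal to
the tactile-only slope. By default the two channels share one prior variance;
a two-prior variant (different $\sigma^2_S$ per channel) is available through
`observer_params()` and reduces to the single-prior model when the variances
are equal.

### Calibrating the prior

The prior variance is not separately identifiable from the likelihood
variances (only the shrinkage weights matter, and a large change in variances
moves the weights very little), so it is *constrained*. The package
calibrates it from the unimodal proprioceptive probit slope via the closed
form in `calibrate_prior_variance()`: a slope of 0.02 at
$\sigma^2_p = 34$ gives $\sigma^2_S \approx 0.4753$. That single calibration
then fixes everything else:

```{r calibration}
s2_prior <- calibrate_prior_variance(0.02, 34)
obs <- observer_params(sigma2_prop = 34, sigma2_tact = 11,
                       sigma2_prior_prop = s2_prior, v_pursuit = 10.8)
predicted_unimodal_slope(s2_prior, 11)      # tactile-only slope ~0.06
predicted_psychometric(obs, "main")$pse     # ~7.2 mm/s
jnd_from_slope(0.02); jnd_from_slope(0.06)  # unimodal JNDs, mm/s
```

The fact that one calibrated parameter reproduces the tactile slope, both
JNDs and the main-task PSE simultaneously is the core consistency check of
the implementation (see `tests/testthat/test-acceptance.R`).

## Parameters that matter

| parameter | units | default | meaning |
|---|---|---|---|
| `sigma2_prop` | mm²/s² | 34 | proprioceptive likelihood variance |
| `sigma2_tact` | mm²/s² | 11 | tactile likelihood variance (high amplitude) |
| `sigma2_prior_prop` | mm²/s² | 0.4753 | stationarity-prior variance (calibrated, see above) |
| `sigma2_prior_tact` | mm²/s² | = prop | separate tactile prior (two-prior variant) |
| `v_pursuit` | mm/s | 10.8 | mean finger velocity in the pursuit task |
| `kappa_low_amp` | — | 2 | variance inflation at low pin-oscillation amplitude |

`kappa_low_amp = 2` (≈1.4× on the SD scale) encodes the observed ratio of
discrimination JNDs between low and high oscillation amplitude; it is a
single multiplicative factor because no functional form linking amplitude to
noise is established — it is exposed, not hard-coded.

## The stimulus simulator

The pin array renders a virtual ridged surface by actuating 8 rows of pins
in sequence (1.6 mm pitch, 1.5 ms refresh); the ridge position advances by
$v_\mathrm{tact}\,\Delta t$ per refresh and wraps over a spatial period of
$(n_\mathrm{rows}-1)\cdot\mathrm{pitch} + \mathrm{gap} = 12.8$ mm, so a
single ridge is felt at any time. `build_row_timeline()` produces the
activation schedule; the emergent period measured from the timeline equals
the geometric one to within one refresh step of travel, and negating the
velocity reverses the activation cycle exactly. The 20 Hz within-row
oscillation is carried as metadata only — downstream analysis needs the
amplitude condition, not the waveform.

## Synthetic experiments

The generator reproduces the session structure of the three tasks:

* **exp1** — 105 main-task trials (7 velocities −30…30 mm/s including 0,
  ×15) plus 90 control trials (6 nonzero velocities ×15), shuffled within
  their blocks. The exact levels/repetitions are not dictated by the session
  totals alone; the defaults factor them as 7×15 and 6×15 and can be
  overridden.
* **exp2** — a single 200-trial block, 5 velocities × 2 amplitudes × 20,
  randomly intermixed.
* **exp3** — two-interval speed discrimination around a 30 mm/s standard
  with signed differences ±{2.5, 5, 10, 15} mm/s × 2 amplitudes × 12.

Two generative routes are provided. `simulate_observer_responses()`
forward-simulates the Bayesian observer itself (Bernoulli draws from the
closed-form response probability; for exp3, explicit two-stage draws per
interval). `simulate_population()` draws per-observer random
intercept/slope pairs from a bivariate Gaussian around condition-specific
fixed effects — the generative counterpart of the hierarchical analysis. Its
defaults encode group PSEs of 6.8 mm/s (main, slope 0.0425) and −1.6 mm/s
(control, slope 0.0601) with a per-observer PSE spread of ≈3.5 mm/s and no
intercept–slope correlation, values consistent with the magnitude of the
effect and the spread of individual observers in this paradigm.

What the generator does *not* emulate: finger-tracking error (pursuit is
treated as perfectly steady), reaction times, trial-order and learning
effects, and any amplitude–noise relationship beyond the single factor
`kappa_low_amp`. Passing recovery tests therefore shows that the estimators
are consistent and calibrated *under the model's own assumptions*, not that
real data satisfy those assumptions.

## Fitting choices

**Per-observer probit fits** (`fit_probit_ml()`) are binomial probit GLMs.
Complete separation and flat (chance-level) responding are *flagged*, not
silently returned as numbers, mirroring the exclusion rules applied to real
observers; delta-method SEs are attached to PSE and JND.

**The hierarchical fit** (`fit_hierarchical_probit()`) uses a probit GLMM
with condition-specific fixed effects and a shared bivariate random
intercept+slope per observer, maximised with `lme4::glmer` under the Laplace
approximation. Adaptive Gauss–Hermite quadrature would be the more accurate
integral, but lme4 restricts `nAGQ > 1` to scalar random effects and the
model's random effect is vector-valued; Laplace is the standard, auditable
choice for this model class and matches the tooling behind the original
analysis. Random effects are shared across conditions (the conditions are
measured within observer); fixed effects are condition-specific, with a
`common_slope` reduced variant for the slope likelihood-ratio test.

**Bootstrap intervals** are percentile intervals from parametric
resampling: the hierarchical route redraws random effects and binomial
responses from the fitted model and refits the GLMM; the single-fit route
redraws binomial counts at the fitted probabilities. 1000 replicates is the
reference setting; the analysis scripts use 100–200 replicates, which is
enough for stable 95% endpoints at the effect sizes involved and keeps each
script in the tens of seconds.

**The observer-model fit** (`fit_observer_model()`) maximises the Bernoulli
likelihood over $(\log\sigma^2_p, \log\sigma^2_t)$ by Nelder–Mead from five
deterministic starts with box bounds $[10^{-2}, 10^4]$, the prior variance
held fixed. The likelihood is nearly flat in directions that inflate a
variance while the weight saturates — visible in bootstrap replicates whose
$\sigma^2_p$ upper percentile hits the search bound — but the *ratio*
$\sigma^2_p/\sigma^2_t$ and the predicted PSE are well identified, and the
fitted ratio is insensitive to the prior constraint (checked over
constraints 0.25–1.0 in the test suite). Response probabilities are clamped
at $10^{-12}$ in the likelihood; clamp events are counted and reported.

**Numerical conventions.** JND uses the 75% criterion
$\Phi^{-1}(0.75)/\mathrm{slope} = 0.6745/\mathrm{slope}$. Velocities are
positive away from the body. A "main"-geometry trial with zero pursuit
velocity is routed to the control formulation (the channel does not exist,
rather than carrying a zero measurement). The attainable range of
`calibrate_prior_variance()` is $0 < s < 1/\sqrt{2\sigma^2}$ — the slope
supremum as the prior variance grows without bound — and targets outside it
are rejected rather than extrapolated.

## Problem sizes

The test suite and acceptance checks use the session sizes of the study
itself where recovery is claimed (10 observers × 195 trials; 200-trial
amplitude sessions), 10⁵–10⁶ Monte-Carlo draws for oracle equivalence of the
closed forms, 200 outer × 200 inner replicates for bootstrap coverage, and
500 simulations for the LRT type-I rate. These sizes give Monte-Carlo
standard errors comfortably below the tolerances asserted.

## Known limitations

* The likelihood variances are treated as speed-independent within the
  ±30 mm/s range (a local linearisation); speed-dependent variance
  functions are deliberately out of scope.
* Likelihood means are unbiased by assumption; surface-texture effects on
  perceived slip are not modelled.
* The hierarchical bootstrap refits a GLMM per replicate and is the
  computational bottleneck; coverage calibration is therefore demonstrated
  on the single-fit binomial bootstrap, with the hierarchical route
  exercised at reduced replicate counts.
* With few observers or trials the random-effect covariance is often
  estimated at the boundary (singular fits); these are reported in the fit
  diagnostics rather than suppressed.
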