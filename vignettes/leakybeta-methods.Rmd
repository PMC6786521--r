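---
title: "Models and methods in leakybeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in leakybeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(leakybeta)
```

# The task being modelled

`leakybeta` models an aversive reversal-learning task in which two visual
stimuli are shown concurrently on every trial. Each stimulus carries its own
probability of delivering an electric shock; within a block one stimulus's
probability is constant ("stable") while the other follows a
piecewise-constant path with change-points ("volatile"). Subjects rate the
shock probability of both stimuli on every trial, then see both outcomes.
The default task layout is 4 blocks of 40 trials with a grand mean shock
probability of 0.36, screen sides randomised per trial, and belief state
reset at block boundaries (subjects are told to disregard earlier blocks).
Eye tracking yields phase-aggregated fixation durations for the
*pre-outcome* window (after rating, before outcomes appear) and the
*outcome* window (while both outcome cues are visible).

Two questions drive the analyses: does learned value and/or estimation
uncertainty guide visual attention, and does attention in turn bias
learning?

# The model family

All models update, per stimulus $X$ and trial $t$, an estimate of the shock
probability. Ratings are modelled as noisy reports of the current estimate.

**Model 1 — Rescorla-Wagner.**
$V^X_{t+1} = V^X_t + \alpha\,(o^X_t - V^X_t) + \omega\,(o^Y_t - V^X_t)$,
where $o$ are binary outcomes and $\omega$ captures interference from the
concurrently shown stimulus $Y$. Both terms are functions of the pre-trial
value and are applied in a single step; the result is clipped to $[0,1]$
because it represents a probability (the update rule itself does not
guarantee this once $\alpha + \omega > 1$).

**Model 2 — dual-rate RW.** As model 1 but with $\alpha^+$ for positive
prediction errors ($\delta_t = o^X_t - V^X_t > 0$) and $\alpha^-$ for
negative ones.

**Models 3 and 4 — RW/Pearce-Hall hybrids.** The learning rate itself is
dynamic: the value update uses the current $\alpha_t$, which then adapts
towards the squared (model 3) or absolute (model 4) prediction error at
rate $k$: $\alpha_{t+1} = \alpha_t + k(\delta_t^2 - \alpha_t)$. Because
this is a convex combination, $\alpha_t$ stays in $[0,1]$ without clipping.
The initial $\alpha_0$ is the fitted $\alpha$ parameter itself — the model
description leaves initialisation open, and using the fitted rate keeps the
nested relationship with model 1 exact when $k = 0$.

**Models 5 and 6 — leaky beta learners.** Beliefs are a Beta distribution
with evidence masses $A$ (shock) and $B$ (no shock):
$$A^X_{t+1} = (1-\lambda)A^X_t + \tau^+ o^X_t + \omega\, o^Y_t, \qquad
  B^X_{t+1} = (1-\lambda)B^X_t + \tau^- (1-o^X_t) + \omega\,(1-o^Y_t),$$
with $\tau^+=\tau^-=\tau$ in model 5. The reported estimate is the mean
$\mu = A/(A+B)$ and the estimation uncertainty is the variance
$\sigma^2 = AB/((A+B)^2(A+B+1))$. The leak $\lambda$ discounts old
evidence so recent outcomes dominate — appropriate since probabilities
change within blocks.

**Models 6A and 6B — attention-coupled learners.** Both extend model 6
with the proportion of outcome-phase fixation time on each stimulus from
the *previous* trial (the first trial of a block uses a neutral 0.5/0.5
split). 6A scales the update rate by
$\pi^X = f^X\gamma + (1-\gamma)$ and weights the cross-stimulus term by
$f^Y$; 6B instead adds value to attended stimuli, $\theta f^X$, directly
on the shock-evidence mass. Binary variants (`6A_bin`, `6B_bin`) replace
the continuous weighting by a winner-based rule; `6A_bin`'s defined
loser branch $1-(f^X-f^Y)\gamma$ exceeds 1 when the difference is
negative and is implemented exactly as defined rather than silently
corrected (it is flagged in the function documentation). In `6B_bin` the
cross-stimulus term is *not* fixation-weighted, again following the
variant's definition.

## Initialisation, resets and numerical floors

The start of every block re-initialises beliefs at ignorance: $V_0 = 0.5$,
$A_0 = B_0 = 1$ (a uniform Beta, $\mu_0 = 0.5$, $\sigma^2_0 = 1/12$).
Evidence masses are floored at $10^{-6}$ so the Beta moments stay defined
under a full leak. Note the variance bound: $\sigma^2 \le 1/12$ only once
$A+B \ge 2$; as both masses shrink towards the floor the variance
approaches its global supremum of $1/4$. Tests assert the correct bound.

The scalar update functions (`rw_update()`, `beta_update()`, ...) define
the semantics; a C++ engine iterates them for whole cohorts. The test
suite requires exact (1e-12) agreement between the engine and an
independent plain-R transcription of the equations on random sequences,
and checks the Beta moments against numerical quadrature at 1e-8.

# Observation model and hierarchical fitting

The update rules say nothing about how ratings are produced, so the
package makes the observation model explicit: ratings are Beta-distributed around the current
estimate with a free per-subject concentration $\phi$,
$y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$. Ratings are compressed away
from the boundary by $(y(n-1)+0.5)/n$ (the standard beta-regression
device) and predicted means are guarded into $(10^{-4}, 1-10^{-4})$.
A bounded-support observation model was preferred to a truncated Gaussian
because ratings are probabilities.

Subject-level parameters live on unconstrained sampling scales (logit for
$[0,1]$ and $[-1,1]$ parameters, log for positive ones) and are drawn from
group-level normal distributions — the hierarchical structure used for
every fit in the package. Priors are weakly informative: group means are
normal with SD 1.5 around neutral locations (e.g. $\log 0.5$ for
increments, logit 0.15 for the leak), group SDs half-normal(1). All prior
scales can be multiplied via `prior_scale` for sensitivity analyses; the
headline recovery results in the test suite are stable under a 2x change
because the data dominate at 160 trials per subject.

Sampling uses a blocked adaptive Metropolis-within-Gibbs scheme written
for this structure and vectorised across subjects: each sweep proposes one
parameter for every subject simultaneously (one trajectory evaluation per
sweep), group means are conjugate Gibbs updates, and group SDs use
log-scale random walks. Proposal scales adapt towards a 0.44 acceptance
rate during warmup. Learning-rate fits for models 1-2 allow
$\alpha \in [-1, 1]$ so that gambler's-fallacy behaviour (ratings that
*fall* after a shock) appears as a negative posterior mean — the basis of
the corresponding exclusion rule. Convergence is monitored with
split-chain R-hat and effective sample sizes on the group level
(via `coda`); non-convergence is flagged on the fit object, never
silently ignored. The default protocol is 2 chains of 1000 warmup + 3000
kept iterations; simulation studies and the test suite use reduced,
explicitly stated settings.

Point estimates used by exclusion rules are posterior means.

## Model comparison

WAIC is reported on the deviance scale (lower is better) with the
posterior-variance penalty (pWAIC2) and a standard error from the
observation-wise contributions; penalty terms with per-observation
variance above 0.4 trigger a warning. Block-wise cross-validation
(`cross_validate_blocks()`) refits on three blocks, predicts held-out
ratings from posterior-mean subject parameters (block resets prevent
leakage), and scores pooled $R^2$; it provides a WAIC-independent check of
the model ranking.

# The gaze analyses

Fixation bias is the left-stimulus share of on-stimulus time,
$d_L/(d_L+d_R)$; trials without on-stimulus fixation are missing, not
imputed. Predictors are left-minus-right differences (value from reported
ratings by default, or model-derived $\mu$; uncertainty from model
$\sigma^2$, or the previous trial's $|\delta|$ as a model-free variant),
z-scored within subject so coefficients are comparable. The hierarchical
beta regression puts a logit link on the bias mean, subject-level
coefficients under group-level normals, and a log-normal per-subject
precision. The outcome-phase specification adds outcome, signed
prediction-error and squared prediction-error differences.

Two sampler refinements matter here. The outcome and prediction-error
difference predictors are nearly collinear within subject (the PE is the
outcome minus a slowly varying estimate), so elementwise proposals mix
poorly; the sampler therefore adds per-subject joint proposals aligned
with $\mathrm{chol}((X_s'X_s)^{-1})$ and a global translation move that
shifts the group mean and every subject's coefficients together. A
common alternative device for hard multilevel regressions is a
non-centred parameterisation of the subject-level coefficients; with
blocked conditional updates the centred form mixes well and keeps the
group updates conjugate, so the package uses the centred parameterisation
plus the moves above. The test suite
cross-checks the sampler against an independent Gibbs implementation
(JAGS) and a maximum-likelihood oracle.

The estimation-error regression targets the reported-minus-true shock
probability with Gaussian likelihood on the error scale and regressors:
both stimuli's true probabilities, the previous trial's outcome, and the
previous trial's outcome-phase fixation proportion on the estimated
stimulus (lags drop each block's first trial). The parameter-influence
regression (mean rating on standardised $\tau^+$, $\tau^-$, $\lambda$) is
an ordinary Bayesian linear model; under its flat prior the posterior
means coincide with least squares, which the tests exploit as an exact
oracle.

The behavioural interference statistic contrasts a stimulus's rating
updates between trials where the other stimulus was or was not shocked;
its null distribution comes from randomly swapping the two stimuli's
labels per trial (5000 permutations by default, seeded). Because the
stable/volatile asymmetry makes label exchange only approximately valid,
the test suite checks the null case against a loose tail bound rather
than exact uniformity.

# The synthetic cohort and its calibration

Every analysis runs on synthetic data, so the generator's defaults define
the study conditions. They were chosen once — calibrated so the simulated
cohort exhibits the behavioural signatures this task family is designed
to elicit — and then frozen:

* **Schedules**: stable levels drawn from {0.2, 0.25, 0.3}; volatile paths
  with 3-5 change-points, minimum segment 5 trials, levels spanning
  0.05-0.9; a final affine adjustment pins the grand mean at 0.36 (or a
  45%/55% block pair with combined mean 0.50 when configured). The
  schedules are structurally realistic rather than copies of any
  particular experiment's sequences.
* **Learning parameters**: $\tau^+/\tau^- = 0.8/0.4$ encodes a strong
  (2:1) bias towards learning from shocks, the signature the asymmetric
  model exists to capture; $\lambda = 0.36$ is set so the
  mean within-subject correlation between $\mu$ and $\sigma^2$ across a
  48-agent cohort is approximately zero, reproducing the value-uncertainty
  dissociation the task was designed to achieve (with a weak leak the
  evidence-mass dynamics induce a spurious negative correlation of about
  -0.25). $\omega = 0.05$ gives the small cross-stimulus interference the
  free-$\omega$ comparison detects; rating precision 20 corresponds to a
  rating noise SD near 0.1 at mid-scale.
* **Fixation coupling**: biases are generated from the same hierarchical
  beta-regression model the analysis fits, with group coefficients at the
  package's reference values (pre-outcome: value 0.13, uncertainty
  -0.004; outcome phase: value 0.10, outcome 0.10, PE 0.07, PE-squared
  0.03; estimation-error model: own probability -0.18, other -0.02,
  fixation 0.017), subject-level SD 0.05 (0.10 for the intercept), and
  per-phase precisions (20 pre-outcome, 60 outcome-phase) chosen so the
  *fitted* group HPD half-widths land near 0.03 — a small, precisely
  estimated effect, with the longer outcome window plausibly yielding
  steadier bias measurements. Off-stimulus time is Beta(2, 8) per trial (mean 0.2),
  safely below the 80% exclusion threshold unless a pathological agent is
  planted.
* **Pathological agents**: gambler's-fallacy learners are simulated from a
  Rescorla-Wagner rule with $\alpha = -0.4$; limited responders snap
  ratings to {0, 0.5, 1}; off-stimulus subjects re-allocate 85-95% of
  fixation time off-stimulus. Each is planted per subject with a
  configurable probability and recorded in the cohort's parameter table,
  so exclusion counts can be verified exactly.

For attention-coupled cohorts fixations must exist before they can
modulate learning; the generator therefore couples fixations to a
first-pass model-6 trajectory and feeds them into the final 6A/6B
trajectory. This two-pass scheme slightly decouples the pre-outcome bias
from the final beliefs and is a known simplification.

What passing tests on this cohort do **not** show: the generator contains
no saccade-level dynamics, no pupil or kinematic measures, no
autocorrelated rating noise, no lapses or missed responses, and its
schedules are not the experiment's actual sequences. Recovery results
certify the estimation machinery, not the psychology.

# Problem sizes and numerical choices

The test suite and the acceptance script scale simulations to run on a
single CPU in minutes: recovery experiments use 48 subjects x 160 trials
with 2 chains of 500-700 kept iterations after 500-600 warmup; the WAIC
model-selection study uses 20-agent cohorts over 5 replications with
single chains; the null-calibration study uses 25 replications of
6-subject, 2-block cohorts. Recovery criteria are replicated over three
seeds and required to hold in at least two, since any single 95% interval
misses about 5% of the time. The acceptance script replicates each
recovery experiment three times and averages the recovered group
coefficients.

Other fixed numerical choices: evidence floors at $10^{-6}$; boundary
compression $(y(n-1)+0.5)/n$; predicted-mean guard $10^{-4}$; HPD
intervals at 95% from pooled chains; permutation count 5000; z-scores set
constant predictors to zero; ties in `6A_bin`/`6B_bin` fixation
comparisons fall to the no-winner branch.

# Known limitations

* The samplers are tuned for this model family; severely unbalanced
  designs (subjects with very few trials) may need longer adaptation.
* WAIC penalties can be unstable for observations with extreme
  leave-one-out influence (the package warns when per-observation
  penalty variance exceeds 0.4).
* The interference permutation test treats stimulus labels as
  exchangeable, which the stable/volatile design only approximates.
* Attention-coupled simulation is two-pass (above); fitting 6A/6B to real
  data does not share this limitation since fixations are observed.
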