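---
title: "Models and methods behind satlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind satlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satlearn)
```

This vignette documents the scientific choices inside `satlearn`: the task
rules it encodes, the synthetic-subject model, the estimation machinery of
the first-level and group analyses, and the places where a design decision
was genuinely open and a convention had to be fixed.

## The task engine

The Salience Attribution Test presents compound cues varying on colour
(blue/red) and shape (animal/household object). One dimension is
task-relevant: its "high" feature is rewarded on 14 of its 16 trials per
cue type (87.5% of its trials), the "low" feature on 2 of 16 (12.5%). The
other dimension is task-irrelevant: both of its levels inherit 16/32 (50%)
rewarded trials. `build_schedule()` enforces these counts exactly by
sampling the reward flags without replacement within each cue type, block
by block; they are invariants of the design, not expectations. Each block
presents each of the 64 distinct stimuli once, in a uniformly shuffled
order, at a constant 9.25 s trial spacing; the probe-onset delay is drawn
uniformly on 3.5–4.5 s and the probe duration uniformly on the subject's
`meanRT ± 2 SDF` window.

Calibration (`calibrate()`) follows the convention that the practice mean
RT is taken over **all** valid practice trials while the SDF is the sample
standard deviation (n − 1) of the **ten fastest**. Restricting the mean to
the ten fastest trials would be an alternative reading of "mean RT"; the
all-trials mean is the natural one and the one adopted. Valid here means responded and at least
100 ms after probe onset. Fewer than ten valid trials, or ten identical
fastest trials (SDF = 0, which would make the payout slope infinite), are
errors.

Two further timing ambiguities were resolved as follows: the 3.5–4.5 s
probe delay is measured **from cue onset** (the cue appears 1 s into the
trial and the probe replaces the fixation cross thereafter), and payouts
`X = 10 + 90(meanRT − RT)/(3 SDF)` are rounded to the nearest penny —
the rule's worked examples (1 SDF → 40p, 2 SDFs → 70p, ≥ 3 SDFs → 100p)
are integers either way and are reproduced exactly, as `test-acceptance.R`
verifies for several calibration profiles.

All randomness flows from one master seed through named substreams
(reward assignment, trial order, probe delay, probe duration, behaviour),
so each component is independently reproducible.

## The synthetic subject

The SAT is a behavioural paradigm, not a behavioural model; the agent
here is an explicit stand-in whose job is to give the scoring and group
analyses data with the right *structure* — graded adaptive learning,
stable individual differences in aberrant learning — not to reproduce
human group means. No claim is made that its defaults match typical human
values (tens of millimetres of explicit adaptive learning, a few
milliseconds of implicit speeding, a few pounds of earnings per block).

The learner is a Rescorla–Wagner delta rule over the four cue *features*.
A compound cue's value is the **mean** of its two feature weights, keeping
`V` in [0, 1] and interpretable as a reward-probability estimate (any
monotone combination would serve; the mean is the simplest that does).
After every trial both presented features move by
`alpha * (reward − V)`; learning updates on every trial, including
omissions, because feedback (and its magnitude-coding tone) is delivered
regardless of the response.

Behaviour is read out as:

* **Reaction times** — `base_rt − beta_rt · V + N(0, rt_noise)`, truncated
  to the valid response window (100 ms to probe offset) by resampling (at
  most 100 draws, then clamping). Omissions and premature responses are
  injected at fixed per-trial rates (defaults 0.07 and 0.042, i.e. about
  4.5 omissions and 2.7 prematures per 64-trial block, matching the scale
  of human error rates).
* **VAS ratings** — `100 · clamp(V̄ + offset) + N(0, rating_noise)` mm,
  clamped to [0, 100], where `V̄` is the cue type's value averaged over
  the block's trials. The block-average readout (rather than the
  end-of-block weight snapshot) reflects that a probability estimate
  integrates the whole block's experience; it also makes mean explicit
  adaptive learning increase monotonically in `alpha`, where the terminal
  snapshot is dominated by trial-to-trial weight jitter at high learning
  rates.

Aberrant salience is modelled as a **stable per-subject bias**, not
trial-wise noise: one draw `delta ~ N(0, kappa)` per subject shifts the
reported value of the first irrelevant level by `+delta/2` and the second
by `−delta/2`, so the expected explicit aberrant measure is `100·|delta|`
mm. A fixed offset was chosen because the phenomenon of interest is a
stable inter-individual difference (it is what the group covariate
analyses correlate against); the realised offset is stored in each log so
parameter recovery can be tested directly. The bias enters the *rating*
readout only — RTs use the learned values — mirroring the empirical
pattern that explicit and implicit aberrant measures are essentially
uncorrelated.

`simulate_cohort()` gives each subject its own practice session (40 trials,
subject mean drawn from N(300, 25) ms, within-subject SD 40 ms), hence its
own calibration profile, schedule randomisation and behaviour stream. The
default cohort size in examples is 19, a typical single-site sample for
this paradigm.

What the generator does **not** emulate: late responses essentially never
occur (the truncation-by-resampling forces a response inside the probe
window on every non-omission trial), so simulated earnings run higher than
human earnings; RT distributions are Gaussian rather than skewed; there is
no fatigue, no drift in attention, and ratings have no anchoring or
rounding habits. Passing tests therefore certify the pipeline's
*computational* behaviour on data with known ground truth, not the realism
of the agent.

## Behavioural scoring

Feature-level ratings are the mean of the two cue-type ratings containing
the feature (the VAS probes cue types; the measures are defined at feature
level). The four measures follow the standard definitions: explicit
adaptive = high − low relevant-feature rating; explicit aberrant =
|difference| across irrelevant levels; implicit adaptive = low − high mean
RT; implicit aberrant = |RT difference| across irrelevant levels. Implicit
measures use trials classified `valid` only — premature, missed and
omitted trials carry no meaningful RT.

**Subjective relabelling**: per block, the irrelevant level with the higher
mean rating becomes subjectively "high-probability". Exact ties are broken
in canonical order (animal before object, blue before red) and carry a
`tie` flag that propagates to the GLM stage, where the aberrant contrast
warns if it is built on a tied block. The relabelling may differ across
blocks within one subject; the aberrant contrast honours that block by
block.

**Outlier exclusion** uses the leave-one-out convention: a subject is
excluded when its value lies more than 3.5 SDs from the mean and SD of
the *remaining* subjects — the rest of the group sets the yardstick, so a
gross outlier cannot mask itself by inflating the pooled SD. It is applied
by default only to the
implicit adaptive measure, where a single slow responder can flip the
group-level sign; the threshold and the measure screened are arguments.

Binary outcome entropy `H(p) = −(p ln p + (1−p) ln(1−p))` is provided in
nats: the task's relevant features carry H(0.875) = H(0.125) = 0.377, the
irrelevant features the maximal H(0.5) = 0.693 — the information-theoretic
asymmetry that motivates interpreting aberrant learning as a response to
outcome uncertainty.

## First-level GLM

Each 64-trial block is treated as one scanner run (217 scans at TR 2.73 s)
with its own design, drift set, intercept and AR(1) estimate. Conditions
are the four cue types (duration 2 s from cue onset), the outcome
(duration 1.5 s from feedback onset) and the outcome parametrically
modulated by reward magnitude in pence. Cue events are dropped when the
subject made no response, or responded within 1250 ms of cue onset
(movement contamination); outcome events are always retained. The 1250 ms
threshold is referenced to cue onset — the separate sub-100 ms "too early"
category is referenced to probe onset — which is the reading under which
the two rules coexist sensibly.

The basis set is the canonical double-gamma HRF (response Gamma(6, 1),
peak at 5 s; undershoot Gamma(16, 1) at ratio 6; support 32 s; unit-peak
normalisation) plus its temporal derivative (finite difference over a 1 s
onset shift) and dispersion derivative (finite difference over a 1% change
in the response-gamma dispersion). Boxcars are built on a 16-bins-per-TR
microtime grid, convolved, and sampled at scan onsets. The magnitude
modulator is mean-centred over **all** outcome events (zeros included for
non-rewarded trials) before convolution, decorrelating it from the
unmodulated outcome regressor — an uncentred modulator at 0–100 pence
would render the outcome regressor nearly redundant. Discrete cosine drift terms run up to
the 1/128 Hz cutoff (`k = floor(2·n·TR/128)`), giving 18 task columns +
k + 1 per run. Global confounds are handled by session grand-mean scaling
to 100 (available via `grand_mean_scale`), avoiding the artefacts of
per-scan proportional scaling.

Estimation is two-pass prewhitened least squares: OLS, a single lag-1
residual autocorrelation pooled over voxels, exact AR(1) whitening of data
and design, refit. The raw residual autocorrelation is biased toward zero
because the projection through a design rich in smooth regressors absorbs
slow noise; `ar1_calibration()` computes the expected residual
autocorrelation `tr(A M Σ_ρ M)/tr(M Σ_ρ M)` on a grid of generating ρ and
`fit_glm()` inverts that curve. Without the correction the estimate sits
near −0.055 for white noise at 500 scans; with it, simulation places the
estimate within ±0.05 of the generating value (0 and 0.3) in the
acceptance suite. One pooled ρ per run is used rather than per-voxel
estimates for stability at the problem sizes the package targets.

Contrasts live on the canonical-HRF columns only: parametric outcome
(+1 on the modulation column), adaptive (+1/2 on each cue type carrying
the high relevant feature, −1/2 on each carrying the low), and aberrant
(same weights keyed to the block's subjective relabelling). Modelling cue
*types* rather than features lets both cue contrasts come from one fit;
summing the two cue types per feature level is algebraically the
feature-level contrast. `fit_first_level()` averages each contrast across
the three runs.

## Group level

`group_fit()` implements the summary-statistics random-effects model:
voxelwise regression of subject contrast values on an intercept plus a
mean-centred covariate (a block-averaged learning measure). Centring keeps
the intercept equal to the group mean effect. The covariate t and Pearson
r satisfy `t² = r²(n−2)/(1−r²)` identically, which the tests assert at
machine precision.

Familywise error is controlled by **max-statistic permutation** instead of
random-field theory: sign flipping across subjects for the mean effect
(exact under symmetric errors), covariate reshuffling for the association
effect; the corrected p of a voxel is the rank of its |t| in the null
distribution of the maximum |t| over voxels, with the (1 + k)/(1 + K)
convention. This is assumption-light and exact at desk scale, needing no
smoothness estimation; only voxel-level correction is provided —
cluster-extent inference is out of scope. Volumes of interest are 8 mm
spheres on a 3 mm isotropic grid (`sphere_mask()`), with membership decided
by voxel-centre distance.

Peak-voxel brain–behaviour correlations observed in human cohorts on this
paradigm are strong (|r| of the order 0.7–0.8); such values are **not**
reproduction targets for the synthetic pipeline, but they set the scale of
plausible effect sizes when constructing demonstration cohorts, e.g. the
test that plants a positive covariate effect at one "MTG-like" voxel and a
negative one at a "DLPFC-like" voxel and checks both survive correction
with opposite signs.

## Numerical conventions and problem sizes

* Payouts are rounded to the nearest penny and capped at [5, 100] on
  rewarded trials; 0 on non-rewarded trials.
* Rating and RT truncation: ratings clamp to [0, 100] mm; RT resampling
  gives up after 100 draws and clamps to the window.
* Degenerate statistics (zero-variance measures, zero-residual voxels) are
  flagged, never silently tested; near-constant data are detected with
  relative tolerances rather than exact zero checks.
* Test problem sizes were chosen so the whole suite runs in a few minutes
  on one core: 500-scan runs for GLM recovery and AR(1) calibration
  (50 and 100 repeats), 200 pure-noise cohorts of n = 19 at 200
  permutations and 64 voxels for the familywise-error check, a 100-subject
  cohort for parameter recovery, and 100 seeds for the schedule
  invariants.

## Known limitations

The agent is a deliberately minimal stand-in (no choice behaviour — the
SAT has none — no drift-diffusion RT model, no model fitting to real
data). The GLM omits slice timing, motion and physiological regressors,
spatial preprocessing and smoothing; designs are per-run only. Group
inference offers voxel-level max-statistic correction, not cluster-extent
or random-field methods. Repeated-measures ANOVA with sphericity
correction is left to standard statistics tooling; block effects are
probed with paired contrasts instead.
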