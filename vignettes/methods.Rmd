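---
title: "Models and methods behind timereprod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind timereprod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timereprod)
```

`timereprod` analyzes time-interval reproduction experiments: a subject
measures the duration of a stimulus (the *measurement* phase) and then
reproduces it by its own timed behavior (the *reproduction* phase), with
adaptive feedback. The package covers the behavioral statistics, the spike
density functions, the population decompositions, the response-type
categorization, and the linear time decoding used to relate prefrontal
population activity to the *regression effect* — the systematic
overestimation of short and underestimation of long intervals. Because such
recordings are large and rarely at hand, the package also ships a
synthetic-data generator that reproduces the statistical structure the
analyses assume; every stage of the pipeline is testable at desk scale.

## The task and the synthetic generator

Stimulus durations are drawn from a discrete uniform grid of seven values
between 3 and 7.5 s (spacing 0.75 s, mean 5.25 s; `stimulus_grid()`). A
reproduction is rewarded when it lands within $(1 \pm k)\,s$ of the stimulus
$s$; the tolerance $k$ narrows by 3 percentage points after a reward and
widens by 3 otherwise (`update_feedback()`). Trained animals in such
experiments reach tolerances of 15 % and below; no floor is part of the
protocol, so $k$ is simply floored at 0 — the walk cannot go negative.

**Observer model.** The generator needs reproductions with a regression
effect and scalar variability. We use a minimal shrinkage observer,

$$ m = s\,(1 + w_m z_1), \qquad
   c = \lambda m + (1-\lambda)\mu, \qquad
   r = c\,(1 + w_p z_2), $$

with standard normal $z_1, z_2$: the measurement $m$ carries a Weber
fraction $w_m$, the estimate is shrunk toward a prior mean $\mu$ (default:
the grid mean) with weight $\lambda \in [0,1]$, and production adds
multiplicative noise $w_p$. Then $E[r \mid s] = \lambda s + (1-\lambda)\mu$,
so the behavioral regression slope identifies $\lambda$, and for $w_m = 0$
the CV of $r$ given $s$ equals $w_p$ for every stimulus (scalar
variability). `optimal_lambda()` gives the shrinkage weight minimizing the
expected squared error, coupling regression strength to measurement noise
the way optimal-estimation accounts do. This observer is the package's
choice of generative stand-in — the analyses themselves fit no observer.

**Stereotype neurons.** Firing-rate profiles found in interval-timing data
are available as parametric stereotypes (`stereotype_params()`): *linear
increasing* (fixed slope, so end rates grow with duration — supports
veridical time decoding), *ramp-to-threshold* up/down (duration-dependent
slope reaching a fixed end level — encodes only the mean duration), phasic
bumps at absolute clock times or at a fixed phase of the interval,
stimulus-tuned constant rates, and task-unrelated constant noise. Spike
trains are inhomogeneous Poisson, generated by thinning against a
per-profile rate bound (`generate_spike_train()`); additive per-trial rate
noise and speed modulation are rectified at 0 Hz. Validity is tested by the
time-rescaling theorem: transformed interspike intervals must pass a
Kolmogorov–Smirnov test against Exp(1).

`generate_session()` glues these together: stimuli → observer → feedback →
per-unit Poisson spikes in both phases, with a reaction-time gap drawn
uniformly from 1–3 s between phases (such reaction times last a few
seconds and correlate only weakly with the stimulus, so the gap is modeled
as stimulus-independent, and no spikes are generated inside it). During
reproduction the profiles are parameterized by the trial's reproduced
duration (the animal times its own response); stimulus-tuned units keep
their stimulus tuning. Running speed is near zero during measurement and a
smoothed positive trace during reproduction. Premature movement during the
measurement phase has no canonical handling convention, so the simulator
simply never produces such trials.

**What the generator does not emulate:** learning across sessions,
treadmill kinematics, sequential (trial-history) effects, non-Poisson spike
statistics, and correlated noise across units. Passing tests on synthetic
data therefore certify the *pipeline* — estimator correctness, calibration,
and the stereotype predictions — not any claim about real recordings.

## Behavioral statistics

`regression_slope()` fits OLS of single-trial reproductions on stimuli
(single-trial OLS rather than a fit on per-stimulus means; both have the
same expectation, but single trials weight leverage differently).
`coefficient_of_variation()` averages the per-stimulus SD-over-mean with
equal stimulus weight, using the population SD (denominator $n$), which
matches the expectation-operator definition; stimuli with fewer than two
trials are excluded with a warning. `bias()` is the mean over stimuli of
(mean reproduction − stimulus). No behavioral trials are filtered.

## Spike density functions

`compute_sdf()` counts spikes in right-aligned ("looking into the past",
hence causal) 100 ms windows, per unit and stimulus, averaged over trials
and divided by the window width. Bins are laid out from the alignment point
(phase begin or end); the partial bin at the non-aligned edge is dropped
rather than padded. Reproduction-phase trials are first warped so each
trial's reproduced duration maps linearly onto the per-stimulus mean
(`warp_reproduction_trials()`), which preserves spike counts and removes
edge effects from response variability.

`normalize_and_zscore()` linearly interpolates every trace to a common
number of bins (default 40, roughly the 3 s stimulus at 100 ms bins; the
count is configurable) and z-scores **per unit across the concatenation of
its stimulus traces within a phase**. The per-unit scope preserves the
across-stimulus amplitude ordering that the stimulus components in the
decomposition rely on; z-scoring each trace separately would erase it.
Linear interpolation is used because rate traces are piecewise smooth and it
preserves centers of mass to first order. Constant traces z-score to zeros.

Two surrogate controls (`control_sdfs()`) support the null calibrations:
*shuffled* permutes unit identities independently per stimulus; *noise*
permutes each trace's bins over time. A causal half-Gaussian kernel
(3-bin SD, support at non-positive lags, edge-renormalized so constants stay
constant) is available for visualization only.

## Correlation battery

`correlate()` computes Pearson correlations on the normalized, z-scored
tensors in five modes (unit pairs; population vectors in corresponding bins
of the two phases; single cells across phases; population activity between
stimulus pairs; single cells between stimulus pairs). Cross-phase modes pair
the i-th normalized bin of one phase with the i-th of the other, and the
cross-phase single-cell mode concatenates all stimuli before correlating.
Each entry gets the standard t-distribution test for a Pearson correlation,
two-sided, with no multiple-testing correction — the summary of interest is
the *fraction* of significant entries, which under a true null sits at the
test level. Zero-variance traces yield undefined entries that are excluded
from fractions.

## Temporal scaling

`center_of_mass()` computes the rate-weighted mean time of a trace. Because
z-scored traces have negative values, each trace is shifted by its minimum
before weighting; the shift convention is the package's choice and is
applied uniformly to data and controls. `scaling_indices()` divides each
unit's center of mass (in seconds) by its value at the 5.25 s reference
stimulus: a perfectly time-rescaling response has indices equal to the
duration ratios, from $3/5.25 \approx 0.57$ to $7.5/5.25 \approx 1.43$,
while an absolute-clock response has indices near 1. For the reproduction
phase the time base is the mean reproduced duration, consistent with the
warping. The shuffled-identity control permutes unit labels per stimulus
before indexing.

`bootstrap_ks_scaling()` repeatedly subsamples 10 % of each index set
without replacement (matching the decomposition's bootstrap convention) and
applies the two-sample KS test, so the verdict reflects effect size rather
than raw sample count. Two numerical caveats are documented because they
shape the calibration tests: (i) the exact two-sample KS test is discretely
conservative at small subsample sizes (at 50-per-group its attainable level
is ≈ 0.035), so calibration studies use subsamples of ~150 where the level
is near nominal; (ii) all runs on one dataset share its fixed halves, so a
single dataset's significant fraction fluctuates by a few percentage points
around the level — calibration is therefore asserted on the mean over
independent populations with its own confidence interval.

## Population decomposition

`demixed_pca()` separates the units × stimuli × bins tensor additively into
a stimulus-independent time course (the mean over stimuli) and a
stimulus-dependent residual, then applies an SVD to each marginalization.
This simplified demixing — no cross-marginal regression or regularization —
is justified by the displayed *perfect demixing* of the replicated time
components (they are stimulus-identical by construction) and validated on
planted two-factor populations, where it recovers the factors with subspace
angles well under 5°; stimulus × time interaction variance is left in the
residual. Explained variances are percentages of total tensor variance, so
time components, stimulus components and residual sum to 100 %.

Sign conventions make decompositions deterministic: time components have
their largest-magnitude element positive; stimulus components are oriented
so their per-stimulus amplitudes increase with duration (the standard
display convention for stimulus-ordered components). `conventional_pca()`
provides the ordinary SVD of the full matrix, whose per-stimulus
trajectories mix time and stimulus information; `trajectory_metrics()`
summarizes them by length (summed state-space step size) and mean speed
(length over real duration). On stereotype populations these reproduce the
signature patterns: absolute-clock ramps travel at equal speed along
duration-proportional paths, time-rescaled profiles travel equal paths at
speeds inversely proportional to duration.

`bootstrap_decomp()` repeats the decomposition on stratified 10 % unit
subsets (strata: e.g. animal of origin), aligns component signs to the
full-data solution, and aggregates spread bands and the distribution of
correlations between time-PC-1 and stimulus-PC-1 scores.

## Response-type categorization

A unit's responses are reconstructed as the score-weighted sum of candidate
components (measurement: time PC 1 and stimulus PC 1; reproduction: time
PCs 1–3 and stimulus PC 1). If the reconstruction explains less variance
than a threshold (defaults 6 % and 28 % for the two phases; such gates are
conventionally set to the cumulative explained variance of the candidate
components on the dataset at hand, so they are configurable), the unit is
"unrelated activity". Otherwise
the strongest component (largest absolute score) contributes, and any other
component whose score forms an angle above 22.5° with it — operationalized
as $\arctan(|s_j|/|s_\max|) > 22.5°$, i.e. an absolute score ratio above
$\tan 22.5° \approx 0.414$ — contributes too. The absolute-value rule makes
categories invariant to component sign flips, and the category lattice over
$K$ candidates has $2^K$ members. Chance counts come from surrogates that
shuffle traces across stimuli and cells before re-running the decomposition
and categorization; `transition_table()` crosses the two phases'
assignments and derives phase-activity shares.

## Time decoding

`build_design()` stacks each unit's normalized SDFs over stimuli; the
target is *real* elapsed time, $t_i = (i/n_\text{bins})\,d_s$ seconds, so
final targets differ across stimuli — required for a meaningful final-value
regression. `fit_time_decoder()` solves the multiple linear regression
$R\beta + b = t$ by least squares (minimum-norm via pseudoinverse when rank
deficient). The bias term $b$ is part of the model: standard Wiener-filter
decoders are linear regressions with an intercept, and without it the
zero-mean (z-scored) regressors of a ramp-to-threshold population could not
read out the mean duration. To avoid overfitting, zero-mean Gaussian noise
(SD 0.5 on the z-scored scale) is added to the SDFs at fit time only.

The decoding experiments quantify the regression effect mechanically: a
pure linear-increasing population decodes time veridically (final-value
slope ≈ 1), a pure ramp-to-threshold population collapses every readout to
the mean duration (slope ≈ 0), and mixtures interpolate — the more
slope-changing cells, the stronger the regression effect
(`mixture_sweep()`). These predictions are exact for *noiseless* stereotype
tensors (`stereotype_sdf_tensor()`), which is how the package's acceptance
checks evaluate them; with Poisson sessions the same patterns hold with
finite-sampling slack. `bootstrap_decode()` fits and decodes on random
20-unit subsets and reports decoded-trajectory means ± SD and the median and
interquartile range of slopes (per-run regression, then the median —
matching the "median slopes" convention).

## Running-speed responses

`speed_response_function()` divides spike counts at each running speed
(5 cm/s bins, 10–100 cm/s) by the time spent at that speed. Significance
compares the response function's across-bin variance to a shuffle control:
spike times are circularly shifted by a uniform offset (chosen over
ISI-destroying permutations because shifts preserve interspike structure —
the conservative option), the response recomputed, and the largest-variance
shuffle of 10 retained; a one-sided two-group Levene (Brown–Forsythe)
comparison — a pooled t-test on absolute deviations from group medians —
then tests for variance *larger* than the control only. Taking the maximum
of 10 shuffles makes the procedure deliberately conservative: its null
rejection rate is essentially zero, and the ~5 % level is a property of the
underlying Levene comparison at a single shuffle, which is how the
calibration tests assess it. The modulation index contrasts mean rates in
the highest and lowest 10 % of occupied speed bins,
$(r_{90}-r_{10})/(r_{90}+r_{10})$ ("percentiles of the response function"
is read as percentiles of the speed axis). Power is occupancy-limited:
with naturalistic, narrowly distributed speeds many bins are barely
visited, so calibration studies use `ou_speed_trace()`, a smooth process
with a uniform speed marginal that gives every bin equal occupancy.

## Pipeline, seeds and problem sizes

`run_pipeline()` executes the stages in dependency order on a synthetic
session and writes CSV/JSON outputs plus a manifest. Every random stage
receives a sub-seed derived deterministically from the master seed and the
stage name, so toggling or adding stages never perturbs the others and a
config plus seed reproduces a run bit for bit. Sessions are serialized as
plain CSV (long-format spikes, trial table, speed traces).

The shipped checks run at desk scale by design: sessions of tens of units
and tens of trials for pipeline tests; 60-unit pools with 200 bootstrap
runs of 20-unit subsets for the decoding experiments; 300-unit Poisson
noise populations for correlation calibration; eight 3000-unit white-noise
populations for the KS calibration; 200 units for the speed-test
calibration; 100 seeds for the spike-generator goodness of fit. These sizes
put Monte-Carlo error comfortably inside the asserted bands while keeping
the whole suite around a minute of compute.

## Known limitations

* The demixed decomposition is the simplified marginalize-then-SVD variant;
  it is validated on planted data, not claimed identical to regularized
  demixed-PCA implementations.
* Reproduction-phase analyses use the mean reproduced duration as the time
  base (consistent with the warping); using the stimulus duration instead
  is an equally defensible convention and changes indices slightly.
* The EV thresholds for categorization are dataset-derived in real
  analyses; on synthetic data they are simply configuration values.
* The speed-significance procedure inherits the conservatism of its
  max-of-shuffles control; treat its significant fractions as lower bounds.
* HDF5 serialization is not provided; the CSV/JSON formats carry the same
  information.
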