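---
title: "Models and methods for serial dependence in orientation estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for serial dependence in orientation estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdep)
```

Serial dependence (SD) is the attraction of a current perceptual report
toward recently seen stimuli. This package implements, for
180°-periodic orientation data, the two normative models that predict how
SD should depend on sensory noise, the behavioral analysis pipeline used to
measure SD in adjustment-task data, a synthetic-experiment generator, and a
simulation-based power analysis. This vignette explains the models, the
numerical choices, and what the simulations do and do not establish.

## The orientation circle

Orientation stimuli repeat every 180°. All circular arithmetic in the
package therefore lives on a 180°-period circle, implemented internally by
doubling angles onto the full circle. `ori_diff()` returns the signed acute
difference in `[-90, 90)`; a tie at exactly 90° maps to −90 by the
half-open convention. Noise SDs quoted in degrees (6°, 9°, 12°, 16.9° …)
are orientation-degree SDs in this space. Wrapped-normal densities
(`dwrapnorm()`) are evaluated by direct wrap summation, truncated only when
the omitted terms are numerically negligible (below 1e−12 of the peak;
at least ±10 wraps), so the density integrates to one to better than 1e−6
at every usable noise level, and tends to the uniform density `1/180` as
the SD grows. `circ_mean_sd()` uses the doubled-angle resultant, so the
circular SD of wrapped-normal data recovers the generating sigma.

## Bayesian ideal observer

The observer receives on each trial a measurement $x$ of the stimulus $s$
corrupted by wrapped-normal noise with SD $\sigma$, and assumes consecutive
stimuli follow natural-scene statistics: with probability $p_\mathrm{same}$
the orientation changes smoothly according to a peaked kernel
$C(\Delta) \propto \exp(-|\Delta|^{\gamma} / 2\sigma_s^2)$, and otherwise it
is redrawn uniformly. Defaults are $\sigma_s = 16.9°$, $\gamma = 2.6$,
$p_\mathrm{same} = 0.64$. Inference is exact Bayes on a discrete grid: the
prior for trial $t$ is the previous *posterior* (not a point estimate)
circularly convolved with the transition mixture; the posterior is the
pointwise product with the wrapped-normal likelihood; the response is the
posterior's circular mean.

Numerical choices:

* **Grid inference.** The transition kernel makes the posterior
  non-conjugate, so belief is discretized on a uniform grid over
  `[0, 180)` (default step 0.5°, configurable). Tests compare the grid
  read-out against a 0.02°-resolution numerical circular mean; the
  discretization error at 0.5° is far below the degree-scale effects of
  interest.
* **Convolution by FFT** on the circular grid; the uniform mixture
  component is added analytically.
* In the sequential simulation (`simulate_bayes_session()`), measurement
  likelihoods are looked up from precomputed per-noise-level profiles at
  the nearest grid point — a 0.25° rounding, again negligible at the
  degree scale.
* Per-trial noise levels are drawn i.i.d. uniformly from
  `noise_levels`; the first trial uses a uniform prior and contributes no
  bias observation. All randomness flows from one seed.

With $p_\mathrm{same}=0$ the transition prior is uniform and the observer
is provably unbiased; the test suite checks this at $10^5$ trials. With the
default prior, the peak attraction (kernel-smoothed mean signed bias,
maximized over dissimilarity) decreases strictly in the previous trial's
noise and increases strictly in the current trial's noise — the signature
pattern the model predicts for prioritization understood as reduced
internal noise.

## The demixing model

The demixing account holds that SD arises when the observer tries to
separate the neural signals of the current and the previous item. Each of
$N$ sensory measurements is bivariate: an orientation (wrapped normal) and
a value on a non-circular "temporal" dimension (normal) that identifies
which item a measurement belongs to. Measurements come from the current
source with probability $\pi_1$ and the previous source otherwise. The
observer fits this two-component mixture by maximum likelihood and responds
with the estimated orientation mean of the component judged most recent
(larger fitted temporal mean).

Default generative settings follow the "average case": $\pi_1 = 0.5$,
shared temporal SD $\sigma_2 = 20$ with temporal discriminability
$d'_\mathrm{temp} = 1$ (temporal means at $\pm 10$; only the difference is
identified, so they are placed symmetrically), $N = 100$.

Fitting (`em_fit()`, C++ core):

* **Multi-restart EM** from random responsibility initializations
  (package default 50 restarts; the large simulation grids use 10), keeping
  the best log-likelihood.
* **M-step**: circular mean and resultant-length-to-sigma inversion for
  the orientation dimension — a standard approximation to the exact
  wrapped-normal MLE — and linear means with a pooled, shared SD for the
  temporal dimension. Because of the approximation, the log-likelihood can
  dip by a few hundredths of a unit between iterations; the `monotone`
  diagnostic flags any decrease beyond 0.05 units (none observed in stress
  tests).
* **Safeguards**: SD floors at 0.5° (orientation) and 0.5 (temporal)
  prevent component collapse; a `degenerate` flag reports floored fits;
  the mixing weight is estimated but can be pinned.
* **Convergence**: absolute log-likelihood tolerance 1e−8 with up to 500
  iterations for single fits. The simulation grids use 1e−5 and 150 —
  at that point parameter movements are far below the bias resolution —
  which matters because the grid fits hundreds of thousands of mixtures.
* **Labels** are resolved by the temporal ordering (later component
  first), which also defines the response read-out; exact temporal ties
  break toward component 1 with a warning.

EM is validated against a brute-force grid-search maximizer of the same
likelihood (orientation means on a fine grid, sigmas on a coarse grid,
evaluated with independent base-R densities): best-of-restarts EM reaches
that benchmark within 0.1 log-likelihood units on every tested instance.

`simulate_dm_grid()` sweeps current-item noise $\sigma_{1,1}$, previous-item
noise $\sigma_{1,2}$ and the orientation difference, refitting the mixture
on fresh measurements per trial. The signed response error relative to the
true current orientation, signed by the direction of the previous item,
gives the bias. Model responses are then put through the same treatment as
behavioral responses, which matters in two ways:

* **Outlier exclusion.** A small fraction of fits mislabel the components
  and read out the previous item, producing errors of tens of degrees.
  These are exactly the trials the behavioral 3-circular-SD outlier rule
  removes, so `simulate_dm_grid()` applies that rule (pooled within each
  noise pair) by default. Without it the mislabeling trials — whose rate
  grows with current-item noise — swamp the mean and hide the downturn of
  the inverted-U; with it, the inlier attraction shows the predicted
  non-monotonic pattern.
* **Kernel smoothing.** `dm_bias_amplitude()` smooths the mean-bias curve
  across the difference grid with the same Gaussian kernel (10°) the
  behavioral curves use before taking the peak, which also keeps per-cell
  Monte-Carlo noise from inflating a raw maximum.

Mean signed error in degrees is the headline statistic (matching the
degree-valued model-prediction figures); the mean sign of the bias is
emitted in parallel. The full-scale protocol (120 difference steps, 10,000
trials per cell, 50 restarts) is exposed through the function's arguments;
the package documentation and tests use a desk-scale grid (differences
every 10°, 500 trials per cell, 10 restarts), which reproduces the
qualitative structure: bias decreasing in previous-item noise, and an
inverted-U in current-item noise peaking at intermediate noise (24° when
the previous item has 60°), because as the current item's noise approaches
the previous item's the bias tips from attraction toward repulsion.

## Synthetic experiments

`generate_experiment()` emulates the statistical structure of three
designs: a single-stream streak design (648 trials per participant; pairs
of consecutively presented stimuli; one third of streaks cued for
report-and-hold-in-memory, adding a delayed re-report of the first
stimulus) and two dual-stimulus designs (720 trials; two simultaneous
stimuli with a pre- or post-cue; the reported item matches the cue on 75%
of trials). Stimuli are i.i.d. uniform; responses are the stimulus plus

* a derivative-of-Gaussian (DoG) serial bias
  $A \cdot (\Delta/w)\exp(\tfrac12 - \Delta^2/2w^2)$ toward the previous
  *reported* item (reports, not mere exposures, drive SD in the data this
  emulates), with the profile chosen by the prioritization status of that
  inducer (cue status of its streak, or previous-trial congruence),
* an optional idiosyncratic cardinal bias, modeled as a single sinusoid of
  the quadrupled orientation — the simplest orientation-dependent bias the
  preprocessing stage must remove,
* wrapped-normal response noise (default SD 9°, matching absolute-error
  levels around 7–9° typical of such tasks), and
* uniform outliers at a configurable rate.

Between-participant variability in SD strength is a normal amplitude
offset (default SD 0.5°) shared across conditions within a participant —
an assumption, as real per-participant variability of SD amplitude is not
well constrained; because it is shared, it cancels from within-participant
condition contrasts. The default width is 35°, where the empirical bias
peaks. The generator reproduces trial counts, role bookkeeping
(`response1/2/3`, target/distractor) and condition fractions, but not
timing, spatial layout, swap errors or reaction times — so passing tests
show the *pipeline* is correct and calibrated, not that real data will be
as clean.

## Bias analysis

The pipeline mirrors standard practice for adjustment-task SD analyses:

1. **Preprocessing** (`preprocess_trials()`): per participant, signed
   errors are regressed on sine/cosine of the doubled and quadrupled
   stimulus angle and the fit subtracted (cardinal-bias removal; validated
   by the property that an injected 3° cardinal sinusoid leaves < 0.3°
   residual structure). Trials beyond 3 circular SDs are excluded;
   participants with error circular SD above 30° are excluded wholesale.
2. **Signed bias** (`signed_bias()`): error times the sign of the
   direction to the inducer; positive is attraction. References can be the
   previous reported item, the previous distractor, or the first stimulus
   of the same streak. Rows whose inducer sits exactly at 0° or ±90° have
   no defined direction and are dropped with a count.
3. **Density-asymmetry curves** (`density_asymmetry_curve()`): at each
   dissimilarity step 0–90°, every trial contributes with a Gaussian
   kernel weight on the difference between its dissimilarity and the step
   (default bandwidth 10°; the kernel and bandwidth are package choices,
   exposed in the configuration). The weighted mean of the *sign* of the
   bias estimates the excess probability of erring toward versus away from
   the inducer (in [−1, 1]); a parallel weighted mean keeps degrees.
   Asymmetry CIs are bootstrapped over trials.
4. **Tests**: per-participant means with one-sample t-tests
   (`mean_bias_test()`); per-degree one-sample t-tests per condition and a
   repeated-measures ANOVA across conditions at each degree
   (`per_degree_condition_tests()`), with maximal contiguous significant
   runs reported as descriptive clusters — deliberately with no correction
   across the 91 steps, matching how such cluster ranges are reported;
   `peak_location()` finds the curve maximum with boundary and flatness
   flags. Incongruent–incongruent trial pairs are dropped from congruence
   contrasts (they are rare by design).

Mean-bias values in asymmetry units and model predictions in degrees are
*not* interconvertible; both are always emitted and never mixed.

## Power analysis

`estimate_power()` repeats, for each of `n_sims` seeds: generate a full
synthetic dataset in which the planted DoG amplitude differs by
`effect_difference` (default 1°) between prioritized and unprioritized
inducers around a 2° baseline; fit per-participant per-condition amplitudes
by least squares with the width profiled on a grid and shared across
conditions within a participant (sharing stabilizes a 1° contrast); apply a
paired t-test (streak design) or a three-level repeated-measures ANOVA over
the congruence conditions (congruent–congruent, congruent–incongruent,
incongruent–congruent); and count rejections at `alpha`. Power is the
rejection proportion with an exact binomial CI. Response noise defaults to
9° circular SD and the baseline amplitude to 2° — both calibrated to the
absolute-error levels such experiments report, both exposed in the
configuration, and both assumptions rather than measurements.

Null calibration (zero effect rejects at the alpha rate) and monotonicity
in effect and sample size are tested at reduced design sizes. At the full
streak-design size (18 participants × 648 trials, 1° effect) the estimated
power is about 0.94. For the dual-stimulus congruence design the same
procedure yields markedly lower power (about 0.7–0.8 at 18 × 648): the
75/25 congruence split leaves only ~19% of trials in each incongruent
condition, which inflates the ANOVA error term. A design that allocated
conditions evenly, or an effect spread across two of three conditions
differently, would raise it; the package reports what the stated design
produces.

## Known limitations

* The wrapped-normal M-step is approximate (see above); exact
  wrapped-normal MLE would remove the 0.05-unit monotonicity slack at
  substantial cost.
* The demixing grid's amplitude estimate takes a maximum over a finite
  difference grid; with 10° steps the peak location is resolved no finer
  than that.
* The generator's outlier process is uniform; real lapses and swap errors
  have richer structure.
* Per-degree inference is descriptive by design; a cluster-mass
  permutation test is a natural extension and deliberately not the
  default.
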