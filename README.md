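# serialdep

Serial dependence (SD) is the attraction of a current perceptual report
toward recently seen stimuli: when people reproduce the orientation of a
grating, their response is pulled a degree or two toward the orientation
they saw on the previous trial, most strongly when the two differ by an
intermediate angle (~35°). `serialdep` is an R package for researchers in
visual psychophysics and computational cognitive modelling who study this
bias in orientation-adjustment tasks. It provides, on the 180°-periodic
orientation circle:

* **Circular primitives** — signed acute differences, wrapped-normal
  densities and sampling, doubled-angle circular means and SDs.
* **A Bayesian ideal observer.** Measurements follow
  $p(x \mid s) = f_{WN}(x; s, \sigma^2)$; consecutive stimuli are assumed
  related by a natural-statistics transition prior
  $p(s_t ; s_{t-1}) = p_\text{same}\, C(s_t; s_{t-1}, \sigma_s, \gamma) +
  (1 - p_\text{same})\, U$, with
  $C \propto \exp\left(-|\mathrm{angle}(s_t, s_{t-1})|^{\gamma} / 2\sigma_s^2\right)$.
  The observer carries the previous posterior forward through this kernel
  and responds with the posterior circular mean. Attraction increases when
  the previous trial was less noisy and decreases when the current trial
  is less noisy.
* **The demixing model.** Each trial yields $N$ bivariate measurements
  (orientation × a non-circular "temporal" dimension) from a two-component
  mixture — current and previous item. The observer demixes by maximum
  likelihood, $\hat\theta = \arg\max L(\theta; \mathbf{x})$ (multi-restart
  EM with a C++ core), and reports the orientation mean of the temporally
  later component. Bias falls with previous-item noise but follows an
  inverted U in current-item noise.
* **A synthetic-experiment generator** for three adjustment-task designs
  (single-stream streaks with report-and-hold cues; dual-stimulus pre- and
  post-cue designs) with a planted derivative-of-Gaussian bias, optional
  cardinal bias and outliers.
* **The bias-analysis pipeline** — cardinal-bias removal, outlier and
  participant exclusion, kernel-weighted density-asymmetry curves,
  per-degree t-tests and repeated-measures ANOVAs with descriptive cluster
  reporting, and peak localization.
* **Simulation-based power analysis** for these repeated-measures designs.

See `vignettes/serial-dependence-methods.Rmd` for the models, parameter
meanings, numerical choices and limitations.

## Worked example

Generate a streak-design experiment in which cued (held-in-memory)
inducers plant a 3° bias and uncued inducers 2°, then run the pipeline:

```r
library(serialdep)

d <- design_spec("exp1", n_participants = 18)      # 648 trials each
profiles <- list(cued   = sd_profile(amplitude = 3, width = 35),
                 uncued = sd_profile(amplitude = 2, width = 35))
tt <- generate_experiment(d, profiles, noise_spec(response_sd = 9), seed = 1)

pp <- preprocess_trials(tt)                         # cardinal bias + outliers
b  <- signed_bias(pp)                               # + = attraction to inducer
b  <- b[!is.na(b$inducer_cued), ]
b$cond <- ifelse(b$inducer_cued, "cued", "uncued")

mean_bias_test(b, "cond")$tests
#>   condition  n mean_asym mean_deg         t df            p degenerate
#> 1      cued 18 0.1771384 1.892975 10.725406 17 5.494373e-09      FALSE
#> 2    uncued 18 0.1009677 1.083922  8.549299 17 1.460854e-07      FALSE

per_degree_condition_tests(b, "cond", value = "mean_deg")
#> Per-degree condition tests (mean_deg curves, bandwidth 10.0 deg, alpha 0.05)
#> Conditions: cued, uncued
#> Clusters (maximal runs of per-degree significance):
#>   condition start end  direction
#> 1      cued     0  90 attraction
#> 2    uncued     0  84 attraction
#> 3     anova    15  76 difference

peak_location(density_asymmetry_curve(b, n_boot = 100), value = "mean_deg")
#> $peak_at    [1] 34
#> $peak_value [1] 2.02

tapply(fit_dog_amplitudes(b, "cond")$amplitude, fit_dog_amplitudes(b, "cond")$condition, mean)
#>     cued   uncued
#> 3.119203 1.812342
```

Both planted amplitudes are recovered (3.12° vs 1.81°), the attraction
peaks at 34° (planted width 35°), the per-participant mean bias is
reliably positive in both conditions, and the repeated-measures ANOVA
localizes the cued-vs-uncued difference to intermediate dissimilarities —
the same cluster-style readout used on real adjustment data. `mean_asym`
is the density-asymmetry statistic (probability of erring toward minus
away from the inducer); `mean_deg` is the same bias in degrees.

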