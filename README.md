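# ratesync

Simulation and analysis pipeline for auditory rate-discrimination
psychophysics and its modulation by auditory–motor coupling.

Listeners discriminate the rate of two isochronous tone sequences with a
roughly constant *relative* threshold
`d = (rate_comparison − rate_standard) / rate_standard` at slow (theta-range)
rates, but the threshold rises at faster rates. Individuals whose whispered
speech spontaneously synchronizes with a heard syllable train ("high
synchronizers", a behavioral proxy for auditory–motor cortical coupling)
keep low thresholds up to higher rates than "low synchronizers". `ratesync`
implements the complete computational chain used to study this:

* **Weighted up-down staircase** (`run_staircase()`): adaptive 1-down/3-up
  threshold measurement at 8 standard rates (4–15 Hz), converging on the
  75%-correct level (`p·s = (1−p)·3s ⇒ p = 3/4`); threshold = mean of the
  last six of 18 reversals.
* **Psychometric validation** (`fit_psychometric()`): method of constant
  stimuli (7 levels at 0.2–3× the staircase threshold, 30 trials/level),
  Weibull fit `p(d) = 0.5 + (0.5 − λ)·F(d; m, w)` with fixed 0.5 guess
  rate, and a parametric-bootstrap deviance goodness-of-fit.
* **Synchronization scoring** (`windowed_plv()`, `cluster_synchronizers()`):
  phase-locking value `|mean(exp(i(φa − φb)))|` between stimulus and
  produced-speech envelope phases (100 Hz resampling, 3.5–5.5 Hz zero-phase
  band-pass, Hilbert phases, 5-s windows with 2-s overlap), then 2-means
  clustering of mean PLVs into high/low synchronizers.
* **149-model Bayesian comparison** (`compare_models()`): log-normal
  threshold models `D ~ LogNormal(log(μj + x_kj·βj), σ²)` over five
  families (constant, group baseline, linear increase with group-specific
  onset, increase + baseline, increase + slope; 7×7 onset pairs per
  increase family), truncated-normal/uniform priors, marginal likelihoods
  by deterministic quadrature (default) or adaptive-Metropolis MCMC with
  bridge sampling, posterior model probabilities under the uniform 1/149
  prior, and posterior-odds evidence ratios `BF = p/(1−p)`.
* **Synthetic cohorts** (`generative_spec()`, `draw_threshold_dataset()`,
  `synth_sync_pair()`): generators whose defaults are the study conditions
  (35 high / 20 low synchronizers; baseline 4.48%, slope 1.44% per grid
  step, onsets 8.71/11.86 Hz; PLV clusters at 0.74/0.34), so every stage is
  testable without human data.

The methods vignette
(`vignettes/rate-discrimination-and-synchronization.Rmd`) documents the
models, parameterizations, numerical choices, and limitations.

## Worked example

```r
library(ratesync)

# a synthetic cohort at the default study conditions
truth <- draw_threshold_dataset(generative_spec(), seed = 11)

# measure one participant's threshold at 4 Hz with the staircase
obs <- make_observer(truth$threshold[1], lapse = 0.02)
est <- run_staircase(obs, staircase_config(start_value = 0.20), seed = 1)
c(true = truth$threshold[1], measured = est$threshold, trials = est$n_trials)
#>       true   measured     trials
#> 0.03333782 0.03541667 60.00000000

# the full 149-model battery on the cohort's true thresholds
cm <- compare_models(truth)
round(cm$family_probs, 4)
#>                    null          group_baseline                increase
#>                  0.0000                  0.0000                  0.9408
#> increase_group_baseline    increase_group_slope
#>                  0.0149                  0.0444
cm$best$id                                        # M33
round(cm$onset_event_probs$p_onset_low_earlier, 3) # 0.997

fit_parameters(truth, model_spec("increase", onset_high = 6, onset_low = 4))
#>   parameter       mean      lower      upper
#> 1        mu 0.04406521 0.04150440 0.04652173
#> 2      beta 0.01482425 0.01249754 0.01708938
#> 3    sigma2 0.24038013 0.20906688 0.27749597
```

The battery recovers the generating structure: the increase family wins
(posterior 0.94), the winning model is the generating one (onsets 11.86 Hz
high / 8.71 Hz low), the onset of the threshold increase is earlier in low
synchronizers with probability 0.997, and the 95% posterior intervals cover
the generating values (μ = 4.48%, β = 1.44%, σ² = 0.25).

The numbered scripts under `analysis/` run the whole study pipeline —
simulate cohort → staircase thresholds → constant-stimuli validation →
PLV + clustering → exclusions → model comparison → correlation report —
writing their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_staircase_thresholds.R
Rscript analysis/03_psychometric_validation.R
Rscript analysis/04_sync_clustering.R
Rscript analysis/05_model_comparison.R
Rscript analysis/06_report.R
```

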