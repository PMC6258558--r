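# plumecoding

Tools for testing the efficient coding hypothesis on the temporal
statistics of turbulent odor plumes, as experienced by moth olfactory
receptor neurons (ORNs).

## The problem

Downwind of a pheromone source, turbulence breaks the odor signal into
*whiffs* (odor present) and *blanks* (clean air). At distance *d* from a
source of size *a*, in wind *U* with fluctuations *δU* and intermittency
*χ*, blank and whiff durations follow truncated power laws

    f_B(x) = x^(-3/2) / [2 (1/√τ − 1/√T_B)],   x ∈ [τ, T_B]

with τ = a²d/[d(δU)²] the shortest duration, T_W = d/U the longest whiff
and T_B = T_W(1/χ − 1) the longest blank. An ORN encodes a whiff encounter
through its spike count in a short post-onset window as a function of the
preceding blank duration (the *duration-rate relationship*). Efficient
coding predicts the neuron's coding accuracy — the Fisher information

    F(s) ≈ γ′(s)² / σ²(s),   s = log10(blank duration)

where γ is the mean duration-response curve and σ² the response variance —
to be allocated to the blank durations that actually occur at the local
distance: the mode of F(s) should align with the mode of the blank
distribution, the average accuracy ⟨F⟩ = ∫ F(s) f(s) ds should be tuned to
the local statistics, and in the many-sensor regime the optimal stimulus
distribution is the Jeffreys prior p_J(s) ∝ √F(s).

The package implements the full chain:

* **Plume simulation** — closed-form densities, quantiles and an
  inverse-transform sampler for the duration distributions;
  whiff/blank sequence generation with the 30 s whiff cap at 64–128 m
  (`plume_params`, `derive_timescales`, `generate_sequence`).
* **Synthetic ORN recordings** — parametric encoders with known ground
  truth, including a Jeffreys-matched construction whose Fisher
  information is exactly c²·f(s)², plus Poisson spike-train simulation
  (`make_saturating_encoder`, `make_jeffreys_matched_encoder`,
  `simulate_recording`, `simulate_population`, `analytic_fisher`).
* **Latency estimation** — the nonparametric estimator based on the
  empirical CDFs of pre- and post-onset spike intervals
  (`collect_intervals`, `estimate_latency`).
* **Encoding-model fit** — spike counts in the latency-corrected 150 ms
  window, cubic smoothing spline mean with smoother trace ≈ 3, robust
  (IQR/1.349)² segment variances smoothed by tricube local-linear
  regression (`extract_responses`, `pool_samples`, `fit_encoding_model`).
* **Efficiency analysis** — Fisher profiles, mode alignment, average
  Fisher information under matched/mismatched statistics, Jeffreys prior
  and quantile comparison (`fisher_profile`, `average_fisher`,
  `matched_vs_mismatched`, `jeffreys_prior`, `qq_compare`,
  `mode_correlation`).
* **I/O and orchestration** — plain-text recording/sequence formats,
  validated study-design keys, and a deterministic multi-group pipeline
  (`read_recording`, `run_config`, `run_pipeline`, `run_condition`).

## Worked example

One synthetic condition at 8 m, end to end — simulate a Jeffreys-matched
ORN population, estimate the latency, fit the encoding model, and compare
the estimated Jeffreys prior with the true blank distribution:

```r
library(plumecoding)

params <- plume_params(d = 8)
derive_timescales(params)
#> Timescale bounds: tau = 1 s, T_W = 8 s, T_B = 12 s

res <- run_condition(distance = 8, dose = 1e-2, seed = 42,
                     target_samples = 2000)
res$latency
#> Latency estimate: theta_hat = 0.0258 s (t_tilde = 0.0965 s, n = 3008 pairs)
res$fit
#> Duration-rate fit: n = 2411, trace = 3.00, support = [0.000, 1.078] log10 s
res$profile
#> Fisher profile on [0.000, 1.078] log10 s: mode at 0.000, max F = 72.5
res$qq
#> QQ comparison over 99 levels: max |predicted - real| = 0.0180 log10 units
```

The injected 26 ms latency is recovered as 25.8 ms; the penalty of the
smoothing spline lands on the target trace of 3; the Fisher-information
mode falls at s = 0.000, exactly the blank-distribution mode log10(τ) = 0;
and the estimated Jeffreys prior tracks the true blank-duration
distribution to 0.018 log10 units across its quantiles — the
efficient-coding signature the construction embeds.

The methods vignette (`vignettes/plume-coding-methods.Rmd`) documents the
model, the estimator conventions, the chosen study conditions, and known
limitations.

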