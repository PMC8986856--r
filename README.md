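# spthmm

Diffusion-state hidden Markov models for live-cell single-particle
tracking, built for quantifying mRNA-binding kinetics of bacterial
ribosomal subunits.

## The problem

In sparse-labeling tracking experiments, a ribosomal subunit engaged on an
mRNA diffuses slowly (apparent D ≈ 0.03–0.06 µm²/s) while a free subunit
diffuses an order of magnitude faster (≈ 0.3–0.7 µm²/s). Trajectories are
short (tens of frames), positions carry localization error, illumination is
stroboscopic (a 3 ms pulse inside a 30 or 60 ms frame), and linkers bridge
single-frame detection gaps. From such data one wants the steady-state
fraction of subunits engaged in translation and the mean dwell times in the
mRNA-bound and free states — dwell times far longer than any single
trajectory.

`spthmm` does this in four stages:

1. **Emission model.** Per-step displacements are zero-mean Gaussians per
   dimension with variance
   `2 D (nΔt) (1 − 2R/n) + σᵢ² + σⱼ²`, where `n ∈ {1,2}` is the number of
   frames spanned (2 across a gap), `R = t_pulse/(6Δt)` is the motion-blur
   coefficient, and `σ` are the per-spot localization uncertainties.
2. **Fitting.** `fit_hmm()` runs EM (vectorized forward–backward, exact
   gap handling via the two-frame transition matrix A²) for a pre-set
   number of diffusion states K; `fit_hmm_sizes()` sweeps K = 2–11, with
   AIC = 2k − 2 ln L for comparison.
3. **Coarse-graining.** States with D < 0.25 µm²/s are labeled mRNA-bound,
   the rest free. Aggregate occupancy sums the stationary law π of the
   fitted per-frame transition matrix; the aggregate dwell time is
   τ = Δt/(1 − p_stay) with p_stay the occupancy-weighted within-aggregate
   transition mass. Estimates are averaged over model sizes 7–11 with
   weighted standard deviations and bootstrap standard errors
   (trajectory-level resampling, warm-started refits).
4. **MSD analysis.** `D_distribution()` cuts trajectories into 7-position
   gap-free segments and fits MSD(t) = 2nDΔt·t through the origin at lags
   1–3, giving the distribution of apparent diffusion coefficients.

A ground-truthed simulator (`simulate_dataset()`, presets in
`scenario_config()`) generates datasets with the same statistical
structure — Markovian state switching, sub-step blur emulation,
localization noise, geometric track lengths, single-frame gaps, optional
spherocylindrical confinement — so every stage is testable without
microscopy data.

## Worked example

Simulate the untreated-50S scenario at study scale (3000 tracks, mean 40
frames, 30 ms frames, ground truth: bound 23.3 s at 0.05 µm²/s, free 1.6 s
at 0.4 µm²/s), then recover the kinetics (about half a minute):

```r
library(spthmm)

sim    <- simulate_dataset(scenario_config("50S_untreated",
                                           n_trajectories = 3000, seed = 1))
tracks <- filter_trajectories(sim$set, min_steps = 10)
tracks
#> Trajectory set: 2349 trajectories, 106459 steps total (dt = 0.03 s)

models <- fit_hmm_sizes(tracks, K_range = 2:4, n_restarts = 2,
                        tol = 1e-7, max_iter = 500)
models$K2
#> 2-state diffusion HMM (R = 0.01667)
#>   D_um2_s occupancy stay_prob
#> 1 0.05002   0.93830    0.9986
#> 2 0.39590   0.06174    0.9794
#> logLik = 240120.3737, n_params = 4, AIC = -480232.7475

summary <- do.call(rbind, lapply(models, coarse_grain,
                                 dt = 0.03, threshold = 0.25))
summary
#>    K occupancy_bound occupancy_free tau_bound tau_free
#> K2 2       0.9382575     0.06174246  22.09595 1.454034
#> K3 3       0.9391696     0.06083039  23.57079 1.526690
#> K4 4       0.9393404     0.06065964  23.60778 1.524516

round(weighted_model_average(summary)$mean, 4)
#> occupancy_bound  occupancy_free       tau_bound        tau_free
#>          0.9389          0.0611         23.0915          1.5017

D_distribution(tracks)
#> MSD result: 12395 segments, mean apparent D = 0.0875 um2/s, median = 0.06257 um2/s
```

The fitted state diffusion coefficients (0.050 / 0.396 µm²/s), the bound
occupancy (93.9%, truth 93.6%), and the dwell times (23.1 s / 1.50 s,
truth 23.3 s / 1.6 s) recover the generating kinetics; the mean apparent D
of ≈ 0.09 µm²/s is what short-segment MSD reports for a population that is
>90% slow — consistent with apparent diffusion near 0.1 µm²/s for
ribosomal particles.

`run_full_analysis()` drives the same workflow (plus AIC table, bootstrap
errors, threshold-sensitivity table, JSON/CSV outputs) from a single
config; `inst/scripts/spthmm-pipeline.R` wraps it for the shell.

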