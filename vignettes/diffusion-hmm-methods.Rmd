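---
title: "Diffusion-state HMMs for single-particle tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-state HMMs for single-particle tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spthmm)
```

## The problem

In live-cell single-particle tracking of bacterial ribosomal subunits, a
sparsely labeled population is imaged with stroboscopic laser illumination
(a few-ms pulse inside each 30 or 60 ms camera frame), localized, and linked
into trajectories of a few tens of frames. A subunit engaged on an mRNA
diffuses slowly (apparent D of a few 0.01 µm²/s, set by the mRNA, polysome
and chromosome context), while a free subunit diffuses an order of magnitude
faster. Because binding and release are much slower than the frame time,
each trajectory samples a hidden, piecewise-constant diffusive state
sequence. `spthmm` estimates the state diffusion coefficients, the per-frame
transition matrix, and from it the steady-state occupancies and mean dwell
times of the mRNA-bound and free populations.

## Emission model

The data enter as per-step displacements. Given the hidden state with
diffusion coefficient $D$, a displacement observed between two
localizations $n \in \{1, 2\}$ frames apart ($n = 2$ spans a single-frame
tracking gap) is modeled per dimension as a zero-mean Gaussian with variance

$$\mathrm{Var} = 2 D (n\,\Delta t)\left(1 - \frac{2R}{n}\right)
  + \sigma_i^2 + \sigma_j^2 ,$$

where $\sigma_i, \sigma_j$ are the per-spot localization uncertainties and
$R$ is the motion-blur coefficient. For a square illumination pulse of
duration $t_p$ within a frame of length $\Delta t$,
$R = t_p / (6 \Delta t)$ — $1/6$ for continuous illumination, $1/60$ for a
3 ms pulse in a 30 ms frame (`blur_coefficient()`).

Two approximations are deliberate and documented:

* **Neglected blur/noise-induced correlation.** Motion blur and
  localization error both induce a negative correlation between
  *consecutive* displacements ($-\sigma^2$ from shared endpoints, plus an
  $O(R)$ blur term). The likelihood treats steps as conditionally
  independent given the state path. For stroboscopic acquisition
  ($R = 1/60$) the neglected blur covariance is at most a few percent of
  the step variance; the $\sigma^2$ cross-covariance is more substantial
  for the slow states, and is the main reason recovered kinetics carry
  extra variance relative to an exact filter. The $R$ parameter is kept so
  continuous-illumination data degrade gracefully.
* **No confinement in the likelihood.** The cell envelope restricts free
  diffusion; this is folded into the *apparent* state D rather than
  modeled, matching how state D values are interpreted downstream.

## Fitting

`fit_hmm()` maximizes the joint likelihood of all trajectories (pooled
across cells and experiments, conditionally independent) by EM:

* **E-step.** Scaled forward–backward per trajectory, vectorized across
  trajectories in step-major order. A gap step uses the two-frame
  transition matrix $A^2$ and the $n = 2$ emission variance.
* **M-step, transitions.** Expected transition counts; for $A^2$ links the
  count is distributed over the latent mid-frame state
  ($P(i \to k \to j \mid i, j) = A_{ik}A_{kj}/(A^2)_{ij}$), which keeps the
  update an exact EM step on the augmented chain.
* **M-step, diffusion coefficients.** Per-spot $\sigma$ heterogeneity
  breaks the closed form, so each $D_k$ is updated by a bounded Brent
  search (steps grouped by identical $(n, \sigma^2)$ pairs; with a single
  group the exact closed form $\hat v = \sum \gamma r^2 / 2\sum\gamma$ is
  used). The update is guarded to never decrease the EM objective.
* **Initial distribution.** During fitting the initial-state distribution
  is a free parameter shared across trajectories, so the EM objective is
  exactly monotone (the package's property tests assert this). The
  *reported* model sets `pi` to the stationary distribution of the fitted
  per-frame transition matrix — occupancy means steady-state fraction —
  and the reported log-likelihood re-scores the data with that stationary
  initial law, which is also what `trajectory_loglik()` computes. The free
  initial distribution is a nuisance parameter and is not counted in
  `n_params` ($K$ diffusion coefficients plus $K(K-1)$ free transition
  entries), the count used for AIC.

Numerical choices: $D$ initialized log-spaced on 0.005–5 µm²/s; transition
matrix initialized at 0.9 on the diagonal; restarts jitter $D$
multiplicatively (lognormal, 20%), seeded; convergence at relative
log-likelihood change below `tol` (default $10^{-8}$) or `max_iter` (2000),
with non-convergence flagged in metadata; $D$ floored at $10^{-6}$ µm²/s to
avoid the zero-variance degeneracy when $\sigma$ terms exceed the observed
variance; states sorted by ascending $D$ so output is deterministic up to
label symmetry. The EM internals (restart count, tolerances, optimizer) are
this package's pragmatic choices and are all surfaced in `fit_options()`.

`stationary_distribution()` rejects reducible transition matrices (naming a
closed communicating block) since the stationary law is then non-unique;
periodic but irreducible chains are accepted, because a finite irreducible
chain has a unique stationary vector regardless of periodicity — and
fitted matrices, built from strictly positive posterior counts, are always
aperiodic in practice.

`bruteforce_loglik()` — exact path enumeration, capped at $K^{steps} \le
10^6$ — exists purely as an independent oracle; the test suite checks
forward/enumeration agreement to $10^{-9}$ relative on randomized small
instances.

## Coarse-graining and dwell times

The bound state is not one diffusion rate but a continuum (polysomes,
chromosome tethering, membrane translocons), so models of many sizes are
fitted (conventionally 2–11) and collapsed to two functional aggregates by
thresholding the state D at 0.25 µm²/s (strictly below = bound; the
threshold value is validated upstream by initiation-inhibition controls).
Fitting many states first also lets the aggregate dwell time be
non-exponential even though each hidden state is.

For an aggregate $S$, the stay probability is the occupancy-weighted
within-aggregate transition mass and
$\tau_S = \Delta t / (1 - p_{stay})$; for a single-state aggregate this is
the familiar $\Delta t/(1 - A_{ii})$. Because $\tau$ comes from per-frame
stay probabilities rather than observed sojourns, dwell times much longer
than any single trajectory are estimable. Dwell times below $\Delta t$
cannot occur; an absorbing aggregate yields `Inf` with a warning.

Per-condition estimates average model sizes 7–11 (`coarse_grain_config()`),
where occupancies and dwell times have converged in model size. The
averaging weights are not prescribed by convention; the default is inverse
bootstrap variance per size, falling back to equal weights when the
bootstrap is disabled, and the scheme used is recorded in the output.
Bootstrap errors resample *trajectories* (the exchangeable unit of the
pooled fit) with replacement and refit warm-started from the full-data fit
(a from-scratch refit per replicate would cost restarts × iterations for
no measurable change in the spread); replicates that fail to converge or
whose coarse-graining degenerates are dropped and counted, with more than
20% dropped treated as an error.

## MSD analysis

`D_distribution()` reproduces the standard apparent-D summary: trajectories
are cut into non-overlapping 7-position gap-free segments ("cut into
segments" read as a partition — overlapping windows would correlate the
distribution), the MSD at lags 1–3 is the time average over all in-segment
pairs at each lag (the usual convention; disjoint-pair averaging would
discard most of a 7-point segment), and an unweighted least-squares line
through the origin is fitted to $\mathrm{MSD}(t) = 2 n D \Delta t\, t$
with $n = 2$. No noise, blur or confinement correction is applied: the
result is deliberately the *apparent* D, comparable across conditions.
With non-negative MSD values and positive lags the origin-constrained
slope is non-negative, so apparent D is never negative.

## The simulator

`simulate_dataset()` generates the statistical structure the analysis
assumes, with known ground truth:

* Markovian state switching at frame boundaries, with the per-frame chain
  built from mean dwell times via $A_{ii} = 1 - \Delta t/\tau_i$
  (`transition_matrix_from_dwells()`); the state is frozen within a frame.
  Mid-frame switching and non-exponential sojourns are *not* emulated —
  a documented limitation, and exactly the regime the per-frame HMM
  assumes.
* Brownian motion integrated in 20 fine sub-steps across the illumination
  pulse, with the observed position the average of midpoint samples —
  converged blur emulation for $R \le 1/6$ (midpoint sampling makes the
  discretization error $O(m^{-2})$).
* Gaussian localization noise, per-spot σ from a constant or lognormal
  law. Default: constant 0.035 µm, typical for organic-dye tracking at
  these exposures; configurable because real per-spot uncertainty
  distributions vary.
* Geometric track lengths (memoryless photobleaching), minimum 2 frames,
  default mean 40 frames; single-frame detection gaps at
  `gap_prob = 0.05` per interior frame, never two in a row.
* Optional reflecting spherocylinder (default 3 × 0.5 µm half-width,
  E. coli-like) applied sub-step-wise; off by default so the analytic
  moment checks hold exactly.

Scenario presets (`scenario_config()`) encode the reported two-state
kinetics per experimental condition — e.g. untreated 50S: bound 23.3 s,
free 1.6 s at 30 ms frames — with bound/free D of 0.05/0.4 µm²/s
representative of the reported state continuum. Two conditions are not
printed as single numbers in the source estimates: the AtaT-treated 30S
bound time (preset uses 30.0 s, between the untreated 28.1 s and
KSG-treated 31.3 s) and the orthogonal-30S bound time (preset uses 8.0 s
from the reported 7–9 s range). Preset occupancies follow from the dwell
times (bound fraction $\tau_b/(\tau_b+\tau_f)$), which for the untreated
conditions reproduces the reported >93% engaged fraction.

What passing tests on simulated data do **not** show: robustness to
detection/linking artifacts, drift, out-of-focus loss, non-Markovian
binding, or mid-frame switching — none of which the simulator emulates.

## Problem sizes and reproducibility

The recovery analyses use 3000 trajectories of mean 40 frames (about
10⁵ steps after the ≥ 10-step filter) and model sizes 2–4 with 2 restarts —
sizes at which the two-state kinetics are identifiable while a full run
stays at desk scale; the per-seed spread of the recovered bound dwell time
at this size is roughly ±10%. The pipeline derives all stage seeds
deterministically from one global seed (simulation: `seed`; fitting:
`seed + 100 + K`; bootstrap: `seed + 200 + K`), so identical configs give
byte-identical reports and changing only bootstrap settings leaves fitted
models untouched.

## Known limitations

* The independent-step emission approximation (above) inflates estimator
  variance when $\sigma^2$ is comparable to $2D\Delta t$, as it is for the
  bound state at 30 ms frames.
* Occupancy is reported as the stationary law of the fitted transition
  matrix; with very rare transitions (bound dwell ≫ track length) this
  estimator is noisier than the posterior step-fraction, which is also
  computed and kept in the fit metadata (`posterior_occupancy`).
* A single model is shared across all cells; per-cell heterogeneity is
  averaged over.
* 2-D tracking only; axial motion is folded into apparent D.
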