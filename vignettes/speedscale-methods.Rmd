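---
title: "Speed-scale channel analysis of ocular following: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-scale channel analysis of ocular following: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedscale)
library(dplyr)
```

This vignette is the package's account of the science it implements: the
stimulus generative models, the behavioural analysis chain, the dynamic
probabilistic decoding model, and the synthetic cohorts that make the whole
pipeline testable without access to laboratory eye-movement recordings. It
also records the numerical conventions and the design decisions taken where
the problem was genuinely open.

## The stimulus space

Motion stimuli live in the plane of spatial frequency (sf, cycles/deg) and
temporal frequency (tf, Hz), analysed throughout on base-2 logarithmic axes
(octaves). Two diagonal coordinates organise the plane: the *speed*
direction, along which `v = tf/sf` is constant (an iso-velocity line), and
the orthogonal *scale* direction, indexed by the product `s = tf·sf`. A
drifting grating (DG) is a single point in this plane; a motion cloud (MC)
is a broadband texture built from dense random-phase Gabor elements whose
spatial frequencies and speeds follow log-normal distributions — an oblique
ellipse of motion energy oriented along its iso-velocity line.

The packaged catalog holds 15 components (sf 0.125–2 c/°, tf 4.15–34.7 Hz,
five speeds from ~11 to ~53 deg/s) and 9 patterns of 2–3 superimposed
components, with the printed relative geometry: distances from the
reference component c1 in *grid units* (one unit = the nearest-ring lattice
spacing, the c1→c5 log distance), polar angles, pattern spans and
orientations. `relative_geometry()` and `pattern_geometry()` recompute all
of these from the frequency coordinates; because both axes share one log
base, angles and normalized distances are base-invariant. A pattern's
catalog "mean speed" is reproduced by the *median* component speed (the
central component for symmetric triplets, the pairwise mean for pairs); the
arithmetic mean does not reproduce the printed triplet values.

All MCs share fixed distribution parameters: vertical orientation (90°),
15° orientation spread, 1-octave FWHM bandwidths in sf and speed, and 60%
RMS contrast. `fwhm_to_sigma()` converts the quoted FWHM bandwidths to
Gaussian SDs (`sigma = fwhm / (2 sqrt(2 ln 2))`).

### Spectral envelopes

`mc_envelope()` discretizes the energy density on a rectangular lattice
(default 64×64 nodes spanning ±3 octaves around the component centre): a
product of Gaussians in `log2 sf` and `log2 v`, sheared to the
(log2 sf, log2 tf) plane via `log2 tf = log2 sf + log2 v`, with mass
normalized to 1. The orientation dimension is marginalized out — the
decoding model is two-dimensional in frequency — while movie synthesis
retains it. `dg_envelope()` puts all mass on the nearest node and keeps the
exact coordinates so the model can bypass the lattice. Pattern envelopes
are node-wise *means* of their component envelopes (matching the model's
averaged pattern drive); the pixel-domain sum-then-rescale composition is
kept separately in `synthesize_movie()`.

### Movies

`synthesize_movie()` builds desk-scale realizations: DGs as the analytic
drifting sinusoid, MCs as a direct sum of `n_elements` drifting Gabor
elements with characteristics sampled from the envelope distributions and
uniform random phases (the streaming autoregressive implementation used
for experimental presentation is deliberately not reproduced). Elements
are energy-normalized (amplitude ∝ sf) so the realized power spectrum
follows the sampled envelope distribution rather than being dominated by
the large-envelope low-frequency elements; final frames are rescaled to
the target RMS contrast exactly. `movie_power_concentration()` measures
spectral fidelity with Hann windows in space and time (rectangular-window
leakage otherwise dominates at desk scale) inside the box spanning ±1
octave in radial sf and in speed — the two axes along which the envelope
is parameterized. At the test configuration (200 elements, 32×32 pixels,
1 s at 100 Hz) concentrations are typically 0.90–0.95; the irreducible
ceiling is ~0.96 because the stimulus itself has 1-octave bandwidths.

## Eye-trace preprocessing and window statistics

`preprocess_trials()` follows the standard OFR chain: eye position
low-pass filtered (5th-order Butterworth, 40 Hz), differentiated by
central difference with positions 10 ms apart (one velocity estimate per
ms), velocity filtered again at 30 Hz, and leftward-motion trials
sign-inverted. Filters are applied zero-phase (forward–backward) to avoid
group-delay bias in latency-sensitive quantities; phase handling is this
package's choice. Odd-reflection padding suppresses the start/end
transients of the forward–backward pass, which would otherwise masquerade
as saccades at the trace edges.

`reject_and_subtract()` flags artifact trials (default: |velocity| >
80 deg/s or |acceleration| > 5000 deg/s² sustained ≥ 5 ms — thresholds are
configuration, standing in for the visual inspection used with real data)
and subtracts the mean blank-trial velocity to remove post-saccadic drift.
`window_stats()` computes, per condition and 50-ms window ([51,100] …
[251,300] ms), Gaussian moments of the per-trial mean velocities, the
coefficient of variation (undefined for non-positive means, excluded from
aggregates), and `sigma_d = sigma − sqrt(mu)`, the deviation from the
shot-noise square-root law.

## Quadric tuning surfaces, Θ, Φ and Q

`fit_quadric()` fits `R(x,t) = q0 + q1 x + q2 t + q3 x² + q4 x t + q5 t²`
(`x = log2 sf`, `t = log2 tf`) to the 15 windowed response amplitudes by
unweighted ordinary least squares (no trial weighting is assumed). In
speed–scale coordinates `u = (t−x)/√2`, `w = (t+x)/√2`:

- **Θ** is the angle of the locus of scales maximizing the surface along
  each iso-speed section — analytic for a quadric (a straight line), and
  cross-checked in the tests against a brute-force per-speed argmax.
- **Φ** is the angle of the dominant-curvature axis of the Hessian.
- **Q** = −(1 + q4/(2 q5)): 0 for speed-tuned (inseparable) surfaces, −1
  for separable sf/tf coding. Q is invariant to joint axis rescaling and
  amplitude offsets, and is treated as the *definition* of the
  separability index here (it is an approximation near the peak of a
  log-Gaussian surface).

Angles are reported clockwise-positive from the speed axis, pinned by
three anchors: a purely speed-tuned surface has Φ = 0, a surface tuned
only to spatial frequency has Θ = Φ = −45°, and one tuned only to temporal
frequency has +45°. The analytic tests fit the quadric to the *log* of
synthetic Gaussian surfaces (exactly quadratic); the pipeline fits raw
amplitudes, as is standard — both paths are exposed.

## Linear predictions, R_NL and separation times

The linear prediction for a pattern is the sample-wise mean of its
components' mean traces; `R_NL = e_obs/e_pred` compares windowed means
(undefined when the prediction is non-positive, e.g. the pre-response
window). `separation_time()` bins observed and predicted trials into 5-ms
windows and runs Welch t tests; the separation time is the start of the
first bin opening a run of `k` consecutive significant bins. The default
`k = 3` guards against isolated false alarms across ~80 bins at α = 0.05
(`k = 1` reproduces the literal first-significant-bin rule). Because the
prediction is a mean trace without its own trial population,
`prediction_pseudo_trials()` builds pseudo-trials by averaging one random
trial per component — this construction of the predicted-side variance is
a package decision. `bootstrap_trimmed_mean_test()` compares separation
times between stimulus types nonparametrically (1000 bootstrap samples of
the trimmed-mean difference by default).

## The decoding model

The channel bank (`build_bank()`) is a regular lattice over log2 sf ×
log2 preferred speed — a homogeneous rectangle of preferred speeds from 1
to 512 deg/s, sheared to (log2 sf, log2 tf) — with 19 × 38 = 722 channels
by default. Each channel is a bivariate Gaussian in the log-frequency
plane with SDs 0.5 octaves and correlation ρ = 0.6, concentrating its
sensitivity along its iso-velocity line.

**Weights.** Channel weights follow a quadratic surface over
(log2 sf, log2 tf) with reference coefficients
`(−23.88, −3.63, 1.95, −0.72, 0.61, −0.45)`. This surface is read as a
*log*-weight: with these coefficients its maximum value is ≈ −19, so raw
polynomial values would be negative for every channel (and clipping at
zero would silence the entire bank). `build_bank()` therefore uses
`w = exp(poly − max poly)`, which keeps every weight positive, preserves
the ordering and the 0.21 c/° location of the maximum, and normalizes the
peak weight to 1; the overall response scale is carried by the gain `g`.
Because the published gain was tied to a different (unrecoverable) weight
normalization, the package's reference participant uses `g = 2`, chosen
once so that one window's likelihood evidence is comparable to the prior
precision and posterior widths are comparable to across-trial eye-velocity
spread; `mu_prior = 2.51` and `sigma_prior = 0.86` are kept in natural-log
speed units as printed (a slow-speed prior near 12.3 deg/s).

**Responses.** `channel_response()` computes
`m_i = g² w_i ⟨φ_i, envelope⟩ c`: gratings evaluate the channel density at
the exact stimulus point; motion clouds integrate over the envelope
lattice (the tests verify < 1% deviation from a dense 512×512 oracle).
Pattern drives are means of component drives. `m` is computed once per
stimulus and held constant across windows; all temporal dynamics come from
the posterior recursion.

**Interactions.** The kernel `d(Δ)` is a difference of two peak-normalized
bivariate Gaussians over log2-frequency displacement, rotated onto the
speed/scale diagonals (θ = 3π/4): an excitatory lobe narrow across /
broad along the speed diagonal (SDs 0.2542, 0.7718 octaves) and an
inhibitory lobe with its SDs (0.2501, 0.7711) assigned to the axes in the
*opposite* order, i.e. elongated along the scale diagonal. This crossed
assignment is what produces the model's mechanism — excitatory pooling
along iso-velocity lines, inhibition between channels separated along the
scale axis; if both lobes shared one orientation the near-identical SDs
would cancel almost exactly and no inhibition would exist anywhere.
`d(0) = 0`, `d` is even, and circular equal-SD lobes cancel identically.
With the reference SDs the strongest inhibition sits ~0.6 octaves out
along the scale diagonal and remains negative (weakly) at 3 octaves.

Each channel's activity is `n_i = max(0, m_i (1 + I_i))` with
`I_i = Σ_j m_j d_ij`. The `1 + I` form is the default because the bare
product `n = m·I` reduces to no-interaction in no parameter limit and can
go negative; the literal product is retained behind `mode = "literal"`.

**Decoding.** Each channel's speed tuning `ψ_i` is a unit-peak Gaussian
over log2 speed centred on its preferred speed with variance σ²(1−ρ),
taken as printed (a cross-section derivation would suggest twice that;
the alternative is configuration). The population log-likelihood is
`Σ n_i log ψ_i` on a 512-point log2-speed grid spanning 0.25–1024 deg/s,
and the posterior recursion multiplies the previous window's posterior by
the (max-normalized) likelihood, starting from the log-normal prior at
ω = 0 (the 101–150 ms window), with updates for 151–200, 201–250 and
251–300 ms.

**Pattern nonlinearity in the model.** `pattern_nonlinearity()` reports
(i) the cross-component part of the interaction energy `mᵀDm` — negative
for scale-aligned triplets, positive for speed-aligned ones — and (ii) the
model's R_NL, the decoded pattern speed over the mean decoded component
speed at the final window. Summed network activity itself is *not* a
usable nonlinearity measure here: averaging the component drives dilutes
each component's positive self-interaction, making every pattern look
sublinear in Σn regardless of the kernel. Note also that under this
package's posterior-over-speed readout, a speed-aligned pattern decodes to
the common component speed, so its model R_NL saturates at 1 rather than
exceeding it; supralinear activity pooling shows up in the interaction
energy, not in the decoded speed. How posterior densities over speed map
onto eye-velocity distributions is this package's own convention: trial
velocities are treated as samples from (and evaluated under) the window
posterior, with the log2 change-of-variables Jacobian included.

## Model fitting and AIC

`data_loglik()` evaluates each valid trial's window-mean velocity under
that window's posterior density (windows ω ≥ 1; velocities ≤ 0.25 deg/s
are excluded from the log mapping and counted; densities are floored at
1e−12 with a count). `fit_channel_model()` maximizes this by Nelder–Mead
on logistic box-transformed parameters from multiple seeded starts (the
default preset plus random draws) — a bounded derivative-free local
search. `aic_compare()` reports `AIC_with − AIC_without`, with the
interaction variant carrying 5 extra parameters (α and the four kernel
SDs; the rotation is fixed).

## Synthetic cohorts

The phenomenological generator emulates the statistical structure the
analyses assume: latency ~ Normal(85, 10) ms; a saturating-exponential
velocity rise (60-ms time constant — trace shapes are shown but not
parameterized in the literature, so this is a package choice) toward a
condition plateau of 0.4 × stimulus speed (eye velocity reaches only a
fraction of target speed, ~10 deg/s for a 24 deg/s stimulus); per-window
across-trial noise enforcing `sigma = kappa sqrt(mu)` (κ = 1, plus a
0.2 deg/s baseline floor added in quadrature), inflated ×1.5 for
high-scale DG conditions after 200 ms (the late-variability excess seen
with gratings; the inflation factor is a package choice); a shared
post-saccadic drift added to all trials and blanks; saccade-like artifact
transients in 8% of trials; balanced left/right directions. Pattern
plateaus default to the linear component-average rule, so the generated
cohort is an end-to-end null for R_NL; a step divergence can be injected
per condition to probe separation-time recovery.

Because the preprocessing filters smear window boundaries, per-window
noise drawn naively would reach the analysis attenuated by several
percent; the generator therefore calibrates the offsets through the
window-coupling matrix of the (linear) preprocessing chain
(`solve(A, eta)`), so the *measured* window-mean noise has exactly the
target SD. Drift is modelled along the tracking axis so blank subtraction
is exact under direction alignment — a simplification of real
post-saccadic drift. Position noise of the tracker, saccade main-sequence
realism and closed-loop retinal feedback are not modelled, so passing
tests demonstrate the analysis chain's correctness on data with the
assumed structure, not robustness to every artifact of real recordings.

The model-driven mode (`forward_simulate_responses()`) samples per-window
trial velocities from the decoding model's posteriors, enabling
closed-loop tests: the suite verifies that `fit_channel_model()` recovers
the generating gain within 10%, the prior mean within 0.15 (natural-log
units) and the prior SD within 20% (medians over 10 seeds, 15 components
× 150 trials), and that AIC prefers the generating variant (with vs
without interactions) in at least 8/10 seeds in both regimes.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own working sizes: 64×64 envelope lattices (±3 octaves),
the 722-channel bank, a 512-point decoding grid, cohorts of 40–600 trials
per condition, 150-trial model-driven recovery, movies of 200 elements ×
32×32 pixels × 1 s. Optimizer defaults (8 starts, 400 Nelder–Mead
iterations) are reduced in the closed-loop simulations (2–3 starts,
200–300 iterations), which the wide AIC margins tolerate. Ties and
degenerate cases: the quadric Q is flagged undefined when |q5| is below
tolerance; saddle-shaped Hessians are flagged; posterior underflow raises
an error rather than returning zeros; zero-variance t-test bins fall back
to p = 1.

## Known limitations

- No reproduction of participant-specific fitted values, latency
  statistics or mixed-effects F tests from laboratory data; those require
  the unavailable human recordings.
- The printed interaction-kernel SDs do not place the inhibition maximum
  at 3 octaves under any reading we found; the package preserves the
  crossed structure and the sign of the 3-octave inhibition.
- The posterior→velocity mapping (and hence the model R_NL ceiling of 1
  for speed-aligned patterns) is a package convention.
- Movie synthesis is a desk-scale direct Gabor sum; no display
  calibration, luminance units, or real-time streaming.
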