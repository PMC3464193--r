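---
title: "A self-organizing map model of grid-cell scale selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A self-organizing map model of grid-cell scale selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridsom)
```

## The scientific problem

Grid cells in layer II of medial entorhinal cortex (MEC) fire on the
vertices of a hexagonal lattice tiling the environment, with lattice
spacing and field width increasing — and peak firing rate decreasing —
from the dorsal to the ventral end of MEC. In vitro, the same dorsoventral
axis shows a gradient of cellular kinetics: subthreshold membrane
potential oscillations (MPOs) elicited by steady current injection slow
down ventrally. `gridsom` implements a self-organizing map (SOM)
explanation of both gradients: map cells that integrate their inputs more
slowly learn to respond to larger-scale path-integration inputs, and the
same slow kinetics produce slower MPOs, so the oscillation gradient needs
no oscillatory-interference mechanism — it is a byproduct of the rate
gradient that drives spatial learning.

## Model structure

**Stripe cells.** Position is delivered to the map not as coordinates but
as the state of directional path integrators. A stripe cell integrates the
signed velocity component along its preferred direction θ
(`directional_velocity()`, a cosine projection; backward motion moves the
integrator backwards — no rectification) and fires with a Gaussian profile
around periodically repeating displacements: spacing λ, spatial phase ψ,
field sd σ. A `make_stripe_bank()` holds all combinations of 9 directions
(−80°…80° in 20° steps), 4 phases, and the configured spacings
(20/35 cm by default, 20/35/50 cm for the three-scale case). The four
phases are equally spaced at {0, λ/4, λ/2, 3λ/4}: equal spacing is the
only symmetric choice and keeps the summed ring activity nearly uniform
in displacement.

**Cross-scale normalization.** In the default `normalized` mode the field
width grows with spacing (σ = 0.0884·λ) while the peak activity shrinks so
the area under each stripe field, ω·σ·√(2π), is scale-invariant. The
ablations keep everything else fixed and change exactly one property:
`equal_peak` equalizes peaks (fields are then *not* normalized — the
large scale gains total activity), `equal_width` equalizes widths while
keeping the normalized-mode peaks, and `equal_both` equalizes both. We
read the width ablation this way because equalizing width *and*
re-normalizing area would collapse it onto `equal_both`; the
area-preserving alternative remains available via
`equal_width_preserve_area = TRUE`.

**Category cells.** Each local population (one per dorsoventral location)
obeys shunting on-center off-surround dynamics with a threshold-linear
signal function, habituative gating of the self-excitatory feedback, and
competitive instar learning of the afferent weights (see `?step_population`
and `?update_weights` for the exact equations and the `v1`/`v2`
variations). Populations do not interact; only their rate constants
differ: the response rate β multiplies the whole membrane equation, the
habituation rate ε multiplies the transmitter equation.

## Parameters, units, and calibration

Fixed network constants (all dimensionless except dt):

| parameter | default | role |
|---|---|---|
| A | 3 | passive decay (leak) rate |
| B | 1 | excitatory saturation; potentials stay below B |
| C | 0.5 | inhibitory saturation; potentials stay above −C |
| γ | 17.5 | self-excitatory feedback gain |
| D_inh | 17.5 | off-surround inhibition strength |
| Γ | 0.1 | output threshold |
| µ | 1.5 | transmitter depletion coefficient |
| λ_w | 0.025 | instar learning rate |
| σ_noise | 0.2 | Brownian noise intensity |
| dt | 0.002 s | Euler step |

Three of these deserve comment because the model's qualitative behaviour
pins them:

* **γ = 17.5.** The ungated single-cell circuit (transmitter held at 1)
  must be bistable so that a transient input leaves the cell persistently
  active — this is the perseveration that motivates habituative gating in
  the first place. Bistability of `−A·V + (1 − V)·γ·(V − Γ)` requires
  γ ≳ 7; modest gains (order 1) cannot produce it, nor can they deplete
  the gate appreciably (the depletion signal is γ·f squared) or generate
  MPOs. 17.5 produces the expected trace shapes in `simulate_case1()`.
* **µ = 1.5.** With shallow depletion the habituated feedback still
  supports a stable suprathreshold fixed point (the maximum of
  γ·f·z*(f) over f exceeds the leak), so a winning cell latches
  tonically, current injection converges to a flat trace, and no
  oscillation exists. Deep depletion removes the tonic state: activity
  becomes phasic bursts, and the burst–recovery cycle is the MPO.
* **ω₀ = 1.25** (peak activity of the smallest stripe scale, the activity
  unit of a bank). The instar law self-normalizes each cell's total
  afferent weight to ≤ 1, and with unit stripe peaks a learned cell's
  drive at its own firing fields sits almost exactly at the firing
  threshold Γ·A/(B − Γ); ω₀ = 1.25 gives the learned state headroom.

The gradient parameters are β ∈ {1, 0.9, …, 0.1} (full response-rate
ladder) and ε ∈ {0.5, 0.2, 0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001}
(full habituation ladder); the fixed habituation rate used in the
response-rate cases defaults to ε = 0.05, the midpoint of that ladder on
a log scale.

**Noise.** The membrane noise term is a Brownian motion: each Euler step
adds an independent N(0, σ_noise²·dt) increment, giving a stationary
potential sd of roughly σ_noise/√(2βA) ≈ 0.04–0.08 — enough to unmask
damped oscillations without drowning the dynamic range [−C, B]. Noise is
used in the noisy-learning case and in the MPO paradigm only.

## The synthetic trajectory generator

`synthesize_trajectory()` emulates the kinematics of a foraging rat in a
square arena. Log running speed follows a mean-reverting
Ornstein–Uhlenbeck process whose stationary law is lognormal with exactly
the target mean (14.03 cm/s) and sd (9.8 cm/s) — always positive and
right-skewed like measured speed distributions; heading is a Brownian walk
(default diffusion 1.0 rad/√s, chosen so a 10-minute trajectory covers
more than 90 % of 2.5-cm bins, as rate-map estimation requires); walls
reflect the path specularly, which preserves the speed statistics. The
generator does **not** emulate several features of real tracking data:
tracking jitter (centimetre-scale piecewise-linear segments), dwell/pause
episodes, wall-following (thigmotaxis), or home-base behaviour. Tests
passing on synthetic trajectories therefore validate the algorithmic
pipeline under idealized smooth kinematics, not performance on real
recordings.

## Post-processing

The arena is binned at 2.5 cm; per-trial occupancy and output activity are
accumulated per bin, smoothed with a truncated 5×5 Gaussian kernel (sd = 1
bin, unit mass), and divided to give rate maps (unsmoothed rates are
retained alongside). The spatial autocorrelogram is the Pearson
correlation of the smoothed map with itself at every 2-D lag over
overlapping defined bins (minimum 20; computed via FFT cross-correlations
of the map and its validity mask — exact, not an approximation). Grid
metrics follow the standard autocorrelogram constructions: the six local
maxima (correlation > 0.1) closest to the central peak; gridness as the
minimum of the annulus correlations at 60°/120° rotations minus the
maximum at 30°/90°/150° (annulus between the central-peak radius and 1.25×
the outermost peak distance; rotation by bilinear interpolation); spacing
as the median peak distance; orientation as the smallest positive angle to
the horizontal, reported in [0°, 60°); field width as twice the radius at
which the radial correlation profile reaches zero or a local minimum,
whichever comes first. Cells with gridness > 0 are classified as grid
cells, and trend tables also report the stricter > 0.3 subset. Note the
gridness > 0 rule is permissive: on featureless noise maps it fires in a
sizable minority of draws (the gridness null distribution is wide and
centred slightly below zero), which is worth remembering when interpreting
percent-grid-cell numbers from small populations.

## Numerical choices

* Euler forward integration at dt = 2 ms throughout; no adaptive stepping.
  One full step agrees with two half steps to well under the per-step
  change (second-order consistency is verified in the test suite).
* All signals in a step are evaluated from the state at the start of the
  step (potentials, gates, weights updated jointly).
* Displacement integrators, potentials, and gates reset at each trial
  start (D = 0, V = 0, z = 1); weights persist for the lifetime of a run.
* Stripe phase wrapping maps the displacement residual to
  (−λ/2, λ/2] with floor-based reduction, keeping activities exactly
  λ-periodic over unbounded displacements.
* Zero-speed samples carry the previous heading forward (the projection is
  undefined at v = 0 but integrates to nothing anyway).
* The FFT frequency estimate subtracts the trace mean, applies no window
  or taper (spectra are bit-reproducible), and reports the argmax of power
  over (0, Nyquist]; frequencies lie on the 1/duration grid (0.02 Hz for
  50-s traces). Constant traces report 0 with a `flat` flag.
* Seeding: one master seed per run; per-population and per-trial child
  seeds are derived deterministically (affine map mod 2³¹ − 1), so any run
  is bit-reproducible from its manifest.

## Simulation cases and problem sizes

`case_spec()` encodes the thirteen standard cases: single-cell dynamics
(1), the response-rate-gradient learning case (2) and its variations —
novel trajectory per trial (3), three stripe scales (4), membrane noise
(5), model variations (6, 7), stripe ablations (8–10) — the
habituation-rate gradient (11), and the MPO sweeps (12, 13). The `full`
presets use the published scale (10 populations × 25 cells, 40 trials);
the `desk` presets, which the package's own tests use, reduce this to 3
gradient values × 10 cells and 10 trials over a 10-minute synthetic
trajectory so a case completes in about a minute on one CPU core.

## Known limitations

* **Desk-scale map learning is fragile.** The learning dynamics sit close
  to the output threshold by construction: the initial afferent weights
  (Uniform(0, 0.1) over 72 stripe cells, total ≈ 3.6) make early drive
  suprathreshold almost everywhere, firing is therefore initially
  unselective, and the instar law's self-normalization then pulls a cell
  whose firing has not yet crystallized below threshold permanently. In
  reduced desk-scale runs most cells end silent, and populations often
  yield zero or one grid-classified cell, with the expected orderings
  (fast populations at small spacing and high peak rate, slow populations
  at large spacing and low peak rate; the reverse peak-rate trend along
  the habituation ladder) appearing only sporadically across seeds. We
  have not found a calibration of the unprinted constants that makes the
  reduced configuration reproduce the published trends reliably;
  robustness at the published scale likely also leans on the real foraging
  trajectory's fine structure. The case runner therefore treats the trend
  assertions as stochastic checks, and users should run several seeds.
* MPO frequencies are in model units (sub-hertz at these rate constants);
  only orderings and trends across β, ε, and current amplitude are
  meaningful, not absolute theta-band values.
* Heading is taken parallel to the trajectory; there is no head-direction
  system, no place-cell stage, and no top-down stabilization, so learned
  maps can drift with continued exposure.
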