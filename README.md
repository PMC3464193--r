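# gridsom

Simulation of how medial entorhinal cortex (MEC) grid cells can *learn*
their hexagonal firing fields — and a dorsoventral gradient of spatial
scales — in a self-organizing map (SOM) driven by stripe cells that perform
linear path integration.

## The model

Stripe cells integrate the velocity component along a preferred direction
θ, `dD/dt = v·cos(φ − θ)`, and fire in periodic bands: with spacing λ,
spatial phase ψ, and field width σ, a stripe cell's activity is

    S = ω · exp(−wrap(D − ψ, λ)² / 2σ²),

λ-periodic in the integrated displacement D. A bank of stripe cells (nine
directions 20° apart, four phases, spacings 20/35 cm, σ = 8.84 % of λ,
fields area-normalized across scales) projects through adaptive weights
W to category (map) cells. A category cell's potential obeys shunting
on-center off-surround dynamics,

    dV/dt = β[ −A·V + (B − V)(ΣW·S + γ·f(V)·z) − (C + V)·D·Σf(V_j) ],

with threshold-linear output `f(V) = [V − Γ]⁺`, habituative transmitter
gate

    dz/dt = ε[ (1 − z) − µ·z·(γ f(V))² ],

and competitive instar learning, gated by the postsynaptic output,

    dW_k/dt = λ_w · f(V) · [ S_k(1 − W_k) − W_k Σ_{m≠k} S_m ],

whose equilibrium is the normalized input pattern `W_k → S_k/ΣS` (total
afferent weight self-normalizes to ≤ 1). The *response rate* β (membrane
rate constant) and *habituation rate* ε decrease along the dorsoventral
axis; they control which stripe spatial scale a cell learns, its peak
firing rate, and the frequency of the subthreshold membrane potential
oscillations (MPOs) that steady current injection elicits *in vitro*.
Two published model variations are included: under `v1` the gate
multiplies bottom-up plus on-center signals and afferent weights compete
for a total of 2; under `v2` output and inhibitory signals are also gated
by z.

The package provides, as separate composable modules: trajectory handling
(delimited-text reader, resampling, rotation with an origin run-in, and a
synthetic foraging-trajectory generator matched to rat running-speed
statistics), stripe banks with cross-scale normalization and its
ablations, the compiled network integrator, the current-injection MPO
paradigm with FFT frequency estimation, the full grid-metrics suite (rate
maps, 5×5 Gaussian smoothing, spatial autocorrelogram, gridness score,
spacing, orientation, field width, peak/mean rates, inter-trial
stability), and a declarative runner for the thirteen published simulation
cases (`case_spec()` / `run_case()`, with `desk` and `full` presets).

## Worked example

Single-cell dynamics along the rate gradient (the Case-1 paradigm: one
category cell, a stripe-field input pulse traversed at 10 cm/s, gated
self-excitatory feedback):

```r
library(gridsom)
library(dplyr)

tr <- simulate_case1(betas = c(1, 0.5, 0.2, 0.1))
tr |>
  filter(circuit == "gated") |>
  group_by(beta) |>
  summarise(peak_output = max(f),
            half_width_s = sum(f > max(f) / 2) * 0.002,
            time_to_peak_s = time[which.max(f)])
#>   beta peak_output half_width_s time_to_peak_s
#> 1  1.0       0.606        0.572           1.05
#> 2  0.5       0.520        0.784           1.21
#> 3  0.2       0.306        1.950           1.71
#> 4  0.1       0.181        4.744           3.82
```

Slower response rates yield smaller, broader, delayed responses — the
signature that lets slow (ventral) cells prefer larger stripe spacings.
The combinatorial root of scale selection is that triple coactivations of
stripe fields recur at hexagonal-lattice vertices, of which a
100 cm × 100 cm arena contains far more at the small scale:

```r
count_coactivation_maxima(35)   # 7
count_coactivation_maxima(20)   # 23
```

MPO frequency rises with the response rate (steady current injection,
FFT-peak frequency, mean over noisy replicates):

```r
sweep_mpo(beta_values = c(0.2, 0.6, 1), amplitudes = 1, reps = 10, seed = 1)
#>   beta  eps I mean_freq sem_freq  n
#> 1  0.2 0.05 1     0.092   0.0235 10
#> 2  0.6 0.05 1     0.162   0.0383 10
#> 3  1.0 0.05 1     0.240   0.0509 10
```

Learning simulations run through the case runner, e.g.
`run_case(case_spec(2, "desk", seed = 1))` for the response-rate-gradient
case at desk scale (3 response rates × 10 cells, 10 trials, synthetic
10-minute trajectory); it returns per-cell grid metrics, gradient trend
tables, final weights, and rate maps. See the methods vignette
(`vignettes/grid-scale-som.Rmd`) for the model's assumptions, parameter
calibration, and known limitations — including the fragility of
desk-scale map learning.

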