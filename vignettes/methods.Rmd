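---
title: "Models, calibration and design choices in vibroseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design choices in vibroseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibroseed)
```

`vibroseed` is a desk-scale, fully self-contained model of
electromagnetic vibration seed treatment: physics, phenotype response,
protocol optimization, and a learned surrogate, with every input
generated by the package itself. This vignette explains the models, the
assumptions behind them, the parameters that matter, and the places
where the design was genuinely open and we had to choose.

## 1. Treatment physics

The applied field is `B(r,t) = B0 cos(2πft + φ) e^(−αr)`. We evaluate
treatments at the chamber centre, so the attenuation coefficient
defaults to `α = 0` (no published value exists for it; it is exposed in
`field_config()` for sensitivity studies). Induced vibration follows
the damped-oscillator amplitude response with the seed's natural
frequency `f_n` and damping ratio `ζ`; for `ζ < 1/√2` this is unimodal
with its peak at `f_n √(1 − 2ζ²)`, about 1% below `f_n` at the default
`ζ = 0.1`.

Absorbed energy is the composite-Simpson quadrature (default 1001
points) of `B²(t) V_seed/(2μ0) · η(t)` over the action time. Two
choices deserve comment:

* **Pulse gating.** Pulse width and duty cycle enter as an on/off gate
  on the integrand with period `pulse_width / duty`. Pulse periods
  (0.1–10 ms) are four to six orders of magnitude shorter than action
  times (30–300 s), so the gate averages *exactly* to the duty
  fraction; we apply that analytic factor by default, which also
  preserves Simpson convergence for smooth absorption efficiencies. A
  `duty_exact = FALSE` switch retains literal pointwise gating.
* **Absorption efficiency.** `η(t)` is never given a functional form in
  the source material; the default is the constant 1, with an
  exponential-saturation alternative `η(t) = 1 − e^(−t/τ)` available
  (`eta_saturating()`).

The Helmholtz centre-field expression is implemented exactly as the
system design states it, including a factor-2 convention that is twice
the textbook Helmholtz value (each coil's Biot–Savart term appears
without its ½). A `textbook_mode` switch applies the conventional
factor; nothing downstream depends on the choice because the coil
constant only enters the energy objective as a linear scale.

**Energy objective.** The electrical cost is
`P_total × duration = (I_rms² R_coil + P_switching + P_control) × T`.
The decision variables include both field strength and voltage
amplitude, and the contract requires the cost to increase in both. A
voltage-only current map (`I = V/Z`) cannot satisfy that, so the RMS
current sums two linear maps: the current needed to command the
requested field through the coil constant, plus the auxiliary drive
current `V/Z` (default `Z = 10 Ω`), both scaled by `√duty`.

## 2. The virtual seed lab

Germination kinetics are logistic in time with asymptote `G_max`, rate
`k` (default 0.9/day) and midpoint `t50` (default 5 days) — typical of
maize at 25 °C scored daily for 14 days. Vigor index is
`germination% × mean seedling length / 100`; note that reproducing the
published vigor indices (≈ 73–92) together with the published
germination rates forces mean "seedling length" values near 90 in the
formula's length unit, which we retain as-is rather than rescale,
since only the product is ever compared.

**Effective dose** couples the physics to the phenotype:
`D = E_total × ρ_f` with `ρ_f` the vibration amplitude at the driving
frequency normalized by its value at `f_n`, clipped to 1 (the raw ratio
can exceed 1 by ~0.5% just below resonance). The coupling is an
artifact construct: the source asserts, but never formalizes, how
energy and resonance combine.

**Hormesis.** Treatment gains follow
`ΔG = ΔG_max u^γ e^(γ(1−u))`, `u = D/D_opt`: zero at zero dose, peak
exactly `ΔG_max` at `D_opt`, decaying at overdose. The shape exponent
defaults to `γ = 2`, a moderately peaked curve — doses within ±30% of
optimum retain >90% of the peak gain, which matches the qualitative
"window" reported for magnetic seed stimulation. `γ` is per-variety
configurable.

**Calibration.** Per variety, control means are set to the published
control cells; `ΔG_max` and `ΔVI_max` to the optimized−control
differences; `D_opt` to the dose delivered by a fixed anchor protocol
(3.5 mT at the variety's resonance frequency for 180 s, 50% duty) —
the winning protocol is never reported, so we place the optimum at a
mid-range, physically sensible setting. Natural frequencies (300, 400,
250 Hz) are chosen inside the tested 10–1000 Hz band, with Xianyu 335
given the highest `f_n` because it is described as most sensitive in
the 300–500 Hz range. Published 95% CIs are treated as CIs of
3-replicate means, so replicate-level standard deviations are
`hw √3 / t_{0.975,2}`; replicate means are drawn from a moment-matched
beta distribution, seeds germinate as Bernoulli trials, and
germination days are inverse-transform samples of the logistic CDF
truncated at the 14-day scoring window.

What a green calibration test establishes: the simulator reproduces the
published first and second moments at the published design size. What
it does not establish: any biology — the hormetic form, the resonance
coupling and the kinetics response to dose are modelling choices, not
fitted mechanisms.

## 3. The optimizer

The hybrid couples a GA population (50) and a swarm (30) through a
shared Pareto archive. Published settings are used as defaults
(crossover 0.8, mutation 0.02, tournament k=3, inertia 0.9→0.4,
c1 = c2 = 2). Where the source is silent we use the NSGA-II de-facto
standards: SBX with `η_c = 15`, polynomial mutation with `η_m = 20`,
boundary handling by clipping, velocity clamp at 20% of each range.
Migration moves the 5 most-crowded (i.e. diversity-bearing) archive
members into both populations every 10 iterations.

The cooperative coupling went through one redesign. A first version
guided particles by crowding-biased roulette over the archive and
updated personal bests on Pareto dominance; that hybrid *lost* to plain
NSGA-II in 17 of 20 paired runs — an unguided swarm spends most of its
evaluations on dominated points. The shipped design decomposes the
problem Tchebycheff-style: particles cycle through a simplex lattice of
weight vectors (on running-min/max-normalized objectives), a particle's
guide is the archive member best on its current scalarized subproblem,
and personal bests accept on scalarized improvement. The swarm's
current positions also compete in the GA's environmental selection, so
swarm discoveries propagate into the genetic population between
migration events. With this design the hybrid reaches higher
hypervolume than budget-matched NSGA-II in 75% of paired runs at
pre-convergence budgets; at long budgets both converge to
indistinguishable fronts on this problem.

The archive is capped at 200; over capacity it is truncated by crowding
distance (boundary members always survive, the most crowded interior
members go first). This makes the recorded hypervolume *almost*
monotone — a truncation can cost a sliver of volume in a dense region,
so the invariant test allows a 10⁻³ relative tolerance.
Hypervolume itself is the standard Lebesgue measure (exact 2-D sweep,
3-D slicing along the third objective), cross-checked against
Monte-Carlo estimates; the integral-of-products formulation printed in
the source is not the standard definition and was not implemented.

Rate adaptation: if archive hypervolume changes by less than 10⁻⁶
(relative) over a 10-iteration window, mutation is multiplied by 1.5
(cap 0.2) and the inertia floor raised by 0.05; if mean archive
crowding falls below 0.05, crossover is reduced by 0.05 (floor 0.6).

## 4. The surrogate

The network follows the published layer table exactly; the only
underdetermined link is how a 16×16×64 convolutional stack feeds a
2176-dim fusion layer. We project with a 1×1 convolution to 8 channels
(16·16·8 = 2048) and concatenate the 128-dim LSTM output — the minimal
reading that matches the printed 2176. Attention (softmax of learned
scores scaled by `√d_k`) pools the second LSTM's 50 hidden states
before the fusion, replacing a bare last-step readout.

Numerical choices: weights initialize uniform ±1/√fan-in with
forget-gate biases at 1; sensor sequences are z-scored per channel with
training-set statistics (raw channels span scales from 0.1 to 60, which
saturates LSTM gates); targets are z-scored per task; the loss is the
uniform-weighted multi-task MSE plus `λ = 10⁻⁴` L2. The learning rate
follows the triangular cyclical schedule (10⁻⁴ to 10⁻², half-cycle 200
iterations, peak at t = 0 as printed) with global gradient-norm
clipping at 1. The inner update is Adam (β₁ = 0.9, β₂ = 0.999) on the
clipped gradient: plain momentum SGD under the same schedule failed to
reach the recovery criterion within the 10-epoch budget, and the source
does not name its optimizer. Because the cyclical schedule can end a
run mid-cycle on a noisy step, test metrics are computed from the
best-validation-epoch weight checkpoint rather than the final weights.
Training is single-threaded deterministic for a fixed seed.

Splitting is by whole experimental batches (variety × replicate ×
treatment cell), shuffled within variety strata and assigned 70/15/15
by largest remainder, so no batch id ever spans partitions.

## 5. Synthetic data: what it emulates and what it does not

The generator reproduces the *structure* of the real experiment: the
5×6×4 factorial with 50-seed cells and 3 replicates, the 3×2,000-seed
dataset skeleton, 64×64×3 seed images (rotated ellipse with
variety-specific size and hue, speckle, Poisson defects, Gaussian
noise; moment-fitted axes recover the latent within 5%), and 50×128
sensor sequences whose documented channel map carries the field
envelope, resonance amplitude, environment walks (22±2 °C, 60±5% RH),
protocol values, a cumulative dose trace, a null channel and lagged
noisy mixtures. In noiseless mode targets are the exact dose-response
expectations, so surrogate-recovery tests measure the learner, not the
noise.

It does **not** emulate: real seed-image texture or defects, sensor
drift or cross-talk, non-stationary environments, genotype × dose
interactions beyond the three fixed profiles, or any biochemical
mechanism. A green surrogate test therefore establishes that the
architecture and training loop can extract a known signal at the stated
scale — not field performance.

## 6. Known limitations

* The published headline deep-learning metrics and algorithm-comparison
  hypervolumes are not reproducible without the original 6,000-seed
  dataset and benchmark definitions; they are replaced throughout by
  property-based checks on generated data.
* The dose–phenotype coupling is a single scalar channel; real
  treatment effects are unlikely to collapse onto one dose axis.
* The benefit–cost helper discounts fixed yearly streams only.
* Feature attribution is permutation-based on channel groups, a
  model-agnostic stand-in for Shapley-value attribution.
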