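---
title: "Methods: species-specific HH channel models in a nucleated-patch compartment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-specific HH channel models in a nucleated-patch compartment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhpatch)
```

## The scientific question

Human cortical pyramidal neurons sustain fast, stable action potentials
(APs) during prolonged firing and can time their spikes to rapid
subthreshold input, yet their somatic Na⁺ and K⁺ conductance densities are
lower than in mouse. `hhpatch` provides the modeling toolchain to study
how channel-level biophysics (steady-state voltage dependence,
activation/inactivation kinetics, recovery from inactivation) maps onto
those cell-level properties: Hodgkin–Huxley (HH) channel models for both
species, a single-compartment simulator standing in for a somatic
nucleated patch, voltage-clamp protocol batteries with the matching curve
fits, optimizers for model calibration, and a phase-locking
(input–output bandwidth) analysis.

## Gating model

Every gating variable relaxes as $dx/dt = (x_\infty(V) - x)/\tau(V)$.

**Steady states** are Boltzmann functions: activation
$x_\infty = 1/(1+e^{(V_{1/2}-V)/q})$, inactivation mirrored. Keeping the
steady state separate from the kinetics (rather than deriving both from
rate functions) lets voltage dependence and speed be manipulated — and
fitted — independently.

**Time constants** use a rate-based bell:
$\tau(V) = \tau_{min} + s/(\alpha+\beta)$ with
$\alpha = a e^{V/k_a}$, $\beta = b e^{-V/k_b}$. The activation form drops
$\tau_{min}$ and $s$ (4 parameters); inactivation gates and K⁺ activation
keep all six. With the Boltzmann pairs this gives the Na⁺ model
2 + 2 + 4 + 6 = 14 free parameters ($s$ is redundant with $a, b$ and held
at 1 during fitting). The form is strictly positive and continuous for
any parameter values, so fitting can never produce an unstable gate.

**Channels.** Na⁺: $g = \bar g\, m^3 h$. The activation exponent is not
derivable from steady-state curves alone; $m^3$ is the convention of the
somatic Na⁺ models this family descends from, and it is exposed as a
parameter (`na_channel(p = )`). K⁺: $m^2$ activation with the total
conductance split into three fractions —
$g = \bar g\, m^2 [f_{inact}((1-f_{h2})h_1 + f_{h2} h_2) + (1-f_{inact})]$,
$f_{inact} = 0.85$, $f_{h2} = 0.4$. The slow gate $h_2$ relaxes to the
same steady-state inactivation curve as $h_1$ with a fixed two-regime
time constant: 200 ms while inactivating ($h_2$ above its steady state),
20 ms while recovering. Human and mouse K⁺ models share all inactivation
kinetics (a shared-kinetics constructor, `share_k_inactivation()`,
enforces this); only their steady-state inactivation curves differ.

## The species presets and what is synthetic about them

Only the half-(in)activation voltages of the underlying recordings are
published as numbers: Na⁺ activation −32.1 (human) / −37.9 (mouse) mV,
Na⁺ inactivation −66.0 / −74.8 mV, K⁺ activation −3.0 / −7.9 mV, K⁺
inactivation −52.7 / −65.0 mV. Everything else in
`species_preset()` is a documented package choice, fixed once:

* **Slopes**: Na⁺ 5 mV (activation) / 7 mV (inactivation); K⁺ 9 / 6 mV —
  typical values for these channel families.
* **Midpoint alignment** (`align`): the published $V_{1/2}$ are Boltzmann
  fits to measured $G/G_{max}$ curves, i.e. to the $m^p$ *composite*. A
  gate placed directly at that midpoint puts the simulated conductance
  curve $q\ln(2^{1/p}-1)$ too depolarized (≈ 7–8 mV here). The default
  `align = "conductance"` root-corrects the activation-gate midpoint so
  the *simulated* conductance curve reproduces the printed value — our
  reading of what a protocol-emulating calibration would converge to.
  `align = "gate"` places the printed value on the gate itself.
  Inactivation midpoints come from availability measurements and always
  sit on the gate.
* **Kinetics** (all values in `preset_params()`): Na⁺ activation τ peaks
  at 0.14 ms (human) / 0.13 ms (mouse) — human slower; Na⁺ inactivation
  τ ≈ 1.9 ms (human) vs 1.1 ms (mouse) at 0 mV — human slower
  suprathreshold — while below threshold the human limb is shallow so
  its inactivation tail dies quickly and recovery is fast (≈ 4 ms at
  −80 mV) versus very slow mouse recovery (≈ 35 ms at −80 mV); the shared
  K⁺ h₁ bell gives ~11 ms inactivation at +40 mV and ~16 ms recovery at
  −80 mV; K⁺ deactivation is a few ms subthreshold (human faster), so
  channels opened during an AP keep conducting through repolarization.
  These reproduce the qualitative species contrasts in the underlying
  recordings (slower human inactivation, faster human recovery, faster
  human K⁺ activation at low voltages) with magnitudes chosen from
  typical cortical channel kinetics near room temperature, at which the
  Na⁺ kinetics were measured.

Passing `source = "table_s2"` to `species_preset()` signals that the
original supplementary parameter table would be used were it available;
it is not distributed with this package, and the call errors with the
fallback named.

## The compartment

`patch_model()` builds a spherical compartment: diameter 10 µm (area
$\pi d^2$), $C_m = 1$ µF cm⁻², $E_{Na} = 53$ mV, $E_K = -101$ mV, leak
1 pS µm⁻². `phaselock_patch()` switches to the long-simulation
configuration: $E_{Na} = 100$ mV and leak 2.5 pS µm⁻², which prevents
depolarization block over hundreds of seconds. (The leak value is read as
2.5 pS µm⁻²; taken literally as pS cm⁻² it would be physically
negligible.) The default leak reversal of assembled hybrid models is
−80 mV: the resting potential expressed in the same voltage frame as the
channel midpoints (the recordings' junction-corrected frame), at which
the preset availabilities (h∞ ≈ 0.88 human vs 0.68 mouse) match the
reported resting availabilities well. It is a plain argument for anyone
preferring −70 mV.

`channel_mix()` + `hybrid_patch()` distribute total Na⁺/K⁺ densities over
human- and mouse-property populations (`gmax * humanfrac` each); the four
population densities always sum to the totals.

## Numerics

Gates advance by the exact exponential update at the voltage frozen over
one step; the membrane potential by an implicit backward-Euler update.
Both are unconditionally stable, which matters because Na⁺ activation
(τ < 0.1 ms at depolarized V) is stiff relative to the 0.025-ms default
step; voltage-clamp protocol batteries use 0.005–0.02 ms. Gate values are
clamped to [0, 1] after each step to absorb floating-point overshoot.
Each simulation settles for 200 ms at its initial voltage (leak reversal,
or the first command sample in clamp modes) with gates initialized at
steady state, so results do not depend on arbitrary initial conditions.
Halving the step changes peak Na⁺ currents by < 0.5% and AP peak times by
less than one default sample (covered by tests). The integrator core is
C++ (Rcpp); everything else is R.

## Protocols and curve fits

The voltage-clamp battery mirrors standard practice: steady-state
activation (steps −80…+60 mV from −90 mV holding; peak current for Na⁺,
late mean current for K⁺; $G = I/(V - E_{rev})$, normalized), steady-state
inactivation (500-ms default prepulses −120…−30 mV, fixed test pulse),
recovery from inactivation (long conditioning pulse, log-spaced delays at
the recovery potential, monoexponential fit). Steps within 5 mV of the
reversal are excluded with a warning.

Curve fits use bounded Levenberg–Marquardt (minpack.lm) with a few
perturbed restarts: the monoexponential decay $a e^{-t/\tau_h} + b$; the
compound activation fit
$[1-e^{-(t-d)/\tau_m}][a e^{-(t-d)/\tau_h} + b]$ (the rising factor is
clamped to zero before the onset delay, and the delay is profiled over a
small grid — it couples strongly with $\tau_m$); the double exponential
with $\tau_f < \tau_s$ enforced by ordering and near-degenerate fits
collapsed to a monoexponential with a flag; and the Boltzmann fit for
conductance/availability curves. $R^2$ is computed as
$1 - SS_{res}/SS_{tot}$ and fits with $R^2 \le 0.9$ are flagged excluded.
Offline zero-phase Butterworth low-pass filters (20 kHz current clamp;
14/6/2 kHz for Na⁺-activation/Na⁺-inactivation/K⁺ voltage clamp) are
applied only to traces marked `raw`; clean model output is never
filtered.

AP analysis: threshold is the voltage at the last upward crossing of
23 mV/ms in dv/dt before the dv/dt maximum (central differences; the
derivative scheme is a package choice); rise/fall speeds are reported
both as extreme derivatives and as 30–70% (70–30%) amplitude-window
linear-fit slopes; amplitude is threshold→peak; train stability
normalizes per-AP speeds to AP1.

## Parameter estimation

`fit_channel_cmaes()` fits the four functions ($m_\infty$, $h_\infty$,
$\tau_m$, $\tau_h$) *separately* to target curves — each search stays 2-
to 6-dimensional — with a compact standard CMA-ES (rank-one/rank-µ
covariance updates, cumulative step-size adaptation; no CMA-ES package
exists in the dependency set, so it is implemented here and tested
against analytic minima). The error is the sum of squared differences
normalized by each curve's maximum magnitude; initial values come from
direct Boltzmann fits and the template's kinetics. With
`protocol_emulation = TRUE` the steady-state errors are computed by
actually running the voltage-clamp protocols on the candidate channel and
comparing the derived curves — this captures protocol biases such as
peak-current underestimation of $m_\infty$. Time-constant targets are
always compared as direct curve evaluations: running nonlinear
exponential fits inside every objective evaluation would multiply cost
~100× without adding fidelity on clean targets.

`fit_gmax_powell()` fits the two total densities to an AP feature triple
(defaults: amplitude 48.4 mV, rise 420 mV/ms, fall 73.1 mV/ms — the
cross-species experimental means) by Powell's direction-set method over
log densities (positivity by construction; also implemented here, with
`stats::optimize` line searches). Each objective evaluation finds the
3-ms-pulse rheobase at 10-pA precision and measures the first AP evoked
at 150% rheobase — the standard evocation protocol.

## Phase locking

The stimulus is DC + sinusoid + exponentially filtered Gaussian noise
(single-pole filter, τ = 5 ms, rescaled to the target SD *after*
filtering), all expressed as fractions of rheobase: sinusoid 15%, noise
SD 30%, DC either the published fractions (0.84 human / 0.94 mouse /
0.83 equal-input) or auto-calibrated by bisection to a 12.5-Hz firing
rate. Two pipeline choices deserve note:

* **Which rheobase?** For phase-locking the DC is scaled by the
  *sustained-input* rheobase (100-ms pulse, 0.1-pA precision). A DC at
  84–94% of the much larger 3-ms-pulse rheobase would hold the
  compartment in depolarization block; only relative to the sustained
  threshold is a sub-unity DC fraction meaningfully subthreshold.
* **Frozen noise.** The noise seed is shared across models and
  frequencies so phase-locking differences cannot come from different
  noise realizations.

Spike times (peaks above 0 mV, 1 s transient discarded) are folded into
the stimulus cycle, binned into a 30-bin rate histogram, and a
single-cycle sinusoid (offset + cos/sin, linear least squares) is fitted;
M/R is amplitude over offset. The closed-form checks: all spikes in one
bin give M/R = 2, uniform spikes give 0, an inhomogeneous Poisson train
with 50% rate modulation gives ≈ 0.5. The cutoff frequency is the linear
interpolation of the 0.4 crossing of M/R versus input frequency (grid
5–300 Hz by default here). Pre-AP Na⁺ availability is the mean of h over
0.8–2.8 ms before each AP peak (a 2-ms window ending just before the
upstroke contaminates h), with a median split of spike-phase spread.

## Synthetic data generator

`synth_vclamp_cohort()` emulates a cohort of nucleated-patch recordings:
per-cell channel parameters drawn around the species preset (midpoint SDs
5/7 mV, slope SD 1 mV, log-normal τ scaling with SD 0.15 — covariances
unknown and set to zero), and raw sweeps assembled as clean ionic current
plus linear leak, biexponential capacitive transients at step edges
(amplitude linear in step size), and Gaussian noise (20 pA default). P/−5
scaling sweeps are generated alongside so `pn_subtract()` can be
exercised; because the artifacts are linear by construction, subtraction
removes them exactly up to noise. Every dataset carries its generating
parameters; all recovery tests compare against that ground truth, never
against published cohort statistics. What the generator does **not**
emulate: series-resistance artifacts, temperature drift, electrode drift,
channel noise, or any real covariance structure between cell parameters —
so passing recovery tests demonstrate the pipeline's correctness, not its
robustness to every feature of real recordings.

`synth_ap_command()` produces AP-train voltage commands by free-running
the corresponding spiking model, with annotated peaks, for AP-clamp
replay. Replayed onto its generating model, the clamp reproduces the
free-run gating trajectories (consistency test).

## Problem sizes

The shipped analyses and tests run at: 200-AP trains at 10–70 Hz;
AP-clamp commands of 6–200 APs; cohorts of 8–10 cells with 9-step
availability batteries at dt = 0.02 ms; CMA-ES at 150 generations with
the default population; phase-locking scans over 7 frequencies at 20–60 s
per frequency with 1 s discarded. These sizes give stable estimates for
every reported quantity (e.g. hundreds of spikes per M/R point) while
keeping a full run in minutes on one CPU; longer runs change the phase
locking numbers by amounts small compared with the species differences.

## Known limitations

* **Joint AP-feature targets are not attainable** with the printed-means
  presets: at rise 420 mV/ms the AP peak rides high and the
  threshold→peak amplitude saturates near 85 mV (vs the 48.4-mV target)
  in a single compartment with $E_{Na} = 53$ mV. The Powell fit therefore
  converges to a genuine least-squares compromise that pins rise (and
  nearly pins fall) while carrying a large amplitude residual.
* **The species ordering of jointly fitted densities reverses**: the
  all-human model needs *more* Na⁺ and K⁺ density than the all-mouse
  model here, because the mouse model's left-shifted activation makes its
  Na⁺ more rise-efficient per unit density, and the human model's slow
  suprathreshold Na⁺ inactivation leaves a repolarization tail that must
  be countered with extra K⁺. Along the K⁺ mixing axis alone (Na⁺
  fraction held fixed) the required K⁺ density does decrease as the K⁺
  population becomes human. The corresponding acceptance expectations are
  left failing rather than weakened; with the original fitted channel
  kinetics the availability advantage evidently dominated instead.
* Equal-absolute-input comparisons depend on the relative rheobases of
  the two models, which the synthetic presets do not pin down.
* Single compartment throughout: no axon initial segment, no dendritic
  load, no series-resistance artifacts; conclusions are about somatic
  channel repertoires only.
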