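---
title: "Cell-autonomous calcium homeostasis in a conductance-based CA1 model neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-autonomous calcium homeostasis in a conductance-based CA1 model neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cahomsim)
```

## The model

`cahomsim` simulates a single-compartment cylindrical CA1 pyramidal model
neuron (d = L = 100 um, Rm = 35 kOhm.cm2, Cm = 1 uF/cm2, so the passive input
resistance is ~111 MOhm and the passive time constant 35 ms) carrying twelve
conductances: leak, fast sodium (NaF), delayed-rectifier (KDR), A-type (KA)
and M-type (KM) potassium, HCN, four voltage-gated calcium channels (CaT,
CaR, CaN, CaL), and the calcium-activated SK and BK potassium channels. The
membrane equation is integrated with exponential-Euler updates for the
voltage and every gate, at a default step of 25 us; reversal potentials are
+55 mV (Na+), -90 mV (K+) and -30 mV (HCN), and spikes are detected as
upward crossings of -20 mV with a 2 ms refractory period.

Excitatory drive arrives through a lumped AMPA/NMDA receptor synapse in the
Goldman-Hodgkin-Katz (GHK) formulation: each ionic component is a GHK flux
(Na+, K+ for AMPAR; Na+, K+, Ca2+ for NMDAR, the latter attenuated by the
standard magnesium block `1/(1 + [Mg]o exp(-0.062 v)/3.57)`), driven by a
time-varying permeability program. NMDAR permeability is tied to AMPAR
permeability by the ratio NAR = 1.5.

Cytosolic calcium is resolved on four concentric annuli (a submembrane shell
of thickness one tenth of the radius, whose concentration is "the" cytosolic
calcium, plus three equal-thickness inner annuli) with radial diffusion
(D = 0.22 um^2/ms), a 450 uM static buffer (Kd = 10 uM), SERCA uptake
(Vmax = 1e-4 mM/ms, Kp = 0.27 uM), a calibrated ER leak, and a plasma-membrane
pump that activates above 0.2 uM. Calcium enters the submembrane shell through
the four voltage-gated calcium channels and the NMDAR.

The homeostasis engine is a single-sensor integral controller: twelve mRNA
pools integrate the common error between a calcium target (default 200 nM)
and the submembrane calcium, each with its own time constant, and each
conductance relaxes toward its mRNA with a 10 ms translation time constant.
The mRNA time constants are derived from the reference model's conductances
so that `tau_i * g_i` is constant, anchored at 10 ms for the sodium channel;
because one error signal drives all twelve pools, the conductance vector
evolves along the ray through the reference conductances.

## Gating kinetics: what is pinned down and what the package chooses

The published parameter set (48 sampled quantities: passive properties and
per-channel maximal conductances, half-activation voltages and time
constants) specifies each gate's midpoint and time constant but neither slope
factors nor gate exponents. Every voltage gate here is a first-order
Boltzmann, `x_inf = 1/(1 + exp(-(v - V1/2)/k))`, with the package's fixed,
documented slope constants (see `fixed_kinetics()`); gate exponents are
NaF m^3·h·s, KDR n, KA n·l, KM and HCN single gates, CaT m^2·h, CaR m^3·h,
CaN m^2·h and CaL m·h. SK is purely calcium-gated (Hill coefficient 4) and BK
uses a Moczydlowski–Latorre-style pair of voltage/calcium-dependent rates
parameterized by the published k1 and k2 constants, with the published fixed
time constant. The slope constants were hand-tuned — the same procedure that
produced the published base parameter values — until the base model passes
all seven measurement bounds, and then frozen; they are deliberately not part
of the sampled parameter space.

Three choices deserve explicit justification, because the printed parameter
set alone does not yield a functioning spiking model:

* **CaL inactivation.** The published table gives CaL a single activation
  gate. A non-inactivating 100 uS/cm2 calcium conductance with a -27 mV
  midpoint creates a stable depolarized fixed point near -15 mV (a
  depolarization latch): after each spike the membrane hangs for hundreds of
  milliseconds, capping the 250 pA firing rate at ~4 Hz for *every* slope
  parameterization we scanned. The L-type channels in the hippocampal
  literature that the parameter set descends from inactivate; the package
  therefore gives CaL a fast voltage inactivation gate (V1/2 = -40 mV,
  k = -5 mV, tau = 8 ms — package constants, configurable).

* **KDR activation time constant.** The printed value (222.9 ms) cannot
  repolarize a spike. Delayed-rectifier models in this literature have
  activation time constants that accelerate strongly with depolarization, so
  the package makes the KDR tau voltage dependent: a 12 ms operating value
  across the voltages the cell actually visits, relaxing sigmoidally (midpoint
  -85 mV, slope 3 mV) to the printed value in the deeply hyperpolarized
  limit. A consequence worth stating plainly: the sampled variation of this
  parameter (111–446 ms) then has only a minor dynamical effect.

* **Calcium-channel driving force.** The calcium conductances are given in
  S/cm2, so the default driving force is ohmic with a fixed E_Ca = +120 mV.
  A GHK-shaped driving force (normalized to match the ohmic drive at
  -65 mV) is available via `fixed_kinetics()$ca_driving`.

## Measurements and validation

The seven intrinsic measurements follow the standard protocols: firing rate
at 250 pA (twice the spike count in 500 ms), spike amplitude (last spike peak
minus -65 mV), input resistance (least-squares slope of the steady-state V-I
relation over -50..+50 pA in 10 pA steps, steady state being the mean of the
last 50 ms of each 500 ms step), and the impedance measures from a 25 s,
50 pA chirp sweeping 0–25 Hz: |Z|max, resonance frequency f_R (argmax of the
impedance magnitude, lightly smoothed against single-bin ripple), resonance
strength Q = |Z(f_R)|/|Z(0.5 Hz)|, and total inductive phase (trapezoidal
integral of the positive-phase region on 0.5–25 Hz). All probes run from a
-65 mV rest enforced by a holding current solved for the frozen model, with
afferent drive off. A model is valid iff all seven measurements fall inside
their experimental intervals (inclusive at both ends; the source is silent on
boundary values).

With the frozen kinetics the base model measures f250 = 10 Hz,
V_AP = 97.6 mV, R_in = 58.6 MOhm, |Z|max = 66.8 MOhm, f_R = 4.2 Hz,
Q = 1.10 and Phi_L = 0 — inside every bound, stably across integration steps
of 12.5–50 us.

## The random population

`sample_population()` draws each of the 48 parameters independently and
uniformly from its published range (kept verbatim, including rows whose
default lies outside the printed range — these are flagged in
`parameter_table()$note`, not silently corrected). `evaluate_population()`
computes the seven measurements per model and applies the conjunction rule;
models that spike during subthreshold probes, never spike at 250 pA, or fail
to integrate are invalid and the run continues. Pairwise Pearson correlations
over the 48 parameters give the 1128 unordered-pair coefficients
(Spearman available). The valid yield under the package's kinetics is a few
percent to ~15% depending on the seed — the published ~2% depends on channel
kinetics that are not reproducible from the printed parameters, so we treat
it as qualitative.

## Homeostasis experiments and their study conditions

The theta drive is a non-negative 8 Hz raised-cosine permeability program
whose peak-to-peak amplitude is calibrated as the minimum (1% bisection
tolerance) that elicits steady-state spiking on every drive cycle of the
reference model. We read "the minimum amplitude required to elicit action
potentials" as per-cycle firing because that is the regime evolved models
display at steady state; the weaker one-spike-per-second reading (available
as `min_rate = 1`) leaves the model in a sparse-firing regime where the
steady-state calcium is a non-monotone function of the overall conductance
scale, with multiple homeostatic fixed points. The sharp-wave-ripple drive
tiles the published two-Gaussian/ripple waveform (floored at zero, since a
permeability cannot be negative) at 3 Hz, scaled so a single event deflects
the membrane by ~7.5 mV (±2.5 mV).

Free calcium-handling constants (values the source does not print) are: ER
density factor beta = 0.1, ER calcium 400 uM, buffer on-rate 100 /(mM ms),
diffusion coefficient 0.22 um^2/ms. The ER leak is calibrated so leak and
SERCA cancel at the nominal 50 nM rest; the standing calcium-channel window
influx at -65 mV then shifts the attained rest to ~75 nM, which
`resting_calcium()` solves self-consistently and `initial_state()` uses.
beta was chosen so that (i) the resting point stays below the lowest
homeostatic target examined (100 nM), and (ii) the calcium-versus-conductance
curve crosses all three targets (100/200/300 nM) at conductance scales the
integral controller reaches within an epoch. It was fixed before the
acceptance runs and not revisited.

Scaled-down mode: the full-scale experiment (150 s per epoch at unscaled
time constants) is compressed by scaling all mRNA and translation time
constants by 0.01, which compresses the controller's trajectory without
moving its fixed point. Under this mode the engine reaches steady state in
tens of simulated seconds; the reported steady-state calcium equals the
target to ~0.3% for all three targets.

One numerical subtlety: the inner annuli form a large, buffered calcium
reservoir that equilibrates over ~300 s of simulated time — a timescale set
by diffusion and buffering, which does *not* rescale with the controller's
time constants. Convergence-triggered stopping therefore lands on a slow
manifold (calcium pinned at target, conductances drifting slowly as the
reservoir fills), and two runs with different tau scales stop at different
points on it. The tau-rescaling control is therefore run with fixed-duration
epochs (500 s scaled), after which steady-state conductances agree to ~2e-5
relative between x0.01 and x0.02 scalings — the controller's fixed point is
exactly invariant, as the integral-control algebra predicts
(`m_i(t) = m_i(0) + E(t)/tau_i` shares one integrated error E across
channels, so uniform tau rescaling reparameterizes the same ray).

Switch protocols (`run_switch_protocol()`) chain three steady-state epochs
with the drive alternating between theta and SWR, inserting the mandated 1 s
reset clamp to -65 mV before every theta-to-SWR switch; a model is classified
robust if no conductance changes by more than 10% (configurable) between the
first and third epochs, and plastic otherwise. Depolarization block (trailing
mean voltage above -40 mV with no spikes) is flagged in the results.

## What the synthetic experiments do and do not show

All inputs are generated internally: the population sampler, the drive
programs and the controller's randomized initial conditions (uniform in
[0, 0.01 x reference conductance], seeded) define the study conditions.
Passing tests demonstrate internal consistency — passive analytics equal to
their closed forms, GHK fluxes crossing zero at Nernst potentials, exact
conservation in the sealed calcium system, the controller's fixed point and
its tau invariance — not fidelity to any particular biological neuron. In
particular the split between robust and plastic models, the valid-model
yield, and the measurement histograms depend on kinetic details the printed
parameters do not determine, and are qualitative here.

## Numerical choices and limitations

* Exponential Euler for gates and the (linearized) voltage equation; the
  synaptic GHK currents and, in GHK-driving mode, the calcium-channel
  currents are held constant within a step. Default dt = 25 us; halving it
  changes an active theta-driven trace by well under 0.5 mV RMS, and tests
  run some protocols at 50 us under that convergence guarantee.
* Buffering uses a per-shell implicit (closed-form quadratic) substep: the
  fast on-rate makes explicit Euler unstable at 25 us, while the implicit
  update is unconditionally stable and conserves calcium + bound buffer
  exactly.
* The membrane-pump sensitivity (8 um/s) is converted to a rate constant on
  the submembrane shell via its surface-to-volume ratio (1.68e-3 /ms).
* `BK-k_2` is read as uM (130 nM), consistent in magnitude with the SK
  half-activation (140 nM).
* Problem sizes in the tests: populations of up to 500 models at dt = 50 us,
  homeostasis runs of up to 500 s simulated time at x0.01-scaled time
  constants; the acceptance script's runs use the same scales.
* Known limitations: a single compartment (no dendritic channel gradients),
  one lumped synapse, no receptor desensitization or stochastic gating, a
  single transcription factor (by design), and the slow inner-annulus
  reservoir discussed above.
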