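# cahomsim

How does a neuron keep its intracellular calcium at a set point while the
activity it receives keeps changing with behavioural state? `cahomsim` is an R
package for studying that question in a conductance-based model of a
hippocampal CA1 pyramidal neuron. It is aimed at computational
neurophysiologists who want a self-contained, scriptable implementation of:

* a single-compartment cylindrical neuron (100 x 100 um, Rm = 35 kOhm.cm2,
  Cm = 1 uF/cm2) with twelve conductances — leak, NaF, KDR, KA, KM, HCN, CaT,
  CaR, CaN, CaL, SK and BK — in Hodgkin-Huxley form,
  `C_m dV/dt = -sum_i g_i * (open fraction)_i * (V - E_i) + I`;
* AMPA/NMDA receptor drive in the Goldman-Hodgkin-Katz formulation with
  magnesium block, driven by theta-frequency (8 Hz) or sharp-wave-ripple
  (150 Hz ripple, 3 Hz repeat) permeability programs;
* detailed calcium handling: four concentric annuli with radial diffusion, a
  static buffer, SERCA uptake `J = Vmax [Ca]^2/([Ca]^2 + Kp^2)`, a calibrated
  ER leak, and a thresholded membrane pump;
* the seven standard intrinsic measurements (f250, V_AP, R_in, |Z|max, f_R,
  Q, Phi_L) with experimentally bounded validation, random model populations,
  and pairwise parameter correlations;
* a cell-autonomous calcium-homeostasis engine — integral control of twelve
  mRNAs and conductances, `tau_i dm_i/dt = [Ca]_target - [Ca]_cyt`,
  `tau_g dg_i/dt = m_i - g_i` — run to steady state under one drive type, or
  through theta/SWR state-switch protocols with robust/plastic
  classification.

The integrator core is compiled (Rcpp); a one-second simulation at the
default 25 us step takes a few milliseconds.

## Worked example

```r
library(cahomsim)

model <- base_model()                      # the hand-tuned reference model
measure_all(model)
#>   f250  v_ap  r_in z_max  f_r   q phi_l valid
#> 1   10 97.53 58.55  66.8 4.16 1.1     0     1
```

The base model fires at 10 Hz to a 250 pA step with 97.5 mV spikes, has an
input resistance of 58.6 MOhm and a 4.2 Hz subthreshold resonance — all seven
measurements inside their experimental bounds (`valid = 1`).

```r
amp <- calibrate_theta_amplitude(model)    # minimum drive spiking every cycle
#> 1.907e-08 cm/s
homeo <- homeostasis_params(model, ca_target = 2e-4, tau_scale = 0.01, seed = 1)
res <- run_to_steady_state(model, epoch_theta(1000, amp), homeo)
#> steady state after 66 s: calcium 200.3 nM (target 200), 8 spikes/s
signif(res$g_steady, 3)
#>     Leak      NaF      KDR       KA       KM      HCN      CaT      CaR
#> 0.011900 2.920000 1.260000 3.380000 0.000416 0.033800 0.042300 0.042100
#>      CaN      CaL       SK       BK
#> 0.042000 0.041500 0.000416 0.000416
```

Starting from near-zero conductances, the controller grows all twelve
conductances along the ray through the reference model (here to ~42% of it)
until the mean submembrane calcium sits on the 200 nM target, with the neuron
firing once per theta cycle at steady state. `run_switch_protocol()` chains
theta -> SWR -> theta epochs (with a 1 s reset clamp before each theta-to-SWR
switch) and classifies the model as robust or plastic from the conductance
change between the first and third epochs.

Population screening mirrors the global-sensitivity-analysis workflow:

```r
pop <- sample_population(500, seed = 1)    # uniform draws of all 48 parameters
ev  <- evaluate_population(pop)            # seven measurements + validity each
pc  <- pairwise_correlations(ev$parameters[ev$measurements$valid, ])  # 1128 pairs
```

The methods vignette (`vignettes/calcium-homeostasis.Rmd`) documents the
model equations, the package's documented choices for quantities the source
parameter tables do not pin down (gate slopes and exponents, CaL
inactivation, the KDR time-constant voltage dependence, calcium-handling
constants), and the study conditions of the homeostasis experiments.

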