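# Single-compartment geometry, passive analytics, and gating primitives.

#' Cylindrical compartment geometry
#'
#' @param diameter Diameter in um (default 100).
#' @param length Length in um (default 100).
#' @return List with `diameter`, `length` (um) and `area`, the lateral
#'   cylindrical surface in cm^2.
#' @export
neuron_geometry <- function(diameter = 100, length = 100) {
  if (!is.finite(diameter) || !is.finite(length) || diameter <= 0 || length <= 0) {
    stop("invalid geometry: diameter and length must be positive")
  }
  list(diameter = diameter, length = length,
       area = lateral_area_um(diameter, length))
}

lateral_area_um <- function(diameter, length) {
  pi * (diameter * 1e-4) * (length * 1e-4)  # um -> cm
}

#' Lateral surface area of the compartment
#'
#' @param geometry A geometry from [neuron_geometry()].
#' @return Area in cm^2 (pi * d * L).
#' @export
lateral_area <- function(geometry) geometry$area

#' Passive input resistance
#'
#' Specific membrane resistance divided by membrane area.
#'
#' @param Rm Specific membrane resistance, kOhm.cm2.
#' @param geometry A geometry from [neuron_geometry()].
#' @return Input resistance in MOhm.
#' @export
passive_input_resistance <- function(Rm, geometry) {
  if (Rm <= 0) stop("Rm must be positive")
  # kOhm.cm2 / cm2 = kOhm; -> MOhm
  Rm / geometry$area * 1e-3
}

#' Boltzmann steady-state activation
#'
#' First-order gate steady state `1/(1 + exp(-(v - half)/slope))`. A positive
#' slope encodes activation (opens with depolarization), a negative slope
#' inactivation.
#'
#' @param v Membrane voltage, mV (vectorized).
#' @param half Half-activation voltage, mV.
#' @param slope Slope factor, mV; must be nonzero.
#' @return Open fraction in (0, 1).
#' @export
boltzmann_ss <- function(v, half, slope) {
  if (slope == 0) stop("invalid gate: slope factor must be nonzero")
  1 / (1 + exp(-(v - half) / slope))
}

#' Hill-type calcium activation
#'
#' Saturating calcium dependence used by the SK channel: half-maximal at
#' `half`, Hill coefficient `n`.
#'
#' @param ca Calcium concentration (any unit, matched with `half`); >= 0.
#' @param half Half-activation concentration (> 0).
#' @param n Hill coefficient.
#' @return Activation in [0, 1).
#' @export
hill_ca <- function(ca, half, n = 4) {
  if (any(ca < 0)) stop("calcium concentration must be non-negative")
  if (half <= 0) stop("half-activation concentration must be positive")
  r <- (ca / half)^n
  r / (1 + r)
}

#' BK gate steady state
#'
#' Voltage- and calcium-dependent activation: a voltage Boltzmann whose
#' half-point shifts with calcium through the published constants k1 (mM) and
#' k2 (Ca half-activation). Implemented as opposing voltage/calcium-dependent
#' rates alpha = abar / (1 + k1 e^(-2 d1 F v / RT) / ca) and
#' beta = bbar / (1 + ca / (k2 e^(-2 d2 F v / RT))), steady state
#' alpha/(alpha+beta); the time constant is the fixed published value.
#'
#' @param v Voltage, mV.
#' @param ca Calcium, mM.
#' @param k1 Calcium slope constant, mM.
#' @param k2 Calcium half-activation, mM.
#' @param kin Fixed kinetics list (for d1, d2, abar, bbar); defaults to
#'   [fixed_kinetics()].
#' @param temperature Temperature, K.
#' @return Open fraction in (0, 1).
#' @export
bk_ss <- function(v, ca, k1, k2, kin = fixed_kinetics(), temperature = 308.15) {
  vfrt <- (v * 1e-3) * FARADAY / (GAS_R * temperature)
  a <- kin$BK_abar / (1 + k1 * exp(-2 * kin$BK_d1 * vfrt) / ca)
  b <- kin$BK_bbar / (1 + ca / (k2 * exp(-2 * kin$BK_d2 * vfrt)))
  a / (a + b)
}

FARADAY <- 96485.33212   # C/mol
GAS_R <- 8.31446         # J/(mol K)

#' Gate steady states of a model
#'
#' All sixteen voltage/calcium gate steady-state values at a given voltage and
#' cytosolic calcium, in the internal gate order used by the integrator.
#'
#' @param model A `cahom_model`.
#' @param v Voltage, mV.
#' @param ca Cytosolic (outer annulus) calcium, mM; defaults to the resting
#'   concentration.
#' @return Named numeric vector of 16 gate open fractions.
#' @export
gate_steady_states <- function(model, v, ca = model$calcium$ca_rest) {
  p <- model$params; k <- model$kinetics
  c(Na_m = boltzmann_ss(v, p$Na_V_m, k$Na_k_m),
    Na_h = boltzmann_ss(v, p$Na_V_h, k$Na_k_h),
    Na_s = boltzmann_ss(v, p$Na_V_s, k$Na_k_s),
    DR_n = boltzmann_ss(v, p$DR_V_n, k$DR_k_n),
    A_n  = boltzmann_ss(v, p$A_V_n,  k$A_k_n),
    A_l  = boltzmann_ss(v, p$A_V_l,  k$A_k_l),
    M_n  = boltzmann_ss(v, p$M_V,    k$M_k),
    h_l  = boltzmann_ss(v, p$h_V_l,  k$h_k),
    T_m  = boltzmann_ss(v, p$T_V_m,  k$T_k_m),
    T_h  = boltzmann_ss(v, p$T_V_h,  k$T_k_h),
    R_m  = boltzmann_ss(v, p$R_V_m,  k$R_k_m),
    R_h  = boltzmann_ss(v, p$R_V_h,  k$R_k_h),
    N_m  = boltzmann_ss(v, p$N_V_m,  k$N_k_m),
    N_h  = boltzmann_ss(v, p$N_V_h,  k$N_k_h),
    L_m  = boltzmann_ss(v, p$L_V_a,  k$L_k_m),
    L_h  = boltzmann_ss(v, k$L_V_h,  k$L_k_h),
    SK_z = hill_ca(ca, p$SK_Ca * 1e-6, k$SK_hill),  # nM -> mM
    BK_z = bk_ss(v, ca, p$BK_k1, p$BK_k2 * 1e-3,    # uM -> mM
                 kin = k, temperature = model$concentrations$temperature))
}

#' Per-channel membrane current densities
#'
#' Steady-state ohmic current density of each of the twelve channels at a
#' voltage and calcium level (gates at steady state). Inward currents are
#' negative.
#'
#' @inheritParams gate_steady_states
#' @return Named 12-vector of current densities, uA/cm^2.
#' @export
channel_currents <- function(model, v, ca = model$calcium$ca_rest) {
  g <- conductance_vector(model)
  x <- gate_steady_states(model, v, ca)
  k <- model$kinetics
  open <- c(Leak = 1,
            NaF = x[["Na_m"]]^k$Na_exp_m * x[["Na_h"]] * x[["Na_s"]],
            KDR = x[["DR_n"]],
            KA  = x[["A_n"]] * x[["A_l"]],
            KM  = x[["M_n"]],
            HCN = x[["h_l"]],
            CaT = x[["T_m"]]^k$T_exp_m * x[["T_h"]],
            CaR = x[["R_m"]]^k$R_exp_m * x[["R_h"]],
            CaN = x[["N_m"]]^k$N_exp_m * x[["N_h"]],
            CaL = x[["L_m"]] * x[["L_h"]],
            SK  = x[["SK_z"]],
            BK  = x[["BK_z"]])
  erev <- c(Leak = k$E_leak, NaF = k$E_Na, KDR = k$E_K, KA = k$E_K,
            KM = k$E_K, HCN = k$E_h, CaT = k$E_Ca, CaR = k$E_Ca,
            CaN = k$E_Ca, CaL = k$E_Ca, SK = k$E_K, BK = k$E_K)
  drive <- v - erev[names(g)]
  ca_ch <- c("CaT", "CaR", "CaN", "CaL")
  if (identical(k$ca_driving, "ghk")) {
    drive[ca_ch] <- vgcc_driving_force(v, model)
  }
  g * open[names(g)] * drive  # mS/cm2 * mV = uA/cm2
}

#' GHK-shaped driving force for the voltage-gated calcium channels
#'
#' The calcium channels carry a GHK-rectified current rather than an ohmic one:
#' the driving-force function is the GHK calcium flux shape, normalized so that
#' it equals the ohmic drive `v_ref - E_Ca` at the resting reference voltage.
#' Table-format maximal conductances (S/cm^2) therefore keep their printed
#' meaning near rest, while the inward current collapses at depolarized
#' voltages as in GHK-based channel models.
#'
#' @param v Voltage, mV (vectorized).
#' @param model A `cahom_model`.
#' @return Effective driving force, mV (negative = inward).
#' @export
vgcc_driving_force <- function(v, model = base_model()) {
  k <- model$kinetics; cc <- model$concentrations
  ref <- ghk_current(1, 2, k$ca_drive_vref, cc$ca_in, cc$ca_out, cc$temperature)
  scale <- (k$ca_drive_vref - k$E_Ca) / ref
  scale * ghk_current(1, 2, v, cc$ca_in, cc$ca_out, cc$temperature)
}

#' Holding current pinning rest at a target voltage
#'
#' Constant injected current that balances the total steady-state membrane
#' current at the target voltage, so probes start from a quiet -65 mV
#' baseline.
#'
#' @param model A `cahom_model`.
#' @param v Holding voltage, mV (default -65).
#' @return Holding current in pA (positive = depolarizing injection).
#' @export
holding_current <- function(model, v = -65) {
  i_net <- sum(channel_currents(model, v))          # uA/cm2
  i_net * model$geometry$area * 1e6                 # uA/cm2 * cm2 -> pA
}
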