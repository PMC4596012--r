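# GHK-based AMPA/NMDA receptor currents with magnesium block.

#' Goldman-Hodgkin-Katz current density for one ion
#'
#' `P z^2 v F^2 / (RT) * (c_in - c_out exp(-z v F/RT)) / (1 - exp(-z v F/RT))`,
#' with the v -> 0 singularity replaced by its analytic (second-order Taylor)
#' limit. Inward current is negative.
#'
#' @param P Permeability, cm/s.
#' @param z Ion valence.
#' @param v Membrane voltage, mV (vectorized).
#' @param c_in,c_out Intra/extracellular concentration, mM.
#' @param temperature Temperature, K (> 0).
#' @return Current density in mA/cm^2.
#' @export
ghk_current <- function(P, z, v, c_in, c_out, temperature = 308.15) {
  if (temperature <= 0) stop("temperature must be positive (K)")
  u <- z * (v * 1e-3) * FARADAY / (GAS_R * temperature)  # dimensionless
  # concentrations mM = 1e-6 mol/cm3; current A/cm2 -> mA/cm2 factor 1e3
  pref <- P * z * FARADAY * 1e-6 * 1e3
  small <- abs(u) < 1e-4
  out <- numeric(length(u))
  if (any(!small)) {
    us <- u[!small]
    out[!small] <- pref * us * (c_in - c_out * exp(-us)) / (1 - exp(-us))
  }
  if (any(small)) {
    us <- u[small]
    # Taylor: u/(1-e^-u) = 1 + u/2 + u^2/12; u e^-u/(1-e^-u) = 1 - u/2 + u^2/12
    out[small] <- pref * ((c_in - c_out) +
                            us / 2 * (c_in + c_out) +
                            us^2 / 12 * (c_in - c_out))
  }
  out
}

#' Magnesium block of the NMDA receptor
#'
#' `1 / (1 + [Mg]_o exp(-0.062 v) / 3.57)`; monotonically relieved by
#' depolarization.
#'
#' @param v Voltage, mV (vectorized).
#' @param mg_out Extracellular Mg2+, mM (>= 0).
#' @return Unblocked fraction in (0, 1].
#' @export
mg_block <- function(v, mg_out = 2) {
  if (mg_out < 0) stop("mg_out must be non-negative")
  1 / (1 + mg_out * exp(-0.062 * v) / 3.57)
}

#' AMPA receptor current
#'
#' Sum of sodium and potassium GHK components with equal relative
#' permeabilities.
#'
#' @param v Voltage, mV (vectorized).
#' @param p_ampar AMPAR maximum permeability, cm/s.
#' @param conc Ion concentrations, see [default_concentrations()].
#' @return Current density, mA/cm^2.
#' @export
ampar_current <- function(v, p_ampar, conc = default_concentrations()) {
  ghk_current(p_ampar, 1, v, conc$na_in, conc$na_out, conc$temperature) +
    ghk_current(p_ampar, 1, v, conc$k_in, conc$k_out, conc$temperature)
}

#' NMDA receptor current
#'
#' Sodium, potassium and calcium GHK components, each scaled by the magnesium
#' block. The calcium component is returned separately: it is a source term
#' for the calcium dynamics.
#'
#' @param v Voltage, mV (vectorized).
#' @param p_ampar AMPAR maximum permeability, cm/s (NMDAR permeability is
#'   `nar * p_ampar`).
#' @param nar NMDAR:AMPAR permeability ratio (default 1.5).
#' @param conc Ion concentrations, see [default_concentrations()].
#' @param syn Relative permeabilities, see [default_synapse()].
#' @return List with `total` and `ca` current densities (mA/cm^2).
#' @export
nmdar_current <- function(v, p_ampar, nar = 1.5,
                          conc = default_concentrations(),
                          syn = default_synapse()) {
  if (nar < 0 || p_ampar < 0) stop("permeabilities must be non-negative")
  p <- nar * p_ampar
  blk <- mg_block(v, conc$mg_out)
  i_na <- blk * ghk_current(p * syn$P_Na, 1, v, conc$na_in, conc$na_out, conc$temperature)
  i_k  <- blk * ghk_current(p * syn$P_K, 1, v, conc$k_in, conc$k_out, conc$temperature)
  i_ca <- blk * ghk_current(p * syn$P_Ca, 2, v, conc$ca_in, conc$ca_out, conc$temperature)
  list(total = i_na + i_k + i_ca, ca = i_ca)
}
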