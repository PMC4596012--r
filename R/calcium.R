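# Cytosolic calcium handling: four concentric annuli with radial diffusion,
# static buffer, SERCA uptake, ER leak and plasma-membrane extrusion.

#' Annulus discretization of the cylindrical compartment
#'
#' Four concentric annuli: a thin submembrane shell (thickness 0.1 * radius)
#' whose concentration is the cytosolic calcium, and the remaining volume split
#' into three equal-thickness annuli.
#'
#' @param geometry A geometry from [neuron_geometry()].
#' @param n_annuli Number of annuli (fixed at 4).
#' @return List with boundary radii `r` (um, outermost first), shell volumes
#'   `volume` (um^2 per unit length), interface areas `interface` (um per unit
#'   length), centre-to-centre distances `dr` (um), and the outer-shell
#'   surface-to-volume ratio `sv_outer` (1/um).
#' @export
annulus_geometry <- function(geometry = neuron_geometry(), n_annuli = 4) {
  if (n_annuli != 4) stop("the radial discretization is fixed at 4 annuli")
  a <- geometry$diameter / 2
  r <- c(a, 0.9 * a, 0.6 * a, 0.3 * a, 0)
  vol <- pi * (r[-5]^2 - r[-1]^2)
  centres <- (r[-5] + r[-1]) / 2
  list(r = r,
       volume = vol,
       interface = 2 * pi * r[2:4],
       dr = centres[-4] - centres[-1],
       sv_outer = 2 * pi * a / vol[1])
}

#' Calcium-handling parameters
#'
#' Defaults: SERCA Vmax 1e-4 mM/ms with Kp 0.27 uM, membrane pump threshold
#' 0.2 uM with sensitivity 8 um/s (converted to a rate constant on the outer
#' shell through its surface-to-volume ratio), 450 uM static buffer with
#' dissociation constant 10 uM and fast on-rate, ER calcium 400 uM, diffusion
#' coefficient 0.22 um^2/ms, resting cytosolic calcium 50 nM. The ER leak
#' constant is calibrated so leak and SERCA cancel at rest.
#'
#' @param geometry A geometry from [neuron_geometry()].
#' @param d_ca Calcium diffusion coefficient, um^2/ms.
#' @param buffer_total Total static buffer, mM.
#' @param k_buf Buffer dissociation constant, mM.
#' @param k_on Buffer on-rate, 1/(mM ms).
#' @param v_max_serca SERCA maximal uptake, mM/ms.
#' @param k_p SERCA dissociation constant, mM.
#' @param gamma_pump Membrane pump sensitivity, um/s.
#' @param ca_crt Pump activation threshold, mM.
#' @param ca_er ER calcium, mM.
#' @param beta_er ER leak/SERCA density factor (dimensionless; scales the net
#'   ER flux term, setting how strongly the ER clears sub-threshold calcium
#'   loads relative to the voltage-gated influx).
#' @param ca_rest Resting cytosolic calcium, mM.
#' @return Named list of calcium parameters, including the derived
#'   `gamma_eff` (1/ms), `leak_constant` (mM/ms) and the annulus geometry.
#' @export
calcium_params <- function(geometry = neuron_geometry(),
                           d_ca = 0.22, buffer_total = 0.45, k_buf = 0.01,
                           k_on = 100, v_max_serca = 1e-4, k_p = 2.7e-4,
                           gamma_pump = 8, ca_crt = 2e-4, ca_er = 0.4,
                           beta_er = 0.1, ca_rest = 50e-6) {
  ann <- annulus_geometry(geometry)
  p <- list(d_ca = d_ca, n_annuli = 4L, buffer_total = buffer_total,
            k_buf = k_buf, k_on = k_on, k_off = k_buf * k_on,
            v_max_serca = v_max_serca, k_p = k_p,
            gamma_pump = gamma_pump,
            gamma_eff = gamma_pump * ann$sv_outer * 1e-3,  # um/s * 1/um -> 1/ms
            ca_crt = ca_crt, ca_er = ca_er, beta_er = beta_er,
            ca_rest = ca_rest, annuli = ann)
  p$leak_constant <- calibrate_leak(p)
  p
}

#' SERCA pump uptake
#'
#' Hill (n = 2) uptake `Vmax ca^2 / (ca^2 + Kp^2)`.
#'
#' @param ca Cytosolic calcium, mM (vectorized, >= 0).
#' @param params Calcium parameters from [calcium_params()].
#' @return Uptake flux, mM/ms.
#' @export
serca_uptake <- function(ca, params = calcium_params()) {
  if (any(ca < 0)) stop("calcium must be non-negative")
  params$v_max_serca * ca^2 / (ca^2 + params$k_p^2)
}

#' Plasma-membrane pump extrusion
#'
#' Inactive below the critical concentration; linear in the excess above it
#' (continuous at the threshold).
#'
#' @inheritParams serca_uptake
#' @return Extrusion flux, mM/ms.
#' @export
membrane_pump <- function(ca, params = calcium_params()) {
  if (any(ca < 0)) stop("calcium must be non-negative")
  params$gamma_eff * pmax(ca - params$ca_crt, 0)
}

#' ER leak flux
#'
#' `L (1 - ca / ca_ER)`: calcium enters the cytosol while below the ER level.
#'
#' @inheritParams serca_uptake
#' @return Leak flux into the cytosol, mM/ms.
#' @export
er_leak <- function(ca, params = calcium_params()) {
  params$leak_constant * (1 - ca / params$ca_er)
}

#' Calibrate the ER leak constant
#'
#' Chooses L so that leak and SERCA cancel at the resting cytosolic calcium
#' (no net ER flux at rest, -65 mV).
#'
#' @param params Calcium parameters (the `leak_constant` field is ignored).
#' @param resting_ca Resting calcium, mM; defaults to `params$ca_rest`.
#' @return Leak constant L, mM/ms.
#' @export
calibrate_leak <- function(params, resting_ca = params$ca_rest) {
  if (resting_ca >= params$ca_er) stop("resting calcium must be below ER calcium")
  j_serca <- params$v_max_serca * resting_ca^2 / (resting_ca^2 + params$k_p^2)
  j_serca / (1 - resting_ca / params$ca_er)
}

#' Buffering rate of the static buffer
#'
#' `R_buf = -k_on ca B_free + k_off CaB`; the bound pool changes by `-R_buf`.
#'
#' @param ca Free calcium, mM.
#' @param b_free Free buffer, mM.
#' @param ca_b Calcium-bound buffer, mM; `b_free + ca_b` must equal the total
#'   buffer concentration.
#' @param params Calcium parameters.
#' @return List with `r_buf` (rate of change of free calcium, mM/ms) and
#'   `d_bound` (rate of change of the bound pool, mM/ms).
#' @export
buffer_rate <- function(ca, b_free, ca_b, params = calcium_params()) {
  if (abs(b_free + ca_b - params$buffer_total) >
      1e-9 * max(1, params$buffer_total)) {
    stop("buffer conservation violated: b_free + ca_b != buffer_total")
  }
  r <- -params$k_on * ca * b_free + params$k_off * ca_b
  list(r_buf = r, d_bound = -r)
}

#' Calcium influx from voltage-gated channels and NMDARs
#'
#' Converts an inward calcium current density into a concentration flux in the
#' submembrane shell: `-I_Ca * (A/V_outer) / (2F)`. Inward (negative) current
#' yields a positive flux.
#'
#' @param i_ca Calcium current density, mA/cm^2 (inward negative).
#' @param geometry A geometry from [neuron_geometry()].
#' @return Concentration flux into the outer shell, mM/ms.
#' @export
vgcc_influx <- function(i_ca, geometry = neuron_geometry()) {
  ann <- annulus_geometry(geometry)
  sv_cm <- ann$sv_outer * 1e4  # 1/um -> 1/cm
  # mA/cm2 * (1/cm) / (2 * F C/mol): mol/(cm3 ms) * 1e6 -> mM/ms (factors cancel)
  -i_ca * sv_cm / (2 * FARADAY)
}

#' One conservative radial diffusion step
#'
#' Explicit finite-volume update of the four annulus concentrations; total
#' volume-weighted calcium is conserved exactly.
#'
#' @param shells Numeric 4-vector of concentrations (outermost first), mM.
#' @param d_ca Diffusion coefficient, um^2/ms.
#' @param dt Time step, ms.
#' @param geometry A geometry from [neuron_geometry()].
#' @return Updated 4-vector.
#' @export
diffuse_step <- function(shells, d_ca = 0.22, dt = 0.025,
                         geometry = neuron_geometry()) {
  stopifnot(length(shells) == 4)
  ann <- annulus_geometry(geometry)
  # stability bound for the explicit scheme
  lam <- d_ca * dt * max(ann$interface / ann$dr / pmin(ann$volume[-4], ann$volume[-1]))
  if (lam > 0.5) {
    stop(sprintf("dt = %g ms too large for stable explicit diffusion; reduce dt below %g ms",
                 dt, 0.5 * dt / lam))
  }
  flux <- d_ca * (shells[-1] - shells[-4]) / ann$dr * ann$interface  # into shell i
  d <- c(flux, 0) - c(0, flux)
  shells + dt * d / ann$volume
}


#' Self-consistent resting cytosolic calcium
#'
#' The ER leak is calibrated so leak and SERCA cancel at the nominal resting
#' concentration; the small standing influx through the calcium-channel
#' windows at -65 mV then shifts the true resting point slightly upward. This
#' solves the full outer-shell balance (ER flux, membrane pump and standing
#' VGCC influx) for the resting concentration actually attained.
#'
#' @param model A `cahom_model`.
#' @param v Resting voltage, mV.
#' @return Resting cytosolic calcium, mM.
#' @export
resting_calcium <- function(model, v = -65) {
  p <- model$calcium
  i_ca <- sum(channel_currents(model, v)[c("CaT", "CaR", "CaN", "CaL")]) * 1e-3
  j_in <- vgcc_influx(i_ca, model$geometry)
  f <- function(ca) {
    p$beta_er * (er_leak(ca, p) - serca_uptake(ca, p)) + j_in -
      membrane_pump(ca, p)
  }
  if (f(p$ca_rest) <= 0) return(p$ca_rest)
  stats::uniroot(f, c(p$ca_rest, 0.99 * p$ca_er), tol = 1e-12)$root
}
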