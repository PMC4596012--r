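# R-side driver for the compiled integrator.

# gate order used by the integrator (15 voltage gates, then SK, BK)
gate_order <- function() {
  c("Na_m", "Na_h", "Na_s", "DR_n", "A_n", "A_l", "M_n", "h_l",
    "T_m", "T_h", "R_m", "R_h", "N_m", "N_h", "L_m", "L_h", "SK_z", "BK_z")
}

# flatten a cahom_model into the parameter list consumed by the C++ core
model_to_core <- function(model) {
  p <- model$params; k <- model$kinetics; cc <- model$concentrations
  cal <- model$calcium; ann <- cal$annuli
  list(
    area = model$geometry$area, Cm = p$Cm,
    g = unname(conductance_vector(model)),
    gate_vhalf = c(p$Na_V_m, p$Na_V_h, p$Na_V_s, p$DR_V_n, p$A_V_n, p$A_V_l,
                   p$M_V, p$h_V_l, p$T_V_m, p$T_V_h, p$R_V_m, p$R_V_h,
                   p$N_V_m, p$N_V_h, p$L_V_a, k$L_V_h),
    gate_slope = c(k$Na_k_m, k$Na_k_h, k$Na_k_s, k$DR_k_n, k$A_k_n, k$A_k_l,
                   k$M_k, k$h_k, k$T_k_m, k$T_k_h, k$R_k_m, k$R_k_h,
                   k$N_k_m, k$N_k_h, k$L_k_m, k$L_k_h),
    gate_tau = c(p$Na_tau_m, p$Na_tau_h, p$Na_tau_s, p$DR_tau_n, p$A_tau_n,
                 p$A_tau_l, p$M_tau, p$h_tau_l, p$T_tau_m, p$T_tau_h,
                 p$R_tau_m, p$R_tau_h, p$N_tau_m, p$N_tau_h, p$L_tau_m,
                 k$L_tau_h),
    gate_tau_vdep = c(0, 0, 0, as.numeric(isTRUE(k$DR_tau_vdep)), 0,
                      as.numeric(isTRUE(k$A_tau_vdep)), rep(0, 10)),
    gate_tau_floor = c(0, 0, 0, k$DR_tau_floor, 0, k$A_tau_depol, rep(0, 10)),
    gate_tau_vhalf = c(0, 0, 0, k$DR_tau_vhalf, 0, k$A_tau_vhalf, rep(0, 10)),
    gate_tau_k = c(1, 1, 1, k$DR_tau_kslope, 1, k$A_tau_kslope, rep(1, 10)),
    exp_na_m = k$Na_exp_m, exp_t_m = k$T_exp_m, exp_r_m = k$R_exp_m,
    exp_n_m = k$N_exp_m,
    sk_ca_half = p$SK_Ca * 1e-6, sk_hill = k$SK_hill, sk_tau = p$SK_tau,
    bk_k1 = p$BK_k1, bk_k2 = p$BK_k2 * 1e-3, bk_tau = p$BK_tau,
    bk_d1 = k$BK_d1, bk_d2 = k$BK_d2, bk_abar = k$BK_abar, bk_bbar = k$BK_bbar,
    E_Na = k$E_Na, E_K = k$E_K, E_h = k$E_h, E_Ca = k$E_Ca, E_leak = k$E_leak,
    ca_ghk = as.numeric(identical(k$ca_driving, "ghk")),
    ca_drive_vref = k$ca_drive_vref,
    nar = model$synapse$nar, P_Ca = model$synapse$P_Ca,
    P_Na = model$synapse$P_Na, P_K = model$synapse$P_K,
    na_in = cc$na_in, na_out = cc$na_out, k_in = cc$k_in, k_out = cc$k_out,
    ca_in = cc$ca_in, ca_out = cc$ca_out, mg_out = cc$mg_out,
    temperature = cc$temperature,
    d_ca = cal$d_ca, ann_volume = ann$volume, ann_interface = ann$interface,
    ann_dr = ann$dr, sv_outer_cm = ann$sv_outer * 1e4,
    buffer_total = cal$buffer_total, k_on = cal$k_on, k_off = cal$k_off,
    v_max_serca = cal$v_max_serca, k_p = cal$k_p, gamma_eff = cal$gamma_eff,
    ca_crt = cal$ca_crt, ca_er = cal$ca_er, beta_er = cal$beta_er,
    leak_constant = cal$leak_constant,
    spike_threshold = k$spike_threshold, spike_refractory = k$spike_refractory
  )
}

epochs_matrix <- function(program) {
  kinds <- c(silent = 0, theta = 1, swr = 2, reset = 3, current_step = 4,
             chirp = 5)
  m <- t(vapply(program, function(e) {
    c(kinds[[e$kind]], e$duration, e$amplitude, e$frequency,
      e$f_ripple %||% 150, (e$span_s %||% 0) * 1000)
  }, numeric(6)))
  colnames(m) <- c("kind", "duration", "amplitude", "frequency", "f_ripple",
                   "span_ms")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial integrator state
#'
#' Voltage at the holding potential, gates at their steady state for that
#' voltage, calcium uniform at the resting concentration with the buffer at
#' binding equilibrium, and (for homeostasis runs) mRNA/conductance 12-vectors.
#'
#' @param model A `cahom_model`.
#' @param v Initial voltage, mV.
#' @param m0,g0 Optional initial mRNA and conductance 12-vectors (mS/cm^2) for
#'   homeostasis runs; default zero.
#' @return Numeric state vector for [simulate()].
#' @export
initial_state <- function(model, v = -65, m0 = numeric(12), g0 = numeric(12)) {
  ca0 <- resting_calcium(model, v)
  gates <- gate_steady_states(model, v, ca0)
  cab <- model$calcium$buffer_total * ca0 / (ca0 + model$calcium$k_buf)
  st <- c(v, unname(gates), rep(ca0, 4), rep(cab, 4), m0, g0, 0)
  stopifnot(length(st) == 52)
  st
}

#' Run the integrator over a stimulus program
#'
#' Advances the full model state (voltage, 17 gates, 4 calcium annuli with
#' buffer, and optionally the 12 mRNA/conductance pairs of the homeostasis
#' engine) over an ordered sequence of stimulus epochs.
#'
#' @param model A `cahom_model`.
#' @param program A `cahom_program` (or single epoch).
#' @param dt Integration step, ms (default 0.025).
#' @param record_dt Recording interval, ms (default 1).
#' @param state Initial state from [initial_state()] (or a previous run's
#'   `state`, allowing chunked continuation); default rest at -65 mV.
#' @param hold Apply the holding current pinning rest at -65 mV (used by all
#'   measurement probes); alternatively a numeric holding current in pA.
#' @param homeostasis Optional homeostasis control list from
#'   [homeostasis_params()]; when supplied the twelve conductances evolve under
#'   integral control and are recorded.
#' @param error Either `"stop"` (raise R errors on integration failure or
#'   windup) or `"return"` (return the flag in `$error`).
#' @return List with `trace` (data.frame: time_ms, v_mV, ca_nM, i_inj_pA and,
#'   for homeostasis runs, the 12 conductances in mS/cm^2), `spikes`
#'   (data.frame: time_ms, peak_mV), `state` (final state vector), and `error`
#'   ("" when clean).
#' @export
simulate <- function(model, program, dt = 0.025, record_dt = 1,
                     state = NULL, hold = FALSE, homeostasis = NULL,
                     error = c("stop", "return")) {
  error <- match.arg(error)
  if (dt <= 0) stop("dt must be positive")
  if (inherits(program, "cahom_epoch")) program <- stimulus_program(program)
  if (is.null(state)) state <- initial_state(model)
  i_hold <- if (isTRUE(hold)) holding_current(model) else
    if (is.numeric(hold)) hold else 0
  ctrl <- list(dt = dt, record_dt = record_dt, i_hold = i_hold,
               homeostasis = !is.null(homeostasis),
               record_g = !is.null(homeostasis))
  if (!is.null(homeostasis)) {
    ctrl$ca_target <- homeostasis$ca_target
    ctrl$tau_g <- homeostasis$tau_g
    ctrl$tau_m <- homeostasis$tau_m
    ctrl$windup_max <- homeostasis$windup_max
  }
  res <- .sim_core(model_to_core(model), state, epochs_matrix(program), ctrl)
  if (nzchar(res$error) && error == "stop") stop(res$error)
  trace <- data.frame(time_ms = res$time, v_mV = res$v,
                      ca_nM = res$ca * 1e6, i_inj_pA = res$i_inj)
  if (!is.null(res$g)) {
    g <- as.data.frame(res$g)
    names(g) <- channel_names()
    trace <- cbind(trace, g)
  }
  list(trace = trace,
       spikes = data.frame(time_ms = res$spike_times, peak_mV = res$spike_peaks),
       state = res$state,
       error = res$error)
}
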