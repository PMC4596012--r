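# Integral-control calcium homeostasis: calcium-dependent transcription of 12
# mRNAs, translation into conductances, steady-state runs and state-switch
# protocols.

#' Transcription time constants from reference conductances
#'
#' Sets the per-channel mRNA time constants so that `tau_i * g_i` is constant
#' across channels (`tau_j / tau_i = g_i / g_j`), anchored at the sodium
#' channel's value.
#'
#' @param reference_conductances Named or plain 12-vector of reference
#'   (valid-model) conductances, mS/cm^2, roster order; all > 0.
#' @param tau_na Sodium anchor, ms (default 10).
#' @return Numeric 12-vector of time constants, ms (named by channel).
#' @export
derive_time_constants <- function(reference_conductances, tau_na = 10) {
  g <- as.numeric(reference_conductances)
  stopifnot(length(g) == 12)
  if (any(g <= 0)) {
    stop("zero or negative reference conductance for channel(s): ",
         paste(channel_names()[g <= 0], collapse = ", "))
  }
  stats::setNames(tau_na * g[2] / g, channel_names())
}

#' Homeostasis engine settings
#'
#' Bundles the calcium target, the per-channel transcription time constants
#' (from the model's own conductances), the translation time constant, the
#' randomized "very low" initial conditions and the windup safety ceilings.
#'
#' @param model The reference `cahom_model` whose conductances set the
#'   transcription time-constant ratios.
#' @param ca_target Cytosolic calcium target, mM (default 2e-4 = 200 nM).
#' @param tau_na Sodium-channel transcription time constant, ms.
#' @param tau_g Translation time constant, ms (default 10).
#' @param tau_scale Uniform scale factor applied to all tau_i and tau_g
#'   (trajectory speed only; steady states are invariant).
#' @param init_scale Initial mRNA/conductance values are drawn uniformly in
#'   [0, init_scale * reference conductance].
#' @param seed Seed for the initial-condition draw.
#' @return List with `ca_target`, `tau_m` (12-vector, ms), `tau_g`, `m0`,
#'   `g0` (mS/cm^2), `windup_max`, `seed`.
#' @export
homeostasis_params <- function(model, ca_target = 2e-4, tau_na = 10,
                               tau_g = 10, tau_scale = 1, init_scale = 0.01,
                               seed = 1L) {
  stopifnot(ca_target > 0, tau_na > 0, tau_g > 0, tau_scale > 0)
  gref <- conductance_vector(model)
  set.seed(seed)
  init <- stats::runif(12, 0, init_scale) * gref
  # windup guard: 100x the upper end of each conductance's sampling range
  tab <- parameter_table()
  gmax_names <- c("Rm", "Na_g", "DR_g", "A_g", "M_g", "h_g", "T_g", "R_g",
                  "N_g", "L_g", "SK_g", "BK_g")
  upper <- vapply(gmax_names, function(nm) {
    row <- tab[tab$name == nm, ]
    if (nm == "Rm") 1 / row$lower else row$upper * row$scale
  }, numeric(1))
  list(ca_target = ca_target,
       tau_m = unname(derive_time_constants(gref, tau_na) * tau_scale),
       tau_g = tau_g * tau_scale,
       m0 = init, g0 = init,
       windup_max = unname(100 * upper),
       seed = seed)
}

#' Evolve the homeostasis state for one step (reference implementation)
#'
#' One explicit update of the transcription/translation dynamics: each mRNA
#' integrates the common calcium error with its own time constant and each
#' conductance relaxes toward its mRNA; both are floored at zero.
#'
#' @param m,g Current mRNA and conductance 12-vectors.
#' @param ca Cytosolic calcium, mM.
#' @param params Homeostasis settings from [homeostasis_params()].
#' @param dt Step, ms.
#' @return List with updated `m` and `g`.
#' @export
evolve_homeostasis <- function(m, g, ca, params, dt = 0.025) {
  if (any(!is.finite(m)) || any(!is.finite(g))) {
    stop("non-finite homeostasis state for channel: ",
         channel_names()[which(!is.finite(m) | !is.finite(g))[1]])
  }
  m <- pmax(m + dt * (params$ca_target - ca) / params$tau_m, 0)
  g <- pmax(g + (m - g) * (1 - exp(-dt / params$tau_g)), 0)
  list(m = m, g = g)
}

#' Run homeostatic evolution to conductance steady state
#'
#' Integrates the biophysics, calcium handling and homeostasis engine jointly
#' under one type of afferent drive, in chunks, until the relative change of
#' every conductance over the trailing second falls below `tol` (or the epoch
#' duration cap elapses).
#'
#' @param model A `cahom_model` (supplies kinetics and the reference
#'   conductances for the time-constant ratios).
#' @param drive_epoch A single drive epoch (theta or SWR), whose `duration` is
#'   ignored; chunks of `chunk_ms` are run until steady state.
#' @param homeo Settings from [homeostasis_params()].
#' @param dt Integration step, ms.
#' @param tol Steady-state tolerance: the run stops once the relative change
#'   of every conductance over one trailing time constant of the slowest mRNA
#'   (at least 1 s) falls below `tol` (default 1e-3).
#' @param max_ms Evolution duration cap, ms (default 150 s).
#' @param chunk_ms Chunk length, ms (>= 1000).
#' @param state Optional initial integrator state (for protocol continuation).
#' @return List with `g_steady` (12-vector, mS/cm^2), `m_steady`,
#'   `ca_mean_final_s` (mM, mean outer-shell calcium over the final second),
#'   `trace` (1 ms-resolution trace of the final chunk), `state`, `elapsed_ms`,
#'   `converged`, `depolarization_block` (mean trailing voltage > -40 mV with
#'   no spikes), and `error`.
#' @export
run_to_steady_state <- function(model, drive_epoch, homeo, dt = 0.025,
                                tol = 1e-3, max_ms = 150e3, chunk_ms = 1000,
                                state = NULL) {
  stopifnot(chunk_ms >= 1000)
  # assess steady state over one time constant of the slowest mRNA so the
  # stopping point is invariant under uniform tau rescaling
  window_ms <- max(1000, ceiling(max(homeo$tau_m) / 1000) * 1000)
  chunk_ms <- max(chunk_ms, window_ms)
  if (is.null(state)) {
    state <- initial_state(model, m0 = homeo$m0, g0 = homeo$g0)
  }
  g_prev <- state[40:51]
  elapsed <- 0
  res <- NULL
  converged <- FALSE
  while (elapsed < max_ms) {
    ep <- drive_epoch
    ep$duration <- min(chunk_ms, max_ms - elapsed)
    res <- simulate(model, stimulus_program(list(ep)), dt = dt, record_dt = 1,
                    state = state, homeostasis = homeo, error = "return")
    if (nzchar(res$error)) break
    state <- res$state
    elapsed <- elapsed + ep$duration
    g_now <- state[40:51]
    rel <- abs(g_now - g_prev) / pmax(abs(g_prev), 1e-12)
    g_prev <- g_now
    if (elapsed >= 2 * chunk_ms && max(rel) < tol) {
      converged <- TRUE
      break
    }
  }
  final_s <- res$trace[res$trace$time_ms > max(res$trace$time_ms) - 1000, ]
  nsp <- sum(res$spikes$time_ms > max(res$trace$time_ms) - 1000)
  list(g_steady = stats::setNames(state[40:51], channel_names()),
       m_steady = stats::setNames(state[28:39], channel_names()),
       ca_mean_final_s = mean(final_s$ca_nM) * 1e-6,
       trace = res$trace, spikes = res$spikes, state = state,
       elapsed_ms = elapsed, converged = converged,
       depolarization_block = mean(final_s$v_mV) > -40 && nsp == 0,
       error = res$error)
}

#' Behavioural state-switch protocol
#'
#' Three consecutive steady-state evolutions with the drive switched between
#' theta oscillations and SWR trains (`theta-swr-theta` or `swr-theta-swr`),
#' with a 1 s reset clamp to -65 mV before every theta-to-SWR switch. Records
#' the steady-state conductance vector and calcium of each epoch and
#' classifies the model as robust or plastic from the first-vs-third epoch
#' conductance change.
#'
#' @param model A `cahom_model`.
#' @param sequence `"theta-swr-theta"` or `"swr-theta-swr"`.
#' @param homeo Settings from [homeostasis_params()].
#' @param theta_amplitude,swr_amplitude Drive amplitudes (cm/s).
#' @param threshold Robust/plastic percentage threshold (default 10).
#' @param ... Passed to [run_to_steady_state()] (dt, tol, max_ms, ...).
#' @return List with per-epoch results (`epochs`), the percentage conductance
#'   changes between the first and third epoch (`pct_change`), and `class`
#'   ("robust" or "plastic").
#' @export
run_switch_protocol <- function(model, sequence = c("theta-swr-theta",
                                                    "swr-theta-swr"),
                                homeo, theta_amplitude,
                                swr_amplitude = theta_amplitude,
                                threshold = 10, ...) {
  sequence <- match.arg(sequence)
  kinds <- strsplit(sequence, "-")[[1]]
  state <- NULL
  out <- vector("list", 3)
  for (i in 1:3) {
    if (i > 1 && kinds[i - 1] == "theta" && kinds[i] == "swr") {
      # reset clamp before a theta -> SWR switch
      r <- simulate(model, epoch_reset(1000), state = state,
                    homeostasis = homeo, error = "return")
      if (nzchar(r$error)) stop("protocol aborted during reset: ", r$error)
      state <- r$state
    }
    ep <- if (kinds[i] == "theta") epoch_theta(1000, theta_amplitude)
          else epoch_swr(1000, swr_amplitude)
    out[[i]] <- run_to_steady_state(model, ep, homeo, state = state, ...)
    if (nzchar(out[[i]]$error)) {
      stop("protocol aborted in epoch ", i, ": ", out[[i]]$error)
    }
    state <- out[[i]]$state
  }
  names(out) <- paste0(kinds, c("_1", "_2", "_3"))
  cls <- classify_robust_plastic(out[[1]]$g_steady, out[[3]]$g_steady,
                                 threshold = threshold)
  list(epochs = out, pct_change = cls$pct_change, class = cls$class)
}

#' Robust/plastic classification
#'
#' Percentage change of each conductance between the steady states of the
#' first and third (same-drive) epochs, `100 (g3 - g1)/g1`; the model is
#' robust iff the largest absolute change is within the threshold.
#'
#' @param g_first,g_third Conductance 12-vectors (mS/cm^2).
#' @param threshold Percentage threshold (default 10).
#' @return List with `class` ("robust"/"plastic") and `pct_change` (channels
#'   with a zero first-epoch conductance are excluded with a warning).
#' @export
classify_robust_plastic <- function(g_first, g_third, threshold = 10) {
  g1 <- as.numeric(g_first); g3 <- as.numeric(g_third)
  stopifnot(length(g1) == 12, length(g3) == 12)
  pct <- stats::setNames(rep(NA_real_, 12), channel_names())
  nz <- g1 > 0
  if (any(!nz)) {
    warning("channel(s) with zero first-epoch conductance excluded: ",
            paste(channel_names()[!nz], collapse = ", "))
  }
  pct[nz] <- 100 * (g3[nz] - g1[nz]) / g1[nz]
  cls <- if (all(abs(pct[nz]) <= threshold)) "robust" else "plastic"
  list(class = cls, pct_change = pct)
}

#' Minimum theta amplitude that elicits spiking
#'
#' Bisection over the peak-to-peak permeability amplitude for the smallest
#' value (1% relative tolerance) that elicits spiking on the
#' (fixed-conductance) model: at least `min_rate` spikes per second of 8 Hz
#' drive. The default demands a spike on every drive cycle, the regime the
#' homeostasis experiments operate in; `min_rate = 1` gives the bare
#' spike-threshold amplitude.
#'
#' @param model A `cahom_model`.
#' @param f Theta frequency, Hz.
#' @param duration Drive duration per trial, ms.
#' @param bracket Initial amplitude bracket, cm/s.
#' @param dt Integration step, ms.
#' @param rel_tol Relative bisection tolerance.
#' @param min_rate Minimum spike rate (per second) that counts as spiking;
#'   defaults to the drive frequency (one spike per cycle).
#' @return Amplitude, cm/s.
#' @export
calibrate_theta_amplitude <- function(model, f = 8, duration = 1000,
                                      bracket = c(1e-9, 1e-3), dt = 0.025,
                                      rel_tol = 0.01, min_rate = f) {
  spikes_at <- function(amp) {
    # settle for one duration, then count at steady state
    r <- simulate(model, epoch_theta(2 * duration, amp, f), dt = dt,
                  error = "return")
    if (nzchar(r$error)) return(Inf)
    sum(r$spikes$time_ms > duration) / (duration / 1000)
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (spikes_at(hi) < min_rate) {
    stop("calibration failure: no spiking at the upper amplitude bracket")
  }
  if (spikes_at(lo) >= min_rate) return(lo)
  while ((hi - lo) / hi > rel_tol) {
    mid <- sqrt(lo * hi)
    if (spikes_at(mid) >= min_rate) hi <- mid else lo <- mid
  }
  hi
}

#' SWR amplitude giving a 5-10 mV subthreshold response
#'
#' Scales the sharp-wave-ripple permeability so that a single SWR event
#' deflects the (held) membrane by about 7.5 mV at its peak (tolerance
#' +/- 2.5 mV), by iterative proportional scaling of the response.
#'
#' @param model A `cahom_model`.
#' @param target_mV Target peak deflection, mV (default 7.5).
#' @param dt Integration step, ms.
#' @param max_iter Maximum scaling iterations.
#' @return Permeability amplitude, cm/s.
#' @export
calibrate_swr_amplitude <- function(model, target_mV = 7.5, dt = 0.025,
                                    max_iter = 12) {
  amp <- 1e-8
  deflection <- function(a) {
    r <- simulate(model, epoch_swr(1000 / 3, a), dt = dt, hold = TRUE,
                  error = "return")
    if (nzchar(r$error) || nrow(r$spikes)) return(NA_real_)
    max(abs(r$trace$v_mV - (-65)))
  }
  for (i in seq_len(max_iter)) {
    d <- deflection(amp)
    if (is.na(d)) { amp <- amp / 4; next }
    if (abs(d - target_mV) <= 2.5) return(amp)
    amp <- amp * target_mV / d
  }
  stop("calibration failure: SWR amplitude search did not settle")
}
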