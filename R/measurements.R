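# The seven intrinsic measurements and their probe protocols, plus validation
# against the experimental bounds.

#' Experimental validation bounds
#'
#' Per-measurement (lower, upper) intervals a model must satisfy (inclusively,
#' on all seven) to be declared valid.
#'
#' @return Data.frame with `measurement`, `lower`, `upper`.
#' @export
validation_bounds <- function() {
  data.frame(
    measurement = c("f250", "v_ap", "r_in", "z_max", "f_r", "q", "phi_l"),
    lower = c(10, 90, 50, 50, 2, 1.01, 0),
    upper = c(35, 110, 90, 110, 5.5, 1.5, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Firing rate at 250 pA
#'
#' Twice the number of action potentials during a 500 ms, 250 pA current step
#' from a held rest of -65 mV.
#'
#' @param model A `cahom_model`.
#' @param dt Integration step, ms.
#' @return Firing rate, Hz.
#' @export
measure_f250 <- function(model, dt = 0.025) {
  r <- simulate(model, epoch_step(500, 250), dt = dt, hold = TRUE)
  2 * nrow(r$spikes)
}

#' Action potential amplitude
#'
#' Peak voltage of the last action potential during the 250 pA step, minus the
#' -65 mV resting voltage.
#'
#' @inheritParams measure_f250
#' @return Amplitude in mV, or `NA` if the model does not spike (the
#'   measurement is undefined and the model fails validation).
#' @export
measure_vap <- function(model, dt = 0.025) {
  r <- simulate(model, epoch_step(500, 250), dt = dt, hold = TRUE)
  if (!nrow(r$spikes)) return(NA_real_)
  r$spikes$peak_mV[nrow(r$spikes)] - (-65)
}

#' Input resistance from subthreshold current steps
#'
#' Steps of -50 to +50 pA (10 pA increments, 500 ms each) from a held -65 mV;
#' the steady-state deflection is the mean over the last 50 ms of each step and
#' the input resistance is the least-squares slope of the V-I relation.
#'
#' @inheritParams measure_f250
#' @param return_fit Also return the per-step deflections and fit.
#' @return Input resistance in MOhm (mV/pA * 1000), or `NA` if any probe
#'   elicited spikes.
#' @export
measure_rin <- function(model, dt = 0.025, return_fit = FALSE) {
  currents <- seq(-50, 50, by = 10)
  hold_pA <- holding_current(model)
  dv <- vapply(currents, function(i_pA) {
    r <- simulate(model, epoch_step(500, i_pA), dt = dt, record_dt = 1,
                  hold = hold_pA)
    if (nrow(r$spikes)) return(NA_real_)
    tail_v <- r$trace$v_mV[r$trace$time_ms > 450]
    mean(tail_v) - (-65)
  }, numeric(1))
  if (anyNA(dv)) return(NA_real_)
  fit <- stats::lm(dv ~ currents)
  slope <- unname(stats::coef(fit)[2]) * 1e3  # mV/pA -> MOhm
  if (return_fit) list(r_in = slope, currents = currents, dv = dv, fit = fit)
  else slope
}

#' Impedance amplitude and phase profile from a chirp probe
#'
#' Injects the 25 s, 50 pA chirp (0 to 25 Hz) from a held -65 mV and returns
#' the complex impedance as the ratio of the Fourier transforms of the voltage
#' response and the injected current, band-limited to 0.5-25 Hz.
#'
#' @param model A `cahom_model`.
#' @param dt Integration step, ms.
#' @param record_dt Sampling interval of the recorded response, ms.
#' @param amplitude_pA,f_max,span_s Chirp settings (50 pA, 25 Hz, 25 s).
#' @return List with `freq` (Hz), `zmag` (MOhm), `phase` (rad) and `spiked`
#'   (TRUE if the probe elicited spikes, flagging the profile).
#' @export
impedance_profile <- function(model, dt = 0.025, record_dt = 1,
                              amplitude_pA = 50, f_max = 25, span_s = 25) {
  r <- simulate(model, epoch_chirp(amplitude_pA, f_max, span_s), dt = dt,
                record_dt = record_dt, hold = TRUE)
  tr <- r$trace[-1, ] # drop the t = 0 sample so the record is uniform
  n <- nrow(tr)
  fs <- 1000 / record_dt
  freq <- (seq_len(n) - 1) * fs / n
  zv <- stats::fft(tr$v_mV - mean(tr$v_mV))
  zi <- stats::fft(tr$i_inj_pA - mean(tr$i_inj_pA))
  keep <- freq >= 0.5 & freq <= f_max
  z <- zv[keep] / zi[keep]
  list(freq = freq[keep],
       zmag = Mod(z) * 1e3,  # mV/pA -> MOhm
       phase = Arg(z),
       spiked = nrow(r$spikes) > 0)
}

#' Resonance measures from an impedance profile
#'
#' Resonance frequency (argmax of |Z|), maximum impedance amplitude, strength
#' of resonance Q = |Z(f_R)|/|Z(0.5)| and total inductive phase (trapezoidal
#' integral of the positive-phase region).
#'
#' @param profile A profile from [impedance_profile()] (fields `freq`, `zmag`,
#'   `phase`).
#' @return List with `f_r` (Hz), `z_max` (MOhm), `q`, `phi_l` (rad.Hz).
#' @export
resonance_measures <- function(profile) {
  f <- profile$freq; zm <- profile$zmag; ph <- profile$phase
  # a light running mean suppresses single-bin ripple from the finite record
  zs <- stats::filter(zm, rep(1 / 5, 5), sides = 2)
  zs[is.na(zs)] <- zm[is.na(zs)]
  imax <- which.max(zs)
  z05 <- stats::approx(f, zm, xout = 0.5, rule = 2)$y
  pos <- pmax(ph, 0)
  phi_l <- sum(diff(f) * (pos[-1] + pos[-length(pos)]) / 2)
  list(f_r = f[imax], z_max = zm[imax], q = zm[imax] / z05, phi_l = phi_l)
}

#' All seven intrinsic measurements
#'
#' Runs the 250 pA step, the V-I step family and the chirp probe on a model and
#' assembles the measurement vector. With `early_exit`, a probe stage whose
#' measurements already violate the bounds short-circuits the remaining
#' (costlier) stages, leaving their entries `NA`; the valid verdict is
#' unaffected because validity is a conjunction.
#'
#' @param model A `cahom_model`.
#' @param dt Integration step, ms.
#' @param bounds Validation bounds (used only for `early_exit`).
#' @param early_exit Stop probing once invalidity is certain.
#' @return One-row data.frame: `f250`, `v_ap`, `r_in`, `z_max`, `f_r`, `q`,
#'   `phi_l`, `valid`.
#' @export
measure_all <- function(model, dt = 0.025, bounds = validation_bounds(),
                        early_exit = FALSE) {
  out <- data.frame(f250 = NA_real_, v_ap = NA_real_, r_in = NA_real_,
                    z_max = NA_real_, f_r = NA_real_, q = NA_real_,
                    phi_l = NA_real_, valid = FALSE)
  inside <- function(nm, val) {
    b <- bounds[bounds$measurement == nm, ]
    !is.na(val) && val >= b$lower && val <= b$upper
  }
  r <- simulate(model, epoch_step(500, 250), dt = dt, hold = TRUE,
                error = "return")
  if (nzchar(r$error)) return(out)
  out$f250 <- 2 * nrow(r$spikes)
  out$v_ap <- if (nrow(r$spikes)) r$spikes$peak_mV[nrow(r$spikes)] + 65 else NA_real_
  if (early_exit && !(inside("f250", out$f250) && inside("v_ap", out$v_ap))) {
    return(out)
  }
  out$r_in <- measure_rin(model, dt = dt)
  if (early_exit && !inside("r_in", out$r_in)) return(out)
  prof <- impedance_profile(model, dt = dt)
  if (!prof$spiked) {
    res <- resonance_measures(prof)
    out$z_max <- res$z_max; out$f_r <- res$f_r; out$q <- res$q
    out$phi_l <- res$phi_l
  }
  out$valid <- validate_measurements(out, bounds)$valid
  out
}

#' Validate a measurement vector against the bounds
#'
#' A model is valid iff every one of the seven measurements lies inside its
#' (inclusive) interval; an undefined (`NA`) measurement is invalid.
#'
#' @param measurements One-row data.frame or named list/vector with the seven
#'   measurement fields.
#' @param bounds Bounds data.frame from [validation_bounds()].
#' @return List with `valid` (logical) and `verdicts` (named logical 7-vector).
#' @export
validate_measurements <- function(measurements, bounds = validation_bounds()) {
  m <- as.list(measurements)
  verdicts <- vapply(seq_len(nrow(bounds)), function(i) {
    val <- m[[bounds$measurement[i]]]
    !is.null(val) && !is.na(val) &&
      val >= bounds$lower[i] && val <= bounds$upper[i]
  }, logical(1))
  names(verdicts) <- bounds$measurement
  list(valid = all(verdicts), verdicts = verdicts)
}
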