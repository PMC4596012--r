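# Afferent drive programs: theta-frequency permeability modulation, sharp-wave
# ripple trains, reset pulses, and current-step / chirp probes.

#' Theta-frequency sinusoidal permeability drive
#'
#' Non-negative sinusoid `amplitude/2 * (1 - cos(2 pi f t))`: peak-to-peak
#' equals `amplitude`, the mean over whole cycles is `amplitude/2`, and the
#' drive starts from zero.
#'
#' @param t Time, ms (vectorized).
#' @param amplitude Peak-to-peak AMPAR permeability, cm/s (>= 0).
#' @param f Frequency, Hz (default 8).
#' @return Permeability, cm/s.
#' @export
theta_drive <- function(t, amplitude, f = 8) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  amplitude / 2 * (1 - cos(2 * pi * f * t / 1000))
}

#' Sharp-wave ripple waveform
#'
#' The published SWR shape: a Gaussian envelope centred at 55 ms minus a
#' ripple-modulated Gaussian centred at 40 ms,
#' `exp(-(t-55)^2/(2*20^2)) - 0.3 exp(-(t-40)^2/(2*15^2)) sin(2 pi f_ripple t/1000)`.
#' One event spans roughly 150 ms.
#'
#' @param t Time within the event, ms (vectorized).
#' @param f_ripple Ripple frequency, Hz (default 150).
#' @return Dimensionless waveform value (may be slightly negative through the
#'   ripple term; permeability drives floor it at zero).
#' @export
swr_waveform <- function(t, f_ripple = 150) {
  exp(-(t - 55)^2 / (2 * 20 * 20)) -
    0.3 * exp(-(t - 40)^2 / (2 * 15 * 15)) * sin(2 * pi * f_ripple * t / 1000)
}

#' Sharp-wave ripple train
#'
#' The SWR waveform, scaled by `amplitude` and floored at zero, tiled at the
#' repeat frequency with silence between events.
#'
#' @param t Time, ms (vectorized).
#' @param amplitude Permeability scale, cm/s.
#' @param repeat_hz Event repetition rate, Hz (default 3); the repeat period
#'   must not be shorter than one 150 ms event.
#' @param f_ripple Ripple frequency, Hz.
#' @return Permeability, cm/s.
#' @export
swr_train <- function(t, amplitude, repeat_hz = 3, f_ripple = 150) {
  period <- 1000 / repeat_hz
  if (period < 150) stop("repeat period shorter than the 150 ms SWR waveform")
  tt <- t %% period
  w <- ifelse(tt <= 150, pmax(swr_waveform(tt, f_ripple), 0), 0)
  amplitude * w
}

#' Chirp probe current
#'
#' Constant-amplitude sinusoid whose instantaneous frequency rises linearly
#' from 0 to `f_max` over `span_s` seconds (phase `pi f_max t^2 / span`).
#'
#' @param t Time, ms (vectorized).
#' @param amplitude_pA Amplitude, pA (default 50, i.e. 100 pA peak-to-peak).
#' @param f_max Final frequency, Hz (default 25).
#' @param span_s Sweep duration, s (default 25).
#' @return Current, pA.
#' @export
chirp_current <- function(t, amplitude_pA = 50, f_max = 25, span_s = 25) {
  span_ms <- span_s * 1000
  amplitude_pA * sin(pi * f_max * t^2 / (1000 * span_ms))
}

epoch <- function(kind, duration, amplitude = 0, frequency = 0,
                  f_ripple = 150) {
  if (duration <= 0) stop("epoch duration must be positive")
  if (kind %in% c("theta", "swr") && amplitude < 0) {
    stop("drive amplitude must be non-negative")
  }
  structure(list(kind = kind, duration = duration, amplitude = amplitude,
                 frequency = frequency, f_ripple = f_ripple),
            class = "cahom_epoch")
}

#' Stimulus epochs
#'
#' Constructors for the epoch types understood by the integrator: theta drive,
#' SWR trains, a -65 mV voltage-clamp reset, constant current steps, chirp
#' probes and silence. Durations in ms; synaptic amplitudes are AMPAR
#' permeabilities (cm/s), current amplitudes are pA.
#'
#' @param duration Epoch duration, ms.
#' @param amplitude Drive amplitude (permeability cm/s, or current pA).
#' @param f Frequency, Hz (theta sinusoid or SWR repeat rate).
#' @param f_ripple SWR ripple frequency, Hz.
#' @param f_max,span_s Chirp sweep: final frequency (Hz) and span (s).
#' @return A `cahom_epoch`.
#' @name epochs
NULL

#' @rdname epochs
#' @export
epoch_theta <- function(duration, amplitude, f = 8) {
  if (f <= 0) stop("theta frequency must be positive")
  epoch("theta", duration, amplitude, f)
}

#' @rdname epochs
#' @export
epoch_swr <- function(duration, amplitude, f = 3, f_ripple = 150) {
  if (1000 / f < 150) stop("repeat period shorter than the 150 ms SWR waveform")
  epoch("swr", duration, amplitude, f, f_ripple)
}

#' @rdname epochs
#' @export
epoch_reset <- function(duration = 1000) epoch("reset", duration)

#' @rdname epochs
#' @export
epoch_step <- function(duration, amplitude) epoch("current_step", duration, amplitude)

#' @rdname epochs
#' @export
epoch_chirp <- function(amplitude = 50, f_max = 25, span_s = 25) {
  e <- epoch("chirp", span_s * 1000, amplitude, f_max)
  e$span_s <- span_s
  e
}

#' @rdname epochs
#' @export
epoch_silent <- function(duration) epoch("silent", duration)

#' Ordered stimulus program
#'
#' @param ... Epochs from the `epoch_*` constructors (or a single list of
#'   them).
#' @return A `cahom_program` (non-empty ordered list of epochs).
#' @export
stimulus_program <- function(...) {
  eps <- list(...)
  if (length(eps) == 1 && !inherits(eps[[1]], "cahom_epoch")) eps <- eps[[1]]
  if (!length(eps)) stop("a stimulus program needs at least one epoch")
  stopifnot(all(vapply(eps, inherits, TRUE, "cahom_epoch")))
  structure(eps, class = "cahom_program")
}

#' Named preset switch programs
#'
#' `"theta"` and `"swr"` are single steady-drive epochs; `"theta-swr-theta"`
#' and `"swr-theta-swr"` are the three-epoch behavioural-state-switch designs,
#' with a 1 s reset clamp to -65 mV preceding every theta-to-SWR switch.
#'
#' @param name Preset name.
#' @param theta_amplitude,swr_amplitude Permeability amplitudes, cm/s.
#' @param epoch_ms Duration of each drive epoch, ms.
#' @return A `cahom_program`.
#' @export
preset_program <- function(name = c("theta", "swr", "theta-swr-theta",
                                    "swr-theta-swr"),
                           theta_amplitude, swr_amplitude = theta_amplitude,
                           epoch_ms = 150e3) {
  name <- match.arg(name)
  th <- function() epoch_theta(epoch_ms, theta_amplitude)
  sw <- function() epoch_swr(epoch_ms, swr_amplitude)
  eps <- switch(name,
    "theta" = list(th()),
    "swr" = list(sw()),
    "theta-swr-theta" = list(th(), epoch_reset(), sw(), th()),
    "swr-theta-swr" = list(sw(), th(), epoch_reset(), sw()))
  stimulus_program(eps)
}
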