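test_that("the SWR waveform matches an independent evaluation on a fine grid", {
  t <- seq(0, 200, by = 0.1)
  # oracle assembled term by term
  envelope <- exp(-(t - 55)^2 / (2 * 20 * 20))
  ripple <- 0.3 * exp(-(t - 40)^2 / (2 * 15 * 15)) * sin(2 * pi * 150 * t / 1000)
  oracle <- envelope - ripple
  expect_equal(swr_waveform(t), oracle, tolerance = 1e-12)
  # spot values: ripple term vanishes at 40 ms; unit envelope at 55 ms
  expect_equal(round(swr_waveform(40), 4), 0.7548)
  expect_equal(round(swr_waveform(55), 4), 0.8180)
  # one event is supported on roughly 150 ms
  expect_true(all(abs(swr_waveform(c(-10, 160, 200))) < 0.01))
})

test_that("the SWR train tiles identical events at the repeat rate", {
  t <- seq(0, 1000, by = 0.1)
  p <- swr_train(t, amplitude = 1, repeat_hz = 3)
  expect_true(all(p >= 0))
  # events are exact copies one period apart
  first <- swr_train(seq(0, 150, by = 0.1), 1)
  second <- swr_train(seq(0, 150, by = 0.1) + 1000 / 3, 1)
  expect_equal(first, second, tolerance = 1e-12)
  expect_equal(swr_train(t, 0), rep(0, length(t)))
  expect_error(epoch_swr(1000, 1, f = 10), "150 ms")
})

test_that("theta drive is a non-negative sinusoid with the stated period and mean", {
  t <- seq(0, 1000, by = 0.01)
  p <- theta_drive(t, amplitude = 2, f = 8)
  expect_true(all(p >= 0))
  expect_equal(max(p) - min(p), 2, tolerance = 1e-6)
  expect_equal(theta_drive(0, 2), theta_drive(125, 2), tolerance = 1e-12)
  cycles <- seq(0, 125 * 8 - 0.01, by = 0.01)
  expect_equal(mean(theta_drive(cycles, 2)), 1, tolerance = 1e-4)
  expect_equal(theta_drive(t, 0), rep(0, length(t)))
})

test_that("the chirp sweeps 0 to 25 Hz linearly over 25 s", {
  # instantaneous frequency at mid-span is half the maximum
  t0 <- 12500
  phase <- function(t) pi * 25 * t^2 / (1000 * 25000)
  f_inst <- (phase(t0 + 0.5) - phase(t0 - 0.5)) / (2 * pi) * 1000
  expect_equal(f_inst, 12.5, tolerance = 1e-6)
  expect_equal(max(abs(chirp_current(seq(0, 25000, by = 0.1)))), 50,
               tolerance = 1e-4)
  # the sweep integrates to approximately zero
  t <- seq(0, 25000, by = 0.05)
  expect_lt(abs(mean(chirp_current(t))), 1)
})

test_that("the reset epoch clamps voltage exactly while state keeps evolving", {
  m <- base_model()
  st <- initial_state(m)
  st[1] <- -30
  gates30 <- gate_steady_states(m, -30, ca = m$calcium$ca_rest)
  st[2:19] <- unname(gates30)
  r <- simulate(m, epoch_reset(1000), state = st, record_dt = 0.5)
  expect_true(all(r$trace$v_mV[-1] == -65))
  # gates relaxed away from their -30 mV values under the clamp
  expect_gt(r$state[3], gates30[["Na_h"]])
})

test_that("drive programs replay bit-identically", {
  m <- base_model()
  r1 <- simulate(m, preset_program("theta-swr-theta", 1e-8, epoch_ms = 300))
  r2 <- simulate(m, preset_program("theta-swr-theta", 1e-8, epoch_ms = 300))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$state, r2$state)
})

test_that("program construction validates its inputs", {
  expect_error(stimulus_program(), "at least one epoch")
  expect_error(epoch_theta(0, 1), "positive")
  expect_error(epoch_theta(100, -1), "non-negative")
  p <- preset_program("swr-theta-swr", 1e-8, epoch_ms = 1000)
  expect_length(p, 4)  # reset inserted before the theta -> SWR switch
  expect_equal(p[[3]]$kind, "reset")
})
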