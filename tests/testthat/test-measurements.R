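test_that("passive impedance matches the analytic RC profile within 2%", {
  pm <- passive_model()
  prof <- impedance_profile(pm, dt = 0.05)
  expect_false(prof$spiked)
  R <- passive_input_resistance(35, pm$geometry)      # MOhm
  tau <- 35                                           # ms
  analytic <- R / sqrt(1 + (2 * pi * prof$freq * tau / 1000)^2)
  expect_true(all(abs(prof$zmag - analytic) / analytic < 0.02))
  # a leaky capacitor is purely restorative: phase lag at every frequency
  expect_true(all(prof$phase < 0))
  res <- resonance_measures(prof)
  expect_lt(res$f_r, 1)                               # monotone decay: peak at the band edge
  expect_equal(res$q, 1, tolerance = 0.01)
  expect_equal(res$phi_l, 0)
  expect_equal(res$z_max, R, tolerance = 0.02)
})

test_that("resonance measures recover a constructed band-pass peak", {
  f <- seq(0.5, 25, by = 0.02)
  zmag <- 60 * exp(-(log(f / 4))^2)   # peak exactly at 4 Hz
  phase <- 0.2 * (4 - f) / 25
  res <- resonance_measures(list(freq = f, zmag = zmag, phase = phase))
  expect_equal(res$f_r, 4, tolerance = 0.011)
  expect_equal(res$z_max, 60, tolerance = 1e-3)
  expect_gt(res$q, 1)
  # trapezoid over the positive-phase region only
  pos <- pmax(phase, 0)
  expect_equal(res$phi_l, sum(diff(f) * (pos[-1] + pos[-length(pos)]) / 2))
})

test_that("Q is never below 1: the peak dominates the 0.5 Hz value", {
  for (model in list(passive_model(), base_model())) {
    res <- resonance_measures(impedance_profile(model, dt = 0.05))
    expect_gte(res$q, 1)
  }
})

test_that("firing measurements count spikes and report the last peak", {
  m <- base_model()
  f250 <- measure_f250(m)
  expect_equal(f250 %% 2, 0)            # twice an integer count
  expect_gte(f250, 10)
  expect_lte(f250, 35)
  vap <- measure_vap(m)
  expect_gte(vap, 90)
  expect_lte(vap, 110)
  # a passive membrane never spikes: rate zero, amplitude undefined
  expect_equal(measure_f250(passive_model()), 0)
  expect_true(is.na(measure_vap(passive_model())))
})

test_that("input resistance from V-I probes matches the passive closed form", {
  pm <- passive_model()
  fit <- measure_rin(pm, return_fit = TRUE)
  expect_equal(fit$r_in, passive_input_resistance(35, pm$geometry),
               tolerance = 0.01)
  # linear responses leave essentially no residual
  expect_lt(summary(fit$fit)$sigma, 1e-3)
})

test_that("validation is an inclusive conjunction over all seven bounds", {
  b <- validation_bounds()
  mv <- list(f250 = 20, v_ap = 100, r_in = 70, z_max = 80, f_r = 4, q = 1.2,
             phi_l = 0.05)
  expect_true(validate_measurements(mv, b)$valid)
  mv$f250 <- 40
  v <- validate_measurements(mv, b)
  expect_false(v$valid)
  expect_false(v$verdicts[["f250"]])
  expect_true(all(v$verdicts[names(v$verdicts) != "f250"]))
  # boundary values are accepted
  mv$f250 <- 10
  expect_true(validate_measurements(mv, b)$valid)
  # undefined measurements invalidate
  mv$v_ap <- NA
  expect_false(validate_measurements(mv, b)$valid)
})

test_that("repeated probes on a frozen model are bit-identical", {
  m <- base_model()
  expect_identical(measure_rin(m, dt = 0.05), measure_rin(m, dt = 0.05))
  p1 <- impedance_profile(m, dt = 0.05)
  p2 <- impedance_profile(m, dt = 0.05)
  expect_identical(p1$zmag, p2$zmag)
})
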