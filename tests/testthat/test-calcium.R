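cal <- calcium_params()

test_that("SERCA uptake is half-maximal at Kp and saturates at Vmax", {
  expect_equal(serca_uptake(0, cal), 0)
  expect_equal(serca_uptake(2.7e-4, cal), 5e-5, tolerance = 1e-12)
  expect_equal(serca_uptake(10, cal), 1e-4, tolerance = 1e-4)
  ca <- seq(0, 1e-3, length.out = 200)
  expect_true(all(diff(serca_uptake(ca, cal)) >= 0))
})

test_that("the membrane pump is silent below threshold and linear above it", {
  expect_equal(membrane_pump(1e-4, cal), 0)        # 0.1 uM < 0.2 uM threshold
  expect_equal(membrane_pump(cal$ca_crt, cal), 0)  # continuous at threshold
  expect_equal(membrane_pump(3e-4, cal), cal$gamma_eff * 1e-4, tolerance = 1e-12)
  ca <- seq(0, 1e-3, length.out = 200)
  expect_true(all(diff(membrane_pump(ca, cal)) >= 0))
})

test_that("the ER leak is calibrated to cancel SERCA uptake at rest", {
  expect_equal(er_leak(cal$ca_er, cal), 0)
  expect_equal(er_leak(0, cal), cal$leak_constant)
  expect_equal(er_leak(cal$ca_rest, cal), serca_uptake(cal$ca_rest, cal),
               tolerance = 1e-12)
  # closed form at 50 nM rest
  j <- 1e-4 * 0.05^2 / (0.05^2 + 0.27^2)  # Vmax times the uM-based Hill ratio
  expect_equal(serca_uptake(5e-5, cal), j, tolerance = 1e-6)
  expect_equal(calibrate_leak(cal), j / (1 - 5e-5 / cal$ca_er), tolerance = 1e-6)
  # doubling Vmax doubles the calibrated leak
  cal2 <- cal; cal2$v_max_serca <- 2 * cal$v_max_serca
  expect_equal(calibrate_leak(cal2), 2 * calibrate_leak(cal), tolerance = 1e-12)
  cal3 <- cal
  expect_error(calibrate_leak(cal3, resting_ca = cal$ca_er), "below ER")
})

test_that("buffering obeys detailed balance and conservation", {
  bt <- cal$buffer_total
  ca <- 1e-4
  cab_eq <- bt * ca / (ca + cal$k_buf)
  r <- buffer_rate(ca, bt - cab_eq, cab_eq, cal)
  expect_equal(r$r_buf, 0, tolerance = 1e-15)
  r2 <- buffer_rate(0, bt - cab_eq, cab_eq, cal)
  expect_gt(r2$r_buf, 0)  # net release when free calcium is stripped
  expect_equal(r2$d_bound, -r2$r_buf)
  expect_error(buffer_rate(ca, bt, bt, cal), "conservation")
})

test_that("VGCC influx converts inward current into positive flux, linearly", {
  expect_equal(vgcc_influx(0), 0)
  expect_gt(vgcc_influx(-0.1), 0)
  expect_equal(vgcc_influx(-0.2), 2 * vgcc_influx(-0.1), tolerance = 1e-12)
})

test_that("radial diffusion conserves volume-weighted calcium exactly", {
  ann <- annulus_geometry()
  shells <- c(4e-4, 1e-4, 5e-5, 2e-4)
  total0 <- sum(shells * ann$volume)
  s <- shells
  for (i in 1:2000) s <- diffuse_step(s, dt = 0.025)
  expect_equal(sum(s * ann$volume), total0, tolerance = 1e-12)
  # uniform profile is a fixed point
  expect_equal(diffuse_step(rep(1e-4, 4)), rep(1e-4, 4), tolerance = 1e-15)
  # long-time limit of a sealed system is uniform at the volume-weighted mean
  for (i in 1:5000) s <- diffuse_step(s, dt = 100)
  expect_equal(s, rep(total0 / sum(ann$volume), 4), tolerance = 1e-6)
  expect_error(diffuse_step(shells, dt = 1e4), "reduce dt")
})

test_that("the sealed integrator conserves calcium plus bound buffer", {
  m <- sealed_calcium_model()
  st <- initial_state(m)
  ann <- m$calcium$annuli
  # impose a non-uniform calcium profile with its local binding equilibrium
  ca <- c(5e-4, 1e-4, 5e-5, 2e-4)
  cab <- m$calcium$buffer_total * ca / (ca + m$calcium$k_buf)
  st[20:23] <- ca
  st[24:27] <- cab
  total0 <- sum((ca + cab) * ann$volume)
  r <- simulate(m, epoch_silent(200), state = st)
  total1 <- sum((r$state[20:23] + r$state[24:27]) * ann$volume)
  expect_equal(total1, total0, tolerance = 1e-12)
})

test_that("with calibrated leak and no VGCC drive, resting calcium holds for 10 s", {
  m <- no_vgcc_model()
  r <- simulate(m, epoch_silent(10e3), hold = TRUE)
  expect_lt(abs(tail(r$trace$ca_nM, 1) - 50), 1)
  expect_lt(max(abs(r$trace$ca_nM - 50)), 1)
})

test_that("the self-consistent resting point zeroes the full outer-shell balance", {
  m <- base_model()
  ca0 <- resting_calcium(m)
  p <- m$calcium
  i_ca <- sum(channel_currents(m, -65)[c("CaT", "CaR", "CaN", "CaL")]) * 1e-3
  net <- p$beta_er * (er_leak(ca0, p) - serca_uptake(ca0, p)) +
    vgcc_influx(i_ca, m$geometry) - membrane_pump(ca0, p)
  expect_lt(abs(net), 1e-12)
  # and the integrator holds that point
  r <- simulate(m, epoch_silent(5e3), hold = TRUE)
  expect_lt(abs(tail(r$trace$ca_nM, 1) - ca0 * 1e6), 2)
})
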