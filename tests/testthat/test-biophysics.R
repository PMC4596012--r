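test_that("geometry and passive analytics follow the closed forms", {
  g <- neuron_geometry(100, 100)
  expect_equal(lateral_area(g), pi * 1e-2 * 1e-2, tolerance = 1e-12)
  expect_error(neuron_geometry(0, 100), "invalid geometry")
  # doubling the length doubles the area
  expect_equal(lateral_area(neuron_geometry(100, 200)), 2 * lateral_area(g))

  expect_equal(passive_input_resistance(35, g), 35000 / (pi * 1e-4) * 1e-6,
               tolerance = 1e-12)
  expect_equal(passive_input_resistance(70, g),
               2 * passive_input_resistance(35, g))
  expect_equal(passive_input_resistance(35, neuron_geometry(100, 200)),
               passive_input_resistance(35, g) / 2)
})

test_that("Boltzmann gates behave at the midpoint, saturation and bad input", {
  expect_equal(boltzmann_ss(-30, -30, 6), 0.5)
  expect_equal(boltzmann_ss(-18, -30, 6), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(boltzmann_ss(500, -30, 6), 1, tolerance = 1e-6)
  expect_error(boltzmann_ss(0, -30, 0), "slope")
  # negative slope encodes inactivation: decreasing in v
  expect_lt(boltzmann_ss(-40, -45, -5), boltzmann_ss(-50, -45, -5))
})

test_that("calcium-gated activation is Hill-shaped with half-max by construction", {
  expect_equal(hill_ca(140e-6, 140e-6, 4), 0.5)
  expect_equal(hill_ca(0, 140e-6, 4), 0)
  expect_gt(hill_ca(1, 140e-6, 4), 0.999)
  expect_error(hill_ca(-1, 140e-6), "non-negative")
})

test_that("channel currents respect zero-conductance, reversal and sign rules", {
  m <- base_model()
  i <- channel_currents(m, -90)  # at E_K the K+ currents vanish
  expect_equal(unname(i[c("KDR", "KA", "KM", "SK", "BK")]), rep(0, 5))
  pm <- passive_model()
  expect_equal(sum(abs(channel_currents(pm, 0)[-1])), 0) # only leak remains
  # inward currents are negative: HCN below its reversal
  expect_lt(channel_currents(m, -65)[["HCN"]], 0)
})

test_that("passive V-I slope and membrane time constant match Rm/area and Rm*Cm", {
  pm <- passive_model()
  rin <- measure_rin(pm)
  expect_equal(rin, passive_input_resistance(35, pm$geometry), tolerance = 0.01)

  r <- simulate(pm, epoch_step(500, 10), record_dt = 0.5)
  dv_ss <- mean(r$trace$v_mV[r$trace$time_ms > 450]) + 65
  expect_equal(dv_ss, 10 * rin * 1e-3, tolerance = 0.01)
  tr <- r$trace[r$trace$time_ms > 0 & r$trace$time_ms < 250, ]
  frac <- 1 - (tr$v_mV + 65) / dv_ss
  keep <- frac > 1e-3
  tau <- -1 / coef(lm(log(frac[keep]) ~ tr$time_ms[keep]))[[2]]
  expect_equal(tau, 35, tolerance = 0.02)
})

test_that("positive injected current depolarizes the leak-only membrane", {
  pm <- passive_model()
  r <- simulate(pm, epoch_step(100, 50))
  expect_gt(tail(r$trace$v_mV, 1), -65)
})

test_that("a passive membrane at rest with no drive stays at rest", {
  pm <- passive_model()
  r <- simulate(pm, epoch_silent(1000))
  expect_lt(max(abs(r$trace$v_mV + 65)), 1e-6)
})

test_that("gate relaxation under a voltage clamp matches the closed form", {
  m <- base_model()
  # start with gates equilibrated at -30 mV, clamp at -65 mV for 40 ms
  st <- initial_state(m)
  gates30 <- gate_steady_states(m, -30, ca = m$calcium$ca_rest)
  st[2:19] <- unname(gates30)
  r <- simulate(m, epoch_reset(40), state = st)
  gates_inf <- gate_steady_states(m, -65, ca = m$calcium$ca_rest)
  # fixed-tau voltage gate: Na inactivation
  expected <- gates_inf[["Na_h"]] +
    (gates30[["Na_h"]] - gates_inf[["Na_h"]]) * exp(-40 / m$params$Na_tau_h)
  expect_equal(r$state[3], expected, tolerance = 1e-10)
})

test_that("all gate fractions stay in [0, 1] through strong afferent drive", {
  m <- base_model()
  st <- initial_state(m)
  for (i in 1:5) {
    r <- simulate(m, epoch_theta(200, 5 * base_theta_amplitude()), state = st)
    st <- r$state
    expect_true(all(st[2:19] >= 0 & st[2:19] <= 1))
  }
})

test_that("halving the time step changes an active theta-driven trace by < 0.5 mV RMS", {
  m <- base_model()
  amp <- base_theta_amplitude()
  r1 <- simulate(m, epoch_theta(1000, amp), dt = 0.025, record_dt = 1)
  r2 <- simulate(m, epoch_theta(1000, amp), dt = 0.0125, record_dt = 1)
  rms <- sqrt(mean((r1$trace$v_mV - r2$trace$v_mV)^2))
  expect_lt(rms, 0.5)
})

test_that("the hand-tuned base model validates against all seven bounds", {
  mv <- measure_all(base_model())
  expect_true(mv$valid)
})
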