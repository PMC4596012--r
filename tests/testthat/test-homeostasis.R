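test_that("transcription time constants keep tau_i * g_i invariant, anchored at Na", {
  g <- conductance_vector(base_model())
  tau <- derive_time_constants(g, tau_na = 10)
  expect_equal(tau[["NaF"]], 10)
  expect_equal(tau[["KDR"]], 10 * 0.007 / 0.003, tolerance = 1e-12)
  expect_equal(unname(tau * g), rep(tau[["NaF"]] * g[["NaF"]], 12),
               tolerance = 1e-12)
  expect_equal(unname(derive_time_constants(rep(2, 12), 10)), rep(10, 12))
  expect_error(derive_time_constants(c(0, g[-1])), "Leak")
})

test_that("the integral controller has its fixed point at the calcium target", {
  m <- base_model()
  h <- homeostasis_params(m, seed = 1)
  s <- evolve_homeostasis(h$m0, h$g0, ca = h$ca_target, h, dt = 0.1)
  expect_equal(s$m, h$m0, tolerance = 1e-12)       # mdot = 0 at target
  # below target every mRNA rises; above target none rises
  lo <- evolve_homeostasis(h$m0, h$g0, ca = h$ca_target / 2, h, dt = 0.1)
  expect_true(all(lo$m > h$m0))
  hi <- evolve_homeostasis(h$m0, h$g0, ca = 2 * h$ca_target, h, dt = 0.1)
  expect_true(all(hi$m <= h$m0))
  # conductances relax toward their mRNA
  g <- rep(1, 12); mm <- rep(2, 12)
  s2 <- evolve_homeostasis(mm, g, ca = h$ca_target, h, dt = 1e3 * h$tau_g)
  expect_equal(s2$g, mm, tolerance = 1e-6)
  expect_error(evolve_homeostasis(c(NaN, h$m0[-1]), h$g0, 1e-4, h), "Leak")
})

test_that("one error signal drives all mRNA increments proportionally to 1/tau", {
  m <- base_model()
  h <- homeostasis_params(m, tau_scale = 0.01, seed = 1)
  h$m0 <- rep(0, 12); h$g0 <- rep(0, 12)
  st <- initial_state(m, m0 = h$m0, g0 = h$g0)
  r <- simulate(m, epoch_theta(500, base_theta_amplitude()),
                state = st, homeostasis = h)
  m_final <- r$state[28:39]
  # m_i(t) - m_i(0) = E(t)/tau_i for the shared integrated error E(t)
  scaled <- m_final * h$tau_m
  expect_equal(scaled, rep(scaled[1], 12), tolerance = 1e-10)
})

test_that("scaled-down evolution reaches the calcium target and tracks variants", {
  m <- base_model()
  amp <- base_theta_amplitude()
  for (tgt in c(1e-4, 2e-4)) {
    h <- homeostasis_params(m, ca_target = tgt, tau_scale = 0.01, seed = 1)
    res <- run_to_steady_state(m, epoch_theta(1000, amp), h, max_ms = 150e3)
    expect_true(res$converged)
    expect_equal(res$ca_mean_final_s, tgt, tolerance = 0.05)
    expect_equal(unname(res$g_steady), unname(res$m_steady), tolerance = 1e-3)
  }
})

test_that("windup aborts with a conductance-naming error", {
  m <- base_model()
  h <- homeostasis_params(m, tau_scale = 0.01, seed = 1)
  h$windup_max <- rep(1e-9, 12)
  expect_error(
    simulate(m, epoch_theta(2000, base_theta_amplitude()),
             state = initial_state(m, m0 = h$m0, g0 = h$g0), homeostasis = h),
    "windup")
})

test_that("robust/plastic classification applies the percentage threshold per channel", {
  g1 <- conductance_vector(base_model())
  expect_equal(classify_robust_plastic(g1, g1)$class, "robust")
  g3 <- g1 * 1.5
  cls <- classify_robust_plastic(g1, g3)
  expect_equal(cls$class, "plastic")
  expect_equal(unname(cls$pct_change), rep(50, 12), tolerance = 1e-12)
  expect_equal(classify_robust_plastic(g1, g3, threshold = Inf)$class, "robust")
  g0 <- g1; g0[5] <- 0
  expect_warning(cls0 <- classify_robust_plastic(g0, g3), "excluded")
  expect_true(is.na(cls0$pct_change[["KM"]]))
})

test_that("a state-switch protocol reaches the target in every epoch", {
  m <- base_model()
  h <- homeostasis_params(m, tau_scale = 0.01, seed = 2)
  sw <- run_switch_protocol(m, "theta-swr-theta", h,
                            theta_amplitude = base_theta_amplitude(),
                            swr_amplitude = calibrate_swr_amplitude(m),
                            max_ms = 100e3)
  for (e in sw$epochs) {
    expect_equal(e$ca_mean_final_s, h$ca_target, tolerance = 0.05)
  }
  expect_true(sw$class %in% c("robust", "plastic"))
  expect_equal(names(sw$epochs), c("theta_1", "swr_2", "theta_3"))
})
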