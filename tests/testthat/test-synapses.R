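test_that("GHK current has the analytic v -> 0 limit and vanishes with P", {
  conc <- default_concentrations()
  i0 <- ghk_current(1e-6, 1, 0, conc$na_in, conc$na_out, conc$temperature)
  # L'Hopital limit: P * F * (c_in - c_out), in mA/cm^2 with mM concentrations
  expect_equal(i0, 1e-6 * 96485.33212 * (18 - 140) * 1e-3, tolerance = 1e-6)
  expect_equal(ghk_current(0, 1, -60, 18, 140), 0)
  expect_error(ghk_current(1e-6, 1, 0, 18, 140, temperature = -1), "temperature")
  # continuity across the series-expansion switch
  near <- ghk_current(1e-6, 1, 1e-7, 18, 140, conc$temperature)
  expect_equal(near, i0, tolerance = 1e-6)
})

test_that("each single-ion GHK flux crosses zero exactly at the Nernst potential", {
  conc <- default_concentrations()
  ions <- list(c(z = 1, cin = conc$na_in, cout = conc$na_out),
               c(z = 1, cin = conc$k_in, cout = conc$k_out),
               c(z = 2, cin = conc$ca_in, cout = conc$ca_out))
  for (ion in ions) {
    nernst <- 1000 * 8.31446 * conc$temperature / (ion[["z"]] * 96485.33212) *
      log(ion[["cout"]] / ion[["cin"]])
    # independent bisection oracle on the current sign
    f <- function(v) ghk_current(1e-6, ion[["z"]], v, ion[["cin"]],
                                 ion[["cout"]], conc$temperature)
    root <- uniroot(f, c(-150, 150), tol = 1e-9)$root
    expect_equal(root, nernst, tolerance = 1e-4)
    expect_lt(abs(f(nernst)), 1e-12)
  }
})

test_that("magnesium block matches the published value and is monotone", {
  expect_equal(mg_block(0, 2), 1 / (1 + 2 / 3.57), tolerance = 1e-12)
  expect_equal(round(mg_block(0, 2), 4), 0.6409)
  expect_equal(mg_block(-70, 0), 1)
  expect_equal(mg_block(1000, 2), 1, tolerance = 1e-6)
  vs <- seq(-100, 60, by = 1)
  expect_true(all(diff(mg_block(vs, 2)) > 0))
  # block is relieved by lowering magnesium
  expect_true(all(mg_block(vs, 1) > mg_block(vs, 2)))
})

test_that("NMDAR current decomposes correctly and scales linearly", {
  conc <- default_concentrations()
  r <- nmdar_current(-40, 1e-6, nar = 1.5, conc = conc)
  expect_lt(r$ca, 0)              # calcium component is inward
  expect_equal(nmdar_current(-40, 1e-6, nar = 0)$total, 0)
  r2 <- nmdar_current(-40, 2e-6, nar = 1.5, conc = conc)
  expect_equal(r2$total, 2 * r$total, tolerance = 1e-12)
  expect_equal(r2$ca, 2 * r$ca, tolerance = 1e-12)
  # with magnesium removed the components sum without attenuation
  conc0 <- conc; conc0$mg_out <- 0
  syn <- default_synapse()
  manual <- ghk_current(1.5e-6 * syn$P_Na, 1, -40, conc$na_in, conc$na_out, conc$temperature) +
    ghk_current(1.5e-6 * syn$P_K, 1, -40, conc$k_in, conc$k_out, conc$temperature) +
    ghk_current(1.5e-6 * syn$P_Ca, 2, -40, conc$ca_in, conc$ca_out, conc$temperature)
  expect_equal(nmdar_current(-40, 1e-6, conc = conc0)$total, manual,
               tolerance = 1e-12)
})

test_that("AMPAR current reverses between E_K and E_Na, near 0 mV", {
  conc <- default_concentrations()
  expect_equal(ampar_current(-40, 0), 0)
  rev <- uniroot(function(v) ampar_current(v, 1e-6, conc), c(-85, 50))$root
  expect_gt(rev, -90)
  expect_lt(rev, 55)
  expect_lt(abs(rev), 10)
  expect_equal(ampar_current(-65, 2e-6, conc), 2 * ampar_current(-65, 1e-6, conc),
               tolerance = 1e-12)
})
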