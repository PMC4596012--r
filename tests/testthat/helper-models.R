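# Shared fixtures, built in code.

# passive cylinder: every active conductance zero
passive_model <- function(Rm = 35, Cm = 1) {
  suppressWarnings(build_model(list(
    Rm = Rm, Cm = Cm,
    Na_g = 0, DR_g = 0, A_g = 0, M_g = 0, h_g = 0,
    T_g = 0, R_g = 0, N_g = 0, L_g = 0, SK_g = 0, BK_g = 0
  ), warn_range = FALSE))
}

# base model without voltage-gated calcium channels (silences the standing
# window influx so rest sits exactly at the nominal 50 nM)
no_vgcc_model <- function() {
  suppressWarnings(build_model(list(T_g = 0, R_g = 0, N_g = 0, L_g = 0),
                               warn_range = FALSE))
}

# sealed-calcium model: no ER/SERCA/pump exchange and no calcium influx
sealed_calcium_model <- function() {
  m <- no_vgcc_model()
  m$calcium$v_max_serca <- 0
  m$calcium$gamma_eff <- 0
  m$calcium$leak_constant <- 0
  m
}

# theta amplitude of the base model, computed once per test run
base_theta_amplitude <- local({
  amp <- NULL
  function() {
    if (is.null(amp)) amp <<- calibrate_theta_amplitude(base_model())
    amp
  }
})
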