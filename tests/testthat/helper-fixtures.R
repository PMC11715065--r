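# shared fixtures, built in code at load time

reference_pk <- function() pk_parameters(CL = 0.0453, Q = 0.268, V1 = 2.94,
                                     V2 = 9.51, t_half_keo = 1.04)
reference_pd <- function() pd_parameters(E0 = 6, Emax = 180, Ce50 = 64.2, N = 1)

# a noise-free population (numerically tiny residual SD so the likelihood
# stays proper) used for exact-recovery and determinism checks
noise_free_population <- function() {
  pop <- default_population()
  population_model(pop$pk, pop$pd, pop$ida, omega = numeric(0),
                   sigma = c(conc_prop = 0, conc_add = 1e-3,
                             r_prop = 0, r_add = 1e-3))
}

study_times <- function() c(5, 15, 30, 60, 90, 120,
                            120 + c(5, 15, 30, 60, 120, 240, 480, 1440))
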