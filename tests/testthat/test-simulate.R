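test_that("bolus and steady-state limits match closed-form expectations", {
  pk <- reference_pk()
  # 280 mg over a vanishing duration: C1 just after the input is dose / V1
  reg <- regimen("dabigatran", 0, 280, 1e-4)
  s <- simulate_pk(pk, reg, c(1e-4, 1, 5))
  expect_equal(s$C1[1], 280 / 2.94, tolerance = 1e-4)
  # constant infusion at rate = CL reaches 1 mg/L at steady state
  reg2 <- regimen("dabigatran", 0, 0.0453 * 5e4, 5e4)
  s2 <- simulate_pk(pk, reg2, c(4.9e4))
  expect_equal(s2$C1, 1, tolerance = 1e-3)
  # empty regimen: every channel identically zero
  s0 <- simulate_pk(pk, regimen(), c(1, 10, 100))
  expect_true(all(s0$C1 == 0 & s0$C2 == 0 & s0$Ce == 0 & s0$C_ida == 0))
})

test_that("closed form and ODE integration agree and conserve mass", {
  pk <- reference_pk()
  reg <- study_regimen(70)
  tt <- c(0.5, 1, 2, study_times())
  s_cf <- simulate_pk(pk, reg, tt)
  s_ode <- simulate_pk(pk, reg, tt, method = "ode")
  for (ch in c("C1", "C2", "Ce", "C_ida"))
    expect_lt(max(abs(s_cf[[ch]] - s_ode[[ch]]) / pmax(s_ode[[ch]], 1e-9)),
              1e-3)
  mb <- mass_balance(s_cf, pk, reg)
  expect_lt(max(mb$relative_error), 1e-3)
  mb_ode <- mass_balance(s_ode, pk, reg)
  expect_lt(max(mb_ode$relative_error), 1e-3)
})

test_that("simulation output is invariant to splitting an infusion", {
  pk <- reference_pk()
  tt <- c(5, 15, 40, 90)
  whole <- simulate_pk(pk, regimen("dabigatran", 0, 60, 30), tt)
  split <- simulate_pk(pk, regimen(c("dabigatran", "dabigatran"),
                                   c(0, 10), c(20, 40), c(10, 20)), tt)
  expect_equal(whole$C1, split$C1, tolerance = 1e-10)
  expect_equal(whole$Ce, split$Ce, tolerance = 1e-10)
})

test_that("effect site lags plasma with the stated half-time", {
  ke <- log(2) / 1.04
  tt <- seq(0, 30, 0.01)
  # step input held at c: exact first-order rise
  ce <- effect_site(tt, rep(2, length(tt)), ke)
  expect_equal(ce[tt == 1.04], 1, tolerance = 1e-3)        # half of 2
  expect_equal(ce[length(ce)], 2, tolerance = 1e-6)        # equilibrium
  # never overshoots a monotone input
  c1 <- 5 * (1 - exp(-0.3 * tt))
  ce2 <- effect_site(tt, c1, ke)
  expect_true(all(ce2 <= c1 + 1e-9))
  expect_error(effect_site(tt, c1, keo = 0), "keo")
})

test_that("sigmoid Emax response has the right anchors and shape", {
  pd <- reference_pd()
  expect_equal(emax_response(0, pd), 6)
  expect_equal(emax_response(64.2, pd), 6 + 90)
  expect_equal(emax_response(1e9, pd), 6 + 180, tolerance = 1e-6)
  # monotone in ce and in Emax
  ce <- seq(0, 500, 5)
  expect_true(all(diff(emax_response(ce, pd)) >= 0))
  pd_hi <- pd_parameters(6, 200, 64.2, 1)
  expect_true(all(emax_response(ce[-1], pd_hi) > emax_response(ce[-1], pd)))
  # symmetric on the log-concentration axis around Ce50
  for (k in c(2, 5, 10)) {
    expect_equal(emax_response(64.2 * k, pd) + emax_response(64.2 / k, pd),
                 2 * 6 + 180, tolerance = 1e-9)
  }
  expect_error(emax_response(-1, pd), "non-negative")
})

test_that("idarucizumab reversal effect is transient and scales with slope", {
  ida <- ida_parameters(K_IDA = 0.1, DUR_IDA = 0.5, SLOPE_IDA = 5)
  reg <- study_regimen(70)
  # zero before the dose, negative after, washed out late
  tt <- c(5, 60, 119, 121, 125, 150, 5000)
  eff <- idarucizumab_effect(reg, ida, tt)
  expect_true(all(eff[tt < 120] == 0))
  expect_lt(eff[tt == 125], 0)
  expect_equal(eff[tt == 5000], 0, tolerance = 1e-8)
  # mono-exponential decay after end of input: half value one half-life on
  t_end <- 120.5
  tt2 <- c(t_end, t_end + log(2) / 0.1)
  e2 <- idarucizumab_effect(reg, ida, tt2)
  expect_equal(e2[2], e2[1] / 2, tolerance = 1e-9)
  # no event -> identically zero
  expect_equal(idarucizumab_effect(study_regimen(70, ida_mgkg = NULL), ida, tt),
               rep(0, length(tt)))
  # monotone in SLOPE_IDA
  ida2 <- ida_parameters(0.1, 0.5, 10)
  expect_true(all(idarucizumab_effect(reg, ida2, c(125, 150)) <
                    idarucizumab_effect(reg, ida, c(125, 150))))
})

test_that("reaction time adds both effects and is floored at zero", {
  pop <- default_population()
  pars <- individual_parameters(pop, 70)
  tt <- c(5, 60, 125, 150)
  reg <- study_regimen(70)
  sim <- simulate_pk(pars$pk, reg, tt, ida = pars$ida)
  r <- predict_r_time(sim, pars$pd, pars$ida)
  expect_equal(r$R, pmax(emax_response(sim$Ce, pars$pd) -
                           pars$ida$SLOPE_IDA * sim$C_ida, 0))
  # a huge slope cannot push R below zero
  big <- ida_parameters(pars$ida$K_IDA, pars$ida$DUR_IDA, 1e6)
  r2 <- predict_r_time(sim, pars$pd, big)
  expect_true(all(r2$R >= 0))
  expect_equal(r2$R[1], r$R[1])   # pre-reversal samples unaffected
  # no dosing at all: R is the baseline
  s0 <- simulate_pk(pars$pk, regimen(), tt, ida = pars$ida)
  expect_equal(predict_r_time(s0, pars$pd, pars$ida)$R, rep(6, 4))
})

test_that("time grids are validated", {
  pk <- reference_pk()
  expect_error(simulate_pk(pk, regimen(), c(5, 3, 10)), "increasing")
  expect_error(simulate_pk(pk, regimen(), c(-1, 3)), "non-negative")
})
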