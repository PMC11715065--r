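test_that("the circuit prime dose is target concentration times volume", {
  expect_equal(prime_dose(5, circuit_spec(V3 = 1.5)), 7.5)
  expect_equal(prime_dose(0, circuit_spec(V3 = 3)), 0)
  expect_equal(prime_dose(5, circuit_spec(V3 = 1.0)), 5)
  expect_error(prime_dose(-1, circuit_spec()), "target")
  expect_error(circuit_spec(V3 = 0), "V3")
})

test_that("a detached circuit reduces to the plain disposition model", {
  pk <- reference_pk()
  plan <- regimen_plan(0.25, 1, data.frame(rate_mgkg_min = 0.0175,
                                           start = 0, end = 30))
  tt <- c(1, 5, 10, 20, 30, 45, 60)
  on_cpb <- simulate_on_cpb(pk, circuit_spec(Q3 = 0, preload_conc = 0),
                            plan, 70, tt)
  plain <- simulate_pk(pk, regimen(c("dabigatran", "dabigatran"), c(0, 0),
                                   c(17.5, 0.0175 * 70 * 30), c(1, 30)), tt)
  expect_equal(on_cpb$C1, plain$C1, tolerance = 1e-6)
  expect_equal(on_cpb$C2, plain$C2, tolerance = 1e-6)
})

test_that("without elimination the preload dilutes into the total volume", {
  pk_noel <- pk_parameters(1e-10, 0.268, 2.94, 9.51, 1.04)
  circ <- circuit_spec(V3 = 1.5, Q3 = 2, preload_conc = 5)
  sim <- simulate_on_cpb(pk_noel, circ, regimen_plan(0, 1), 70, c(2000, 5000))
  eq <- 5 * 1.5 / (2.94 + 9.51 + 1.5)
  expect_equal(sim$C1[2], eq, tolerance = 1e-6)
  expect_equal(sim$C3[2], eq, tolerance = 1e-6)
})

test_that("steady state under constant infusion is rate/CL regardless of circuit", {
  pk <- reference_pk()
  rate <- 5 * pk$CL / 70   # mg/kg/min aiming at 5 mg/L
  plan <- regimen_plan(0, 1, data.frame(rate_mgkg_min = rate,
                                        start = 0, end = 1e5))
  for (circ in list(circuit_spec(V3 = 1, Q3 = 2),
                    circuit_spec(V3 = 4, Q3 = 0.5))) {
    sim <- simulate_on_cpb(pk, circ, plan, 70, c(9e4))
    expect_equal(sim$C1, 5, tolerance = 1e-3)
  }
})

test_that("regimen design hits the target and responds to clearance", {
  pk <- reference_pk()
  plan <- design_regimen(pk, circuit_spec(), target = 5, weight = 70)
  # loading close to the published 0.25 mg/kg (target * V1 / weight = 0.21)
  expect_equal(plan$loading_mgkg, 5 * 2.94 / 70, tolerance = 1e-9)
  expect_gt(plan$loading_mgkg, 0.15)
  expect_lt(plan$loading_mgkg, 0.3)
  expect_true(attr(plan, "feasible"))
  # the plan's own tolerance report is reproducible by re-simulation
  circ <- circuit_spec(preload_conc = 5)
  grid <- seq(0, 90, 1)
  sim <- simulate_on_cpb(pk, circ, plan, 70, grid)
  dev <- max(abs(sim$C1[grid >= 10] / 5 - 1))
  expect_equal(dev, attr(plan, "max_rel_dev"), tolerance = 1e-9)
  expect_lte(dev, 0.20)
  # doubling clearance raises the late maintenance rate
  pk_fast <- pk_parameters(2 * 0.0453, 0.268, 2.94, 9.51, 1.04)
  plan_fast <- design_regimen(pk_fast, circuit_spec(), 5, 70)
  expect_gt(plan_fast$segments$rate_mgkg_min[2], plan$segments$rate_mgkg_min[2])
  # degenerate target
  plan0 <- design_regimen(pk, circuit_spec(), 0, 70)
  expect_equal(plan0$loading_mgkg, 0)
  expect_true(all(plan0$segments$rate_mgkg_min == 0))
})

test_that("the target reaction time inverts through the Emax model", {
  pd <- pd_parameters(E0 = 4, Emax = 180, Ce50 = 64.2, N = 1)
  # half-maximal response inverts to Ce50 exactly
  expect_equal(concentration_to_target_effect(4 + 90, pd), 64.2)
  # the 13-min target effect sits near the 5 mg/L target concentration
  expect_equal(concentration_to_target_effect(17, pd), 64.2 * 13 / 167,
               tolerance = 1e-9)
  expect_equal(concentration_to_target_effect(17, pd), 4.998, tolerance = 1e-3)
  # approaching the baseline sends the required concentration to zero
  expect_lt(concentration_to_target_effect(4 + 1e-6, pd), 1e-6)
  expect_error(concentration_to_target_effect(3, pd), "strictly")
  expect_error(concentration_to_target_effect(200, pd), "strictly")
})
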