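test_that("the combined-error likelihood kernel evaluates exactly", {
  # one exact observation under pure additive error: log(2*pi)
  expect_equal(individual_neg2ll(1, 1, 0, 1), log(2 * pi), tolerance = 1e-12)
  expect_equal(individual_neg2ll(1, 1, 0, 1), 1.837877, tolerance = 1e-6)
  # doubling the additive SD with y = f adds 2 log 2 per observation
  y <- f <- c(2, 3, 4)
  expect_equal(individual_neg2ll(y, f, 0, 2) - individual_neg2ll(y, f, 0, 1),
               3 * 2 * log(2), tolerance = 1e-12)
  # growing variance dominates any fixed residual (log term)
  vals <- vapply(c(1e2, 1e4, 1e6), function(s)
    individual_neg2ll(5, 1, 0, s), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(individual_neg2ll(1, 0, 0.1, 0), "degenerate")
})

test_that("naive pooling recovers generating parameters from noise-free data", {
  pop <- default_population()
  dat <- generate_cohort(noise_free_population(),
                         sheep_design(n_subjects = 1, rich = TRUE,
                                      weight_range = c(70, 70)), seed = 42)
  spec <- model_spec(pop, channels = "conc",
                     estimate_theta = c("CL", "Q", "V1", "V2"),
                     estimate_omega = character(0),
                     estimate_sigma = character(0),
                     omega = numeric(0),
                     sigma = c(conc_prop = 1e-3, conc_add = 1e-3,
                               r_prop = 0.1, r_add = 0.5))
  fit <- fit_population(dat, spec, method = "np")
  truth <- c(CL = 0.0453, Q = 0.268, V1 = 2.94, V2 = 9.51)
  expect_equal(fit$theta[names(truth)], truth, tolerance = 1e-3)
  # same data, same inits, run twice: identical objective
  fit2 <- fit_population(dat, spec, method = "np")
  expect_identical(fit$objective, fit2$objective)
})

test_that("FOCE-I and Laplace objectives agree on near-linear problems", {
  pop <- default_population()
  small <- population_model(pop$pk, pop$pd, pop$ida,
                            omega = c(CL = 0.0025, V1 = 0.0025),
                            sigma = pop$sigma)
  dat <- generate_cohort(small, sheep_design(n_subjects = 5, ida_mgkg = NULL),
                         seed = 77)
  spec <- model_spec(small, channels = "conc",
                     estimate_theta = c("CL", "V1"),
                     estimate_omega = c("CL", "V1"),
                     estimate_sigma = c("conc_prop", "conc_add"))
  blocks <- dabipkpd:::.prepare_blocks(dat, "conc")
  par0 <- dabipkpd:::.pack_init(spec)
  st1 <- new.env(); st1$etas <- matrix(0, 5, 2)
  st2 <- new.env(); st2$etas <- matrix(0, 5, 2)
  o_focei <- dabipkpd:::.population_obj(par0, blocks, spec, "focei", st1)
  o_lap <- dabipkpd:::.population_obj(par0, blocks, spec, "laplace", st2)
  expect_lt(abs(o_focei - o_lap), 1)
})

test_that("estimates sharpen as the cohort grows", {
  pop <- default_population()
  pop_fix <- population_model(pop$pk, pop$pd, pop$ida, omega = numeric(0),
                              sigma = c(conc_prop = 0.1, conc_add = 0.1,
                                        r_prop = 0.1, r_add = 0.5))
  spec <- model_spec(pop, channels = "conc",
                     estimate_theta = c("CL", "Q", "V1", "V2"),
                     estimate_omega = character(0),
                     estimate_sigma = character(0),
                     omega = numeric(0), sigma = pop$sigma)
  err <- function(n) {
    dat <- generate_cohort(pop_fix, sheep_design(n_subjects = n, rich = TRUE),
                           seed = 300 + n)
    fit <- fit_population(dat, spec, method = "np")
    truth <- c(CL = 0.0453, Q = 0.268, V1 = 2.94, V2 = 9.51)
    mean(abs(fit$theta[names(truth)] / truth - 1))
  }
  expect_lt(err(48), err(3))
})

test_that("the sequential PK-then-PD fit is anchored by its PK stage", {
  pop <- noise_free_population()
  dat <- generate_cohort(pop, sheep_design(n_subjects = 2, rich = TRUE),
                         seed = 55)
  ctl <- list(simplex_iter = 0, rel_tol = 1e-6)
  fit <- fit_sequential_pppd(dat, pop, method = "np", control = ctl,
                             pk_estimate_sigma = character(0),
                             pd_estimate_sigma = character(0))
  # stage 1 is by definition the concentration-only population fit
  pk_spec <- model_spec(pop, channels = "conc",
                        estimate_theta = c("CL", "Q", "V1", "V2"),
                        estimate_omega = character(0),
                        estimate_sigma = character(0),
                        omega = numeric(0))
  direct <- fit_population(dat, pk_spec, method = "np", control = ctl)
  expect_equal(fit$stages$pk$objective, direct$objective, tolerance = 1e-8)
  expect_equal(fit$stages$pk$theta, direct$theta, tolerance = 1e-10)
  # stage 2 on noise-free data sits at the generating response parameters
  expect_equal(fit$theta[["Emax"]], 180, tolerance = 0.02)
  expect_equal(fit$theta[["Ce50"]], 64.2, tolerance = 0.02)
  expect_equal(fit$theta[["E0"]], 6, tolerance = 0.02)
  expect_equal(fit$theta[["t_half_keo"]], 1.04, tolerance = 0.02)
  # PK fixed effects are carried over, fixed
  expect_identical(fit$theta[["CL"]], fit$stages$pk$theta[["CL"]])
  expect_false("CL" %in% fit$spec$estimate_theta)
})

test_that("likelihood-ratio decisions use the chi-square threshold", {
  d1 <- compare_models(100, 104, df = 1)   # objectives may be given directly
  expect_true(d1$significant)
  expect_equal(d1$delta_obj, 4)
  d2 <- compare_models(100, 103, df = 1)
  expect_false(d2$significant)
  d3 <- compare_models(100, 105, df = 2)
  expect_equal(d3$threshold, stats::qchisq(0.95, 2), tolerance = 1e-9)
  expect_equal(d3$threshold, 5.991465, tolerance = 1e-6)
  expect_warning(compare_models(100, 99, df = 1), "lower objective")
  expect_error(compare_models(100, 104, df = 0), "df")
})

test_that("heuristic initial estimates land near the data scale", {
  dat <- generate_cohort(default_population(), sheep_design(n_subjects = 5),
                         seed = 12)
  ini <- initial_estimates(dat)
  # dose/Cmax puts V1 within a small factor of the generating 2.94 L
  expect_gt(ini[["V1"]], 1)
  expect_lt(ini[["V1"]], 10)
  expect_gt(ini[["CL"]], 0.005)
  expect_lt(ini[["CL"]], 0.5)
  expect_true(all(c("E0", "Emax", "Ce50") %in% names(ini)))
})
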