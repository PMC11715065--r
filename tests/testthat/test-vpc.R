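test_that("prediction correction is the stated rescaling", {
  expect_equal(prediction_correct(10, 5, 6), 12)
  expect_equal(prediction_correct(7, 3, 3), 7)          # identity in-bin
  # all-equal predictions: correction is a no-op for every record
  y <- c(1, 2, 3)
  expect_equal(prediction_correct(y, rep(4, 3), 4), y)
  expect_warning(out <- prediction_correct(c(1, 2), c(0, 2), 2), "excluded")
  expect_true(is.na(out[1]) && out[2] == 2)
})

test_that("VPC bands are ordered and respect a single-time design", {
  pop <- default_population()
  des <- study_design(n_subjects = 12, times_conc = 30, times_r = 30)
  dat <- generate_cohort(pop, des, seed = 4)
  v <- run_vpc(dat, pop, n_replicates = 100, seed = 8)
  # one bin per channel; observed percentiles equal the empirical ones
  conc <- v$bins[v$bins$channel == "conc", ]
  expect_equal(nrow(conc), 3)
  y <- dat$DV[dat$EVID == 0 & dat$DVID == 1]
  p <- dat$DV  # prediction-corrected values, recomputed independently
  blocks <- dabipkpd:::.prepare_blocks(dat, "conc")
  th <- unlist(dabipkpd:::theta_vector(pop))[dabipkpd:::.par_names]
  pred <- unlist(lapply(blocks, function(b)
    dabipkpd:::.block_predict_p(th * b$wfac, b)[b$is_conc]))
  pc <- y * stats::median(pred) / pred
  expect_equal(conc$observed, unname(stats::quantile(pc, c(0.1, 0.5, 0.9))),
               tolerance = 1e-9)
  # percentile ordering within each bin, CI bounds ordered
  for (ch in unique(v$bins$channel)) {
    b <- v$bins[v$bins$channel == ch, ]
    expect_true(all(diff(b$observed[order(b$percentile)]) >= 0))
    expect_true(all(b$sim_lower <= b$sim_upper))
  }
})

test_that("VPC results are invariant to row shuffling and subject order", {
  pop <- default_population()
  dat <- generate_cohort(pop, sheep_design(n_subjects = 6), seed = 14)
  set.seed(1)
  shuffled <- dat[sample(nrow(dat)), ]
  v1 <- run_vpc(dat, pop, n_replicates = 100, seed = 21)
  v2 <- run_vpc(shuffled, pop, n_replicates = 100, seed = 21)
  expect_equal(v1$bins, v2$bins, tolerance = 1e-12)
})

test_that("replicate count is enforced and bands tighten with replicates", {
  pop <- default_population()
  dat <- generate_cohort(pop, sheep_design(n_subjects = 6), seed = 14)
  expect_error(run_vpc(dat, pop, n_replicates = 50), "at least 100")
  v_small <- run_vpc(dat, pop, n_replicates = 100, seed = 3)
  v_big <- run_vpc(dat, pop, n_replicates = 400, seed = 3)
  # Monte-Carlo consistency: median bands from independent replicate sets
  # stay close, and the CI width shrinks on average with more replicates
  expect_equal(v_small$bins$sim_median, v_big$bins$sim_median,
               tolerance = 0.15)
  w_small <- mean(v_small$bins$sim_upper - v_small$bins$sim_lower)
  w_big <- mean(v_big$bins$sim_upper - v_big$bins$sim_lower)
  expect_lt(abs(w_big - w_small) / w_small, 0.35)
})

test_that("a fit result converts to a generative population model", {
  pop <- default_population()
  dat <- generate_cohort(noise_free_population(),
                         sheep_design(n_subjects = 1, rich = TRUE,
                                      weight_range = c(70, 70)), seed = 42)
  spec <- model_spec(pop, channels = "conc",
                     estimate_theta = c("CL", "V1"),
                     estimate_omega = character(0),
                     estimate_sigma = character(0),
                     omega = numeric(0),
                     sigma = c(conc_prop = 1e-3, conc_add = 1e-3,
                               r_prop = 0.1, r_add = 0.5))
  fit <- fit_population(dat, spec, method = "np")
  pop2 <- as_population(fit)
  expect_s3_class(pop2, "population_model")
  expect_equal(pop2$pk$CL, fit$theta[["CL"]])
  expect_identical(as_population(pop), pop)
  # plotting machinery returns a ggplot without evaluation errors
  v <- run_vpc(dat, pop2, n_replicates = 100, seed = 2)
  expect_s3_class(plot_vpc(v), "ggplot")
})
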