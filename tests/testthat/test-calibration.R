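test_that("rmse behaves as a root mean square error should", {
  expect_equal(rmse(c(50, 60, 70), c(50, 60, 70)), 0)
  expect_equal(rmse(c(52, 62, 72), c(50, 60, 70)), 2)
  # direct arithmetic on the six baseline postpartum rates vs their
  # rounded values: mean squared diff 0.86330/6, root 0.3793196
  expect_equal(rmse(c(77.41, 68.86, 55.62, 35.20, 24.46, 13.86),
                    c(78, 69, 56, 35, 25, 14)),
               0.3793196, tolerance = 1e-6)
  expect_error(rmse(1:3, 1:4), "equal length")
  a <- c(3, 1, 4, 1, 5); b <- c(2, 7, 1, 8, 2)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(rmse(a, b), rmse(a[perm], b[perm]))
  expect_gte(rmse(a, b), 0)
})

test_that("a degenerate single-point grid returns that point", {
  coh <- small_cohort(300)
  ic <- calibrate_intercepts(coh)
  g <- grid_spec(excl_to_formula = c(0.02, 0.02),
                 partial_to_formula = c(0.1, 0.1),
                 excl_to_partial = c(0.1, 0.1))
  cal <- suppressWarnings(
    calibrate_rates(coh, ic$intent_model, ic$initiation_model,
                    grid = g, refine = FALSE))
  expect_equal(cal$rates$excl_to_formula, 0.02)
  expect_equal(cal$rates$partial_to_formula, 0.1)
  expect_equal(cal$rates$excl_to_partial, 0.1)
  expect_equal(nrow(cal$table), 1L)
  expect_gte(cal$rmse, 0)
})

test_that("self-calibration recovers known transition rates", {
  # parameter-recovery experiment: for random true rate triples inside the
  # searched ranges, calibrating against the exact expected rates they
  # generate must land within one coarse grid step of the truth
  coh <- small_cohort(400, seed = 61)
  ic <- calibrate_intercepts(coh)
  prep <- expectation_prep(coh, ic$intent_model, ic$initiation_model)
  g <- grid_spec(points = 8L)
  step <- vapply(list(g$excl_to_formula, g$partial_to_formula,
                      g$excl_to_partial),
                 function(r) diff(r) / 7, 0)
  set.seed(303)
  hits <- 0L
  for (k in 1:10) {
    truth <- transition_rates(
      runif(1, 0.004 + step[1], 0.08 - step[1]),
      runif(1, 0.02 + step[2], 0.5 - step[2]),
      runif(1, 0.015 + step[3], 0.3 - step[3]))
    s_true <- runif(1, 0.3, 0.7)
    target <- expected_rates(prep, rates = truth,
                             p_exclusive_init = s_true)[3:8]
    cal <- suppressWarnings(
      calibrate_rates(coh, ic$intent_model, ic$initiation_model,
                      target = target, grid = g))
    ok <- abs(cal$rates$excl_to_formula - truth$excl_to_formula) <= step[1] &&
      abs(cal$rates$partial_to_formula - truth$partial_to_formula) <= step[2] &&
      abs(cal$rates$excl_to_partial - truth$excl_to_partial) <= step[3]
    hits <- hits + ok
  }
  expect_gte(hits, 9L)
})

test_that("refinement never worsens the incumbent RMSE", {
  coh <- small_cohort(300)
  ic <- calibrate_intercepts(coh)
  target <- c(any_1m = 80, any_3m = 70, any_6m = 58,
              excl_1m = 35, excl_3m = 25, excl_6m = 14)
  cal <- suppressWarnings(
    calibrate_rates(coh, ic$intent_model, ic$initiation_model,
                    target = target, grid = grid_spec(points = 5L)))
  expect_lte(cal$rmse, min(cal$table$rmse) + 1e-12)
})

test_that("a best fit on the searched boundary raises a warning", {
  coh <- small_cohort(300)
  ic <- calibrate_intercepts(coh)
  # targets needing faster decline than the narrow range allows
  target <- c(any_1m = 60, any_3m = 35, any_6m = 15,
              excl_1m = 20, excl_3m = 8, excl_6m = 2)
  expect_warning(
    calibrate_rates(coh, ic$intent_model, ic$initiation_model,
                    target = target,
                    grid = grid_spec(excl_to_formula = c(0.004, 0.01),
                                     partial_to_formula = c(0.02, 0.05),
                                     excl_to_partial = c(0.015, 0.05),
                                     points = 4L),
                    refine = FALSE),
    "boundary")
})

test_that("stochastic grid evaluation agrees with the exact evaluator", {
  coh <- small_cohort(2000, seed = 71)
  ic <- calibrate_intercepts(coh)
  g <- grid_spec(excl_to_formula = c(0.016, 0.016),
                 partial_to_formula = c(0.059, 0.059),
                 excl_to_partial = c(0.139, 0.139))
  target <- baseline_targets()$rates
  exact <- suppressWarnings(
    calibrate_rates(coh, ic$intent_model, ic$initiation_model,
                    target = target, grid = g, refine = FALSE))
  simu <- suppressWarnings(
    calibrate_rates(coh, ic$intent_model, ic$initiation_model,
                    target = target, grid = g, refine = FALSE,
                    method = "simulated", reps_per_point = 8L,
                    p_exclusive_init = exact$p_exclusive_init, seed = 5))
  expect_lt(max(abs(exact$fitted - simu$fitted)), 2.0)
})

test_that("end-to-end baseline calibration returns a coherent model", {
  model <- baseline_model()
  expect_s3_class(model, "bf_model")
  expect_equal(
    unname(model$calibration$fitted),
    unname(expected_rates(model$ref_cohort, model$intent_model,
                          model$initiation_model, model$rates,
                          model$p_exclusive_init)[3:8]),
    tolerance = 1e-10)
  g <- grid_spec()
  r <- model$rates
  expect_true(r$excl_to_formula >= g$excl_to_formula[1] &&
                r$excl_to_formula <= g$excl_to_formula[2])
  expect_true(r$partial_to_formula >= g$partial_to_formula[1] &&
                r$partial_to_formula <= g$partial_to_formula[2])
  expect_true(r$excl_to_partial >= g$excl_to_partial[1] &&
                r$excl_to_partial <= g$excl_to_partial[2])
  expect_true(model$p_exclusive_init >= 0 && model$p_exclusive_init <= 1)
})
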