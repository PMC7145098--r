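test_that("monthly-to-daily conversion compounds back to the monthly rate", {
  for (p in c(0.016, 0.059, 0.139, 0.5, 0)) {
    q <- monthly_to_per_step(p)
    expect_equal(1 - (1 - q)^30.4375, p, tolerance = 1e-12)
  }
  expect_equal(monthly_to_per_step(0.139), 0.00490492, tolerance = 1e-5)
  expect_equal(monthly_to_per_step(0.059), 0.00199594, tolerance = 1e-5)
  expect_warning(q1 <- monthly_to_per_step(1), "degenerate")
  expect_equal(q1, 1)
  expect_error(monthly_to_per_step(1.5), "\\[0, 1\\]")
})

test_that("the clock maps evaluation months to unique step indices", {
  cl <- sim_clock()
  expect_equal(cl$eval_days, c(30L, 91L, 183L))
  expect_equal(cl$horizon_days, 183L)
  expect_error(sim_clock(month_length = 1e-9), "distinct")
})

test_that("with zero rates and no barriers the status never changes", {
  coh <- strip_barriers(small_cohort(300))
  im <- intent_model(intercept = 50)        # everyone intends
  nm <- initiation_model(intercept = 50)    # everyone initiates
  r0 <- transition_rates(0, 0, 0)
  tr <- run_cohort(coh, im, nm, r0, p_exclusive_init = 1, seed = 1,
                   keep_trace = TRUE)
  expect_true(all(tr$trace == 1L))
  out <- summarize_trajectories(tr)
  expect_equal(unname(out[c("any_1m", "any_3m", "any_6m")]), rep(100, 3))
  expect_equal(unname(out[c("excl_1m", "excl_3m", "excl_6m")]), rep(100, 3))
})

test_that("women who never initiate are formula-feeding throughout", {
  coh <- small_cohort(300)
  im <- intent_model(intercept = -50)
  nm <- initiation_model(intercept = -50)
  tr <- run_cohort(coh, im, nm, transition_rates(), 0.5, seed = 1,
                   keep_trace = TRUE)
  expect_true(all(tr$trace == 3L))
  out <- summarize_trajectories(tr)
  expect_equal(unname(out[3:8]), rep(0, 6))
})

test_that("competing-risk survival matches the analytic closed form", {
  # exclusive start, residual hazards only, evaluated at 1 month: the
  # analytic survivor fraction is (1 - q_ef - q_ep)^30 at daily steps
  coh <- strip_barriers(sample_cohort(150000, seed = 55))
  im <- intent_model(intercept = 50)
  nm <- initiation_model(intercept = 50)
  rates <- transition_rates(0.016, 0, 0.139)
  cl <- sim_clock(horizon_months = 1, eval_months = 1)
  tr <- run_cohort(coh, im, nm, rates, p_exclusive_init = 1, clock = cl,
                   seed = 8)
  q_ef <- 1 - (1 - 0.016)^(1 / 30.4375)
  q_ep <- 1 - (1 - 0.139)^(1 / 30.4375)
  analytic <- (1 - q_ef - q_ep)^30 * 100
  sim <- summarize_trajectories(tr)[["excl_1m"]]
  expect_lt(abs(sim - analytic), 0.3)
})

test_that("trajectories are monotone and FORMULA is absorbing", {
  coh <- small_cohort(2000, seed = 17)
  im <- intent_model(intercept = 1.5)
  nm <- initiation_model(intercept = 1)
  tr <- run_cohort(coh, im, nm, transition_rates(), 0.5, seed = 3,
                   keep_trace = TRUE)
  # status codes are ordered EXCLUSIVE(1) < PARTIAL(2) < FORMULA(3):
  # monotone non-increasing feeding level = non-decreasing codes
  expect_true(all(tr$trace[, -1] >= tr$trace[, -ncol(tr$trace)]))
  out <- summarize_trajectories(tr)
  expect_true(out[["any_1m"]] >= out[["any_3m"]])
  expect_true(out[["any_3m"]] >= out[["any_6m"]])
  expect_true(all(out[c("excl_1m", "excl_3m", "excl_6m")] <=
                    out[c("any_1m", "any_3m", "any_6m")]))
})

test_that("runs are bitwise reproducible and order-invariant", {
  coh <- small_cohort(100, seed = 23)
  im <- intent_model(intercept = 1.5)
  nm <- initiation_model(intercept = 1)
  a <- run_cohort(coh, im, nm, transition_rates(), 0.5, seed = 12)
  b <- run_cohort(coh, im, nm, transition_rates(), 0.5, seed = 12)
  expect_identical(a, b)
  perm <- sample(nrow(coh))
  shuffled <- coh[perm, ]
  c_ <- run_cohort(shuffled, im, nm, transition_rates(), 0.5, seed = 12)
  back <- match(coh$id, shuffled$id)
  expect_identical(c_$status[back, ], a$status)
  expect_identical(c_$intent[back], a$intent)
  expect_identical(c_$initiated[back], a$initiated)
})

test_that("cohorts with missing required fields are rejected up front", {
  coh <- small_cohort(10)
  coh$knowledge[4] <- NA
  expect_error(run_cohort(coh, intent_model(), initiation_model(),
                          transition_rates(), 0.5, seed = 1),
               "missing values")
  coh2 <- small_cohort(10)[, -3]
  expect_error(run_cohort(coh2, intent_model(), initiation_model(),
                          transition_rates(), 0.5, seed = 1),
               "missing column")
})

test_that("run_one_agent returns a complete single trajectory", {
  w <- small_cohort(5)[3, ]
  tr <- run_one_agent(w, intent_model(intercept = 2),
                      initiation_model(intercept = 2),
                      transition_rates(), 0.9, seed = 4)
  expect_equal(nrow(tr$status), 1L)
  expect_equal(ncol(tr$trace), 183L)
})

test_that("expected rates agree with large-cohort simulation", {
  coh <- sample_cohort(30000, seed = 91)
  ic <- calibrate_intercepts(coh)
  rates <- transition_rates()
  exp_r <- expected_rates(coh, ic$intent_model, ic$initiation_model,
                          rates, 0.5)
  tr <- run_cohort(coh, ic$intent_model, ic$initiation_model, rates, 0.5,
                   seed = 6)
  sim_r <- summarize_trajectories(tr)
  expect_lt(max(abs(exp_r - sim_r[names(exp_r)])), 1.0)
})

test_that("trajectory export writes one labelled row per woman", {
  coh <- small_cohort(20)
  tr <- run_cohort(coh, intent_model(intercept = 2),
                   initiation_model(intercept = 2), transition_rates(),
                   0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  export_trajectories(tr, path)
  out <- utils::read.csv(path)
  expect_equal(nrow(out), 20L)
  expect_true(all(out$status_6m %in% BF_STATUS))
})
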