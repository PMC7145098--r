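#' Residual monthly transition rates
#'
#' The three residual transition proportions of the feeding-status state
#' chart, accounting for reasons to reduce breastfeeding other than the two
#' explicit barriers.  Each is the proportion of women transitioning per
#' month.
#'
#' @param excl_to_formula,partial_to_formula,excl_to_partial Monthly
#'   proportions in \[0, 1\].
#' @return An object of class `bf_rates`.
#' @export
transition_rates <- function(excl_to_formula = 0.016,
                             partial_to_formula = 0.059,
                             excl_to_partial = 0.139) {
  r <- c(excl_to_formula = excl_to_formula,
         partial_to_formula = partial_to_formula,
         excl_to_partial = excl_to_partial)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("transition rates must lie in [0, 1]")
  structure(as.list(r), class = "bf_rates")
}

#' Convert a monthly transition proportion to a per-step probability
#'
#' Geometric compounding: a per-day probability `q` such that
#' `1 - (1 - q)^month_length = p_month`, i.e.
#' `q = 1 - (1 - p_month)^(1/month_length)`.
#'
#' @param p_month Monthly proportion(s) in \[0, 1\].  The degenerate value
#'   1 maps to a per-step probability of 1 with a warning.
#' @param month_length Days per month (default 30.4375).
#' @return Per-step (daily) probability vector.
#' @examples
#' monthly_to_per_step(0.139)  # ~0.00490 per day
#' @export
monthly_to_per_step <- function(p_month, month_length = 30.4375) {
  if (any(!is.finite(p_month)) || any(p_month < 0) || any(p_month > 1))
    stop("p_month must lie in [0, 1]")
  if (any(p_month == 1))
    warning("p_month = 1 is degenerate: per-step probability is 1")
  1 - (1 - p_month)^(1 / month_length)
}

#' Simulation clock
#'
#' Discrete daily steps from childbirth (day 0) to the horizon.  The
#' hospital stay covers days 0 to `hospital_days - 1`; barriers can only
#' fire after discharge.  Evaluation instants (point-prevalence readings)
#' fall at whole months.
#'
#' @param month_length Days per month (default 30.4375).
#' @param horizon_months Simulation horizon after childbirth (default 6).
#' @param eval_months Months at which prevalences are recorded
#'   (default 1, 3, 6).
#' @param hospital_days Length of the hospital stay in days (default 3:
#'   childbirth day plus the 1-2 day stay; postpartum life starts on the
#'   third day).
#' @return An object of class `bf_clock`.
#' @export
sim_clock <- function(month_length = 30.4375, horizon_months = 6,
                      eval_months = c(1, 3, 6), hospital_days = 3) {
  stopifnot(month_length > 0, horizon_months > 0,
            all(eval_months <= horizon_months))
  eval_days <- as.integer(round(eval_months * month_length))
  if (anyDuplicated(eval_days))
    stop("evaluation instants must map to distinct step indices")
  structure(list(month_length = month_length,
                 horizon_months = horizon_months,
                 horizon_days = as.integer(round(horizon_months * month_length)),
                 eval_months = eval_months,
                 eval_days = eval_days,
                 hospital_days = hospital_days),
            class = "bf_clock")
}

# event day for a barrier time in months; NA if absent or at/after horizon
barrier_day <- function(time_months, clock) {
  d <- ifelse(!is.na(time_months) & time_months < clock$horizon_months,
              pmax(1, ceiling(time_months * clock$month_length)), NA_real_)
  as.integer(d)
}

check_cohort <- function(cohort) {
  need <- cohort_columns()
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  core <- setdiff(need, c("lactation_problem_time", "return_to_work_time"))
  bad <- vapply(core, function(cc) anyNA(cohort[[cc]]), TRUE)
  if (any(bad))
    stop("cohort has missing values in: ", paste(core[bad], collapse = ", "))
  if (anyDuplicated(cohort$id)) stop("cohort ids must be unique")
  invisible(cohort)
}

#' Simulate a cohort through the perinatal and feeding-status state charts
#'
#' Advances every woman through pregnancy (intent draw), childbirth /
#' hospital stay (initiation draw, exclusive-vs-partial split) and the
#' postpartum period in daily steps.  Each postpartum day, scheduled
#' barrier events (lactation problem, return to work) are resolved first by
#' their decision trees, then the residual transition hazards are applied
#' to the current status by a single uniform draw against the cumulative
#' per-step probabilities.  Women who never initiate are formula-feeding
#' throughout.
#'
#' All randomness comes from an id-keyed stream: each woman's draws depend
#' only on `seed` and her `id`, so results are invariant to the order of
#' the cohort rows.
#'
#' @param cohort Cohort `data.frame` (validated; any missing required field
#'   rejects the run).
#' @param intent_model,initiation_model Calibrated behavior models.
#' @param rates A [transition_rates()] object.
#' @param p_exclusive_init Proportion of initiators who start exclusively.
#' @param clock A [sim_clock()].
#' @param network Optional [build_network()] object; only consulted when
#'   the intent model has a nonzero `peer_weight` (the intent draw is then
#'   a two-pass computation: provisional intents without the peer term,
#'   peer fractions, final intents reusing the same uniforms).
#' @param seed Integer seed for this run.
#' @param zero_support_steps,rtw_steps Decision-tree step-down depths (see
#'   [lactation_problem_decision()], [return_to_work_decision()]).
#' @param keep_trace Keep the full day-by-day status matrix (memory: n x
#'   horizon_days integers).
#' @return An object of class `bf_trajectories`: list with `intent`,
#'   `initiated`, `status` (integer matrix, one column per evaluation
#'   instant; 1 = exclusive, 2 = partial, 3 = formula), `eval_months`,
#'   `p_exclusive_init`, and optionally `trace`.
#' @export
run_cohort <- function(cohort, intent_model, initiation_model, rates,
                       p_exclusive_init, clock = sim_clock(), network = NULL,
                       seed = NULL, zero_support_steps = 2L, rtw_steps = 1L,
                       keep_trace = FALSE) {
  check_cohort(cohort)
  stopifnot(inherits(rates, "bf_rates"), inherits(clock, "bf_clock"),
            p_exclusive_init >= 0, p_exclusive_init <= 1)
  n <- nrow(cohort)
  D <- clock$horizon_days
  ndraw <- 3L + D

  # id-keyed uniforms: row r of the freshly drawn matrix belongs to the
  # r-th smallest id, then rows are mapped onto the cohort's row order
  if (!is.null(seed)) set.seed(seed)
  U <- matrix(stats::runif(n * ndraw), n, ndraw)
  pos <- match(cohort$id, sort(cohort$id))
  U <- U[pos, , drop = FALSE]

  lp_fix <- intent_model$intercept + intent_lp_fixed(intent_model, cohort)
  if (!is.null(network) && intent_model$peer_weight != 0) {
    intent0 <- U[, 1L] < stats::plogis(lp_fix)
    pif <- peer_intent_fractions(network, intent0)
    p_intent <- stats::plogis(lp_fix + intent_model$peer_weight * pif)
  } else {
    p_intent <- stats::plogis(lp_fix)
  }
  intent <- U[, 1L] < p_intent
  p_init <- initiation_probability(initiation_model, intent, cohort$bfhi)
  init <- U[, 2L] < p_init
  st <- ifelse(init, ifelse(U[, 3L] < p_exclusive_init, 1L, 2L), 3L)

  q_ef <- monthly_to_per_step(rates$excl_to_formula, clock$month_length)
  q_ep <- monthly_to_per_step(rates$excl_to_partial, clock$month_length)
  q_pf <- monthly_to_per_step(rates$partial_to_formula, clock$month_length)
  if (q_ef + q_ep > 1) stop("exclusive-state per-step hazards exceed 1")

  d_lact <- barrier_day(cohort$lactation_problem_time, clock)
  d_rtw <- barrier_day(cohort$return_to_work_time, clock)
  lact_by_day <- vector("list", D)
  rtw_by_day <- vector("list", D)
  il <- which(!is.na(d_lact))
  if (length(il)) {
    sp <- split(il, d_lact[il])
    lact_by_day[as.integer(names(sp))] <- sp
  }
  iw <- which(!is.na(d_rtw))
  if (length(iw)) {
    sp <- split(iw, d_rtw[iw])
    rtw_by_day[as.integer(names(sp))] <- sp
  }

  supports <- cohort$counseling + cohort$partner
  lact_steps <- ifelse(supports >= 2L, 0L,
                       ifelse(supports == 1L, 1L,
                              as.integer(zero_support_steps)))
  wp_steps <- ifelse(cohort$workplace >= 1L, 0L, as.integer(rtw_steps))

  eval_set <- clock$eval_days
  status <- matrix(NA_integer_, n, length(eval_set))
  trace <- if (keep_trace) matrix(NA_integer_, n, D) else NULL

  for (d in seq_len(D)) {
    # barriers resolve before the day's residual hazards
    e <- lact_by_day[[d]]
    if (!is.null(e)) {
      e <- e[st[e] <= 2L]
      if (length(e)) st[e] <- pmin(st[e] + lact_steps[e], 3L)
    }
    e <- rtw_by_day[[d]]
    if (!is.null(e)) {
      e <- e[st[e] <= 2L]
      if (length(e)) st[e] <- pmin(st[e] + wp_steps[e], 3L)
    }
    u <- U[, 3L + d]
    isE <- st == 1L
    isP <- st == 2L
    st[isP & u < q_pf] <- 3L
    st[isE & u < q_ef] <- 3L
    st[isE & u >= q_ef & u < q_ef + q_ep] <- 2L
    k <- match(d, eval_set)
    if (!is.na(k)) status[, k] <- st
    if (keep_trace) trace[, d] <- st
  }
  colnames(status) <- paste0("m", clock$eval_months)
  structure(list(intent = intent, initiated = init, status = status,
                 eval_months = clock$eval_months,
                 p_exclusive_init = p_exclusive_init, id = cohort$id,
                 trace = trace),
            class = "bf_trajectories")
}

#' Simulate a single woman
#'
#' Convenience wrapper around [run_cohort()] for a one-row cohort; the full
#' day-by-day trace is kept.
#'
#' @param woman One-row cohort `data.frame`.
#' @inheritParams run_cohort
#' @return A `bf_trajectories` object with `trace`.
#' @export
run_one_agent <- function(woman, intent_model, initiation_model, rates,
                          p_exclusive_init, clock = sim_clock(),
                          seed = NULL, ...) {
  stopifnot(nrow(woman) == 1L)
  run_cohort(woman, intent_model, initiation_model, rates, p_exclusive_init,
             clock = clock, seed = seed, keep_trace = TRUE, ...)
}

#' Summarize trajectories into outcome rates
#'
#' Point-prevalence outcome rates in percent: prenatal intent, initiation,
#' and any / exclusive breastfeeding at each evaluation instant ("any"
#' means exclusive-or-partial status at that instant).
#'
#' @param traj A `bf_trajectories` object from [run_cohort()].
#' @return Named numeric vector, e.g. `intent`, `initiation`, `any_1m`,
#'   `any_3m`, `any_6m`, `excl_1m`, `excl_3m`, `excl_6m`.
#' @export
summarize_trajectories <- function(traj) {
  stopifnot(inherits(traj, "bf_trajectories"))
  any_bf <- colMeans(traj$status <= 2L) * 100
  excl_bf <- colMeans(traj$status == 1L) * 100
  m <- traj$eval_months
  out <- c(mean(traj$intent) * 100, mean(traj$initiated) * 100,
           any_bf, excl_bf)
  names(out) <- c("intent", "initiation",
                  paste0("any_", m, "m"), paste0("excl_", m, "m"))
  out
}

#' Export trajectories to CSV
#'
#' One row per woman: id, intent and initiation flags, and the feeding
#' status at each evaluation instant.
#'
#' @param traj A `bf_trajectories` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "bf_trajectories"))
  df <- data.frame(id = traj$id, intent = as.integer(traj$intent),
                   initiated = as.integer(traj$initiated))
  for (k in seq_along(traj$eval_months)) {
    df[[paste0("status_", traj$eval_months[k], "m")]] <-
      BF_STATUS[traj$status[, k]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- deterministic expectation propagator -------------------------------
#
# The feeding-status process, conditional on a woman's covariates and
# barrier schedule, is a time-inhomogeneous 3-state Markov chain: constant
# residual hazards interrupted by at most two deterministic barrier maps.
# Expected population rates are therefore computable exactly by propagating
# each woman's state-occupancy probabilities, piecewise-analytically
# between events, and averaging.  Outcomes are linear in the
# exclusive-at-initiation share s: rate(s) = s * A + (1 - s) * B with A/B
# the rates for all-exclusive / all-partial starts.

#' Precompute the expectation-propagation structure for a cohort
#'
#' @inheritParams run_cohort
#' @return An object of class `bf_expectation_prep` holding per-woman
#'   initiation weights, barrier event days and decision-tree maps, used by
#'   [expected_rates()] and the calibration grid search.
#' @export
expectation_prep <- function(cohort, intent_model, initiation_model,
                             clock = sim_clock(), zero_support_steps = 2L,
                             rtw_steps = 1L) {
  check_cohort(cohort)
  lp_fix <- intent_model$intercept + intent_lp_fixed(intent_model, cohort)
  p_intent <- stats::plogis(lp_fix)
  bb <- initiation_model$beta_bfhi * cohort$bfhi
  p_init <- p_intent *
    stats::plogis(initiation_model$intercept + initiation_model$beta_intent + bb) +
    (1 - p_intent) * stats::plogis(initiation_model$intercept + bb)

  supports <- cohort$counseling + cohort$partner
  lact_steps <- ifelse(supports >= 2L, 0L,
                       ifelse(supports == 1L, 1L,
                              as.integer(zero_support_steps)))
  wp_steps <- ifelse(cohort$workplace >= 1L, 0L, as.integer(rtw_steps))

  dl <- barrier_day(cohort$lactation_problem_time, clock)
  dw <- barrier_day(cohort$return_to_work_time, clock)
  dl_f <- ifelse(is.na(dl), Inf, as.numeric(dl))
  dw_f <- ifelse(is.na(dw), Inf, as.numeric(dw))
  # two ordered event slots per woman; lactation resolves first on ties
  first_is_lact <- dl_f <= dw_f
  d1 <- ifelse(first_is_lact, dl_f, dw_f)
  d2 <- ifelse(first_is_lact, dw_f, dl_f)
  s1 <- ifelse(first_is_lact, lact_steps, wp_steps)
  s2 <- ifelse(first_is_lact, wp_steps, lact_steps)
  s1[!is.finite(d1)] <- 0L
  s2[!is.finite(d2)] <- 0L

  structure(list(w = p_init, p_intent = p_intent, d1 = d1, d2 = d2,
                 s1 = s1, s2 = s2, clock = clock, n = nrow(cohort)),
            class = "bf_expectation_prep")
}

# advance (E, P) occupancy masses by L residual-hazard days (L vectorized)
propagate_interval <- function(E, P, L, x, y, r) {
  xl <- x^L
  yl <- y^L
  geo <- if (abs(x - y) > 1e-12) (xl - yl) / (x - y) else L * x^pmax(L - 1, 0)
  list(E = E * xl, P = P * yl + E * r * geo)
}

# apply a barrier map with per-woman step depths to occupancy masses
apply_map <- function(E, P, steps) {
  list(E = ifelse(steps == 0L, E, 0),
       P = ifelse(steps == 0L, P, ifelse(steps == 1L, E, 0)))
}

# expected any/exclusive rates (%) at the clock's evaluation instants for
# the two pure starting states; returns list(A, B) of named vectors
expected_components <- function(prep, rates) {
  clock <- prep$clock
  q_ef <- monthly_to_per_step(rates$excl_to_formula, clock$month_length)
  q_ep <- monthly_to_per_step(rates$excl_to_partial, clock$month_length)
  q_pf <- monthly_to_per_step(rates$partial_to_formula, clock$month_length)
  x <- 1 - q_ef - q_ep
  y <- 1 - q_pf
  one_start <- function(E0, P0) {
    out <- matrix(NA_real_, 2, length(clock$eval_days))
    for (k in seq_along(clock$eval_days)) {
      T <- clock$eval_days[k]
      t1 <- pmin(prep$d1 - 1, T)
      st <- propagate_interval(E0, P0, t1, x, y, q_ep)
      s1 <- ifelse(prep$d1 <= T, prep$s1, 0L)
      st <- apply_map(st$E, st$P, s1)
      cut2 <- pmin(prep$d2 - 1, T)
      st <- propagate_interval(st$E, st$P, cut2 - t1, x, y, q_ep)
      s2 <- ifelse(prep$d2 <= T, prep$s2, 0L)
      st <- apply_map(st$E, st$P, s2)
      st <- propagate_interval(st$E, st$P, T - cut2, x, y, q_ep)
      out[1, k] <- mean(st$E + st$P) * 100
      out[2, k] <- mean(st$E) * 100
    }
    stats::setNames(c(out[1, ], out[2, ]),
                    c(paste0("any_", clock$eval_months, "m"),
                      paste0("excl_", clock$eval_months, "m")))
  }
  list(A = one_start(prep$w, 0 * prep$w),
       B = one_start(0 * prep$w, prep$w))
}

#' Exact expected outcome rates
#'
#' Noise-free population expectations of the outcome rates under the
#' current models, residual rates and exclusive-at-initiation share,
#' computed by per-woman state-probability propagation (see the methods
#' vignette).  Useful as an analytic cross-check of the stochastic engine
#' and as the objective of the calibration grid search.
#'
#' @param cohort Cohort `data.frame` (or a precomputed
#'   [expectation_prep()] object).
#' @inheritParams run_cohort
#' @return Named numeric vector matching [summarize_trajectories()].
#' @export
expected_rates <- function(cohort, intent_model, initiation_model, rates,
                           p_exclusive_init, clock = sim_clock(),
                           zero_support_steps = 2L, rtw_steps = 1L) {
  prep <- if (inherits(cohort, "bf_expectation_prep")) cohort else
    expectation_prep(cohort, intent_model, initiation_model, clock,
                     zero_support_steps, rtw_steps)
  comp <- expected_components(prep, rates)
  s <- p_exclusive_init
  c(intent = mean(prep$p_intent) * 100,
    initiation = mean(prep$w) * 100,
    s * comp$A + (1 - s) * comp$B)
}
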