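#' Feeding-status levels
#'
#' Postpartum feeding statuses, ordered from highest to lowest level of
#' breastfeeding: `EXCLUSIVE` > `PARTIAL` > `FORMULA`.  Transitions after
#' initiation only ever step *down* this ordering (path dependence:
#' breastfeeding cannot resume once interrupted); `FORMULA` is absorbing.
#' `NOT_STARTED` exists only before childbirth.
#'
#' @export
BF_STATUS <- c("EXCLUSIVE", "PARTIAL", "FORMULA")

#' Step a feeding status down one or more levels
#'
#' @param status Character vector of statuses in [BF_STATUS].
#' @param steps Integer number of levels to drop (capped at `FORMULA`).
#' @return Character vector of stepped-down statuses.
#' @export
bf_step_down <- function(status, steps = 1L) {
  i <- match(status, BF_STATUS)
  if (anyNA(i)) stop("unknown feeding status")
  BF_STATUS[pmin(i + as.integer(steps), 3L)]
}

#' Prenatal intent model
#'
#' Logistic model for a woman's intent to breastfeed, formed during
#' pregnancy: `logit P = intercept + beta_knowledge * knowledge +
#' sociodemographic terms + peer_weight * peer_intent_fraction`.  The
#' sociodemographic coefficients default to zero (no estimates exist for
#' this population); heterogeneity enters through the knowledge score and,
#' optionally, the peer network.
#'
#' @param intercept Log-odds intercept (typically set by
#'   [calibrate_intercepts()]).
#' @param beta_knowledge Log-odds per unit knowledge score (default 1.17).
#' @param sociodem_betas Named vector of log-odds coefficients for
#'   `age` (per year, centred at 28.1), `less_than_hs`, `hispanic`,
#'   `low_income` indicators.
#' @param peer_weight Log-odds per unit fraction of peers intending to
#'   breastfeed (default 0: the network is inert).
#' @return An object of class `bf_intent_model`.
#' @export
intent_model <- function(intercept = 0, beta_knowledge = 1.17,
                         sociodem_betas = c(age = 0, less_than_hs = 0,
                                            hispanic = 0, low_income = 0),
                         peer_weight = 0) {
  stopifnot(is.finite(intercept), is.finite(beta_knowledge),
            all(is.finite(sociodem_betas)), is.finite(peer_weight))
  full <- c(age = 0, less_than_hs = 0, hispanic = 0, low_income = 0)
  full[names(sociodem_betas)] <- sociodem_betas
  structure(list(intercept = intercept, beta_knowledge = beta_knowledge,
                 sociodem_betas = full, peer_weight = peer_weight),
            class = "bf_intent_model")
}

# non-intercept, non-peer part of the intent linear predictor
intent_lp_fixed <- function(model, cohort) {
  b <- model$sociodem_betas
  model$beta_knowledge * cohort$knowledge +
    b[["age"]] * (cohort$age - 28.1) +
    b[["less_than_hs"]] * (cohort$education == "less_than_hs") +
    b[["hispanic"]] * (cohort$ethnicity == "hispanic") +
    b[["low_income"]] * (cohort$income == "le_100_fpl")
}

#' Probability of prenatal intent to breastfeed
#'
#' @param model A [intent_model()].
#' @param cohort Cohort `data.frame` (uses `knowledge` and the
#'   sociodemographic columns).
#' @param peer_intent_fraction Per-woman fraction of network peers who
#'   intend to breastfeed, in \[0, 1\] (recycled; default 0).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
intent_probability <- function(model, cohort, peer_intent_fraction = 0) {
  stopifnot(inherits(model, "bf_intent_model"))
  if (any(cohort$knowledge < 0 | cohort$knowledge > 1))
    stop("knowledge scores must lie in [0, 1]")
  if (any(peer_intent_fraction < 0 | peer_intent_fraction > 1))
    stop("peer_intent_fraction must lie in [0, 1]")
  stats::plogis(model$intercept + intent_lp_fixed(model, cohort) +
                  model$peer_weight * peer_intent_fraction)
}

#' Breastfeeding-initiation model
#'
#' Logistic model for initiating breastfeeding during the hospital stay:
#' `logit P = intercept + beta_intent * intent + beta_bfhi * bfhi`.
#' Intent raises but does not determine initiation (women without intent
#' may still initiate, and vice versa).
#'
#' @param intercept Log-odds intercept (typically set by
#'   [calibrate_intercepts()]).
#' @param beta_intent Log-odds for prenatal intent (default 2.0; not
#'   identifiable from marginal rates, exposed as configuration).
#' @param beta_bfhi Log-odds for delivery at a Baby-Friendly facility
#'   (default 0.155).
#' @return An object of class `bf_initiation_model`.
#' @export
initiation_model <- function(intercept = 0, beta_intent = 2.0,
                             beta_bfhi = 0.155) {
  stopifnot(is.finite(intercept), is.finite(beta_intent), is.finite(beta_bfhi))
  structure(list(intercept = intercept, beta_intent = beta_intent,
                 beta_bfhi = beta_bfhi),
            class = "bf_initiation_model")
}

#' Probability of initiating breastfeeding
#'
#' @param model A [initiation_model()].
#' @param intent Logical/0-1 vector: prenatal intent.
#' @param bfhi Logical/0-1 vector: birth at a Baby-Friendly facility.
#' @return Numeric vector of probabilities.
#' @export
initiation_probability <- function(model, intent, bfhi) {
  stopifnot(inherits(model, "bf_initiation_model"))
  stats::plogis(model$intercept + model$beta_intent * as.numeric(intent) +
                  model$beta_bfhi * as.numeric(bfhi))
}

#' Decision tree: lactation problem
#'
#' Resolves a lactation-problem event for a breastfeeding woman based on
#' her support: with support from both a lactation consultant and her
#' partner she continues as she was; with exactly one source of support she
#' steps down one level (exclusive to partial, partial to formula); with no
#' support she steps down `zero_support_steps` levels (default 2, i.e.
#' straight to formula).  Women already on formula (or not yet started) are
#' unaffected; calling the tree on them is a no-op with a warning.
#'
#' @param status Feeding status vector (see [BF_STATUS]).
#' @param counseling,partner Logical/0-1 support flags (recycled).
#' @param zero_support_steps Levels dropped with no support (default 2).
#' @return Updated status vector.
#' @examples
#' lactation_problem_decision("EXCLUSIVE", 1, 1)  # unchanged
#' lactation_problem_decision("PARTIAL", 1, 0)    # "FORMULA"
#' @export
lactation_problem_decision <- function(status, counseling, partner,
                                       zero_support_steps = 2L) {
  m <- max(length(status), length(counseling), length(partner))
  status <- rep_len(status, m)
  counseling <- rep_len(as.integer(counseling), m)
  partner <- rep_len(as.integer(partner), m)
  eligible <- status %in% c("EXCLUSIVE", "PARTIAL")
  if (!all(eligible))
    warning("lactation_problem_decision called on non-breastfeeding ",
            "status; no-op for those entries")
  supports <- counseling + partner
  steps <- ifelse(supports >= 2L, 0L,
                  ifelse(supports == 1L, 1L, as.integer(zero_support_steps)))
  out <- status
  out[eligible] <- bf_step_down(status[eligible], steps[eligible])
  out
}

#' Decision tree: return to work
#'
#' Resolves a return-to-work event: a supportive workplace (break time and
#' private space for pumping) lets the woman continue as she was; an
#' unsupportive one steps her feeding status down `steps` levels
#' (default 1).  Non-breastfeeding statuses are unaffected (no-op with a
#' warning).
#'
#' @param status Feeding status vector (see [BF_STATUS]).
#' @param workplace_support Logical/0-1 flag (recycled).
#' @param steps Levels dropped without support (default 1).
#' @return Updated status vector.
#' @export
return_to_work_decision <- function(status, workplace_support, steps = 1L) {
  m <- max(length(status), length(workplace_support))
  status <- rep_len(status, m)
  workplace_support <- rep_len(as.integer(workplace_support), m)
  eligible <- status %in% c("EXCLUSIVE", "PARTIAL")
  if (!all(eligible))
    warning("return_to_work_decision called on non-breastfeeding status; ",
            "no-op for those entries")
  steps <- ifelse(workplace_support >= 1L, 0L, as.integer(steps))
  out <- status
  out[eligible] <- bf_step_down(status[eligible], steps[eligible])
  out
}

#' Calibrate the intent and initiation intercepts
#'
#' One-dimensional root-finds on each logistic intercept so that the
#' cohort-expected prevalence of prenatal intent and the cohort-expected
#' initiation rate match their targets.  Expectations are exact (no
#' simulation): the intent expectation averages the per-woman logistic
#' probabilities; the initiation expectation marginalizes over the intent
#' draw.  When the intent model has a nonzero peer weight the peer-intent
#' fraction is taken at the target prevalence (self-consistent field).
#'
#' @param cohort Cohort `data.frame`.
#' @param targets List with elements `intent` and `initiation`
#'   (proportions).
#' @param intent_model,initiation_model Model templates whose intercepts
#'   are replaced.
#' @param tol Root-finding tolerance on the intercepts.
#' @return List with the two calibrated models and `achieved`, the exact
#'   expected rates at the calibrated intercepts.
#' @export
calibrate_intercepts <- function(cohort,
                                 targets = list(intent = 0.885,
                                                initiation = 0.9296),
                                 intent_model = bfabm::intent_model(),
                                 initiation_model = bfabm::initiation_model(),
                                 tol = 1e-10) {
  stopifnot(targets$intent > 0, targets$intent < 1,
            targets$initiation > 0, targets$initiation < 1)
  lp_fix <- intent_lp_fixed(intent_model, cohort) +
    intent_model$peer_weight * targets$intent
  f_int <- function(a) mean(stats::plogis(a + lp_fix)) - targets$intent
  a <- tryCatch(
    stats::uniroot(f_int, c(-30, 30), tol = tol)$root,
    error = function(e) stop(sprintf(
      "intent target %.4f unreachable within intercept bracket [-30, 30]; ",
      targets$intent), "achievable range: [",
      sprintf("%.4f, %.4f", mean(stats::plogis(-30 + lp_fix)),
              mean(stats::plogis(30 + lp_fix))), "]", call. = FALSE))
  intent_model$intercept <- a
  p_int <- stats::plogis(a + lp_fix)

  bi <- initiation_model$beta_intent
  bb <- initiation_model$beta_bfhi * cohort$bfhi
  f_ini <- function(b)
    mean(p_int * stats::plogis(b + bi + bb) +
           (1 - p_int) * stats::plogis(b + bb)) - targets$initiation
  b <- tryCatch(
    stats::uniroot(f_ini, c(-30, 30), tol = tol)$root,
    error = function(e) stop(sprintf(
      "initiation target %.4f unreachable within intercept bracket [-30, 30]",
      targets$initiation), call. = FALSE))
  initiation_model$intercept <- b

  list(intent_model = intent_model,
       initiation_model = initiation_model,
       achieved = c(intent = f_int(a) + targets$intent,
                    initiation = f_ini(b) + targets$initiation))
}
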