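#' Default parameter registry
#'
#' Returns the full set of default model parameters, grouped by module.  The
#' population block holds the marginal distributions used to synthesize
#' cohorts of primiparous WIC participants: sociodemographics (age,
#' education, race/ethnicity, household income), baseline coverage of the
#' five intervention exposures, the Beta-distributed breastfeeding-knowledge
#' score, and the occurrence of the two barriers to breastfeeding
#' maintenance (lactation problems, return to work).  All values are
#' editable; the defaults describe the 2014 Los Angeles County WIC
#' primiparous population.
#'
#' @return A nested list with components `population`, `behavior`,
#'   `network` and `engine`.
#' @examples
#' p <- default_parameters()
#' p$population$cov_bfhi
#' @export
default_parameters <- function() {
  list(
    population = list(
      age_mean = 28.1,
      age_sd = 6.4,
      age_range = c(15, 50),
      p_less_than_hs = 0.365,
      p_hispanic = 0.850,
      p_low_income = 0.484,            # <= 100% federal poverty level
      knowledge_mean = 0.67,
      knowledge_sd = 0.10,
      cov_bfhi = 0.114,
      cov_counseling = 0.7812,
      cov_partner = 0.6774,
      cov_workplace = 0.5205,
      p_lactation_problem = 0.874,     # cumulative incidence, 0-6 months
      # onset of lactation problems, months postpartum: uniform on
      # (hospital discharge, horizon]
      lactation_window = c(3 / 30.4375, 6),
      # return-to-work category probabilities (months postpartum)
      rtw_probs = c(m0_2 = 0.091, m3_5 = 0.144, m6_plus = 0.130,
                    not_employed = 0.635)
    ),
    behavior = list(
      beta_knowledge = 1.17,           # log-odds per unit knowledge, intent
      beta_bfhi = 0.155,               # log-odds for baby-friendly birth
      beta_intent = 2.0,               # log-odds for prenatal intent
      zero_support_steps = 2L,         # lactation tree, no support
      rtw_steps = 1L                   # return-to-work tree, no support
    ),
    network = list(
      mean_degree = 8,
      homophily = 0.9,
      peer_weight = 0
    ),
    engine = list(
      month_length = 30.4375,
      horizon_months = 6,
      hospital_days = 3
    )
  )
}

#' Beta shape parameters from mean and standard deviation
#'
#' Method-of-moments inversion: for a Beta distribution on \[0, 1\] with the
#' requested mean m and standard deviation s, the shapes are
#' `alpha = m * nu` and `beta = (1 - m) * nu` with
#' `nu = m (1 - m) / s^2 - 1`.  Feasibility requires `s^2 < m (1 - m)`.
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param sd Target standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_shape_from_moments(0.67, 0.10)
#' @export
beta_shape_from_moments <- function(mean, sd) {
  stopifnot(length(mean) == 1L, length(sd) == 1L,
            is.finite(mean), is.finite(sd))
  if (mean <= 0 || mean >= 1)
    stop("`mean` must lie strictly inside (0, 1)")
  v <- sd^2
  bound <- mean * (1 - mean)
  if (v <= 0 || v >= bound)
    stop(sprintf(
      "infeasible (mean, sd) pair: need 0 < sd^2 < mean*(1-mean) = %.6g", bound))
  nu <- bound / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

# columns every cohort must carry; *_time columns may contain NA (absent)
cohort_columns <- function() {
  c("id", "age", "education", "ethnicity", "income", "knowledge",
    "bfhi", "counseling", "partner", "workplace",
    "lactation_problem_time", "return_to_work_time")
}

sociodem_columns <- function() c("age", "education", "ethnicity", "income")

#' Sample a synthetic cohort of primiparous women
#'
#' Draws `n` independent agent records from the marginal distributions in
#' the parameter registry.  Age is truncated-normal on `age_range`;
#' education, race/ethnicity, income and the four binary intervention
#' exposures are independent Bernoulli draws; the knowledge score is Beta
#' with the registry mean/SD; the lactation-problem indicator is Bernoulli
#' with onset drawn uniformly on `lactation_window` (months); the
#' return-to-work time is drawn uniformly within its sampled category
#' (categories at or beyond the horizon are recorded but never fire).
#'
#' Marginals are independent by default (no joint distribution is available
#' for this population); see `vignette("bfabm-methods")`.
#'
#' @param n Number of women (>= 1).
#' @param params Population parameter block, see [default_parameters()].
#' @param seed Optional integer seed; fixing it makes the cohort fully
#'   reproducible.
#' @return A `data.frame` with one row per woman and the columns documented
#'   in [read_cohort_csv()].
#' @examples
#' head(sample_cohort(5, seed = 1))
#' @export
sample_cohort <- function(n, params = default_parameters()$population,
                          seed = NULL) {
  stopifnot(length(n) == 1L, n >= 1)
  n <- as.integer(n)
  probs <- c(params$p_less_than_hs, params$p_hispanic, params$p_low_income,
             params$cov_bfhi, params$cov_counseling, params$cov_partner,
             params$cov_workplace, params$p_lactation_problem)
  if (any(probs < 0 | probs > 1))
    stop("all marginal probabilities must lie in [0, 1]")
  rtw <- params$rtw_probs
  if (length(rtw) != 4L || any(rtw < 0) || abs(sum(rtw) - 1) > 1e-8)
    stop("return-to-work category probabilities must be 4 values summing to 1")
  if (!is.null(seed)) set.seed(seed)

  sh <- beta_shape_from_moments(params$knowledge_mean, params$knowledge_sd)
  # exact truncated normal via inverse-cdf on a truncated uniform
  lo <- stats::pnorm(params$age_range[1], params$age_mean, params$age_sd)
  hi <- stats::pnorm(params$age_range[2], params$age_mean, params$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), params$age_mean, params$age_sd)

  education <- ifelse(stats::runif(n) < params$p_less_than_hs,
                      "less_than_hs", "hs_or_above")
  ethnicity <- ifelse(stats::runif(n) < params$p_hispanic,
                      "hispanic", "non_hispanic")
  income <- ifelse(stats::runif(n) < params$p_low_income,
                   "le_100_fpl", "gt_100_fpl")
  knowledge <- stats::rbeta(n, sh[["alpha"]], sh[["beta"]])
  bfhi       <- as.integer(stats::runif(n) < params$cov_bfhi)
  counseling <- as.integer(stats::runif(n) < params$cov_counseling)
  partner    <- as.integer(stats::runif(n) < params$cov_partner)
  workplace  <- as.integer(stats::runif(n) < params$cov_workplace)

  has_lact <- stats::runif(n) < params$p_lactation_problem
  lact_draw <- stats::runif(n, params$lactation_window[1],
                            params$lactation_window[2])
  lactation_problem_time <- ifelse(has_lact, lact_draw, NA_real_)

  u <- stats::runif(n)
  cat_idx <- findInterval(u, cumsum(rtw)) + 1L   # 1..4
  rtw_draw_early <- stats::runif(n, 0, 2)
  rtw_draw_mid   <- stats::runif(n, 3, 5)
  rtw_draw_late  <- stats::runif(n, 6, 12)
  return_to_work_time <- rep(NA_real_, n)
  return_to_work_time[cat_idx == 1L] <- rtw_draw_early[cat_idx == 1L]
  return_to_work_time[cat_idx == 2L] <- rtw_draw_mid[cat_idx == 2L]
  return_to_work_time[cat_idx == 3L] <- rtw_draw_late[cat_idx == 3L]

  data.frame(
    id = seq_len(n), age = age, education = education, ethnicity = ethnicity,
    income = income, knowledge = knowledge, bfhi = bfhi,
    counseling = counseling, partner = partner, workplace = workplace,
    lactation_problem_time = lactation_problem_time,
    return_to_work_time = return_to_work_time,
    stringsAsFactors = FALSE
  )
}

#' Read / write a cohort CSV
#'
#' The on-disk format has one row per woman with columns `id`, `age`,
#' `education` (`less_than_hs` / `hs_or_above`), `ethnicity` (`hispanic` /
#' `non_hispanic`), `income` (`le_100_fpl` / `gt_100_fpl`), `knowledge`
#' (score in \[0, 1\]), the four 0/1 exposure flags `bfhi`, `counseling`,
#' `partner`, `workplace`, and the barrier times in months
#' `lactation_problem_time`, `return_to_work_time` (empty = absent).
#' Unknown extra columns are accepted and ignored.  Rows with a missing
#' value in any of the four sociodemographic fields are dropped with a
#' warning, mirroring the exclusion of incomplete survey records.
#' Numeric fields are written with full precision so that a write/read
#' round trip reproduces the cohort exactly.
#'
#' @param path File path.
#' @param cohort A cohort `data.frame` as produced by [sample_cohort()].
#' @return `read_cohort_csv()` returns the cohort `data.frame`;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- cohort_columns()
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[required]
  for (cc in c("age", "knowledge", "lactation_problem_time",
               "return_to_work_time"))
    raw[[cc]] <- as.numeric(raw[[cc]])
  for (cc in c("id", "bfhi", "counseling", "partner", "workplace"))
    raw[[cc]] <- as.integer(raw[[cc]])
  chr <- c("education", "ethnicity", "income")
  for (cc in chr) {
    raw[[cc]] <- as.character(raw[[cc]])
    raw[[cc]][!is.na(raw[[cc]]) & raw[[cc]] == ""] <- NA
  }
  bad <- Reduce(`|`, lapply(sociodem_columns(), function(cc) is.na(raw[[cc]])))
  if (any(bad)) {
    warning(sprintf(
      "dropped %d row(s) with missing sociodemographic field(s)", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
  }
  rownames(raw) <- NULL
  raw
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- cohort[cohort_columns()]
  fmt <- function(x) {
    if (is.double(x)) {
      s <- vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v), "")
      s
    } else x
  }
  out[] <- lapply(out, fmt)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
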