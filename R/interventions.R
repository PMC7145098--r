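#' Intervention scenario
#'
#' A fully specified experiment condition for the five intervention levers:
#' the knowledge lever is a shift of the Beta knowledge-score mean (its
#' "levels" are score means, not coverages); the other four levers are
#' population coverages.  A scenario never lowers a lever below its
#' baseline value — interventions only add coverage.
#'
#' @param name Scenario label.
#' @param knowledge_mean,knowledge_sd Beta parameters of the knowledge
#'   score (baseline 0.67 / 0.10).
#' @param cov_bfhi,cov_counseling,cov_partner,cov_workplace Target
#'   coverages of the four binary levers.
#' @param beta_knowledge,beta_bfhi Effect coefficients (overriding these
#'   triggers intercept re-calibration in [run_scenario()]).
#' @param replicates Default replicate count for [run_scenario()].
#' @param base_seed Optional default seed.
#' @param base Population block the baseline levers are read from.
#' @return An object of class `bf_scenario`.
#' @export
scenario <- function(name = "scenario",
                     knowledge_mean = NULL, knowledge_sd = NULL,
                     cov_bfhi = NULL, cov_counseling = NULL,
                     cov_partner = NULL, cov_workplace = NULL,
                     beta_knowledge = NULL, beta_bfhi = NULL,
                     replicates = 100L, base_seed = NULL,
                     base = default_parameters()$population) {
  pick <- function(x, b) if (is.null(x)) b else x
  s <- list(
    name = name,
    knowledge_mean = pick(knowledge_mean, base$knowledge_mean),
    knowledge_sd = pick(knowledge_sd, base$knowledge_sd),
    cov_bfhi = pick(cov_bfhi, base$cov_bfhi),
    cov_counseling = pick(cov_counseling, base$cov_counseling),
    cov_partner = pick(cov_partner, base$cov_partner),
    cov_workplace = pick(cov_workplace, base$cov_workplace),
    beta_knowledge = beta_knowledge,   # NULL = model default
    beta_bfhi = beta_bfhi,
    replicates = as.integer(replicates),
    base_seed = base_seed,
    base = base[c("knowledge_mean", "knowledge_sd", "cov_bfhi",
                  "cov_counseling", "cov_partner", "cov_workplace")]
  )
  covs <- c(s$cov_bfhi, s$cov_counseling, s$cov_partner, s$cov_workplace)
  if (any(covs < 0 | covs > 1)) stop("coverages must lie in [0, 1]")
  if (s$knowledge_mean <= 0 || s$knowledge_mean >= 1)
    stop("knowledge_mean must lie strictly inside (0, 1)")
  low <- c(bfhi = s$cov_bfhi < base$cov_bfhi - 1e-9,
           counseling = s$cov_counseling < base$cov_counseling - 1e-9,
           partner = s$cov_partner < base$cov_partner - 1e-9,
           workplace = s$cov_workplace < base$cov_workplace - 1e-9)
  if (any(low))
    stop("a scenario may not lower a lever below its baseline coverage: ",
         paste(names(low)[low], collapse = ", "))
  structure(s, class = "bf_scenario")
}

#' Apply a scenario to a cohort
#'
#' Knowledge scores are re-drawn from the scenario's Beta distribution when
#' its mean or SD differs from baseline (the SD is clipped to the Beta
#' feasibility bound if necessary).  Binary exposures are "topped up":
#' currently unexposed women flip to exposed with probability
#' `(target - base) / (1 - base)`, so already-exposed women are preserved
#' and the realized coverage converges to the target.  A target below the
#' cohort's baseline coverage is a contract violation.
#'
#' @param cohort Cohort `data.frame` generated at baseline coverages.
#' @param scen A [scenario()].
#' @param seed Optional integer seed for the upgrade draws.
#' @return The modified cohort.
#' @export
apply_scenario <- function(cohort, scen, seed = NULL) {
  stopifnot(inherits(scen, "bf_scenario"))
  if (!is.null(seed)) set.seed(seed)
  base <- scen$base
  out <- cohort
  if (scen$knowledge_mean != base$knowledge_mean ||
      scen$knowledge_sd != base$knowledge_sd) {
    m <- scen$knowledge_mean
    sd_max <- sqrt(m * (1 - m))
    sd_eff <- min(scen$knowledge_sd, 0.99 * sd_max)
    sh <- beta_shape_from_moments(m, sd_eff)
    out$knowledge <- stats::rbeta(nrow(out), sh[["alpha"]], sh[["beta"]])
  }
  top_up <- function(flag, target, b, lever) {
    if (target < b - 1e-9)
      stop("scenario coverage for ", lever,
           " is below the baseline coverage (contract violation)")
    if (target <= b + 1e-12) return(flag)
    p_flip <- (target - b) / (1 - b)
    flip <- stats::runif(length(flag)) < p_flip
    as.integer(flag | flip)
  }
  out$bfhi <- top_up(out$bfhi, scen$cov_bfhi, base$cov_bfhi, "bfhi")
  out$counseling <- top_up(out$counseling, scen$cov_counseling,
                           base$cov_counseling, "counseling")
  out$partner <- top_up(out$partner, scen$cov_partner, base$cov_partner,
                        "partner")
  out$workplace <- top_up(out$workplace, scen$cov_workplace,
                          base$cov_workplace, "workplace")
  out
}

# the five levers and their level values; KNWL levels are score means
lever_codes <- function() c("KNWL", "BFHI", "COUL", "PTR", "WP")

#' Build a single-lever or package scenario at a given level
#'
#' @param levers Character subset of `KNWL`, `BFHI`, `COUL`, `PTR`, `WP`.
#' @param level Intervention level: for coverage levers the target coverage
#'   (0.80 / 0.90 / 0.95); for `KNWL` the knowledge-score mean at the same
#'   numeric value.
#' @param name Optional label.
#' @param base Baseline population block.
#' @return A [scenario()].
#' @export
package_scenario <- function(levers, level,
                             name = paste0(paste(levers, collapse = "+"),
                                           "@", level),
                             base = default_parameters()$population) {
  levers <- match.arg(levers, lever_codes(), several.ok = TRUE)
  scenario(
    name = name,
    knowledge_mean = if ("KNWL" %in% levers) level else NULL,
    cov_bfhi = if ("BFHI" %in% levers) level else NULL,
    cov_counseling = if ("COUL" %in% levers) level else NULL,
    cov_partner = if ("PTR" %in% levers) level else NULL,
    cov_workplace = if ("WP" %in% levers) level else NULL,
    base = base)
}

#' The standard experiment grid
#'
#' The full set of scenarios of the headline coverage experiments: one
#' shared baseline, the 15 single-lever scenarios (5 levers at levels
#' 0.80 / 0.90 / 0.95) and the 15 nested-package scenarios
#' (KNWL, +BFHI, +COUL, +PTR, +WP at the same three levels).
#'
#' @param base Baseline population block.
#' @return Named list of 31 [scenario()] objects; the attribute `"kind"`
#'   on each element is `"base"`, `"single"` or `"package"`.
#' @export
scenario_grid_standard <- function(base = default_parameters()$population) {
  levels <- c(0.80, 0.90, 0.95)
  out <- list(base = scenario(name = "base", base = base))
  attr(out$base, "kind") <- "base"
  for (lv in lever_codes()) {
    for (l in levels) {
      nm <- sprintf("%s_%0.2f", lv, l)
      out[[nm]] <- package_scenario(lv, l, name = nm, base = base)
      attr(out[[nm]], "kind") <- "single"
    }
  }
  packages <- lapply(seq_along(lever_codes()),
                     function(k) lever_codes()[seq_len(k)])
  for (pk in packages) {
    for (l in levels) {
      nm <- sprintf("PKG_%s_%0.2f", paste(pk, collapse = "+"), l)
      out[[nm]] <- package_scenario(pk, l, name = nm, base = base)
      attr(out[[nm]], "kind") <- "package"
    }
  }
  out
}
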