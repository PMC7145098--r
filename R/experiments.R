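#' Run a scenario over replicates
#'
#' Runs `replicates` independent simulations of a scenario: each replicate
#' draws a fresh cohort at baseline marginals (or reuses the model's
#' reference cohort when `resample_cohort = FALSE`), applies the scenario's
#' coverage top-ups and knowledge shift, and simulates it through the state
#' charts.  Outcomes are the replicate means of the eight rates with
#' Monte-Carlo standard errors.  Replicate seeds are derived
#' deterministically from `seed`, so two scenarios run with the same `seed`
#' share cohorts and downstream uniforms (common random numbers); pass
#' different seeds per scenario for fully independent runs.
#'
#' If the scenario overrides `beta_knowledge` or `beta_bfhi`, the logistic
#' intercepts are first re-calibrated on the model's reference cohort so
#' the baseline intent/initiation rates are preserved (see the methods
#' vignette).
#'
#' @param model A calibrated [calibrate_baseline()] object.
#' @param scen A [scenario()].
#' @param n Cohort size per replicate (default: the model's reference
#'   size).
#' @param replicates Number of replicates (default: the scenario's).
#' @param seed Integer base seed.
#' @param resample_cohort Draw a fresh cohort per replicate (default TRUE).
#' @param use_network Build the peer network each replicate (only relevant
#'   when the intent model's `peer_weight` is nonzero).
#' @return An object of class `bf_outcome_summary`: list with `mean`, `se`
#'   (named 8-vectors, percent), `outcomes` (replicates x 8 matrix),
#'   `scenario`, `n`, `replicates`.
#' @export
run_scenario <- function(model, scen = scenario(), n = model$n,
                         replicates = scen$replicates, seed = 1L,
                         resample_cohort = TRUE, use_network = FALSE) {
  stopifnot(inherits(model, "bf_model"), inherits(scen, "bf_scenario"),
            replicates >= 1)
  im <- model$intent_model
  nm <- model$initiation_model
  if (!is.null(scen$beta_knowledge) &&
      scen$beta_knowledge != im$beta_knowledge)
    im$beta_knowledge <- scen$beta_knowledge
  if (!is.null(scen$beta_bfhi) && scen$beta_bfhi != nm$beta_bfhi)
    nm$beta_bfhi <- scen$beta_bfhi
  if (im$beta_knowledge != model$intent_model$beta_knowledge ||
      nm$beta_bfhi != model$initiation_model$beta_bfhi) {
    ic <- calibrate_intercepts(
      model$ref_cohort,
      targets = list(intent = model$targets$intent,
                     initiation = model$targets$initiation),
      intent_model = im, initiation_model = nm)
    im <- ic$intent_model
    nm <- ic$initiation_model
  }
  pb <- model$params$behavior
  out <- matrix(NA_real_, replicates, 8)
  for (r in seq_len(replicates)) {
    coh <- if (resample_cohort)
      sample_cohort(n, model$params$population, seed = mix_seed(seed, r, 1))
    else model$ref_cohort
    coh <- apply_scenario(coh, scen, seed = mix_seed(seed, r, 2))
    net <- if (use_network || im$peer_weight != 0)
      build_network(coh, model$params$network$mean_degree,
                    model$params$network$homophily,
                    seed = mix_seed(seed, r, 3))
    else NULL
    traj <- run_cohort(coh, im, nm, model$rates, model$p_exclusive_init,
                       clock = model$clock, network = net,
                       seed = mix_seed(seed, r, 4),
                       zero_support_steps = pb$zero_support_steps,
                       rtw_steps = pb$rtw_steps)
    res <- summarize_trajectories(traj)
    if (r == 1L) colnames(out) <- names(res)
    out[r, ] <- res
  }
  mu <- colMeans(out)
  se <- if (replicates > 1L) apply(out, 2, stats::sd) / sqrt(replicates)
  else stats::setNames(rep(NA_real_, 8), colnames(out))
  structure(list(mean = mu, se = se, outcomes = out, scenario = scen,
                 n = n, replicates = replicates, seed = seed),
            class = "bf_outcome_summary")
}

#' @export
print.bf_outcome_summary <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d replicates of n = %d\n",
              x$scenario$name, x$replicates, x$n))
  tab <- rbind(`mean (%)` = round(x$mean, 2), `MC se` = round(x$se, 3))
  print(tab)
  invisible(x)
}

#' Synergy of an intervention package
#'
#' Excess of a package's effect over the sum of the corresponding
#' single-lever effects against the shared baseline, for one outcome:
#' `(package - baseline) - sum(singles - baseline)`, in percentage points.
#' All summaries must share the same baseline lever values.
#'
#' @param package_summary,baseline_summary [run_scenario()] summaries.
#' @param single_summaries List of single-lever summaries.
#' @param outcome Outcome name (default `"any_6m"`).
#' @return Synergy in percentage points.
#' @export
synergy <- function(package_summary, single_summaries, baseline_summary,
                    outcome = "any_6m") {
  all_sum <- c(list(package_summary, baseline_summary), single_summaries)
  stopifnot(all(vapply(all_sum, inherits, TRUE, "bf_outcome_summary")))
  bases <- lapply(all_sum, function(s) s$scenario$base)
  if (!all(vapply(bases, identical, TRUE, bases[[1]])))
    stop("summaries do not share the same baseline lever values")
  base <- baseline_summary$mean[[outcome]]
  pkg_eff <- package_summary$mean[[outcome]] - base
  single_eff <- vapply(single_summaries,
                       function(s) s$mean[[outcome]] - base, 0)
  pkg_eff - sum(single_eff)
}

#' Sensitivity-sweep specification
#'
#' @param parameter `"beta_knowledge"` or `"beta_bfhi"`.
#' @param values Coefficient values to sweep (defaults: 1.0, 1.17, 1.25,
#'   1.5 for `beta_knowledge`; 0.1, 0.155, 0.25, 0.5 for `beta_bfhi`).
#'   The in-model default value should appear in the list (warned
#'   otherwise).
#' @param coverage Shared intervention level for all five levers
#'   (default 0.95).
#' @return An object of class `bf_sensitivity_spec`.
#' @export
sensitivity_spec <- function(parameter = c("beta_knowledge", "beta_bfhi"),
                             values = NULL, coverage = 0.95) {
  parameter <- match.arg(parameter)
  if (is.null(values))
    values <- if (parameter == "beta_knowledge") c(1.0, 1.17, 1.25, 1.5)
  else c(0.1, 0.155, 0.25, 0.5)
  default <- if (parameter == "beta_knowledge") 1.17 else 0.155
  if (!any(abs(values - default) < 1e-12))
    warning("the in-model default value ", default,
            " is not in the sweep list")
  structure(list(parameter = parameter, values = values,
                 coverage = coverage, default = default),
            class = "bf_sensitivity_spec")
}

#' Sensitivity sweep over an effect coefficient
#'
#' One full scenario run per coefficient value with every lever at the
#' spec's coverage level (knowledge mean at the same value), all else
#' fixed, and shared replicate seeds across values (common random numbers).
#' For each value the logistic intercepts are re-calibrated against the
#' baseline intent/initiation targets before the scenario is applied, so
#' each swept model is anchored to the same observed baseline.
#'
#' @param model A [calibrate_baseline()] object.
#' @param spec A [sensitivity_spec()].
#' @param n,replicates,seed As in [run_scenario()]; the same `seed` is used
#'   for every value.
#' @return An object of class `bf_sensitivity`: list with `table` (one row
#'   per value: parameter value + the eight outcome means) and `summaries`.
#' @export
sensitivity_sweep <- function(model, spec = sensitivity_spec(), n = model$n,
                              replicates = 100L, seed = 1L) {
  stopifnot(inherits(spec, "bf_sensitivity_spec"))
  summaries <- vector("list", length(spec$values))
  for (k in seq_along(spec$values)) {
    v <- spec$values[k]
    scen <- package_scenario(lever_codes(), spec$coverage,
                             name = sprintf("%s=%g@%0.2f", spec$parameter,
                                            v, spec$coverage),
                             base = model$params$population)
    if (spec$parameter == "beta_knowledge") scen$beta_knowledge <- v
    else scen$beta_bfhi <- v
    summaries[[k]] <- run_scenario(model, scen, n = n,
                                   replicates = replicates, seed = seed)
  }
  tab <- data.frame(value = spec$values,
                    do.call(rbind, lapply(summaries, `[[`, "mean")))
  structure(list(parameter = spec$parameter, table = tab,
                 summaries = summaries, spec = spec),
            class = "bf_sensitivity")
}

#' Collect outcome summaries into a table
#'
#' @param summaries Non-empty list of [run_scenario()] summaries.
#' @return `data.frame` with one row per scenario: name, replicate count,
#'   cohort size and the eight outcome means.
#' @export
outcome_table <- function(summaries) {
  if (length(summaries) == 0L) stop("no summaries supplied")
  stopifnot(all(vapply(summaries, inherits, TRUE, "bf_outcome_summary")))
  data.frame(
    scenario = vapply(summaries, function(s) s$scenario$name, ""),
    replicates = vapply(summaries, function(s) as.integer(s$replicates), 0L),
    n = vapply(summaries, function(s) as.integer(s$n), 0L),
    do.call(rbind, lapply(summaries, `[[`, "mean")),
    row.names = NULL)
}

#' Write outcome tables and run metadata
#'
#' Writes `outcomes.csv` (one row per scenario, the eight outcome-rate
#' columns) and `metadata.csv` (seeds, cohort size, replicate counts,
#' calibrated rates and intercepts, package version) to a directory.
#' Re-running the scenarios with the recorded seeds reproduces the table.
#'
#' @param summaries Non-empty list of [run_scenario()] summaries.
#' @param dir Output directory (created if needed).
#' @param model Optional [calibrate_baseline()] object whose calibrated
#'   parameters are recorded in the metadata.
#' @return Invisible character vector of the files written.
#' @export
write_outcome_tables <- function(summaries, dir, model = NULL) {
  tab <- outcome_table(summaries)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  f1 <- file.path(dir, "outcomes.csv")
  utils::write.csv(tab, f1, row.names = FALSE)
  meta <- data.frame(
    key = c("package_version",
            paste0("seed_", vapply(summaries,
                                   function(s) s$scenario$name, ""))),
    value = c(as.character(utils::packageVersion("bfabm")),
              vapply(summaries, function(s) as.character(s$seed), "")))
  if (!is.null(model)) {
    meta <- rbind(meta, data.frame(
      key = c("n_ref", "intent_intercept", "initiation_intercept",
              "rate_excl_to_formula", "rate_partial_to_formula",
              "rate_excl_to_partial", "p_exclusive_init"),
      value = as.character(c(model$n, model$intent_model$intercept,
                             model$initiation_model$intercept,
                             model$rates$excl_to_formula,
                             model$rates$partial_to_formula,
                             model$rates$excl_to_partial,
                             model$p_exclusive_init))))
  }
  f2 <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
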