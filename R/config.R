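#' Default model configuration
#'
#' Builds the packaged configuration of the 28-week stepped-care cost-utility
#' model for mild-to-moderate depression: three strategies (antidepressant
#' treatment-as-usual, face-to-face CBT, and the myCompass internet program),
#' four 7-week cycles, a willingness-to-pay of AUD 50,000/QALY, the 68.8/31.2
#' moderate/mild severity mix, and the full parameter table (effect sizes,
#' non-adherence rates, switch-remission probabilities, utilities, resource
#' counts and 2013/14 Australian unit costs) with their uncertainty
#' distributions.
#'
#' Point estimates are stored verbatim; for a few Beta rows the printed point
#' estimate differs in the third decimal from alpha/(alpha+beta). Deterministic
#' (base-case) evaluation uses the point estimates, probabilistic analysis
#' samples the distributions; neither is silently recomputed from the other.
#'
#' The antidepressant unit cost `cost_medication_per_cycle` is not part of the
#' published cost table; the default (AUD 80 per 7-week cycle) is a documented
#' placeholder derived from typical PBS dispensed prices and should be replaced
#' with a jurisdiction-specific value for any costing exercise that depends on
#' it.
#'
#' @param psa_iterations number of probabilistic sensitivity analysis
#'   iterations (default 10000).
#' @param wtp_grid grid of willingness-to-pay values (AUD/QALY) for
#'   acceptability curves; strictly increasing and nonnegative.
#' @return A validated object of class `cea_config`: a list with fields
#'   `strategies`, `cycle_length_weeks`, `n_cycles`, `weeks_per_year`,
#'   `wtp_default`, `severity_moderate`, `severity_mild`, `psa_iterations`,
#'   `wtp_grid`, and `parameters` (a tibble with one row per model input).
#' @examples
#' cfg <- default_config()
#' dplyr::filter(cfg$parameters, name == "utility_maintenance")
#' @export
default_config <- function(psa_iterations = 10000,
                           wtp_grid = seq(0, 100000, by = 1000)) {
  p <- tibble::tribble(
    ~name, ~role, ~point_estimate, ~dist, ~a, ~b, ~lo, ~hi, ~source_note,
    "eff_initial_tau", "probability", 0.462, "beta", 121, 140, 0, 1,
    "Initial effect size, antidepressants; review of clinical trials",
    "eff_initial_cbt", "probability", 0.479, "beta", 127, 139, 0, 1,
    "Initial effect size, face-to-face CBT; review of CBT trials",
    "eff_initial_mycompass", "probability", 0.449, "beta", 202, 247, 0, 1,
    "Initial effect size, myCompass; RCT data",
    "eff_maintenance_tau", "probability", 0.374, "beta", 1075, 1801, 0, 1,
    "Maintenance effect size, antidepressants; trial data",
    "eff_maintenance_cbt", "probability", 0.559, "beta", 146, 115, 0, 1,
    "Maintenance effect size, CBT; meta-analysis",
    "eff_maintenance_mycompass", "probability", 0.349, "beta", 122, 228, 0, 1,
    "Maintenance effect size, myCompass follow-up; RCT data",
    "p_return_to_treatment", "probability", 0.4, "fixed", NA, NA, 0, 1,
    "Probability that maintenance non-adherers return to treatment",
    "p_remit_switch_antidepressant", "probability", 0.306, "beta", 440, 999, 0, 1,
    "Remission on second-line antidepressants after a first antidepressant failed",
    "p_remit_switch_after_cbt", "probability", 0.585, "lognormal", -0.713, 0.188, 0, 1,
    "Remission on antidepressants after failure of CBT-based therapy; meta-analysis",
    "p_nonadherence_acute_tau", "probability", 0.163, "beta", 599, 3072, 0, 1,
    "Acute-phase non-adherence, antidepressants",
    "p_nonadherence_acute_cbt", "probability", 0.222, "beta", 59, 206, 0, 1,
    "Acute-phase non-adherence, CBT",
    "p_nonadherence_acute_mycompass", "probability", 0.279, "beta", 201, 519, 0, 1,
    "Acute-phase non-adherence, myCompass; RCT data",
    "p_nonadherence_maintenance_tau", "probability", 0.336, "beta", 1436, 2839, 0, 1,
    "Maintenance non-adherence, antidepressants; retrospective database analysis",
    "p_nonadherence_maintenance_cbt", "probability", 0.184, "beta", 962, 4268, 0, 1,
    "Maintenance non-adherence, CBT; discontinuation meta-analysis",
    "p_nonadherence_maintenance_mycompass", "probability", 0.486, "beta", 350, 370, 0, 1,
    "Maintenance non-adherence, myCompass follow-up; RCT data",
    "utility_mild", "utility", 0.78, "beta", 15.74, 4.44, 0, 1,
    "Utility weight, mild depressive episode",
    "utility_moderate", "utility", 0.58, "beta", 0.88, 0.65, 0, 1,
    "Utility weight, moderate depressive episode",
    "utility_maintenance", "utility", 0.88, "beta", 1.44, 0.19, 0, 1,
    "Utility weight, remission/maintenance",
    "gp_visits_episode", "resource-count", 2.48, "fixed", NA, NA, 0, Inf,
    "GP visits per 7-week cycle in the episode state; longitudinal database",
    "gp_visits_remission", "resource-count", 1.89, "fixed", NA, NA, 0, Inf,
    "GP visits per 7-week cycle in remission/maintenance; longitudinal database",
    "psychiatrist_visits_episode", "resource-count", 0.056, "fixed", NA, NA, 0, Inf,
    "Psychiatrist consultations per depressive episode; population survey",
    "booster_sessions_maintenance", "resource-count", 4.846, "fixed", NA, NA, 0, Inf,
    "Monthly CBT booster sessions over the 21-week maintenance phase (21 x 12/52)",
    "completion_fraction", "scaling-constant", 0.5, "fixed", NA, NA, 0, 1,
    "Fraction of a phase's intervention cost incurred by non-completers (pro-rata)",
    "cost_gp_plan", "unit-cost", 71.70, "fixed", NA, NA, 0, Inf,
    "GP mental health plan, MBS items 2700/2712, AUD",
    "cost_gp_consultation", "unit-cost", 36.88, "fixed", NA, NA, 0, Inf,
    "Standard GP consultation, MBS items 3/23, AUD",
    "cost_psychiatrist_consultation", "unit-cost", 367.80, "fixed", NA, NA, 0, Inf,
    "Psychiatric consultation, MBS items 291/293, AUD",
    "cost_psychologist_session", "unit-cost", 141.87, "fixed", NA, NA, 0, Inf,
    "Single clinical psychology session, MBS items 80000/80010, AUD",
    "cost_cbt_course", "unit-cost", 737.72, "fixed", NA, NA, 0, Inf,
    "Full course of face-to-face CBT, AUD",
    "cost_mycompass", "unit-cost", 56.39, "fixed", NA, NA, 0, Inf,
    "myCompass delivery cost per user (12-month budgeted cost), AUD",
    "cost_medication_per_cycle", "unit-cost", 80.00, "fixed", NA, NA, 0, Inf,
    "PLACEHOLDER: antidepressant cost per 7-week cycle, AUD; not in the published cost table",
    "population_mental_illness", "scaling-constant", 4.4e6, "fixed", NA, NA, 0, Inf,
    "Australians with a mental illness (population EVPI scaling)",
    "proportion_mood_disorder", "scaling-constant", 0.206, "fixed", NA, NA, 0, 1,
    "Proportion of those with a mood disorder",
    "treatment_presentation_mix", "scaling-constant", 0.84, "fixed", NA, NA, 0, 1,
    "Treatment presentation rates, mild + moderate (25% + 59%)",
    "acceptability_rate", "scaling-constant", 0.02, "fixed", NA, NA, 0, 1,
    "Assumed low intervention acceptability rate"
  )
  cfg <- structure(
    list(
      strategies = c("TAU", "CBT", "myCompass"),
      cycle_length_weeks = 7L,
      n_cycles = 4L,
      weeks_per_year = 52L,
      wtp_default = 50000,
      severity_moderate = 0.688,
      severity_mild = 0.312,
      psa_iterations = as.integer(psa_iterations),
      wtp_grid = as.numeric(wtp_grid),
      parameters = p
    ),
    class = "cea_config"
  )
  validate_config(cfg)
}

#' @export
print.cea_config <- function(x, ...) {
  cat("<cea_config> ", paste(x$strategies, collapse = " / "), "\n", sep = "")
  cat("  horizon: ", x$n_cycles, " x ", x$cycle_length_weeks, " weeks; WTP default AUD ",
      format(x$wtp_default, big.mark = ","), "/QALY\n", sep = "")
  cat("  parameters: ", nrow(x$parameters), " (",
      sum(x$parameters$dist != "fixed"), " with uncertainty distributions)\n", sep = "")
  invisible(x)
}

.param_roles <- c("probability", "utility", "unit-cost", "resource-count",
                  "scaling-constant")
.param_dists <- c("beta", "lognormal", "fixed", "uniform")

#' Validate a model configuration
#'
#' Checks the structural invariants of a `cea_config`: known strategy names,
#' the cycle grid covering the horizon, a strictly increasing nonnegative
#' willingness-to-pay grid, severity proportions summing to one, and for every
#' parameter a legal role/distribution combination, positive Beta shape
#' parameters, nonnegative lognormal sigma, bounds containing the point
#' estimate, and probability/utility bounds inside the unit interval.
#'
#' @param config a `cea_config` object (see [default_config()]).
#' @return The config, invisibly unchanged, if valid; otherwise an error
#'   naming the offending field.
#' @export
validate_config <- function(config) {
  fail <- function(...) stop("config validation: ", sprintf(...), call. = FALSE)
  if (!inherits(config, "cea_config")) fail("not a cea_config object")
  need <- c("strategies", "cycle_length_weeks", "n_cycles", "weeks_per_year",
            "wtp_default", "severity_moderate", "severity_mild",
            "psa_iterations", "wtp_grid", "parameters")
  miss <- setdiff(need, names(config))
  if (length(miss)) fail("missing field(s): %s", paste(miss, collapse = ", "))
  if (length(config$strategies) != 3 || anyDuplicated(config$strategies))
    fail("strategies: need three distinct strategy names")
  if (abs(config$severity_moderate + config$severity_mild - 1) > 1e-9)
    fail("severity_moderate + severity_mild must sum to 1 (got %.4f)",
         config$severity_moderate + config$severity_mild)
  if (config$psa_iterations < 1) fail("psa_iterations: must be >= 1")
  g <- config$wtp_grid
  if (length(g) < 1 || any(g < 0) || (length(g) > 1 && any(diff(g) <= 0)))
    fail("wtp_grid: must be nonnegative and strictly increasing")
  p <- config$parameters
  cols <- c("name", "role", "point_estimate", "dist", "a", "b", "lo", "hi",
            "source_note")
  miss <- setdiff(cols, names(p))
  if (length(miss)) fail("parameters: missing column(s) %s",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(p$name)) fail("parameters: duplicated name(s)")
  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    ctx <- function(msg, ...) fail(paste0("parameter '%s': ", msg), r$name, ...)
    if (!r$role %in% .param_roles) ctx("unknown role '%s'", r$role)
    if (!r$dist %in% .param_dists) ctx("unknown distribution '%s'", r$dist)
    if (!is.finite(r$point_estimate)) ctx("point_estimate is not finite")
    if (r$dist == "beta" && (!is.finite(r$a) || !is.finite(r$b) ||
                             r$a <= 0 || r$b <= 0))
      ctx("beta shape parameters must be > 0")
    if (r$dist == "lognormal" && (!is.finite(r$b) || r$b < 0))
      ctx("lognormal sigma must be >= 0")
    if (r$dist == "uniform" && (!is.finite(r$a) || !is.finite(r$b) || r$a > r$b))
      ctx("uniform needs lo <= hi arguments")
    if (r$lo > r$hi) ctx("bounds: lo > hi")
    if (r$role %in% c("probability", "utility")) {
      if (r$lo < 0 || r$hi > 1) ctx("bounds must lie within [0, 1]")
      if (r$point_estimate < r$lo || r$point_estimate > r$hi)
        ctx("point_estimate %.4f outside bounds [%g, %g]",
            r$point_estimate, r$lo, r$hi)
    }
    if (r$role %in% c("unit-cost", "resource-count") && r$point_estimate < 0)
      ctx("point_estimate must be >= 0")
  }
  invisible(config)
}

#' Write a configuration to a JSON file
#'
#' The schema is one JSON object with the scalar model settings and a
#' `parameters` array holding one block per model input (`name`, `role`,
#' `point_estimate`, `distribution` with `kind` and its arguments, `bounds`,
#' `source_note`). [read_config()] restores an identical `cea_config`.
#'
#' @param config a `cea_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  p <- config$parameters
  params <- purrr::pmap(p, function(name, role, point_estimate, dist, a, b,
                                    lo, hi, source_note) {
    d <- switch(dist,
      beta = list(kind = "beta", alpha = a, beta = b),
      lognormal = list(kind = "lognormal", mu = a, sigma = b),
      uniform = list(kind = "uniform", lo = a, hi = b),
      fixed = list(kind = "fixed")
    )
    list(name = name, role = role, point_estimate = point_estimate,
         distribution = d, bounds = c(lo, hi), source_note = source_note)
  })
  out <- list(
    strategies = config$strategies,
    cycle_length_weeks = config$cycle_length_weeks,
    n_cycles = config$n_cycles,
    weeks_per_year = config$weeks_per_year,
    wtp_default = config$wtp_default,
    severity_moderate = config$severity_moderate,
    severity_mild = config$severity_mild,
    psa_iterations = config$psa_iterations,
    wtp_grid = config$wtp_grid,
    parameters = params
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and validate a configuration file
#'
#' @param path path to a JSON configuration written by [write_config()] (the
#'   packaged default is available through [default_config()]).
#' @return A validated `cea_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  fail <- function(...) stop("config schema: ", sprintf(...), call. = FALSE)
  sc <- function(field, as = as.numeric) {
    if (is.null(x[[field]])) fail("missing field '%s'", field)
    as(x[[field]])
  }
  params <- x$parameters
  if (is.null(params) || !length(params)) fail("missing 'parameters' array")
  rows <- purrr::map(params, function(q) {
    for (f in c("name", "role", "point_estimate", "distribution", "bounds"))
      if (is.null(q[[f]])) fail("parameter block missing field '%s'", f)
    d <- q$distribution
    kind <- d$kind
    if (is.null(kind)) fail("parameter '%s': distribution has no 'kind'", q$name)
    ab <- switch(kind,
      beta = c(d$alpha, d$beta),
      lognormal = c(d$mu, d$sigma),
      uniform = c(d$lo, d$hi),
      fixed = c(NA_real_, NA_real_),
      fail("parameter '%s': malformed distribution kind '%s'", q$name, kind)
    )
    if (kind != "fixed" && (length(ab) != 2 || any(!is.finite(unlist(ab)))))
      fail("parameter '%s': malformed %s arguments", q$name, kind)
    tibble::tibble(
      name = q$name, role = q$role,
      point_estimate = as.numeric(q$point_estimate),
      dist = kind, a = as.numeric(ab[[1]]), b = as.numeric(ab[[2]]),
      lo = as.numeric(q$bounds[[1]]), hi = as.numeric(q$bounds[[2]]),
      source_note = q$source_note %||% ""
    )
  })
  cfg <- structure(
    list(
      strategies = as.character(unlist(x$strategies)),
      cycle_length_weeks = sc("cycle_length_weeks", as.integer),
      n_cycles = sc("n_cycles", as.integer),
      weeks_per_year = sc("weeks_per_year", as.integer),
      wtp_default = sc("wtp_default"),
      severity_moderate = sc("severity_moderate"),
      severity_mild = sc("severity_mild"),
      psa_iterations = sc("psa_iterations", as.integer),
      wtp_grid = as.numeric(unlist(x$wtp_grid)),
      parameters = dplyr::bind_rows(rows)
    ),
    class = "cea_config"
  )
  validate_config(cfg)
}

#' Point-estimate parameter set
#'
#' Returns the deterministic (base-case) parameter set of a configuration as a
#' one-row wide tibble: one column per parameter, each holding its printed
#' point estimate.
#'
#' @param config a `cea_config`.
#' @return A one-row tibble.
#' @export
point_estimates <- function(config) {
  validate_config(config)
  p <- config$parameters
  tibble::as_tibble(stats::setNames(as.list(p$point_estimate), p$name))
}
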