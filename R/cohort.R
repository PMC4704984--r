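#' QALYs accrued along one path's state schedule
#'
#' Time in each health state is valued with its utility weight and converted
#' to years: `QALY = (weeks_episode * u_episode + weeks_maintenance *
#' u_maintenance) / 52`, where the episode utility is the severity-weighted
#' mixture `u_episode = 0.688 * u_moderate + 0.312 * u_mild` (moderate cases
#' present to services at roughly twice the rate of mild ones) and the
#' remission and maintenance states share `u_maintenance`.
#'
#' @param schedule a list or one-row tibble with `episode_weeks` and
#'   `maintenance_weeks` (nonnegative, summing to the 28-week horizon).
#' @param params a one-row parameter set containing the utility parameters.
#' @param config a `cea_config` (severity mix and weeks per year).
#' @return QALYs, a single number.
#' @export
path_qaly <- function(schedule, params, config = default_config()) {
  P <- as.list(params)
  s <- as.list(schedule)
  u_episode <- config$severity_moderate * P$utility_moderate +
    config$severity_mild * P$utility_mild
  (s$episode_weeks * u_episode +
      s$maintenance_weeks * P$utility_maintenance) / config$weeks_per_year
}

#' Cost of one path's resource tally
#'
#' Inner product of the resource counts with their unit costs: GP mental
#' health plan items, GP consultations, psychiatrist consultations, CBT
#' courses, psychologist booster sessions, myCompass deliveries, and first-
#' and second-line medication cycles. Counts may be fractional (they are
#' expectations); missing tally columns count as zero.
#'
#' @param tally a list or one-row tibble of resource counts, as produced by
#'   [enumerate_paths()] (or a realised per-patient tally from
#'   [simulate_cohort()]).
#' @param params a one-row parameter set containing the unit-cost parameters.
#' @return Cost in AUD, a single number.
#' @export
path_cost <- function(tally, params) {
  P <- as.list(params)
  t <- as.list(tally)
  cnt <- function(f) {
    v <- t[[f]] %||% 0
    if (any(v < 0)) stop("tally count '", f, "' is negative", call. = FALSE)
    v
  }
  unit <- function(f) {
    if (is.null(P[[f]]))
      stop("missing unit-cost parameter '", f, "'", call. = FALSE)
    P[[f]]
  }
  unit("cost_gp_plan") * cnt("gp_plan_items") +
    unit("cost_gp_consultation") * cnt("gp_consultations") +
    unit("cost_psychiatrist_consultation") * cnt("psychiatrist_consultations") +
    unit("cost_cbt_course") * cnt("cbt_courses") +
    unit("cost_psychologist_session") * cnt("booster_sessions") +
    unit("cost_mycompass") * cnt("mycompass_deliveries") +
    unit("cost_medication_per_cycle") *
      (cnt("med_cycles_first_line") + cnt("med_cycles_second_line"))
}

#' Expected cost and QALYs of a strategy for one parameter set
#'
#' Probability-weighted sum of path costs and path QALYs over the exhaustive
#' path enumeration of the strategy tree; deterministic for fixed inputs.
#'
#' @param tree a `cea_tree`.
#' @param params a one-row parameter set.
#' @param config a `cea_config`.
#' @return A one-row tibble with columns `strategy`, `cost_aud`, `qaly`.
#' @export
expected_outcomes <- function(tree, params, config = default_config()) {
  q <- .path_quantities(tree, as.list(params), config)
  cost <- sum(vapply(q, function(pk) pk$prob * pk$cost, numeric(1)))
  qaly <- sum(vapply(q, function(pk) pk$prob * pk$qaly, numeric(1)))
  tibble::tibble(strategy = tree$strategy, cost_aud = cost, qaly = qaly)
}

# Vectorised cost/qaly for all strategies over a parameter set P (list of
# n-vectors or scalars). Returns list(cost =, qaly =) of n x S matrices.
.outcomes_all <- function(config, P, topology = NULL) {
  topo <- if (is.list(topology) && !is.null(topology$strategies)) topology
          else read_topology(topology)
  n <- max(vapply(P, length, integer(1)))
  S <- length(config$strategies)
  cost <- matrix(0, n, S, dimnames = list(NULL, config$strategies))
  qaly <- matrix(0, n, S, dimnames = list(NULL, config$strategies))
  for (s in config$strategies) {
    tree <- build_strategy_tree(s, config, topo)
    q <- .path_quantities(tree, P, config)
    cs <- 0; qs <- 0
    for (pk in q) {
      cs <- cs + pk$prob * pk$cost
      qs <- qs + pk$prob * pk$qaly
    }
    cost[, s] <- cs
    qaly[, s] <- qs
  }
  list(cost = cost, qaly = qaly)
}

#' Deterministic base-case evaluation of all strategies
#'
#' Evaluates every strategy tree at the printed point estimates and reports
#' expected cost, expected QALYs and the net monetary benefit at the chosen
#' willingness-to-pay.
#'
#' @param config a `cea_config`.
#' @param wtp willingness-to-pay in AUD/QALY (default: the config's 50,000).
#' @param topology optional topology (path or list); `NULL` uses the packaged
#'   default.
#' @return A tibble with one row per strategy: `strategy`, `cost_aud`,
#'   `qaly`, `nmb`.
#' @examples
#' base_case(default_config())
#' @export
base_case <- function(config = default_config(), wtp = config$wtp_default,
                      topology = NULL) {
  P <- as.list(point_estimates(config))
  o <- .outcomes_all(config, P, topology)
  tibble::tibble(
    strategy = config$strategies,
    cost_aud = unname(o$cost[1, ]),
    qaly = unname(o$qaly[1, ]),
    nmb = unname(nmb(o$qaly[1, ], o$cost[1, ], wtp))
  )
}

#' Net monetary benefit
#'
#' `NMB = E * lambda - C`: effectiveness monetised at the willingness-to-pay
#' threshold, minus cost. The strategy with the highest NMB is optimal.
#'
#' @param E effectiveness in QALYs.
#' @param C cost in AUD.
#' @param wtp willingness-to-pay lambda in AUD/QALY (>= 0).
#' @return NMB in AUD (vectorised).
#' @export
nmb <- function(E, C, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  E * wtp - C
}

#' Incremental cost-effectiveness ratio
#'
#' `ICER = delta_cost / delta_qaly`. When `delta_qaly` is zero the ratio is
#' undefined and flagged rather than thrown; negative ratios are reported
#' as-is with a dominance annotation derived from the signs (deltas are
#' comparator minus reference).
#'
#' @param delta_cost incremental cost (AUD).
#' @param delta_qaly incremental effectiveness (QALYs).
#' @return A one-row tibble: `icer` (NA when undefined), `undefined`,
#'   `dominance` annotation.
#' @export
icer <- function(delta_cost, delta_qaly) {
  undefined <- delta_qaly == 0
  value <- ifelse(undefined, NA_real_, delta_cost / delta_qaly)
  dominance <- dplyr::case_when(
    undefined & delta_cost > 0 ~ "undefined: same effect, comparator costlier (reference dominates)",
    undefined & delta_cost < 0 ~ "undefined: same effect, comparator cheaper (comparator dominates)",
    undefined ~ "undefined: identical outcomes",
    delta_qaly > 0 & delta_cost < 0 ~ "comparator dominates (more effective, cheaper)",
    delta_qaly < 0 & delta_cost > 0 ~ "reference dominates (comparator less effective, costlier)",
    TRUE ~ ""
  )
  tibble::tibble(icer = value, undefined = undefined, dominance = dominance)
}

#' Average cost-effectiveness ratio
#'
#' Total cost divided by total effectiveness for a single strategy (not
#' incremental).
#'
#' @param C cost in AUD.
#' @param E effectiveness in QALYs (> 0).
#' @return `C / E` in AUD/QALY (vectorised).
#' @export
average_cer <- function(C, E) {
  if (any(E <= 0)) stop("average_cer requires E > 0", call. = FALSE)
  C / E
}

#' Incremental comparison of two strategies
#'
#' Deltas are computed as comparator minus reference, so a positive
#' incremental NMB favours the comparator; `incremental_nmb = delta_qaly *
#' wtp - delta_cost` holds as an identity. This sign convention is stated in
#' every written report header.
#'
#' @param reference one-row cohort result (`strategy`, `cost_aud`, `qaly`),
#'   e.g. one row of [base_case()].
#' @param comparator one-row cohort result from the same configuration.
#' @param wtp willingness-to-pay in AUD/QALY.
#' @return A one-row tibble: `reference`, `comparator`, `delta_cost`,
#'   `delta_qaly`, `icer`, `icer_undefined`, `dominance`, `incremental_nmb`.
#' @export
incremental_summary <- function(reference, comparator, wtp) {
  dc <- comparator$cost_aud - reference$cost_aud
  de <- comparator$qaly - reference$qaly
  ic <- icer(dc, de)
  tibble::tibble(
    reference = reference$strategy,
    comparator = comparator$strategy,
    delta_cost = dc,
    delta_qaly = de,
    icer = ic$icer,
    icer_undefined = ic$undefined,
    dominance = ic$dominance,
    incremental_nmb = nmb(de, dc, wtp)
  )
}
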