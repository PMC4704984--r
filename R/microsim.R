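#' Patient-level microsimulation of a strategy tree
#'
#' Brute-force Monte-Carlo oracle for the cohort expectations: `n` patients
#' each walk the strategy tree (equivalently, draw a terminal path with its
#' enumeration probability), and per-cycle visit counts are realised from
#' Poisson distributions with the stated expected rates (GP visits per cycle
#' by state, psychiatrist consultations per episode, booster sessions), so
#' that the microsimulation mean converges to the cohort expectation.
#' Intervention cost fractions (courses, deliveries, medication cycles) are
#' pro-rata cost adjustments rather than utilisation counts and are kept at
#' their per-path values. Per-patient QALYs are deterministic given the path
#' and utilities.
#'
#' @param config a `cea_config`.
#' @param strategy strategy name.
#' @param params a one-row parameter set (default: point estimates).
#' @param n number of simulated patients (>= 1).
#' @param seed integer seed; identical seeds reproduce identical trajectories.
#' @param topology optional topology.
#' @return A list of class `cea_microsim`: `strategy`, `n`, `seed`,
#'   `mean_cost`, `mean_qaly`, and `trajectories` — a tibble with one row per
#'   patient holding the per-cycle state sequence (`state_cycle1` ...),
#'   realised resource tally, `cost_aud` and `qaly`. Each trajectory's cost
#'   equals [path_cost()] recomputed from its own tally.
#' @export
simulate_cohort <- function(config, strategy, params = point_estimates(config),
                            n, seed = 1L, topology = NULL) {
  validate_config(config)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  tree <- build_strategy_tree(strategy, config, topology)
  P <- as.list(params)
  q <- .path_quantities(tree, P, config)
  probs <- vapply(q, function(pk) pk$prob, numeric(1))
  set.seed(.param_seed(seed, paste0("microsim_", strategy)))
  idx <- sample.int(length(q), n, replace = TRUE, prob = probs)
  leaf_field <- function(f, how = function(pk) pk$leaf[[f]])
    vapply(q, how, numeric(1))[idx]
  ep_cycles <- leaf_field("episode_cycles")
  rem_cycles <- leaf_field("remission_cycles")
  spells <- leaf_field("episode_spells")
  boosters_exp <- vapply(q, function(pk) pk$booster_sessions, numeric(1))[idx]
  # realised utilisation counts (Poisson with the stated means)
  gp <- 1 + stats::rpois(n, ep_cycles * P$gp_visits_episode) +
    stats::rpois(n, rem_cycles * P$gp_visits_remission)
  psych <- stats::rpois(n, spells * P$psychiatrist_visits_episode)
  boosters <- stats::rpois(n, boosters_exp)
  traj <- tibble::tibble(
    patient_id = seq_len(n),
    strategy = strategy,
    path = vapply(q, function(pk) pk$path, character(1))[idx],
    episode_weeks = leaf_field("episode_weeks"),
    maintenance_weeks = leaf_field("maintenance_weeks"),
    gp_plan_items = 1,
    gp_consultations = gp,
    psychiatrist_consultations = psych,
    cbt_courses = vapply(q, function(pk) pk$cbt_courses, numeric(1))[idx],
    booster_sessions = boosters,
    mycompass_deliveries =
      vapply(q, function(pk) pk$mycompass_deliveries, numeric(1))[idx],
    med_cycles_first_line =
      vapply(q, function(pk) pk$med_cycles_first_line, numeric(1))[idx],
    med_cycles_second_line =
      vapply(q, function(pk) pk$med_cycles_second_line, numeric(1))[idx]
  )
  states <- t(vapply(q, function(pk) unlist(pk$leaf$states),
                     character(config$n_cycles)))[idx, , drop = FALSE]
  colnames(states) <- paste0("state_cycle", seq_len(config$n_cycles))
  traj <- dplyr::bind_cols(traj, tibble::as_tibble(states))
  traj$cost_aud <- path_cost(traj, params)
  traj$qaly <- path_qaly(traj, params, config)
  structure(
    list(strategy = strategy, n = as.integer(n), seed = as.integer(seed),
         mean_cost = mean(traj$cost_aud), mean_qaly = mean(traj$qaly),
         trajectories = traj),
    class = "cea_microsim"
  )
}

#' @export
print.cea_microsim <- function(x, ...) {
  cat("<cea_microsim> ", x$strategy, ": n = ", x$n,
      ", mean cost AUD ", sprintf("%.2f", x$mean_cost),
      ", mean QALY ", sprintf("%.4f", x$mean_qaly), "\n", sep = "")
  invisible(x)
}

#' Long-format export of simulated trajectories
#'
#' One row per patient and cycle: `patient_id`, `strategy`, `cycle`, `state`,
#' `cost_aud`, `qaly` (patient totals repeated on each cycle row).
#'
#' @param sim a `cea_microsim`.
#' @return A tibble.
#' @export
trajectories_long <- function(sim) {
  stopifnot(inherits(sim, "cea_microsim"))
  tr <- sim$trajectories
  tidyr::pivot_longer(
    dplyr::select(tr, "patient_id", "strategy",
                  dplyr::starts_with("state_cycle"), "cost_aud", "qaly"),
    cols = dplyr::starts_with("state_cycle"),
    names_to = "cycle", names_prefix = "state_cycle",
    names_transform = as.integer, values_to = "state"
  ) |>
    dplyr::select("patient_id", "strategy", "cycle", "state",
                  "cost_aud", "qaly")
}

#' Simulate a Bernoulli trial behind a Beta parameter
#'
#' Emulates the trial outcomes underlying the Beta(events, non-events) rows of
#' the parameter table: a binomial success count for `n` subjects at success
#' probability `p`.
#'
#' @param p true success probability in \[0, 1\].
#' @param n number of subjects (>= 1).
#' @param seed integer seed.
#' @return A one-row tibble: `true_p`, `n`, `successes`.
#' @export
generate_trial <- function(p, n, seed = 1L) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("p must lie in [0, 1]", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(.param_seed(seed, "synthetic_trial"))
  tibble::tibble(true_p = p, n = as.integer(n),
                 successes = stats::rbinom(1, n, p))
}

#' Fit a Beta parameter specification from trial counts
#'
#' Adopts the events/non-events convention of the parameter table: a trial
#' with `s` successes and `f` failures yields Beta(s, f) with point estimate
#' `s / (s + f)`.
#'
#' @param successes,failures nonnegative counts with `successes + failures
#'   >= 1`.
#' @param name parameter name for the returned specification.
#' @return A one-row parameter-specification tibble in the same layout as
#'   `config$parameters`.
#' @export
fit_beta <- function(successes, failures, name = "fitted") {
  if (successes < 0 || failures < 0 || successes + failures < 1)
    stop("need nonnegative counts with successes + failures >= 1",
         call. = FALSE)
  tibble::tibble(
    name = name, role = "probability",
    point_estimate = successes / (successes + failures),
    dist = "beta", a = as.numeric(successes), b = as.numeric(failures),
    lo = 0, hi = 1,
    source_note = sprintf("fitted from %d successes / %d failures",
                          as.integer(successes), as.integer(failures))
  )
}
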