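test_that("path_qaly applies severity-weighted utilities over the schedule", {
  P <- point_estimates(cfg0)
  # full horizon in episode
  expect_equal(path_qaly(list(episode_weeks = 28, maintenance_weeks = 0),
                         P, cfg0),
               (0.688 * 0.58 + 0.312 * 0.78) * 28 / 52)
  # 7 weeks episode + 21 weeks maintenance
  expect_equal(path_qaly(list(episode_weeks = 7, maintenance_weeks = 21),
                         P, cfg0),
               (0.688 * 0.58 + 0.312 * 0.78) * 7 / 52 + 0.88 * 21 / 52)
  # zero utilities everywhere
  P0 <- P
  P0[c("utility_mild", "utility_moderate", "utility_maintenance")] <- 0
  expect_equal(path_qaly(list(episode_weeks = 7, maintenance_weeks = 21),
                         P0, cfg0), 0)
})

test_that("path_cost is the inner product of counts and unit costs", {
  P <- point_estimates(cfg0)
  # one episode cycle of GP visits only
  expect_equal(path_cost(list(gp_consultations = 2.48), P), 2.48 * 36.88)
  # one CBT course
  expect_equal(path_cost(list(cbt_courses = 1), P), 737.72)
  # empty tally
  expect_equal(path_cost(list(), P), 0)
  expect_error(path_cost(list(gp_consultations = -1), P), "negative")
  expect_error(path_cost(list(cbt_courses = 1), P["utility_mild"]),
               "missing unit-cost parameter")
})

test_that("expected_outcomes is the probability-weighted two-point expectation on a toy tree", {
  # leaf A: cost 100 (one delivery at unit cost 100), QALY 0.1; leaf B: 0, 0
  leaf_a <- toy_leaf(ep_w = 0, m_w = 26, acute = "1")
  leaf_b <- toy_leaf(ep_w = 28, m_w = 0)
  tr <- toy_tree("0.5", leaf_a, leaf_b,
                 intervention = list(acute = "mycompass",
                                     maintenance = "none"))
  P <- zeroed_params(cost_mycompass = 100)
  P$utility_maintenance <- 0.2          # 26 * 0.2 / 52 = 0.1
  P$utility_mild <- 0
  P$utility_moderate <- 0
  out <- expected_outcomes(tr, P, cfg0)
  expect_equal(out$cost_aud, 50)
  expect_equal(out$qaly, 0.05)
})

test_that("cohort expectation matches the microsimulation oracle at moderate n", {
  for (s in cfg0$strategies) {
    tr <- build_strategy_tree(s, cfg0)
    eo <- expected_outcomes(tr, point_estimates(cfg0), cfg0)
    sim <- simulate_cohort(cfg0, s, n = 20000, seed = 17)
    se_cost <- stats::sd(sim$trajectories$cost_aud) / sqrt(sim$n)
    se_qaly <- stats::sd(sim$trajectories$qaly) / sqrt(sim$n)
    expect_lt(abs(sim$mean_cost - eo$cost_aud), 3 * se_cost, label = s)
    expect_lt(abs(sim$mean_qaly - eo$qaly), 3 * se_qaly, label = s)
  }
})

test_that("myCompass has the strictly lowest expected cost at the point estimates", {
  bc <- base_case(cfg0)
  expect_equal(bc$strategy[which.min(bc$cost_aud)], "myCompass")
  expect_lt(bc$cost_aud[bc$strategy == "myCompass"],
            min(bc$cost_aud[bc$strategy != "myCompass"]))
})

test_that("expected cost is linear in unit costs and leaves QALYs unchanged", {
  P <- point_estimates(cfg0)
  P2 <- P
  unit_cost <- cfg0$parameters$name[cfg0$parameters$role == "unit-cost"]
  P2[unit_cost] <- P2[unit_cost] * 2
  for (s in cfg0$strategies) {
    tr <- build_strategy_tree(s, cfg0)
    o1 <- expected_outcomes(tr, P, cfg0)
    o2 <- expected_outcomes(tr, P2, cfg0)
    expect_equal(o2$cost_aud, 2 * o1$cost_aud, label = s)
    expect_equal(o2$qaly, o1$qaly, label = s)
  }
})

test_that("perfect adherence, response and maintenance yield the maximum-QALY path exactly", {
  cfg <- with_points(cfg0,
    p_nonadherence_acute_tau = 0, p_nonadherence_acute_cbt = 0,
    p_nonadherence_acute_mycompass = 0,
    p_nonadherence_maintenance_tau = 0, p_nonadherence_maintenance_cbt = 0,
    p_nonadherence_maintenance_mycompass = 0,
    eff_initial_tau = 1, eff_initial_cbt = 1, eff_initial_mycompass = 1,
    eff_maintenance_tau = 1, eff_maintenance_cbt = 1,
    eff_maintenance_mycompass = 1)
  P <- point_estimates(cfg)
  best <- path_qaly(list(episode_weeks = 7, maintenance_weeks = 21), P, cfg)
  for (s in cfg$strategies) {
    tr <- build_strategy_tree(s, cfg)
    expect_equal(expected_outcomes(tr, P, cfg)$qaly, best, label = s)
  }
})

test_that("nmb, icer and average_cer follow their defining formulas", {
  expect_equal(nmb(0.5, 1000, 50000), 24000)
  expect_equal(nmb(0.5, 1000, 0), -1000)
  expect_error(nmb(0.5, 1000, -1), ">= 0")

  expect_equal(icer(100, 0.01)$icer, 10000)
  expect_equal(icer(0, 0.1)$icer, 0)
  z <- icer(100, 0)
  expect_true(z$undefined)
  expect_true(is.na(z$icer))
  expect_match(z$dominance, "undefined")
  expect_match(icer(-50, 0.1)$dominance, "comparator dominates")

  expect_lt(abs(average_cer(524.91, 0.24) - 2187.13), 0.01)
  expect_equal(average_cer(0, 0.1), 0)
  expect_error(average_cer(100, 0), "E > 0")
})

test_that("incremental_summary satisfies the NMB identity and handles identical inputs", {
  a <- tibble::tibble(strategy = "A", cost_aud = 100, qaly = 0.2)
  same <- incremental_summary(a, dplyr::mutate(a, strategy = "B"), 50000)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_true(same$icer_undefined)
  expect_equal(same$incremental_nmb, 0)

  set.seed(42)
  for (i in 1:20) {
    ref <- tibble::tibble(strategy = "ref", cost_aud = stats::runif(1, 0, 3000),
                          qaly = stats::runif(1, 0, 0.5))
    cmp <- tibble::tibble(strategy = "cmp", cost_aud = stats::runif(1, 0, 3000),
                          qaly = stats::runif(1, 0, 0.5))
    wtp <- stats::runif(1, 0, 1e5)
    inc <- incremental_summary(ref, cmp, wtp)
    expect_lt(abs(inc$incremental_nmb -
                    (inc$delta_qaly * wtp - inc$delta_cost)), 1e-9)
    expect_equal(inc$delta_cost, cmp$cost_aud - ref$cost_aud)
  }
})
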