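# Shared fixtures, all built in code.

# Default configuration reused across tests (cheap to build, immutable).
cfg0 <- default_config()

# A configuration with every distribution degenerate (fixed at the point
# estimate): useful for exact-determinism checks.
all_fixed_config <- function() {
  cfg <- default_config()
  cfg$parameters$dist <- "fixed"
  cfg$parameters$a <- NA_real_
  cfg$parameters$b <- NA_real_
  validate_config(cfg)
}

# Override selected point estimates (and freeze their distributions so the
# override also holds under sampling).
with_points <- function(cfg, ...) {
  pts <- list(...)
  for (nm in names(pts)) {
    i <- match(nm, cfg$parameters$name)
    stopifnot(!is.na(i))
    cfg$parameters$point_estimate[i] <- pts[[nm]]
    cfg$parameters$dist[i] <- "fixed"
    cfg$parameters$a[i] <- NA_real_
    cfg$parameters$b[i] <- NA_real_
  }
  cfg
}

# Hand-built toy trees (bypassing the topology file) for unit tests of the
# enumeration and expectation machinery.
toy_leaf <- function(ep_w = 28, m_w = 0, ep_c = 4, rem_c = 0, spells = 0,
                     acute = "0", maint = "0", maint_cycles = 0, sl = 0) {
  list(type = "terminal",
       episode_weeks = ep_w, maintenance_weeks = m_w,
       states = as.list(rep("episode", 4)),
       episode_cycles = ep_c, remission_cycles = rem_c,
       episode_spells = spells,
       acute_fraction = acute, maintenance_fraction = maint,
       maintenance_cycles_on_treatment = maint_cycles,
       secondline_med_cycles = sl)
}

toy_tree <- function(p_expr, leaf_a, leaf_b, strategy = "toy",
                     intervention = list(acute = "none", maintenance = "none")) {
  structure(
    list(strategy = strategy, intervention = intervention,
         root = list(type = "chance", label = "toss", branches = list(
           list(label = "a", prob = p_expr, node = leaf_a),
           list(label = "b", prob = paste("1 -", p_expr), node = leaf_b)
         ))),
    class = "cea_tree"
  )
}

# Parameter set with every resource/unit-cost zeroed, for toy-tree tests
# where costs are injected through a single resource.
zeroed_params <- function(...) {
  P <- point_estimates(cfg0)
  zero <- grep("^cost_|^gp_visits|^psychiatrist_visits|^booster_sessions",
               names(P), value = TRUE)
  P[zero] <- 0
  over <- list(...)
  P[names(over)] <- over
  P
}

# Minimal hand-built PSA container for functions that consume draws only.
fake_psa <- function(cost, qaly, config = cfg0, seed = 0L) {
  strategies <- config$strategies
  stopifnot(ncol(cost) == length(strategies))
  n <- nrow(cost)
  draws <- purrr::map_dfr(seq_along(strategies), function(s) {
    tibble::tibble(iteration = seq_len(n), strategy = strategies[s],
                   cost_aud = cost[, s], qaly = qaly[, s])
  })
  structure(list(draws = draws, params = tibble::tibble(.rows = n),
                 n = n, seed = seed, config = config),
            class = "cea_psa")
}

# Recursive walk asserting that every chance node's branch probabilities sum
# to one under a parameter set (independent of the path-table machinery).
check_branch_sums <- function(node, P, tol = 1e-12) {
  if (!identical(node$type, "chance")) return(invisible(TRUE))
  probs <- vapply(node$branches, function(br) {
    expr <- br$prob
    if (grepl("^[0-9.]+$", expr)) as.numeric(expr)
    else if (grepl("^1\\s*-\\s*", expr)) 1 - P[[sub("^1\\s*-\\s*", "", expr)]]
    else P[[expr]]
  }, numeric(1))
  expect_lt(abs(sum(probs) - 1), tol)
  for (br in node$branches) check_branch_sums(br$node, P, tol)
  invisible(TRUE)
}
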