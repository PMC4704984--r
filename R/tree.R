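#' Read a strategy-tree topology file
#'
#' The topology file is the single source of truth for the tree structure of
#' every strategy: a JSON document with one entry per strategy holding the
#' intervention cost mapping and the unrolled chance/terminal node structure.
#' Branch probabilities are expressions over parameter names — a bare name
#' `p`, its complement `1 - p`, or a numeric literal — so reviewers can amend
#' the reconstruction without code changes. The packaged default reproduces
#' the documented 28-week, four-cycle stepped-care reconstruction.
#'
#' @param path path to a topology JSON file; `NULL` (default) loads the
#'   packaged topology.
#' @return A nested list describing the per-strategy trees.
#' @export
read_topology <- function(path = NULL) {
  path <- path %||% system.file("extdata", "topology.json", package = "stepcea")
  if (!nzchar(path) || !file.exists(path))
    stop("topology file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# Evaluate a branch-probability / fraction expression against a parameter set
# (a list of vectors; fixed parameters may be length-1 scalars). Grammar:
# "name", "1 - name", or a numeric literal.
.eval_expr <- function(expr, P) {
  expr <- trimws(as.character(expr))
  if (grepl("^[0-9.eE+-]+$", expr) && !is.na(suppressWarnings(as.numeric(expr))))
    return(as.numeric(expr))
  if (grepl("^1\\s*-\\s*", expr))
    return(1 - .eval_expr(sub("^1\\s*-\\s*", "", expr), P))
  if (is.null(P[[expr]]))
    stop("unresolvable parameter reference '", expr, "' in topology",
         call. = FALSE)
  P[[expr]]
}

# Depth-first enumeration of root-to-terminal paths of a topology node.
# Returns a list of paths: (labels, prob_exprs, leaf).
.tree_paths <- function(node, labels = character(), exprs = character()) {
  if (identical(node$type, "terminal")) {
    return(list(list(labels = labels, prob_exprs = exprs, leaf = node)))
  }
  if (!identical(node$type, "chance"))
    stop("topology node has unknown type '", node$type %||% "<missing>", "'",
         call. = FALSE)
  out <- list()
  for (br in node$branches) {
    out <- c(out, .tree_paths(br$node,
                              c(labels, br$label),
                              c(exprs, br$prob)))
  }
  out
}

#' Build the decision tree for one strategy
#'
#' Constructs the unrolled four-cycle tree of a treatment arm from the
#' topology file: cycle 1 is the acute phase (adherence, then response);
#' acute non-adherers and adherent non-responders switch to second-line
#' antidepressant treatment-as-usual (one treatment cycle, then remission or
#' discontinuation); acute responders enter the 21-week maintenance phase,
#' where the maintenance effect and maintenance non-adherence each apply once,
#' non-adherers return to treatment with probability 0.4 and otherwise
#' discontinue, and relapse returns the patient to the episode state for the
#' remainder of the horizon.
#'
#' @param strategy one of the configured strategy names.
#' @param config a `cea_config`.
#' @param topology a topology list from [read_topology()]; `NULL` uses the
#'   packaged default.
#' @return An object of class `cea_tree` with fields `strategy`,
#'   `intervention` (acute/maintenance cost mapping) and `root`.
#' @export
build_strategy_tree <- function(strategy, config, topology = NULL) {
  validate_config(config)
  if (!strategy %in% config$strategies)
    stop("unknown strategy '", strategy, "'; configured strategies: ",
         paste(config$strategies, collapse = ", "), call. = FALSE)
  topo <- if (is.list(topology) && !is.null(topology$strategies)) topology
          else read_topology(topology)
  st <- topo$strategies[[strategy]]
  if (is.null(st))
    stop("strategy '", strategy, "' not present in topology", call. = FALSE)
  tree <- structure(
    list(strategy = strategy, intervention = st$intervention, root = st$root),
    class = "cea_tree"
  )
  # structural validation: every referenced parameter resolves, and branch
  # probabilities at every chance node sum to 1 at the point estimates
  P <- as.list(point_estimates(config))
  .check_node <- function(node) {
    if (identical(node$type, "chance")) {
      s <- sum(vapply(node$branches,
                      function(br) .eval_expr(br$prob, P), numeric(1)))
      if (abs(s - 1) > 1e-12)
        stop("chance node '", node$label %||% "?",
             "': branch probabilities sum to ", format(s), call. = FALSE)
      for (br in node$branches) .check_node(br$node)
    }
  }
  .check_node(tree$root)
  tree
}

#' @export
print.cea_tree <- function(x, ...) {
  paths <- .tree_paths(x$root)
  cat("<cea_tree> strategy ", x$strategy, ": ", length(paths),
      " root-to-terminal paths\n", sep = "")
  for (p in paths) cat("  ", paste(p$labels, collapse = " > "), "\n", sep = "")
  invisible(x)
}

# Per-path quantities for a tree under a parameter set P (list of vectors of
# common length n, or scalars). Returns a list with, per path k, n-vectors
# prob[[k]], cost[[k]], qaly[[k]], and the resource-count vectors used to
# build them. This is the single evaluation engine shared by the cohort
# expectation, the PSA and the microsimulation.
.path_quantities <- function(tree, P, config) {
  paths <- .tree_paths(tree$root)
  iv <- tree$intervention
  u_episode <- config$severity_moderate * P$utility_moderate +
    config$severity_mild * P$utility_mild
  u_maint <- P$utility_maintenance
  wpy <- config$weeks_per_year
  lapply(paths, function(pth) {
    leaf <- pth$leaf
    prob <- Reduce(`*`, lapply(pth$prob_exprs, .eval_expr, P = P), 1)
    acute_frac <- .eval_expr(leaf$acute_fraction, P)
    maint_frac <- .eval_expr(leaf$maintenance_fraction, P)
    counts <- list(
      gp_plan_items = 1,
      gp_consultations = 1 +  # end-of-treatment GP review
        leaf$episode_cycles * P$gp_visits_episode +
        leaf$remission_cycles * P$gp_visits_remission,
      psychiatrist_consultations =
        leaf$episode_spells * P$psychiatrist_visits_episode,
      cbt_courses = if (identical(iv$acute, "cbt_course")) acute_frac else 0,
      booster_sessions = if (identical(iv$maintenance, "booster"))
        maint_frac * P$booster_sessions_maintenance else 0,
      mycompass_deliveries =
        if (identical(iv$acute, "mycompass")) acute_frac else 0,
      med_cycles_first_line =
        (if (identical(iv$acute, "medication")) acute_frac else 0) +
        (if (identical(iv$maintenance, "medication"))
           maint_frac * leaf$maintenance_cycles_on_treatment else 0),
      med_cycles_second_line = leaf$secondline_med_cycles
    )
    cost <- P$cost_gp_plan * counts$gp_plan_items +
      P$cost_gp_consultation * counts$gp_consultations +
      P$cost_psychiatrist_consultation * counts$psychiatrist_consultations +
      P$cost_cbt_course * counts$cbt_courses +
      P$cost_psychologist_session * counts$booster_sessions +
      P$cost_mycompass * counts$mycompass_deliveries +
      P$cost_medication_per_cycle *
        (counts$med_cycles_first_line + counts$med_cycles_second_line)
    qaly <- (leaf$episode_weeks * u_episode +
               leaf$maintenance_weeks * u_maint) / wpy
    c(list(path = paste(pth$labels, collapse = " > "),
           leaf = leaf, prob = prob, cost = cost, qaly = qaly), counts)
  })
}

#' Enumerate all root-to-terminal paths of a strategy tree
#'
#' Walks the unrolled tree under one realised parameter set and returns one
#' row per path: the path probability (branch probabilities multiplied along
#' the path), the weeks spent in the episode and remission/maintenance states,
#' the expected resource tally (fractional counts are expectations), and the
#' resulting path cost and QALYs. Path probabilities sum to one.
#'
#' @param tree a `cea_tree` from [build_strategy_tree()].
#' @param params a one-row parameter set, e.g. [point_estimates()] or one row
#'   of [sample_parameters()].
#' @param config a `cea_config`.
#' @return A tibble with one row per path.
#' @export
enumerate_paths <- function(tree, params, config = default_config()) {
  P <- as.list(params)
  stopifnot(inherits(tree, "cea_tree"))
  q <- .path_quantities(tree, P, config)
  out <- purrr::map_dfr(q, function(pk) {
    tibble::tibble(
      path = pk$path,
      probability = pk$prob,
      episode_weeks = pk$leaf$episode_weeks,
      maintenance_weeks = pk$leaf$maintenance_weeks,
      gp_plan_items = pk$gp_plan_items,
      gp_consultations = pk$gp_consultations,
      psychiatrist_consultations = pk$psychiatrist_consultations,
      cbt_courses = pk$cbt_courses,
      booster_sessions = pk$booster_sessions,
      mycompass_deliveries = pk$mycompass_deliveries,
      med_cycles_first_line = pk$med_cycles_first_line,
      med_cycles_second_line = pk$med_cycles_second_line,
      cost_aud = pk$cost,
      qaly = pk$qaly
    )
  })
  s <- sum(out$probability)
  if (abs(s - 1) > 1e-9)
    stop("path probabilities sum to ", format(s), ", not 1", call. = FALSE)
  out
}
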