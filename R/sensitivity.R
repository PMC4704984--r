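# Default one-way sweep brackets shipped for the three parameters whose
# published ranges are known; other parameters need an explicit lo/hi.
.default_brackets <- list(
  p_nonadherence_acute_mycompass = c(0, 0.35),
  cost_cbt_course = c(0, 619),
  cost_mycompass = c(0, 564)
)

# NMB of every strategy on a grid of values of one parameter, all other
# parameters held at their point estimates. Returns list(values, nmb) with
# nmb a grid x S matrix.
.sweep_nmb <- function(config, param, values, wtp, topology = NULL) {
  if (!param %in% config$parameters$name)
    stop("unknown parameter '", param, "'", call. = FALSE)
  P <- as.list(point_estimates(config))
  P[[param]] <- as.numeric(values)
  o <- .outcomes_all(config, P, topology)
  list(values = as.numeric(values), nmb = nmb(o$qaly, o$cost, wtp),
       cost = o$cost, qaly = o$qaly)
}

#' One-way (univariate) sensitivity analysis
#'
#' Deterministic sweep of a single parameter across a grid, every other
#' parameter held at its point estimate. At each grid point the expected net
#' monetary benefit of every strategy is computed and the optimal strategy
#' recorded; the reported `expected_nmb` is that of the optimal strategy (the
#' standard tornado construction).
#'
#' @param config a `cea_config`.
#' @param param parameter name to vary.
#' @param lo,hi sweep bracket; for the three parameters with published ranges
#'   (`p_nonadherence_acute_mycompass` 0–0.35, `cost_cbt_course` 0–619,
#'   `cost_mycompass` 0–564) they default to those ranges.
#' @param wtp willingness-to-pay in AUD/QALY.
#' @param grid_points number of grid points (default 101).
#' @param topology optional topology.
#' @return A tibble of class `cea_oneway` with columns `parameter`, `value`,
#'   `optimal_strategy`, `expected_nmb`; attributes `lowest` and `highest`
#'   hold the extreme expected NMB over the range, and attribute
#'   `strategy_nmb` the full per-strategy NMB grid in long form.
#' @export
one_way <- function(config, param, lo = NULL, hi = NULL,
                    wtp = config$wtp_default, grid_points = 101,
                    topology = NULL) {
  validate_config(config)
  br <- .default_brackets[[param]]
  lo <- lo %||% br[1]
  hi <- hi %||% br[2]
  if (is.null(lo) || is.null(hi))
    stop("no default bracket for '", param, "'; supply lo and hi",
         call. = FALSE)
  if (lo > hi) stop("one_way requires lo <= hi", call. = FALSE)
  values <- if (lo == hi) rep(lo, grid_points)
            else seq(lo, hi, length.out = grid_points)
  sw <- .sweep_nmb(config, param, values, wtp, topology)
  win <- .winner_index(sw$nmb, sw$cost)
  strategies <- config$strategies
  out <- tibble::tibble(
    parameter = param,
    value = sw$values,
    optimal_strategy = strategies[win],
    expected_nmb = sw$nmb[cbind(seq_along(win), win)]
  )
  attr(out, "lowest") <- min(out$expected_nmb)
  attr(out, "highest") <- max(out$expected_nmb)
  attr(out, "wtp") <- wtp
  attr(out, "strategy_nmb") <- tibble::tibble(
    value = rep(sw$values, times = length(strategies)),
    strategy = rep(strategies, each = length(sw$values)),
    nmb = as.vector(sw$nmb)
  )
  class(out) <- c("cea_oneway", class(out))
  out
}

#' Threshold analysis on one parameter
#'
#' Finds the parameter value at which the identity of the NMB-optimal
#' strategy changes, by bisection on the sign of the incumbent's NMB margin
#' (`NMB` of the strategy optimal at `lo` minus the best of the others) to an
#' absolute tolerance of 0.01 in the parameter's units. A coarse scan first
#' brackets the earliest crossing; if the optimal strategy is constant over
#' `[lo, hi]` no threshold is reported.
#'
#' @param config a `cea_config`.
#' @param param parameter name to vary.
#' @param lo,hi search bracket (lo < hi).
#' @param wtp willingness-to-pay in AUD/QALY.
#' @param tol absolute tolerance in parameter units (default 0.01).
#' @param topology optional topology.
#' @return A one-row tibble: `parameter`, `found`, `threshold` (NA when no
#'   change), `strategy_below`, `strategy_above`, `wtp`.
#' @export
threshold_search <- function(config, param, lo, hi,
                             wtp = config$wtp_default, tol = 0.01,
                             topology = NULL) {
  validate_config(config)
  if (!(lo < hi)) stop("threshold_search requires lo < hi", call. = FALSE)
  topo <- if (is.list(topology) && !is.null(topology$strategies)) topology
          else read_topology(topology)
  strategies <- config$strategies
  opt_at <- function(x) {
    sw <- .sweep_nmb(config, param, x, wtp, topo)
    strategies[.winner_index(sw$nmb, sw$cost)]
  }
  incumbent <- opt_at(lo)
  # margin of the incumbent over the best alternative; positive while the
  # incumbent stays optimal
  margin <- function(x) {
    sw <- .sweep_nmb(config, param, x, wtp, topo)
    i <- match(incumbent, strategies)
    sw$nmb[, i] - apply(sw$nmb[, -i, drop = FALSE], 1, max)
  }
  grid <- seq(lo, hi, length.out = 257)
  g <- margin(grid)
  flip <- which(g[-1] <= 0 & g[-length(g)] > 0)
  if (!length(flip))
    return(tibble::tibble(parameter = param, found = FALSE,
                          threshold = NA_real_,
                          strategy_below = incumbent,
                          strategy_above = incumbent, wtp = wtp))
  a <- grid[flip[1]]; b <- grid[flip[1] + 1]
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (margin(mid) > 0) a <- mid else b <- mid
  }
  thr <- (a + b) / 2
  tibble::tibble(
    parameter = param,
    found = TRUE,
    threshold = thr,
    strategy_below = opt_at(max(lo, thr - tol)),
    strategy_above = opt_at(min(hi, thr + tol)),
    wtp = wtp
  )
}
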