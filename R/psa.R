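#' Probabilistic sensitivity analysis
#'
#' Propagates the parameter uncertainty distributions through the cohort
#' model: each iteration draws one parameter set (common random numbers — the
#' same draw is applied to all strategies, the only coherent choice when
#' utilities and switch probabilities are shared) and records the expected
#' cost and QALYs of every strategy under that draw.
#'
#' @param config a `cea_config`.
#' @param n iteration count (default `config$psa_iterations`).
#' @param seed integer root seed; the same seed reproduces all values
#'   bit-identically.
#' @param topology optional topology (path or list).
#' @return An object of class `cea_psa`: a list with `draws` (tibble
#'   `iteration`, `strategy`, `cost_aud`, `qaly`), `params` (the sampled
#'   parameter sets, one row per iteration), `n`, `seed` and `config`.
#' @examples
#' psa <- run_psa(default_config(), n = 200, seed = 1)
#' summarize_psa(psa, wtp = 50000)
#' @export
run_psa <- function(config, n = config$psa_iterations, seed = 1L,
                    topology = NULL) {
  validate_config(config)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  params <- sample_parameters(config, n, seed)
  o <- .outcomes_all(config, as.list(params), topology)
  stopifnot(all(o$cost >= 0),
            all(o$qaly >= 0),
            all(o$qaly <= 28 / config$weeks_per_year + 1e-12))
  draws <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(iteration = seq_len(n)),
      tibble::as_tibble(o$cost) |>
        stats::setNames(paste0("cost.", config$strategies)),
      tibble::as_tibble(o$qaly) |>
        stats::setNames(paste0("qaly.", config$strategies))
    ),
    cols = -"iteration",
    names_to = c(".value", "strategy"), names_sep = "\\."
  )
  structure(
    list(draws = dplyr::select(draws, "iteration", "strategy",
                               cost_aud = "cost", "qaly"),
         params = params, n = as.integer(n), seed = as.integer(seed),
         config = config),
    class = "cea_psa"
  )
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("<cea_psa> ", x$n, " iterations, seed ", x$seed, ", strategies: ",
      paste(x$config$strategies, collapse = " / "), "\n", sep = "")
  print(summarize_psa(x, wtp = x$config$wtp_default))
  invisible(x)
}

# n x S matrices of cost and qaly from a cea_psa
.psa_matrices <- function(psa) {
  strategies <- psa$config$strategies
  d <- psa$draws
  cost <- qaly <- matrix(0, psa$n, length(strategies),
                         dimnames = list(NULL, strategies))
  for (s in strategies) {
    ds <- d[d$strategy == s, ]
    ds <- ds[order(ds$iteration), ]
    cost[, s] <- ds$cost_aud
    qaly[, s] <- ds$qaly
  }
  list(cost = cost, qaly = qaly)
}

#' Summarise PSA draws
#'
#' Per-strategy means and equal-tailed 95% credible intervals (empirical
#' 2.5/97.5 percentiles, no smoothing) of cost, QALYs and net monetary
#' benefit, plus the average cost-effectiveness ratio (mean cost / mean
#' QALY).
#'
#' @param psa a `cea_psa` with at least two iterations.
#' @param wtp willingness-to-pay in AUD/QALY.
#' @return A tibble with one row per strategy.
#' @export
summarize_psa <- function(psa, wtp = psa$config$wtp_default) {
  stopifnot(inherits(psa, "cea_psa"))
  if (psa$n < 2) stop("summarize_psa needs n >= 2 iterations", call. = FALSE)
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  m <- .psa_matrices(psa)
  purrr::map_dfr(psa$config$strategies, function(s) {
    cost <- m$cost[, s]; qaly <- m$qaly[, s]
    v <- nmb(qaly, cost, wtp)
    cci <- ci(cost); qci <- ci(qaly); nci <- ci(v)
    tibble::tibble(
      strategy = s,
      mean_cost = mean(cost), cost_lo = cci[1], cost_hi = cci[2],
      mean_qaly = mean(qaly), qaly_lo = qci[1], qaly_hi = qci[2],
      mean_nmb = mean(v), nmb_lo = nci[1], nmb_hi = nci[2],
      avg_cer = average_cer(mean(cost), mean(qaly))
    )
  })
}

# Index of the NMB-optimal strategy per iteration, with deterministic ties:
# highest NMB, then lowest cost, then declaration order.
.winner_index <- function(nmb_mat, cost_mat) {
  n <- nrow(nmb_mat)
  best <- rep(1L, n)
  bv <- nmb_mat[, 1]
  bc <- cost_mat[, 1]
  for (s in seq_len(ncol(nmb_mat))[-1]) {
    up <- nmb_mat[, s] > bv |
      (nmb_mat[, s] == bv & cost_mat[, s] < bc)
    best[up] <- s
    bv[up] <- nmb_mat[up, s]
    bc[up] <- cost_mat[up, s]
  }
  best
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in which
#' each strategy attains the highest net monetary benefit. Ties (probability
#' zero under continuous draws, but possible for degenerate configurations)
#' are broken by lowest cost, then strategy declaration order. At a
#' willingness-to-pay of zero the winner is the minimum-cost strategy by
#' construction.
#'
#' @param psa a `cea_psa`.
#' @param wtp_grid nonempty vector of willingness-to-pay values (default: the
#'   config's grid, 0 to 100,000 in steps of 1,000).
#' @return A tibble of class `cea_ceac` with columns `wtp`, `strategy`,
#'   `probability`; at each `wtp` the probabilities sum to 1.
#' @export
ceac <- function(psa, wtp_grid = psa$config$wtp_grid) {
  stopifnot(inherits(psa, "cea_psa"))
  if (!length(wtp_grid)) stop("wtp_grid must be nonempty", call. = FALSE)
  m <- .psa_matrices(psa)
  strategies <- psa$config$strategies
  out <- purrr::map_dfr(wtp_grid, function(l) {
    win <- .winner_index(nmb(m$qaly, m$cost, l), m$cost)
    tibble::tibble(
      wtp = l,
      strategy = strategies,
      probability = tabulate(win, nbins = length(strategies)) / psa$n
    )
  })
  class(out) <- c("cea_ceac", class(out))
  out
}

#' Export the cost-effectiveness plane
#'
#' Writes the per-iteration incremental pairs of every comparator against the
#' reference strategy — one row per iteration and comparator with columns
#' `iteration`, `comparator`, `delta_qaly`, `delta_cost_aud` (deltas are
#' comparator minus reference) — at full precision, so re-importing the file
#' reproduces the values exactly.
#'
#' @param psa a `cea_psa`.
#' @param reference reference strategy name (default `"myCompass"`).
#' @param path output CSV path, or `NULL` to skip writing.
#' @return The exported tibble, invisibly.
#' @export
export_ce_plane <- function(psa, reference = "myCompass", path = NULL) {
  stopifnot(inherits(psa, "cea_psa"))
  strategies <- psa$config$strategies
  if (!reference %in% strategies)
    stop("reference strategy '", reference, "' not in PSA", call. = FALSE)
  m <- .psa_matrices(psa)
  out <- purrr::map_dfr(setdiff(strategies, reference), function(s) {
    tibble::tibble(
      iteration = seq_len(psa$n),
      comparator = s,
      delta_qaly = m$qaly[, s] - m$qaly[, reference],
      delta_cost_aud = m$cost[, s] - m$cost[, reference]
    )
  })
  if (!is.null(path)) .write_csv_full(out, path)
  invisible(out)
}
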