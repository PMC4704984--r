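#' Per-patient expected value of perfect information
#'
#' `EVPI = E[max_s NMB_s] - max_s E[NMB_s]` over the PSA draws: the expected
#' gain from learning all parameters before choosing a strategy. Always
#' nonnegative, and exactly zero when every iteration is won by the same
#' strategy. The Monte-Carlo standard error is estimated by a bootstrap over
#' iterations.
#'
#' @param psa a `cea_psa` with at least two iterations.
#' @param wtp willingness-to-pay in AUD/QALY.
#' @param n_boot bootstrap resamples for the standard error (default 500).
#' @return A one-row tibble of class `cea_voi`: `kind`, `parameter` (NA),
#'   `wtp`, `value` (AUD per patient), `mc_se`, `method`, `n`.
#' @export
evpi <- function(psa, wtp = psa$config$wtp_default, n_boot = 500) {
  stopifnot(inherits(psa, "cea_psa"))
  if (psa$n < 2) stop("evpi needs n >= 2 iterations", call. = FALSE)
  m <- .psa_matrices(psa)
  v <- nmb(m$qaly, m$cost, wtp)
  rmax <- do.call(pmax, as.data.frame(v))
  value <- mean(rmax) - max(colMeans(v))
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(psa$n, psa$n, replace = TRUE)
    mean(rmax[i]) - max(colMeans(v[i, , drop = FALSE]))
  }, numeric(1))
  out <- tibble::tibble(kind = "EVPI", parameter = NA_character_, wtp = wtp,
                        value = value, mc_se = stats::sd(boot),
                        method = "psa", n = psa$n)
  class(out) <- c("cea_voi", class(out))
  out
}

# Generic two-level nested Monte-Carlo EVPPI engine.
#   draw_target(k)  -> k draws of the parameter(s) of interest (vector)
#   draw_rest(k)    -> k draws of all remaining uncertain parameters (list of
#                      vectors, possibly empty)
#   nmb_fun(target, rest) -> n x S matrix of NMB, vectorised over rows
# EVPPI = mean over outer draws of max_s (inner-mean NMB_s) - max_s mean NMB_s.
# The reported SE captures the outer-level Monte-Carlo error of the first
# term (the dominant component).
.evppi_nested_engine <- function(draw_target, draw_rest, nmb_fun,
                                 outer, inner) {
  theta <- draw_target(outer)
  rest <- draw_rest(outer * inner)
  v <- nmb_fun(rep(theta, each = inner), rest)
  grp <- rep(seq_len(outer), each = inner)
  inner_means <- rowsum(v, grp) / inner            # outer x S
  outer_max <- do.call(pmax, as.data.frame(inner_means))
  value <- mean(outer_max) - max(colMeans(v))
  list(value = value, se = stats::sd(outer_max) / sqrt(outer))
}

#' Expected value of partial perfect information for one parameter
#'
#' Two estimators with the same contract:
#' \describe{
#'   \item{`nested`}{two-level Monte Carlo — `outer` draws of the target
#'     parameter, `inner` draws of all other uncertain parameters per outer
#'     draw; `EVPPI = E_theta[max_s E[NMB_s | theta]] - max_s E[NMB_s]`. The
#'     standard error reflects the outer-level Monte-Carlo error.}
#'   \item{`regression`}{single-loop estimator: on an ordinary PSA, each
#'     strategy's NMB is regressed on the target parameter with a spline
#'     smoother (`mgcv::gam`), and the fitted conditional expectations
#'     replace the inner loop. The standard error is a bootstrap over the
#'     fitted values and is approximate.}
#' }
#' A parameter with a degenerate (fixed) distribution carries no information
#' value: the estimate is 0 and flagged.
#'
#' @param config a `cea_config`.
#' @param param name of the parameter of interest.
#' @param wtp willingness-to-pay in AUD/QALY.
#' @param outer,inner nested Monte-Carlo sample sizes (defaults 1000/1000).
#' @param seed integer root seed.
#' @param method `"nested"` or `"regression"`.
#' @param draws optional `cea_psa` reused by the regression method; when
#'   `NULL` a PSA of `config$psa_iterations` iterations is run.
#' @param topology optional topology.
#' @return A one-row tibble of class `cea_voi`: `kind`, `parameter`, `wtp`,
#'   `value`, `mc_se`, `method`, `n`, `degenerate`.
#' @export
evppi <- function(config, param, wtp = config$wtp_default,
                  outer = 1000, inner = 1000, seed = 1L,
                  method = c("nested", "regression"), draws = NULL,
                  topology = NULL) {
  validate_config(config)
  method <- match.arg(method)
  spec <- config$parameters[config$parameters$name == param, ]
  if (nrow(spec) != 1)
    stop("unknown parameter '", param, "'", call. = FALSE)
  if (spec$dist == "fixed") {
    out <- tibble::tibble(kind = "EVPPI", parameter = param, wtp = wtp,
                          value = 0, mc_se = 0, method = method,
                          n = 0L, degenerate = TRUE)
    class(out) <- c("cea_voi", class(out))
    return(out)
  }
  topo <- if (is.list(topology) && !is.null(topology$strategies)) topology
          else read_topology(topology)
  if (method == "nested") {
    others <- config$parameters[config$parameters$name != param &
                                  config$parameters$dist != "fixed", ]
    fixed <- config$parameters[config$parameters$dist == "fixed", ]
    Pfix <- stats::setNames(as.list(fixed$point_estimate), fixed$name)
    est <- .evppi_nested_engine(
      draw_target = function(k) .sample_one(as.list(spec), k, seed),
      draw_rest = function(k) {
        stats::setNames(
          lapply(seq_len(nrow(others)),
                 function(i) .sample_one(as.list(others[i, ]), k, seed)),
          others$name
        )
      },
      nmb_fun = function(target, rest) {
        P <- c(stats::setNames(list(target), param), rest, Pfix)
        o <- .outcomes_all(config, P, topo)
        nmb(o$qaly, o$cost, wtp)
      },
      outer = outer, inner = inner
    )
    n_used <- as.integer(outer) * as.integer(inner)
    value <- est$value; se <- est$se
  } else {
    psa <- draws %||% run_psa(config, n = config$psa_iterations, seed = seed,
                              topology = topo)
    m <- .psa_matrices(psa)
    v <- nmb(m$qaly, m$cost, wtp)
    x <- psa$params[[param]]
    fitted <- vapply(seq_len(ncol(v)), function(s) {
      stats::fitted(mgcv::gam(y ~ s(x), data = data.frame(y = v[, s], x = x)))
    }, numeric(nrow(v)))
    value <- mean(do.call(pmax, as.data.frame(fitted))) -
      max(colMeans(fitted))
    boot <- vapply(seq_len(200), function(b) {
      i <- sample.int(nrow(fitted), nrow(fitted), replace = TRUE)
      mean(do.call(pmax, as.data.frame(fitted[i, , drop = FALSE]))) -
        max(colMeans(fitted[i, , drop = FALSE]))
    }, numeric(1))
    se <- stats::sd(boot)
    n_used <- psa$n
  }
  out <- tibble::tibble(kind = "EVPPI", parameter = param, wtp = wtp,
                        value = value, mc_se = se, method = method,
                        n = n_used, degenerate = FALSE)
  class(out) <- c("cea_voi", class(out))
  out
}

#' EVPPI of every uncertain parameter
#'
#' Convenience wrapper computing the single-loop regression EVPPI of every
#' non-fixed parameter on one shared set of PSA draws, returned in
#' descending order of information value.
#'
#' @param config a `cea_config`.
#' @param wtp willingness-to-pay in AUD/QALY.
#' @param seed integer root seed (used when `draws` is NULL).
#' @param draws optional `cea_psa` to reuse.
#' @param topology optional topology.
#' @return A tibble of class `cea_voi`, one row per uncertain parameter.
#' @export
evppi_all <- function(config, wtp = config$wtp_default, seed = 1L,
                      draws = NULL, topology = NULL) {
  validate_config(config)
  psa <- draws %||% run_psa(config, n = config$psa_iterations, seed = seed,
                            topology = topology)
  params <- config$parameters$name[config$parameters$dist != "fixed"]
  out <- purrr::map_dfr(params, function(p)
    evppi(config, p, wtp = wtp, method = "regression", draws = psa,
          topology = topology))
  out <- dplyr::arrange(out, dplyr::desc(.data$value))
  class(out) <- c("cea_voi", class(out))
  out
}

#' Scale per-patient EVPI to the eligible population
#'
#' Multiplies the per-patient value by the eligible treated population over a
#' one-year horizon: the population with a mental illness, the proportion
#' with a mood disorder, the mild+moderate treatment-presentation mix, and an
#' assumed acceptability rate.
#'
#' @param per_patient per-patient EVPI in AUD.
#' @param population population with a mental illness (default 4.4 million).
#' @param proportion_mood proportion with a mood disorder (default 0.206).
#' @param treatment_mix treatment presentation rates, mild 25% + moderate 59%
#'   summed (default 0.84).
#' @param acceptability assumed acceptability rate (default 0.02).
#' @param horizon_years time horizon in years (default 1).
#' @return Population EVPI in AUD (unrounded; reports round to the nearest
#'   AUD).
#' @examples
#' round(population_evpi(79.37))  # 1208608
#' @export
population_evpi <- function(per_patient, population = 4.4e6,
                            proportion_mood = 0.206, treatment_mix = 0.84,
                            acceptability = 0.02, horizon_years = 1) {
  props <- c(proportion_mood, treatment_mix, acceptability)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (population <= 0) stop("population must be > 0", call. = FALSE)
  per_patient * population * proportion_mood * treatment_mix *
    acceptability * horizon_years
}
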