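#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PSA object
#'
#' One row per strategy with means, 95% credible intervals and the average
#' cost-effectiveness ratio (see [summarize_psa()]).
#'
#' @param x a `cea_psa`.
#' @param wtp willingness-to-pay in AUD/QALY.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.cea_psa <- function(x, wtp = x$config$wtp_default, ...) {
  summarize_psa(x, wtp = wtp)
}

#' Glance at a PSA object
#'
#' @param x a `cea_psa`.
#' @param ... unused.
#' @return A one-row tibble: iteration count, seed, number of strategies,
#'   number of uncertain parameters, default willingness-to-pay.
#' @export
glance.cea_psa <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    seed = x$seed,
    n_strategies = length(x$config$strategies),
    n_uncertain_parameters = sum(x$config$parameters$dist != "fixed"),
    wtp_default = x$config$wtp_default
  )
}

#' @export
tidy.cea_ceac <- function(x, ...) tibble::as_tibble(unclass(x))

#' Tidy a one-way sensitivity sweep
#'
#' @param x a `cea_oneway`.
#' @param ... unused.
#' @return The sweep as a plain tibble.
#' @export
tidy.cea_oneway <- function(x, ...) tibble::as_tibble(unclass(x))

#' Glance at a one-way sensitivity sweep
#'
#' @param x a `cea_oneway`.
#' @param ... unused.
#' @return A one-row tibble with the parameter, range, and the lowest and
#'   highest expected NMB over the sweep.
#' @export
glance.cea_oneway <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter[1],
    lo = min(x$value), hi = max(x$value),
    wtp = attr(x, "wtp"),
    lowest_expected_nmb = attr(x, "lowest"),
    highest_expected_nmb = attr(x, "highest")
  )
}

#' @export
tidy.cea_voi <- function(x, ...) tibble::as_tibble(unclass(x))
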