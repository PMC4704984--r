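#' Analytic mean of a parameter's uncertainty distribution
#'
#' beta(a, b) has mean a/(a+b); lognormal(mu, sigma) has mean
#' exp(mu + sigma^2/2); a fixed parameter's mean is its point estimate; a
#' uniform's mean is the midpoint of its arguments.
#'
#' @param spec a single parameter specification: one row of
#'   `config$parameters` (or an equivalent list with fields `dist`, `a`, `b`,
#'   `point_estimate`).
#' @return The analytic mean, a single number.
#' @examples
#' cfg <- default_config()
#' spec <- dplyr::filter(cfg$parameters, name == "eff_maintenance_tau")
#' distribution_mean(spec)  # 1075/2876 = 0.374 at 3 dp
#' @export
distribution_mean <- function(spec) {
  spec <- as.list(spec)
  if (length(spec$dist) != 1)
    stop("distribution_mean() expects a single parameter spec", call. = FALSE)
  switch(spec$dist,
    beta = spec$a / (spec$a + spec$b),
    lognormal = exp(spec$a + spec$b^2 / 2),
    uniform = (spec$a + spec$b) / 2,
    fixed = spec$point_estimate,
    stop("unknown distribution '", spec$dist, "'", call. = FALSE)
  )
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive a
# per-parameter substream seed from the root seed, so that adding or reordering
# parameters does not reshuffle the draws of the others.
.hash31 <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  m <- 2147483647
  for (ch in v) h <- (h * 131 + ch) %% m
  h
}

.param_seed <- function(root_seed, name) {
  (as.numeric(root_seed) %% 2147483647 + .hash31(name)) %% 2147483647
}

# Draw n values for one parameter spec under its own substream. Lognormal
# draws outside the parameter's bounds (a probability-role parameter is
# bounded above by 1) are resampled until inside.
.sample_one <- function(spec, n, root_seed) {
  set.seed(.param_seed(root_seed, spec$name))
  draw <- switch(spec$dist,
    beta = function(k) stats::rbeta(k, spec$a, spec$b),
    lognormal = function(k) stats::rlnorm(k, spec$a, spec$b),
    uniform = function(k) stats::runif(k, spec$a, spec$b),
    fixed = function(k) rep(spec$point_estimate, k)
  )
  x <- draw(n)
  bad <- which(x < spec$lo | x > spec$hi)
  guard <- 0
  while (length(bad)) {
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] < spec$lo | x[bad] > spec$hi]
    guard <- guard + 1
    if (guard > 1000)
      stop("parameter '", spec$name,
           "': distribution mass lies almost entirely outside bounds",
           call. = FALSE)
  }
  x
}

#' Sample parameter sets for probabilistic analysis
#'
#' Draws `n` independent parameter sets, each parameter from its own
#' uncertainty distribution; fixed parameters stay at their point estimates.
#' Each parameter uses a deterministic substream derived from the root seed
#' and the parameter's name, so the same seed always reproduces the same
#' draws and adding a new parameter leaves the others' draws unchanged.
#' Draws falling outside a parameter's bounds (only possible for the
#' lognormal) are resampled.
#'
#' @param config a `cea_config`.
#' @param n number of draws (>= 1).
#' @param seed integer root seed.
#' @return A tibble with `n` rows and one column per parameter.
#' @export
sample_parameters <- function(config, n, seed) {
  validate_config(config)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  p <- config$parameters
  cols <- purrr::map(seq_len(nrow(p)),
                     function(i) .sample_one(as.list(p[i, ]), n, seed))
  tibble::as_tibble(stats::setNames(cols, p$name))
}
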