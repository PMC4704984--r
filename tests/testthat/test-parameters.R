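test_that("packaged default config reproduces the published parameter table", {
  p <- cfg0$parameters
  row <- function(nm) p[p$name == nm, ]
  # spot checks across every block of the table
  expect_equal(row("utility_maintenance")$point_estimate, 0.88)
  expect_equal(row("utility_mild")$point_estimate, 0.78)
  expect_equal(row("utility_moderate")$point_estimate, 0.58)
  expect_equal(row("eff_initial_tau")$point_estimate, 0.462)
  expect_equal(row("eff_initial_cbt")$point_estimate, 0.479)
  expect_equal(row("eff_initial_mycompass")$point_estimate, 0.449)
  expect_equal(row("eff_maintenance_cbt")$point_estimate, 0.559)
  expect_equal(row("p_return_to_treatment")$point_estimate, 0.4)
  expect_equal(row("gp_visits_episode")$point_estimate, 2.48)
  expect_equal(row("gp_visits_remission")$point_estimate, 1.89)
  expect_equal(row("psychiatrist_visits_episode")$point_estimate, 0.056)
  expect_equal(unlist(row("p_remit_switch_after_cbt")[, c("a", "b")],
                      use.names = FALSE), c(-0.713, 0.188))
  expect_equal(row("p_nonadherence_acute_mycompass")$a, 201)
  expect_equal(row("p_nonadherence_acute_mycompass")$b, 519)
  # unit costs
  costs <- c(cost_gp_plan = 71.70, cost_gp_consultation = 36.88,
             cost_psychiatrist_consultation = 367.80,
             cost_psychologist_session = 141.87,
             cost_cbt_course = 737.72, cost_mycompass = 56.39)
  for (nm in names(costs)) expect_equal(row(nm)$point_estimate, costs[[nm]])
  # the packaged JSON equals the in-code default
  cfg_file <- read_config(system.file("extdata", "default_config.json",
                                      package = "stepcea"))
  expect_equal(cfg_file, cfg0)
})

test_that("config validation names the offending field", {
  bad <- cfg0
  bad$severity_moderate <- 0.5
  bad$severity_mild <- 0.6
  expect_error(validate_config(bad), "severity")

  bad <- cfg0
  bad$parameters$point_estimate[bad$parameters$name == "utility_mild"] <- 1.4
  expect_error(validate_config(bad), "utility_mild")

  bad <- cfg0
  bad$parameters$a[bad$parameters$name == "eff_initial_tau"] <- -2
  expect_error(validate_config(bad), "eff_initial_tau")

  bad <- cfg0
  bad$parameters$dist[1] <- "gamma"
  expect_error(validate_config(bad), "unknown distribution")

  bad <- cfg0
  bad$wtp_grid <- c(0, 0)
  expect_error(validate_config(bad), "wtp_grid")
})

test_that("config round-trips losslessly through the JSON schema", {
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg0, path)
  expect_equal(read_config(path), cfg0)
  # malformed file: drop a required field from one parameter block
  x <- jsonlite::read_json(path)
  x$parameters[[1]]$distribution <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_config(path), "missing field 'distribution'")
})

test_that("distribution_mean matches the analytic forms", {
  mk <- function(dist, a = NA, b = NA, pt = NA)
    list(name = "x", dist = dist, a = a, b = b, point_estimate = pt)
  expect_equal(distribution_mean(mk("beta", 1075, 1801)), 1075 / 2876)
  expect_equal(round(distribution_mean(mk("beta", 1075, 1801)), 3), 0.374)
  expect_equal(distribution_mean(mk("beta", 1, 1)), 0.5)
  # independent closed form computed in place
  expect_equal(distribution_mean(mk("lognormal", -0.713, 0.188)),
               exp(-0.713 + 0.188^2 / 2))
  expect_equal(round(distribution_mean(mk("lognormal", -0.713, 0.188)), 3),
               0.499)
  expect_equal(distribution_mean(mk("uniform", 2, 6)), 4)
  expect_equal(distribution_mean(mk("fixed", pt = 0.4)), 0.4)
})

test_that("Beta rows whose printed point estimate equals alpha/(alpha+beta) match at 3 dp", {
  matching <- c(
    eff_maintenance_tau = 0.374,
    eff_maintenance_mycompass = 0.349,
    p_remit_switch_antidepressant = 0.306,
    p_nonadherence_acute_tau = 0.163,
    p_nonadherence_acute_mycompass = 0.279,
    p_nonadherence_maintenance_tau = 0.336,
    p_nonadherence_maintenance_cbt = 0.184,
    p_nonadherence_maintenance_mycompass = 0.486
  )
  for (nm in names(matching)) {
    spec <- cfg0$parameters[cfg0$parameters$name == nm, ]
    expect_equal(round(distribution_mean(spec), 3), unname(matching[nm]),
                 info = nm)
    expect_equal(spec$point_estimate, unname(matching[nm]), info = nm)
  }
})

test_that("sampling is seed-reproducible, bounded, and moment-faithful", {
  d1 <- sample_parameters(cfg0, 2, seed = 1)
  d2 <- sample_parameters(cfg0, 2, seed = 1)
  expect_identical(d1, d2)
  expect_false(isTRUE(all.equal(d1, sample_parameters(cfg0, 2, seed = 2))))

  n <- 10000
  d <- sample_parameters(cfg0, n, seed = 7)
  # all probability/utility draws in [0, 1]
  pnames <- cfg0$parameters$name[cfg0$parameters$role %in%
                                   c("probability", "utility")]
  for (nm in pnames) expect_true(all(d[[nm]] >= 0 & d[[nm]] <= 1), info = nm)
  # fixed parameters constant
  expect_true(all(d$cost_cbt_course == 737.72))
  # empirical mean within 4 Monte-Carlo SE of the analytic Beta moments
  a <- 350; b <- 370
  se <- sqrt(a * b / ((a + b)^2 * (a + b + 1))) / sqrt(n)
  expect_lt(abs(mean(d$p_nonadherence_maintenance_mycompass) - a / (a + b)),
            4 * se)
  expect_error(sample_parameters(cfg0, 0, seed = 1), ">= 1")
})

test_that("adding a parameter does not reshuffle the other parameters' draws", {
  d1 <- sample_parameters(cfg0, 50, seed = 11)
  cfg2 <- cfg0
  cfg2$parameters <- dplyr::bind_rows(
    tibble::tibble(name = "aaa_new_param", role = "probability",
                   point_estimate = 0.5, dist = "beta", a = 2, b = 2,
                   lo = 0, hi = 1, source_note = "synthetic extra"),
    cfg2$parameters
  )
  d2 <- sample_parameters(validate_config(cfg2), 50, seed = 11)
  expect_identical(d1, d2[names(d1)])
})

test_that("lognormal draws for a probability-role parameter are truncated at 1 by resampling", {
  cfg <- cfg0
  i <- match("p_remit_switch_after_cbt", cfg$parameters$name)
  cfg$parameters$a[i] <- 0.3  # mean exp(0.3) > 1: heavy truncation
  d <- sample_parameters(cfg, 2000, seed = 3)
  expect_true(all(d$p_remit_switch_after_cbt <= 1))
  expect_true(all(d$p_remit_switch_after_cbt >= 0))
})
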