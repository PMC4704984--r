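test_that("degenerate distributions reproduce the deterministic result in every iteration", {
  cfg <- all_fixed_config()
  psa <- run_psa(cfg, n = 10, seed = 1)
  bc <- base_case(cfg)
  for (s in cfg$strategies) {
    d <- psa$draws[psa$draws$strategy == s, ]
    expect_equal(d$cost_aud, rep(bc$cost_aud[bc$strategy == s], 10))
    expect_equal(d$qaly, rep(bc$qaly[bc$strategy == s], 10))
  }
})

test_that("the same seed reproduces the PSA bit-identically", {
  p1 <- run_psa(cfg0, n = 50, seed = 3)
  p2 <- run_psa(cfg0, n = 50, seed = 3)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$params, p2$params)
})

test_that("PSA means are stable across seeds within Monte-Carlo error", {
  n <- 2000
  p1 <- run_psa(cfg0, n = n, seed = 101)
  p2 <- run_psa(cfg0, n = n, seed = 202)
  m1 <- .psa_matrices(p1); m2 <- .psa_matrices(p2)
  for (s in cfg0$strategies) {
    se <- sqrt(stats::var(m1$cost[, s]) / n + stats::var(m2$cost[, s]) / n)
    expect_lt(abs(mean(m1$cost[, s]) - mean(m2$cost[, s])), 4 * se, label = s)
    se <- sqrt(stats::var(m1$qaly[, s]) / n + stats::var(m2$qaly[, s]) / n)
    expect_lt(abs(mean(m1$qaly[, s]) - mean(m2$qaly[, s])), 4 * se, label = s)
  }
})

test_that("summarize_psa reports means, percentile intervals and average CER", {
  # constant draws: CI collapses onto the mean; NMB = 0.2*50000 - 100 = 9900
  psa <- fake_psa(matrix(100, 50, 3), matrix(0.2, 50, 3))
  s <- summarize_psa(psa, wtp = 50000)
  expect_equal(s$mean_nmb, rep(9900, 3))
  expect_equal(s$nmb_lo, rep(9900, 3))
  expect_equal(s$nmb_hi, rep(9900, 3))
  # printed-table identity: constant (524.91, 0.24) draws
  psa <- fake_psa(matrix(524.91, 10, 3), matrix(0.24, 10, 3))
  expect_lt(abs(summarize_psa(psa, 50000)$avg_cer[1] - 2187.13), 0.01)
  expect_error(summarize_psa(fake_psa(matrix(1, 1, 3), matrix(0, 1, 3))),
               "n >= 2")

  # percentile bounds agree with an independent type-7 interpolation oracle
  psa <- run_psa(cfg0, n = 500, seed = 13)
  m <- .psa_matrices(psa)
  s <- summarize_psa(psa, wtp = 50000)
  q7 <- function(x, p) {             # textbook type-7 formula
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  for (i in seq_along(cfg0$strategies)) {
    cost <- m$cost[, cfg0$strategies[i]]
    expect_lt(abs(s$cost_lo[i] - q7(cost, 0.025)), 1e-9)
    expect_lt(abs(s$cost_hi[i] - q7(cost, 0.975)), 1e-9)
  }
})

test_that("CEAC probabilities are exhaustive, exclusive and anchored at lambda = 0", {
  psa <- run_psa(cfg0, n = 500, seed = 23)
  cc <- ceac(psa, wtp_grid = seq(0, 100000, by = 10000))
  sums <- dplyr::summarise(dplyr::group_by(cc, wtp),
                           total = sum(probability))
  expect_equal(sums$total, rep(1, nrow(sums)))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))

  # independent recount at lambda = 0: winner is the min-cost strategy
  m <- .psa_matrices(psa)
  lowest <- apply(m$cost, 1, which.min)
  at0 <- cc[cc$wtp == 0, ]
  for (i in seq_along(cfg0$strategies)) {
    expect_equal(at0$probability[at0$strategy == cfg0$strategies[i]],
                 mean(lowest == i))
  }

  # independent recount of the argmax at one interior lambda
  v <- nmb(m$qaly, m$cost, 50000)
  wins <- apply(v, 1, which.max)     # no ties under continuous draws
  at50 <- ceac(psa, wtp_grid = 50000)
  for (i in seq_along(cfg0$strategies)) {
    expect_equal(at50$probability[at50$strategy == cfg0$strategies[i]],
                 mean(wins == i))
  }

  # a strategy dominating every iteration gets probability 1 at every lambda
  cost <- cbind(TAU = rep(500, 20), CBT = rep(900, 20), myCompass = rep(100, 20))
  qaly <- cbind(TAU = rep(0.2, 20), CBT = rep(0.25, 20), myCompass = rep(0.3, 20))
  cc <- ceac(fake_psa(cost, qaly), wtp_grid = c(0, 1e4, 1e5))
  expect_equal(cc$probability[cc$strategy == "myCompass"], rep(1, 3))
  expect_error(ceac(fake_psa(cost, qaly), wtp_grid = numeric()), "nonempty")
})

test_that("CEAC ties break by lowest cost, then declaration order", {
  # identical NMB everywhere: cheaper strategy wins; fully identical rows
  # fall to the first declared strategy
  cost <- cbind(TAU = rep(200, 5), CBT = rep(100, 5), myCompass = rep(300, 5))
  qaly <- cbind(TAU = rep(0.2, 5), CBT = rep(0.2, 5), myCompass = rep(0.2, 5))
  cc <- ceac(fake_psa(cost, qaly + (cost - 200) / 5e4), wtp_grid = 50000)
  # NMB equal for all three at wtp 50000 by construction; CBT is cheapest
  expect_equal(cc$probability[cc$strategy == "CBT"], 1)
  cc <- ceac(fake_psa(cost * 0 + 100, qaly), wtp_grid = 50000)
  expect_equal(cc$probability[cc$strategy == "TAU"], 1)
})

test_that("the cost-effectiveness plane export round-trips at full precision", {
  psa <- run_psa(cfg0, n = 100, seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  d <- export_ce_plane(psa, reference = "myCompass", path = path)
  expect_equal(nrow(d), 100 * 2)
  back <- utils::read.csv(path)
  expect_equal(back$delta_qaly, d$delta_qaly, tolerance = 0)
  expect_equal(back$delta_cost_aud, d$delta_cost_aud, tolerance = 0)
  # identical strategies: every point at the origin
  same <- fake_psa(matrix(100, 10, 3), matrix(0.2, 10, 3))
  d0 <- export_ce_plane(same, reference = "TAU")
  expect_true(all(d0$delta_qaly == 0) && all(d0$delta_cost_aud == 0))
  expect_error(export_ce_plane(psa, reference = "nope"), "not in PSA")
})

test_that("autoplot and tidiers return well-formed objects", {
  psa <- run_psa(cfg0, n = 50, seed = 37)
  expect_s3_class(autoplot(psa), "ggplot")
  cc <- ceac(psa, wtp_grid = c(0, 50000))
  expect_s3_class(autoplot(cc), "ggplot")
  expect_s3_class(tidy(psa), "tbl_df")
  expect_equal(glance(psa)$n, 50)
  expect_equal(nrow(tidy(cc)), 6)
})
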