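# Probabilistic engine: moment matching, fitting, simulation, percentiles
# and contribution-to-variance sensitivity.

test_that("lognormal moment matching matches the closed form and round
           trips", {
  lp <- lognormal_from_moments(2.00e-5, 5.66e-5)
  expect_equal(lp$sdlog^2, log(1 + (5.66 / 2)^2), tolerance = 1e-12)
  expect_equal(lp$meanlog, log(2e-5) - lp$sdlog^2 / 2, tolerance = 1e-12)
  # frozen closed-form values: log1p(2.83^2) and log(2e-5) - s2/2
  expect_equal(lp$sdlog^2, 2.19821298, tolerance = 1e-7)
  expect_equal(lp$meanlog, -11.91888477, tolerance = 1e-7)

  # inverse identity to 1e-12 relative
  for (m in c(0.1, 5, 2e-5)) {
    for (s in c(0.01, 1, 5.66e-5)) {
      p <- lognormal_from_moments(m, s)
      back <- lognormal_moments(p$meanlog, p$sdlog)
      expect_equal(back$mean, m, tolerance = 1e-12)
      expect_equal(back$sd, s, tolerance = 1e-12)
    }
  }
  # degenerate limit sd -> 0+
  p0 <- lognormal_from_moments(5, 1e-12)
  expect_equal(p0$meanlog, log(5), tolerance = 1e-9)
  expect_lt(p0$sdlog, 1e-9)
  expect_error(lognormal_from_moments(-1, 1), "> 0")
})

test_that("percentiles use linear interpolation and are order invariant", {
  p <- percentiles(1:100)
  expect_equal(unname(p), c(10.9, 50.5, 90.1))
  expect_equal(percentiles(5), setNames(rep(5, 3), c("p10", "p50", "p90")))
  set.seed(1)
  x <- rnorm(500)
  expect_equal(percentiles(x), percentiles(sample(x)))
  expect_error(percentiles(x, probs = c(-1, 50)), "\\[0, 100\\]")
  expect_error(percentiles(numeric(0)), "non-empty")
})

test_that("fit_distribution selects the generating family and reports both
           statistics", {
  set.seed(42)
  draws <- rlnorm(10000, -11.92, 1.48)
  fits <- fit_distribution(draws, c("normal", "lognormal", "uniform"))
  expect_equal(sum(vapply(fits, `[[`, TRUE, "selected")), 1)
  sel <- fits[[which(vapply(fits, `[[`, TRUE, "selected"))]]
  expect_equal(sel$family, "lognormal")
  expect_true(all(vapply(fits, `[[`, 0, "ad_stat") >= 0))
  expect_true(all(vapply(fits, `[[`, 0, "chi2_stat") >= 0))
})

test_that("fit_distribution edge cases: constants and support violations", {
  expect_error(fit_distribution(rep(1, 100)), "constant samples")
  set.seed(7)
  withneg <- rnorm(100)
  expect_error(
    suppressMessages(fit_distribution(withneg, "lognormal")),
    "no candidate family is valid")
  expect_error(fit_distribution(rnorm(10)), "at least 20")
})

test_that("family recovery across seeded repetitions (scaled-down
           property; the full 100-rep check runs in the acceptance
           suite)", {
  hits <- 0
  for (k in 1:20) {
    set.seed(k)
    draws <- rlnorm(2000, -11.92, 1.48)
    fits <- fit_distribution(draws, c("normal", "lognormal", "uniform"))
    sel <- fits[[which(vapply(fits, `[[`, TRUE, "selected"))]]
    hits <- hits + (sel$family == "lognormal")
  }
  expect_gte(hits, 19)
})

test_that("simulate_ilcr collapses to the deterministic risk when every
           input is a point", {
  fac <- point_factors(dr = 5, csf = 7.3, ed = 30, bw = 60, at = 25550)
  mc <- simulate_ilcr(2e-3, fac, n = 100, seed = 1)
  det <- ilcr(2e-3, fac)$ilcr
  expect_equal(unique(mc$draws), det)
  expect_equal(mc$sd, 0)
  expect_equal(unname(mc$percentiles), rep(det, 3))
  expect_length(mc$sensitivity, 0)
})

test_that("simulate_ilcr is bit-identical across runs with the same seed", {
  fac <- exposure_factors("adult",
                          dr = dist_spec("lognormal", mean = 5, sd = 2),
                          csf = 7.3, ef = 365, ed = 30,
                          bw = dist_spec("normal", mean = 60, sd = 10,
                                         truncation = c(30, 120)),
                          at = 25550)
  spec <- dist_spec("lognormal", mean = 2e-5, sd = 5.66e-5)
  a <- simulate_ilcr(spec, fac, n = 2000, seed = 99)
  b <- simulate_ilcr(spec, fac, n = 2000, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(a$percentiles, b$percentiles)
  expect_identical(a$sensitivity, b$sensitivity)
  expect_false(identical(a$draws,
                         simulate_ilcr(spec, fac, n = 2000, seed = 100)$draws))
})

test_that("sampled quantiles agree with the closed-form lognormal quantiles
           within 3 bootstrap SEs at n = 10,000", {
  lp <- lognormal_from_moments(2.00e-5, 5.66e-5)
  spec <- dist_spec("lognormal", mean = 2.00e-5, sd = 5.66e-5)
  mc <- simulate_ilcr(spec, point_factors(), n = 10000, seed = 314)
  set.seed(271)
  boot <- replicate(200, {
    quantile(sample(mc$draws, replace = TRUE), c(0.1, 0.5, 0.9), type = 7)
  })
  se <- apply(boot, 1, sd)
  closed <- exp(lp$meanlog + qnorm(c(0.1, 0.5, 0.9)) * lp$sdlog)
  expect_true(all(abs(mc$percentiles - closed) < 3 * se))
})

test_that("sensitivity shares: normalization, sign and symmetry
           contracts", {
  set.seed(8)
  n <- 2000
  x <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  # output = the single stochastic input (other columns constant)
  s <- sensitivity(cbind(a = x[, "a"], d = rep(1, n), e = rep(2, n)),
                   x[, "a"])
  expect_equal(unname(s[["a"]]), 100, tolerance = 1e-9)
  expect_equal(unname(s[["d"]]), 0)
  expect_equal(sum(abs(s)), 100)

  # duplicated columns share equally
  dup <- cbind(u = x[, 1], v = x[, 1])
  s2 <- sensitivity(dup, x[, 1])
  expect_equal(unname(s2[["u"]]), unname(s2[["v"]]))
  expect_equal(sum(abs(s2)), 100)

  # monotone rescaling of an input leaves shares unchanged
  y <- x[, 1] + 0.5 * x[, 2]
  s3 <- sensitivity(x, y)
  x_scaled <- x
  x_scaled[, 2] <- exp(x_scaled[, 2])
  expect_equal(sensitivity(x_scaled, y), s3)

  expect_error(sensitivity(x, rep(1, n)), "constant output")
  expect_error(sensitivity(x[1:5, ], y[1:5]), "at least 10")
})

test_that("dominant-variance input ranks first with a positive share and
           body weight acts negatively", {
  fac <- exposure_factors("adult",
    dr = dist_spec("lognormal", mean = 5, sd = 0.5),
    csf = 7.3, ef = 365, ed = 30,
    bw = dist_spec("normal", mean = 60, sd = 6, truncation = c(30, 120)),
    at = 25550)
  spec <- dist_spec("lognormal", mean = 2e-5, sd = 3e-5)  # CV 1.5
  mc <- simulate_ilcr(spec, fac, n = 10000, seed = 55)
  s <- mc$sensitivity
  expect_equal(sum(abs(s)), 100)
  expect_equal(names(which.max(abs(s))), "teq")
  expect_gt(s[["teq"]], 0)
  expect_lt(s[["bw"]], 0)
})

test_that("mc results carry provenance and a lognormal fit of the output", {
  spec <- dist_spec("lognormal", mean = 2e-5, sd = 5.66e-5)
  mc <- simulate_ilcr(spec, point_factors(), n = 1000, seed = 12)
  expect_equal(mc$seed, 12)
  expect_equal(mc$n, 1000)
  expect_equal(mc$fitted$family, "lognormal")
  expect_true(all(mc$draws >= 0))
  expect_true(mc$percentiles[["p10"]] <= mc$percentiles[["p50"]] &&
              mc$percentiles[["p50"]] <= mc$percentiles[["p90"]])
})
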