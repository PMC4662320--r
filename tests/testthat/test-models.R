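test_that("annual correlation matches direct Pearson evaluation", {
  x <- c(1, 2, 3, 4)
  expect_equal(annual_correlation(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(annual_correlation(x, -2 * x + 7)$r, -1, tolerance = 1e-12)
  y <- c(1, 3, 2, 5)
  res <- annual_correlation(x, y)
  expect_equal(res$r, pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(res$r, 0.83152, tolerance = 1e-4)
  expect_identical(res$n, 4L)
  # affine invariance
  expect_equal(annual_correlation(10 * x - 3, 0.5 * y + 2)$r, res$r,
               tolerance = 1e-12)
  expect_error(annual_correlation(x, rep(1, 4)), "zero variance")
  expect_error(annual_correlation(1:2, 2:3), "3 complete")
})

test_that("within/between partition is exact and balanced-orthogonal", {
  p <- partition_within_between(c(100, 104), c(1, 1))
  expect_equal(p$between, c(102, 102))
  expect_equal(p$within, c(-2, 2))

  # all equal within a year -> within all zero
  p2 <- partition_within_between(rep(107, 5), rep(2003, 5))
  expect_equal(p2$within, rep(0, 5))

  # reconstruction identity to 1e-12
  set.seed(3)
  v <- rnorm(200, 110, 6)
  yr <- rep(2001:2010, each = 20)
  p3 <- partition_within_between(v, yr)
  expect_true(all(abs(p3$between + p3$within - v) < 1e-12))

  # balanced groups: components empirically uncorrelated
  expect_lt(abs(cor(p3$between, p3$within)), 1e-10)
})

test_that("mixed model recovers OLS when random-effect variance is zero", {
  # a response exactly linear in the predictors leaves nothing for the
  # random intercepts, so the REML fit sits on the variance boundary and
  # the fixed effects must match ordinary regression
  set.seed(8)
  n <- 400
  d <- data.frame(year = rep(2001:2008, each = n / 8),
                  box_id = sprintf("b%03d", rep(1:40, 10)))
  d$nestbox_greenup <- 110 + rnorm(n, 0, 5)
  pw <- partition_within_between(d$nestbox_greenup, d$year)
  noise <- rnorm(n, 0, 2)
  d$laying_day <- 5 + 0.4 * pw$within + 0.1 * pw$between +
    noise - ave(noise, d$box_id) - ave(noise, d$year) + mean(noise)
  f <- suppressMessages(fit_breeding_lmm(d, covariates = "minimal"))
  ref <- lm(d$laying_day ~ pw$within + pw$between)
  est <- f$coefficients$estimate
  names(est) <- f$coefficients$term
  expect_equal(unname(est["gu_within"]), unname(coef(ref)[2]),
               tolerance = 1e-4)
  expect_equal(unname(est["gu_between"]), unname(coef(ref)[3]),
               tolerance = 1e-4)
})

test_that("within-year coefficient ignores year-constant green-up shifts", {
  sim <- simulate_phenology_data(tiny_config(seed = 31))
  tab <- truth_table(sim)
  shifted <- tab
  yr0 <- sort(unique(shifted$year))[2]
  shifted$nestbox_greenup[shifted$year == yr0] <-
    shifted$nestbox_greenup[shifted$year == yr0] + 50

  # in the minimal model with a year-level random intercept every other
  # column (intercept, between-year mean) lies in the span of the year
  # indicators, so the centred predictor's normal equations decouple:
  # exact invariance
  f1 <- suppressMessages(fit_breeding_lmm(tab, covariates = "minimal",
                                          random = "year"))
  f2 <- suppressMessages(fit_breeding_lmm(shifted, covariates = "minimal",
                                          random = "year"))
  w1 <- f1$coefficients$estimate[f1$coefficients$term == "gu_within"]
  w2 <- f2$coefficients$estimate[f2$coefficients$term == "gu_within"]
  expect_lt(abs(w1 - w2), 1e-8)

  # the crossed nestbox intercept couples the columns; the coefficient
  # may drift, but only marginally
  g1 <- suppressMessages(fit_breeding_lmm(tab, covariates = "full"))
  g2 <- suppressMessages(fit_breeding_lmm(shifted, covariates = "full"))
  v1 <- g1$coefficients$estimate[g1$coefficients$term == "gu_within"]
  v2 <- g2$coefficients$estimate[g2$coefficients$term == "gu_within"]
  expect_lt(abs(v1 - v2), 0.01)
})

test_that("female random effect restricts to identified females", {
  sim <- simulate_phenology_data(tiny_config(seed = 32))
  tab <- truth_table(sim)
  f <- suppressMessages(fit_breeding_lmm(tab, covariates = "minimal",
                                         female_re = TRUE))
  expect_identical(f$n, sum(!is.na(tab$female_id) & tab$female_id != ""))
  expect_true("female_id" %in% names(f$ranef_sd))
})

test_that("annual mean green-up uses strictly woodland pixels with valid dates", {
  grid <- data.frame(pixel_id = c("a", "b", "c", "d", "e"),
                     woodland_fraction = c(0.9, 0.8, 0.6, 0.5, 0.2))
  map <- data.frame(pixel_id = c("a", "b", "c", "d", "e"), year = 2001,
                    greenup_day = c(100, 110, 120, 999, 999))
  expect_equal(annual_mean_greenup(map, grid, 2001), 110)
  # invalid pixels ignored
  map$greenup_day[2] <- NA
  expect_equal(annual_mean_greenup(map, grid, 2001), 110)
  grid2 <- grid; grid2$woodland_fraction <- 0.3
  expect_error(annual_mean_greenup(map, grid2, 2001), "no qualifying")
})
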