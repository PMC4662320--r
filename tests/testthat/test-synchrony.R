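sync_fixture <- function() {
  # 2 pixels, 8 years; pixel q1: laying tracks green-up exactly
  years <- 2001:2008
  grid <- data.frame(pixel_id = c("q1", "q2"),
                     woodland_fraction = c(0.9, 0.8))
  gu <- rbind(data.frame(pixel_id = "q1", year = years,
                         greenup_day = 100 + (1:8) * 2),
              data.frame(pixel_id = "q2", year = years,
                         greenup_day = 110 + c(3, -1, 2, 0, 4, -2, 1, 5)))
  tab <- rbind(data.frame(pixel_id = "q1", year = years,
                          laying_day = (100 + (1:8) * 2) - 30),
               data.frame(pixel_id = "q2", year = years,
                          laying_day = c(25, 18, 22, 20, 21, 24, 19, 23)))
  list(grid = grid, gu = gu, tab = tab)
}

test_that("pixel synchrony is the across-year Pearson r of mean laying vs green-up", {
  fx <- sync_fixture()
  sm <- pixel_synchrony(fx$tab, fx$gu, fx$grid)
  q1 <- sm[sm$pixel_id == "q1", ]
  expect_true(q1$included)
  expect_equal(q1$r, 1, tolerance = 1e-12)
  q2 <- sm[sm$pixel_id == "q2", ]
  lay <- fx$tab$laying_day[fx$tab$pixel_id == "q2"]
  g <- fx$gu$greenup_day[fx$gu$pixel_id == "q2"]
  expect_equal(q2$r, pearson_oracle(lay, g), tolerance = 1e-12)
  expect_identical(q1$n_years, 8L)
})

test_that("low-support and non-woodland pixels are excluded with reasons", {
  fx <- sync_fixture()
  # keep only 4 years of attempts in q1
  tab <- fx$tab[!(fx$tab$pixel_id == "q1" & fx$tab$year > 2004), ]
  sm <- pixel_synchrony(tab, fx$gu, fx$grid, min_years = 6)
  expect_false(sm$included[sm$pixel_id == "q1"])
  expect_identical(sm$exclude_reason[sm$pixel_id == "q1"],
                   "too_few_years")
  grid2 <- fx$grid; grid2$woodland_fraction[2] <- 0.5
  sm2 <- pixel_synchrony(fx$tab, fx$gu, grid2)
  expect_identical(sm2$exclude_reason[sm2$pixel_id == "q2"],
                   "non_woodland")
})

test_that("habitat overlay area-weights compartment proportions", {
  comps <- data.frame(compartment_id = c("c1", "c2"),
                      canopy_oak = c(0.8, 0.2), under_hazel = c(0.4, 0))
  # wholly inside one compartment
  ov1 <- data.frame(pixel_id = "p1", compartment_id = "c1", area = 100)
  h1 <- habitat_overlay(ov1, comps)
  expect_equal(h1$canopy_oak, 0.8)
  # 50/50 split
  ov2 <- data.frame(pixel_id = "p2", compartment_id = c("c1", "c2"),
                    area = c(50, 50))
  expect_equal(habitat_overlay(ov2, comps)$canopy_oak, 0.5)
  # 25/75 split on hazel
  ov3 <- data.frame(pixel_id = "p3", compartment_id = c("c1", "c2"),
                    area = c(25, 75))
  expect_equal(habitat_overlay(ov3, comps)$under_hazel, 0.1)
  # never exceeds the largest contributing proportion
  expect_lte(max(habitat_overlay(ov3, comps)$canopy_oak), 0.8)
})

test_that("habitat regression is exact on planted linear structure", {
  set.seed(13)
  n <- 30
  oak <- runif(n, 0, 0.6)
  sm <- data.frame(pixel_id = sprintf("p%02d", 1:n),
                   r = 0.1 + 0.4 * oak, n_years = 10,
                   n_attempts = sample(5:40, n, TRUE),
                   woodland_fraction = 0.9, included = TRUE,
                   exclude_reason = "")
  hab <- data.frame(pixel_id = sm$pixel_id, canopy_oak = oak)
  rg <- synchrony_habitat_regression(sm, hab)
  expect_equal(rg$slope, 0.4, tolerance = 1e-10)
  expect_lt(rg$se, 1e-8)

  # WLS scale invariance: doubling all weights changes nothing
  sm$r <- sm$r + rnorm(n, 0, 0.1)
  rg1 <- synchrony_habitat_regression(sm, hab)
  sm2 <- sm; sm2$n_attempts <- 2 * sm2$n_attempts
  rg2 <- synchrony_habitat_regression(sm2, hab)
  expect_equal(rg1$slope, rg2$slope, tolerance = 1e-12)
  expect_equal(rg1$se, rg2$se, tolerance = 1e-12)

  # equal weights reduce to OLS
  sm3 <- sm; sm3$n_attempts <- 7
  rg3 <- synchrony_habitat_regression(sm3, hab)
  ols <- lm(sm3$r ~ hab$canopy_oak)
  expect_equal(rg3$slope, unname(coef(ols)[2]), tolerance = 1e-10)
})

test_that("species comparison runs a Welch test plus paired correlation", {
  mk <- function(r) data.frame(pixel_id = sprintf("p%d", seq_along(r)),
                               r = r, n_years = 10, n_attempts = 10,
                               woodland_fraction = 0.9, included = TRUE,
                               exclude_reason = "")
  same <- compare_species_synchrony(mk(c(0.1, 0.2, 0.3)),
                                    mk(c(0.1, 0.2, 0.3)))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$paired_r, 1, tolerance = 1e-12)

  res <- compare_species_synchrony(mk(c(0.1, 0.2, 0.3)),
                                   mk(c(0.4, 0.5, 0.6)))
  # hand Welch: means .2/.5, sd .1, n 3 -> t = -.3/(.1*sqrt(2/3))
  expect_equal(res$t, -0.3 / (0.1 * sqrt(2 / 3)), tolerance = 1e-6)
  expect_equal(res$t, -3.6742, tolerance = 1e-4)
  expect_equal(res$mean_a, 0.2); expect_equal(res$mean_b, 0.5)

  deg <- compare_species_synchrony(mk(c(0, 0, 0, 0)), mk(c(1, 1, 1, 1)))
  expect_true(deg$degenerate)
})

test_that("synchrony r is invariant to location/scale changes of laying", {
  fx <- sync_fixture()
  sm0 <- pixel_synchrony(fx$tab, fx$gu, fx$grid)
  tab2 <- fx$tab
  tab2$laying_day <- 3 * tab2$laying_day + 17
  sm1 <- pixel_synchrony(tab2, fx$gu, fx$grid)
  expect_equal(sm1$r, sm0$r, tolerance = 1e-12)
})
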