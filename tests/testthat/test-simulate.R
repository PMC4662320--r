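test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(grid_rows = 1), "grid dimensions")
  expect_error(sim_config(year_sd = -1), "standard deviations")
  expect_error(sim_config(senescence_day = 100, mean_greenup = 110),
               "senescence_day")
  expect_error(sim_config(evi_base = 0), "evi_base")
})

test_that("generators are pure functions of the configuration", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_phenology_data(cfg)
  b <- simulate_phenology_data(cfg)
  expect_identical(a$grid, b$grid)
  expect_identical(a$nestboxes, b$nestboxes)
  expect_identical(a$truth$greenup, b$truth$greenup)
  expect_identical(a$records, b$records)
  expect_identical(a$cloud, b$cloud)
  c2 <- simulate_phenology_data(tiny_config(seed = 8))
  expect_false(identical(a$records, c2$records))
})

test_that("landscape proportions respect the simplex and border structure", {
  for (s in 1:5) {
    land <- generate_landscape(tiny_config(seed = s))
    g <- land$grid
    can <- rowSums(g[grep("^canopy_", names(g))])
    und <- rowSums(g[grep("^under_", names(g))])
    expect_true(all(can >= 0 & can <= 1 + 1e-9))
    expect_true(all(und >= 0 & und <= 1 + 1e-9))
    expect_true(all(g$woodland_fraction >= 0 & g$woodland_fraction <= 1))
    border <- g$row %in% range(g$row) | g$col %in% range(g$col)
    expect_lt(mean(g$woodland_fraction[border]),
              mean(g$woodland_fraction[!border]))
    # nestboxes only inside woodland pixels, within the grid extent
    nb <- land$nestboxes
    wf <- g$woodland_fraction[match(nb$pixel_id, g$pixel_id)]
    expect_true(all(wf > 0.5))
    expect_true(all(nb$oak_density_75m >= 0))
  }
})

test_that("zero smoothing range leaves oak proportions spatially unstructured", {
  # lag-1 spatial autocorrelation of the oak field at range 0, 20 seeds
  rs <- sapply(1:20, function(s) {
    cfg <- sim_config(grid_rows = 20, grid_cols = 20, spatial_range = 0,
                      n_nestboxes = 10, seed = 400 + s)
    g <- generate_landscape(cfg)$grid
    m <- matrix(g$canopy_oak[order(g$row, g$col)], 20, 20, byrow = TRUE)
    cor(as.vector(m[, -1]), as.vector(m[, -20]))
  })
  expect_lt(abs(mean(rs)), 0.15)
  expect_lt(max(abs(rs)), 0.3)
})

test_that("true green-up decomposes into year, space and noise", {
  cfg <- tiny_config(seed = 9, year_sd = 0, spatial_sd = 0,
                     interaction_sd = 0)
  tg <- generate_true_greenup(cfg, generate_landscape(cfg)$grid)
  expect_true(all(tg$greenup$greenup_day == cfg$mean_greenup))

  # empirical sd of year means across many years within 15% of year_sd
  cfg2 <- sim_config(n_years = 200, n_nestboxes = 10, seed = 10)
  tg2 <- generate_true_greenup(cfg2, generate_landscape(cfg2)$grid)
  expect_lt(abs(sd(tg2$year_means) - cfg2$year_sd) / cfg2$year_sd, 0.15)
})

test_that("cloud thinning follows the binomial look model", {
  cfg <- sim_config(n_nestboxes = 10, seed = 11)
  tg <- data.frame(pixel_id = "p001", year = 2001, greenup_day = 110)

  # full cloud -> no clear look in that period
  cl <- data.frame(year = 2001, period = 1:46,
                   cloud_fraction = c(100, rep(0, 45)))
  obs <- generate_observations(cfg, tg, cl)
  ser <- aggregate_periods(obs)
  expect_identical(ser$n_clear[ser$period == 1], 0L)
  expect_true(is.na(ser$evi2[ser$period == 1]))

  # thinning identity: clear + cloudy = looks per period, exactly
  doy <- as.integer(format(as.Date(obs$date), "%j"))
  per_period <- table(pmin(ceiling(doy / 8), 46))
  expect_true(all(per_period == cfg$looks_per_period))

  # 75% cloud -> about 4 clear looks on average (16 looks)
  cl75 <- data.frame(year = 2001, period = 1:46, cloud_fraction = 75)
  tg_many <- data.frame(pixel_id = sprintf("p%03d", 1:40), year = 2001,
                        greenup_day = 110)
  ser75 <- aggregate_periods(generate_observations(cfg, tg_many, cl75))
  expect_lt(abs(mean(ser75$n_clear) - 4), 0.2)
  expect_error(generate_observations(cfg, tg,
                                     transform(cl, cloud_fraction = 150)),
               "\\[0, 100\\]")
})

test_that("noiseless cloud-free period means equal the analytic curve", {
  cfg <- sim_config(obs_noise_sd = 0, n_nestboxes = 10, seed = 12)
  tg <- data.frame(pixel_id = "p001", year = 2001, greenup_day = 117.3)
  cl <- data.frame(year = 2001, period = 1:46, cloud_fraction = 0)
  ser <- aggregate_periods(generate_observations(cfg, tg, cl))
  truth <- evi2_curve(ser$midpoint_day, 117.3, cfg)
  expect_true(all(abs(ser$evi2 - truth) < 1e-9))
})

test_that("degenerate breeding model collapses to the intercept", {
  cfg <- tiny_config(seed = 13, alpha = 21, beta_within = 0,
                     beta_between = 0, beta_altitude = 0, beta_edge = 0,
                     beta_oak = 0, residual_sd = 0, year_re_sd = 0,
                     box_re_sd = 0)
  land <- generate_landscape(cfg)
  tg <- generate_true_greenup(cfg, land$grid)
  br <- generate_breeding(cfg, land, tg)
  expect_true(all(br$records$laying_day == 21))
  # laying-date inference round-trips the clutch observation encoding
  expect_equal(infer_laying_date(br$records$observation_day,
                                 br$records$eggs_observed),
               br$records$laying_day)
})

test_that("oak coupling raises laying/green-up tracking in oak-rich pixels", {
  # mechanism check: full occupancy and small nuisance variances isolate
  # the oak-modulated coupling from pixel-level sampling noise (the
  # default-conditions version of this check lives with the end-to-end
  # habitat-regression tests)
  diffs <- sapply(1:5, function(s) {
    cfg <- sim_config(seed = 600 + s, oak_coupling_gain = 25,
                      occupancy_great = 1, residual_sd = 1,
                      year_re_sd = 1)
    sim <- simulate_phenology_data(cfg)
    tab <- truth_table(sim)
    sm <- pixel_synchrony(tab, sim$truth$greenup, sim$grid)
    d <- merge(sm[sm$included & is.finite(sm$r), ],
               sim$grid[c("pixel_id", "canopy_oak")], by = "pixel_id")
    # attempt-weighted oak contrast in pixel-level tracking
    stats::cov.wt(cbind(d$canopy_oak, d$r), wt = d$n_attempts,
                  cor = TRUE)$cor[1, 2]
  })
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 4)
})

test_that("written simulations reproduce and carry the truth bundle", {
  dir <- tempfile("simout")
  sim <- simulate_phenology_data(tiny_config(seed = 14))
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$betas$beta_within, sim$config$beta_within)
  expect_equal(length(truth$greenup$greenup_day), nrow(sim$truth$greenup))
  rec <- read.csv(paths[["breeding"]])
  expect_identical(nrow(rec), nrow(sim$records))
})
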