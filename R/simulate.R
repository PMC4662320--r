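#' Simulation configuration
#'
#' Collects every parameter of the synthetic woodland generator, with
#' defaults mirroring the scale of a 13-year study of a ~385 ha
#' mixed-deciduous woodland observed at 240 m resolution: an 11 x 11
#' pixel grid (121 pixels, of which the woodland core resembles the ~117
#' pixels intersecting such a site), 1207 nestboxes, green-up around day
#' 110 with ~5 days of between-year and ~4 days of within-year spatial
#' spread, 16 satellite looks per 8-day period thinned by cloud, and a
#' laying-date model whose within-year coupling to green-up defaults to
#' 0.02 days per day.
#'
#' @param grid_rows,grid_cols grid dimensions (>= 2).
#' @param pixel_size pixel edge length, metres.
#' @param n_years number of study years.
#' @param first_year first calendar year.
#' @param n_nestboxes number of nestboxes.
#' @param mean_greenup long-run mean green-up day of year.
#' @param year_sd sd of annual mean green-up (days).
#' @param spatial_sd sd of the time-invariant spatial green-up field
#'   (days).
#' @param spatial_range Gaussian-kernel bandwidth of the spatial fields,
#'   metres.
#' @param interaction_sd sd of independent pixel-by-year green-up noise
#'   (days); this is what makes the spatial green-up pattern differ
#'   between years.
#' @param evi_base,evi_amplitude winter baseline and seasonal amplitude
#'   of the EVI2 curve (index units).
#' @param logistic_rate steepness of the spring logistic rise (per day).
#' @param senescence_day day of year of the autumn decline's midpoint.
#' @param obs_noise_sd sd of per-look EVI2 observation noise (index
#'   units).
#' @param looks_per_period available satellite looks per 8-day period.
#' @param alpha intercept of the laying-date model (day-of-April scale).
#' @param beta_within,beta_between days of laying per day of within-year
#'   / between-year green-up.
#' @param beta_altitude,beta_edge,beta_oak effects of altitude (per m),
#'   edge distance (per m) and local oak count (per tree) on laying.
#' @param oak_coupling_gain dimensionless modulation of the within-year
#'   coupling by pixel oak canopy proportion: the effective slope is
#'   `beta_within * (1 + oak_coupling_gain * oak_proportion)`.
#' @param residual_sd,year_re_sd,box_re_sd residual and random-effect
#'   sds of the laying model (days).
#' @param occupancy_great,occupancy_blue probability a box hosts a
#'   breeding attempt of each species in a year.
#' @param halffall_intercept,halffall_slope,halffall_sd linear link from
#'   annual mean green-up to caterpillar half-fall date (day of year).
#' @param cloud_winter_mean,cloud_year_sd,cloud_period_sd mean early-year
#'   cloud fraction (percent), between-year offset sd, and within-year
#'   period noise sd of the cloud generator.
#' @param seed integer seed; every generator is a pure function of the
#'   configuration including this seed.
#' @return validated list of class `phenosync_config`.
#' @export
sim_config <- function(grid_rows = 11, grid_cols = 11, pixel_size = 240,
                       n_years = 13, first_year = 2001,
                       n_nestboxes = 1207,
                       mean_greenup = 110, year_sd = 5, spatial_sd = 4,
                       spatial_range = 480, interaction_sd = 4,
                       evi_base = 0.2, evi_amplitude = 0.35,
                       logistic_rate = 0.1, senescence_day = 280,
                       obs_noise_sd = 0.02, looks_per_period = 16,
                       alpha = -15, beta_within = 0.02,
                       beta_between = 0.3, beta_altitude = 0.028,
                       beta_edge = 0.003, beta_oak = -0.043,
                       oak_coupling_gain = 0, residual_sd = 3,
                       year_re_sd = 2, box_re_sd = 1,
                       occupancy_great = 0.3, occupancy_blue = 0.3,
                       halffall_intercept = 85, halffall_slope = 0.5,
                       halffall_sd = 2.3,
                       cloud_winter_mean = 79, cloud_year_sd = 8,
                       cloud_period_sd = 6,
                       seed = 1) {
  cfg <- as.list(environment())
  sds <- c("year_sd", "spatial_sd", "interaction_sd", "obs_noise_sd",
           "residual_sd", "year_re_sd", "box_re_sd", "halffall_sd",
           "cloud_year_sd", "cloud_period_sd")
  if (any(unlist(cfg[sds]) < 0)) {
    stop("all standard deviations must be >= 0", call. = FALSE)
  }
  if (grid_rows < 2 || grid_cols < 2) {
    stop("grid dimensions must be >= 2", call. = FALSE)
  }
  if (!(0 < evi_base && evi_amplitude > 0)) {
    stop("need 0 < evi_base and evi_amplitude > 0", call. = FALSE)
  }
  if (senescence_day <= mean_greenup) {
    stop("senescence_day must exceed mean_greenup", call. = FALSE)
  }
  if (n_years < 1 || n_nestboxes < 1 || looks_per_period < 1) {
    stop("counts must be positive", call. = FALSE)
  }
  structure(cfg, class = "phenosync_config")
}

#' Noiseless seasonal EVI2 curve
#'
#' Double-logistic seasonal profile: a logistic rise centred on the
#' green-up day minus a logistic fall centred on the senescence day, on a
#' winter baseline. Its first derivative is maximal at the green-up day,
#' which is what the extraction stage must recover.
#'
#' @param day day of year (vector).
#' @param greenup_day inflection day of the spring rise.
#' @param config a `phenosync_config` (supplies baseline, amplitude,
#'   rate, senescence day).
#' @return EVI2 index values.
#' @export
evi2_curve <- function(day, greenup_day, config) {
  s <- function(x) 1 / (1 + exp(-x))
  config$evi_base + config$evi_amplitude *
    (s(config$logistic_rate * (day - greenup_day)) -
       s(config$logistic_rate * (day - config$senescence_day)))
}

#' Generate the synthetic landscape
#'
#' Builds the pixel grid (woodland fraction lower towards the grid
#' border, emulating the farmland fringe), spatially autocorrelated
#' canopy (oak, ash, beech, sycamore, other) and understory (hazel,
#' hawthorn, elder, field maple, other) composition via softmax of
#' Gaussian-smoothed fields, an altitude surface, and nestboxes placed
#' uniformly within woodland pixels (woodland fraction > 0.5) with
#' altitude, edge distance and a local oak count proportional to the
#' local oak canopy proportion.
#'
#' Grid indexing is row-major from the north-west corner; pixel (r, c)
#' covers the half-open square `[x0, x0 + pixel)` and its centre carries
#' the coordinates.
#'
#' @param config a `phenosync_config`.
#' @return list with `grid` (pixel table incl. habitat columns),
#'   `nestboxes`, and `compartments`/`overlay` (a simple rectangular
#'   compartmentization of the grid with per-compartment habitat values,
#'   for exercising the overlay path).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "phenosync_config"))
  set.seed(config$seed + 101L)
  nr <- config$grid_rows; nc <- config$grid_cols; px <- config$pixel_size

  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  grid <- data.frame(
    pixel_id = sprintf("p%03d", seq_len(nr * nc)),
    row = rows, col = cols,
    x_center = (cols - 0.5) * px,
    y_center = (nr - rows + 0.5) * px) # row 1 at the north

  border_dist <- pmin(rows - 1, nr - rows, cols - 1, nc - cols)
  wnoise <- as.vector(t(smooth_field(nr, nc, config$spatial_range, px)))
  grid$woodland_fraction <- pmin(1, pmax(0, stats::plogis(
    1.2 * border_dist - 0.6 + 0.8 * wnoise)))

  softmax_layer <- function(targets, total) {
    fields <- lapply(targets, function(tg) {
      log(tg) + 0.9 * as.vector(t(smooth_field(nr, nc,
                                               config$spatial_range, px)))
    })
    ex <- lapply(fields, exp)
    denom <- Reduce(`+`, ex)
    lapply(ex, function(e) total * e / denom)
  }
  canopy <- softmax_layer(c(oak = 0.27, ash = 0.31, beech = 0.14,
                            sycamore = 0.11, other = 0.12), total = 0.95)
  under <- softmax_layer(c(hazel = 0.44, hawthorn = 0.33, elder = 0.07,
                           field_maple = 0.06, other = 0.10), total = 0.90)
  for (nm in names(canopy)) grid[[paste0("canopy_", nm)]] <- canopy[[nm]]
  for (nm in names(under)) grid[[paste0("under_", nm)]] <- under[[nm]]

  alt_field <- as.vector(t(smooth_field(nr, nc, 2 * config$spatial_range,
                                        px)))
  grid$altitude_pix <- 110 + 25 * alt_field

  # nestboxes: uniform within woodland pixels
  wood <- which(grid$woodland_fraction > 0.5)
  if (length(wood) == 0L) stop("no woodland pixel to place nestboxes in",
                               call. = FALSE)
  pick <- sample(wood, config$n_nestboxes, replace = TRUE)
  off_x <- stats::runif(config$n_nestboxes, -px / 2, px / 2)
  off_y <- stats::runif(config$n_nestboxes, -px / 2, px / 2)
  edge_pix <- pmax(0, border_dist[pick] - 1 +
                     stats::runif(config$n_nestboxes)) * px / 2
  nb <- data.frame(
    box_id = sprintf("b%04d", seq_len(config$n_nestboxes)),
    pixel_id = grid$pixel_id[pick],
    x = grid$x_center[pick] + off_x,
    y = grid$y_center[pick] + off_y,
    altitude = grid$altitude_pix[pick] + stats::rnorm(config$n_nestboxes,
                                                      0, 3),
    edge_distance = edge_pix,
    oak_density_75m = stats::rpois(config$n_nestboxes,
                                   lambda = 60 * grid$canopy_oak[pick]),
    oak_proportion = grid$canopy_oak[pick])

  # simple rectangular "compartments": split the grid into 2x2-pixel
  # blocks with habitat values equal to the mean of their pixels
  blk_r <- (rows - 1) %/% 2; blk_c <- (cols - 1) %/% 2
  comp_id <- sprintf("c%02d_%02d", blk_r, blk_c)
  hab_cols <- grep("^(canopy|under)_", names(grid), value = TRUE)
  comp <- stats::aggregate(grid[hab_cols], by = list(compartment_id = comp_id),
                           FUN = mean)
  overlay <- data.frame(pixel_id = grid$pixel_id, compartment_id = comp_id,
                        area = px^2)
  list(grid = grid, nestboxes = nb, compartments = comp, overlay = overlay)
}

#' Generate true per-pixel green-up dates
#'
#' `date(year, pixel) = year_mean(year) + spatial(pixel) +
#' noise(year, pixel)` with `year_mean ~ N(mean_greenup, year_sd^2)`, a
#' Gaussian-smoothed spatial field scaled to `spatial_sd`, and
#' independent pixel-by-year noise with sd `interaction_sd`.
#'
#' @param config a `phenosync_config`.
#' @param grid pixel grid from [generate_landscape()].
#' @return list with `greenup` (long data frame `pixel_id`, `year`,
#'   `greenup_day`), `year_means` (named vector), `spatial` (per-pixel
#'   field).
#' @export
generate_true_greenup <- function(config, grid) {
  set.seed(config$seed + 202L)
  years <- config$first_year + seq_len(config$n_years) - 1L
  year_means <- stats::rnorm(config$n_years, config$mean_greenup,
                             config$year_sd)
  names(year_means) <- years
  spat <- config$spatial_sd *
    as.vector(t(smooth_field(config$grid_rows, config$grid_cols,
                             config$spatial_range, config$pixel_size)))
  np <- nrow(grid)
  rows <- lapply(seq_along(years), function(i) {
    data.frame(pixel_id = grid$pixel_id, year = years[i],
               greenup_day = year_means[i] + spat +
                 stats::rnorm(np, 0, config$interaction_sd))
  })
  list(greenup = do.call(rbind, rows), year_means = year_means,
       spatial = stats::setNames(spat, grid$pixel_id))
}

#' Generate the per-period cloud-fraction series
#'
#' Cloud fraction (percent) per year and 8-day period: a seasonal mean
#' profile, high (~79%) in the first quarter and easing through summer,
#' plus a between-year offset and independent period noise, clamped to
#' \[0, 100\].
#'
#' @param config a `phenosync_config`.
#' @return data frame `year`, `period` (1..46), `cloud_fraction`.
#' @export
generate_cloud <- function(config) {
  set.seed(config$seed + 303L)
  years <- config$first_year + seq_len(config$n_years) - 1L
  periods <- 1:46
  seasonal <- config$cloud_winter_mean - 25 *
    sin(pmax(0, pmin(pi, (periods - 8) * pi / 30)))
  rows <- lapply(years, function(yr) {
    off <- stats::rnorm(1, 0, config$cloud_year_sd)
    cf <- seasonal + off + stats::rnorm(46, 0, config$cloud_period_sd)
    data.frame(year = yr, period = periods,
               cloud_fraction = pmin(100, pmax(0, cf)))
  })
  do.call(rbind, rows)
}

#' Generate cloud-thinned multispectral observations
#'
#' For each pixel, year and 8-day period, the number of clear looks is
#' `Binomial(looks_per_period, 1 - cloud/100)`; the remaining looks are
#' flagged cloudy. Clear looks carry reflectances constructed so that the
#' noiseless EVI2 equals the double-logistic seasonal curve at the
#' period's midpoint day, plus Normal index noise, with red fixed at 0.05
#' and NIR solved from the target index (the inversion is exact and
#' monotone; only EVI2 is consumed downstream). Dating every look at the
#' period midpoint makes the noiseless period mean equal the analytic
#' curve at the midpoint exactly; only period means are consumed
#' downstream. Cloudy looks carry bright cloud-top reflectances.
#'
#' @param config a `phenosync_config`.
#' @param true_greenup data frame `pixel_id`, `year`, `greenup_day`.
#' @param cloud data frame `year`, `period`, `cloud_fraction`.
#' @param include_cloudy emit rows for cloudy looks (default TRUE; the
#'   thinning identity clear + cloudy = total looks holds exactly).
#' @return data frame `pixel_id`, `date`, `red`, `nir`, `cloudy`.
#' @export
generate_observations <- function(config, true_greenup, cloud,
                                  include_cloudy = TRUE) {
  if (any(cloud$cloud_fraction < 0 | cloud$cloud_fraction > 100)) {
    stop("cloud fractions must lie in [0, 100]", call. = FALSE)
  }
  set.seed(config$seed + 404L)
  looks <- config$looks_per_period
  out <- vector("list", nrow(true_greenup))
  for (i in seq_len(nrow(true_greenup))) {
    px <- true_greenup$pixel_id[i]
    yr <- true_greenup$year[i]
    g <- true_greenup$greenup_day[i]
    cf <- cloud[cloud$year == yr, , drop = FALSE]
    cf <- cf[order(cf$period), , drop = FALSE]
    n_clear <- stats::rbinom(nrow(cf), looks, 1 - cf$cloud_fraction / 100)
    n_cloudy <- if (include_cloudy) looks - n_clear else 0L
    tot <- sum(n_clear) + sum(n_cloudy)
    if (tot == 0L) next
    period <- rep(cf$period, n_clear + n_cloudy)
    is_clear <- unlist(lapply(seq_len(nrow(cf)), function(k) {
      rep(c(TRUE, FALSE), c(n_clear[k], n_cloudy[k]))
    }))
    doy <- pmin(period_midpoint(period),
                365 + as.integer(is_leap_year(yr)))
    evi_true <- evi2_curve(doy, g, config)
    evi_obs <- evi_true + stats::rnorm(tot, 0, config$obs_noise_sd)
    evi_obs <- pmax(-0.2, pmin(0.9, evi_obs))
    red <- ifelse(is_clear, 0.05, 0.42)
    nir <- ifelse(is_clear, evi2_to_nir(evi_obs, 0.05), 0.45)
    out[[i]] <- data.frame(
      pixel_id = px,
      date = as.Date(doy - 1, origin = paste0(yr, "-01-01")),
      red = red, nir = nir, cloudy = as.integer(!is_clear))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate breeding records and the caterpillar half-fall series
#'
#' Laying dates (day-of-April scale) follow
#' `alpha + beta_within * dev * (1 + gain * oak_prop) +
#' beta_between * gbar(year) + beta_altitude * altitude +
#' beta_edge * edge + beta_oak * oak_count + yearRE + boxRE + resid`,
#' where `dev` is the box's true nestbox green-up minus the annual mean
#' over all boxes, `gbar(year)` that annual mean, and `oak_prop` the oak
#' canopy proportion of the box's pixel. Dates are rounded to integer
#' days and re-expressed as a clutch observation (observation date + egg
#' count) so the laying-date inference round-trips exactly. Hatch dates
#' add clutch completion plus a 14-day incubation with 1-day noise. The
#' half-fall series is linear in the annual mean green-up with Normal
#' noise. Occupancy subsamples boxes per species per year.
#'
#' @param config a `phenosync_config`.
#' @param landscape output of [generate_landscape()].
#' @param true_greenup output of [generate_true_greenup()].
#' @return list: `records` (breeding table with clutch observations),
#'   `halffall` (`year`, `halffall_day` on day-of-year),
#'   `nestbox_truth` (true nestbox green-up per box-year), `gbar`
#'   (annual means used).
#' @export
generate_breeding <- function(config, landscape, true_greenup) {
  set.seed(config$seed + 505L)
  nb <- landscape$nestboxes
  grid <- landscape$grid
  years <- config$first_year + seq_len(config$n_years) - 1L

  nb_truth <- nestbox_greenup_table(nb, true_greenup$greenup, grid,
                                    pixel_size = config$pixel_size)
  gbar <- tapply(nb_truth$greenup_day, nb_truth$year,
                 function(v) mean(v, na.rm = TRUE))

  year_re <- stats::setNames(stats::rnorm(length(years), 0,
                                          config$year_re_sd), years)
  box_re_g <- stats::setNames(stats::rnorm(nrow(nb), 0, config$box_re_sd),
                              nb$box_id)
  box_re_b <- stats::setNames(stats::rnorm(nrow(nb), 0, config$box_re_sd),
                              nb$box_id)

  mk_species <- function(species, occupancy, box_re) {
    rows <- list()
    for (yr in years) {
      occ <- which(stats::runif(nrow(nb)) < occupancy)
      if (!length(occ)) next
      bt <- nb_truth[nb_truth$year == yr, , drop = FALSE]
      g <- bt$greenup_day[match(nb$box_id[occ], bt$box_id)]
      dev <- g - gbar[as.character(yr)]
      mult <- 1 + config$oak_coupling_gain * nb$oak_proportion[occ]
      mu <- config$alpha + config$beta_within * dev * mult +
        config$beta_between * gbar[as.character(yr)] +
        config$beta_altitude * nb$altitude[occ] +
        config$beta_edge * nb$edge_distance[occ] +
        config$beta_oak * nb$oak_density_75m[occ] +
        year_re[as.character(yr)] + box_re[nb$box_id[occ]]
      lay <- round(mu + stats::rnorm(length(occ), 0, config$residual_sd))
      clutch <- pmax(4L, pmin(12L, stats::rpois(length(occ), 8)))
      eggs_at_obs <- pmin(clutch, 1L + stats::rpois(length(occ), 2))
      hatch <- lay + clutch + 14L +
        round(stats::rnorm(length(occ), 0, 1))
      known_female <- stats::runif(length(occ)) < 0.7
      rows[[length(rows) + 1L]] <- data.frame(
        box_id = nb$box_id[occ], year = yr, species = species,
        observation_day = lay + eggs_at_obs - 1L,
        eggs_observed = eggs_at_obs,
        laying_day = lay, hatch_day = hatch,
        female_id = ifelse(known_female,
                           paste0("f", species, "_", nb$box_id[occ]), ""))
    }
    do.call(rbind, rows)
  }
  records <- rbind(
    mk_species("great_tit", config$occupancy_great, box_re_g),
    mk_species("blue_tit", config$occupancy_blue, box_re_b))
  rownames(records) <- NULL

  halffall <- data.frame(
    year = years,
    halffall_day = config$halffall_intercept +
      config$halffall_slope * as.numeric(gbar[as.character(years)]) +
      stats::rnorm(length(years), 0, config$halffall_sd))

  list(records = records, halffall = halffall, nestbox_truth = nb_truth,
       gbar = gbar)
}

#' Run the whole synthetic generator
#'
#' Convenience wrapper producing every input the analysis pipeline
#' consumes, together with the truth bundle (true green-up, annual means,
#' spatial field, generating coefficients) that downstream tests compare
#' estimates against.
#'
#' @param config a `phenosync_config`.
#' @param observations also generate the look-level multispectral table
#'   (the slowest part; skip when only the breeding branch is needed).
#' @return list of class `phenosync_sim`: `config`, `grid`, `nestboxes`,
#'   `compartments`, `overlay`, `truth` (list: `greenup`, `year_means`,
#'   `spatial`, `nestbox_truth`, `gbar`, `betas`), `cloud`, `records`,
#'   `halffall`, and optionally `observations`.
#' @export
simulate_phenology_data <- function(config = sim_config(),
                                    observations = FALSE) {
  land <- generate_landscape(config)
  tg <- generate_true_greenup(config, land$grid)
  cloud <- generate_cloud(config)
  br <- generate_breeding(config, land, tg)
  betas <- config[c("alpha", "beta_within", "beta_between",
                    "beta_altitude", "beta_edge", "beta_oak",
                    "oak_coupling_gain")]
  sim <- list(config = config, grid = land$grid,
              nestboxes = land$nestboxes,
              compartments = land$compartments, overlay = land$overlay,
              truth = list(greenup = tg$greenup,
                           year_means = tg$year_means,
                           spatial = tg$spatial,
                           nestbox_truth = br$nestbox_truth,
                           gbar = br$gbar, betas = betas),
              cloud = cloud, records = br$records,
              halffall = br$halffall)
  if (observations) {
    sim$observations <- generate_observations(config, tg$greenup, cloud)
  }
  class(sim) <- "phenosync_sim"
  sim
}

#' Write a simulation to CSV files
#'
#' Emits the same files the pipeline stages read, plus `truth.json`.
#'
#' @param sim a `phenosync_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    grid = file.path(dir, "grid.csv"),
    nestboxes = file.path(dir, "nestboxes.csv"),
    compartments = file.path(dir, "compartments.csv"),
    overlay = file.path(dir, "overlay.csv"),
    cloud = file.path(dir, "cloud.csv"),
    breeding = file.path(dir, "breeding.csv"),
    halffall = file.path(dir, "halffall.csv"))
  write_csv_atomic(sim$grid, paths["grid"])
  write_csv_atomic(sim$nestboxes, paths["nestboxes"])
  write_csv_atomic(sim$compartments, paths["compartments"])
  write_csv_atomic(sim$overlay, paths["overlay"])
  write_csv_atomic(sim$cloud, paths["cloud"])
  write_csv_atomic(sim$records, paths["breeding"])
  write_csv_atomic(sim$halffall, paths["halffall"])
  if (!is.null(sim$observations)) {
    paths["observations"] <- file.path(dir, "observations.csv")
    write_csv_atomic(sim$observations, paths["observations"])
  }
  truth <- sim$truth
  truth$config <- unclass(sim$config)
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
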