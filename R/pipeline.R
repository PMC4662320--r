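#' Pipeline configuration
#'
#' A plain list (serializable to YAML) naming the data directory, output
#' directory, thresholds and the top-level seed from which every stage's
#' randomness is derived. `read_pipeline_config()` /
#' `write_pipeline_config()` round-trip the file representation.
#'
#' @param data_dir directory of input CSVs (the simulate stage writes
#'   here).
#' @param out_dir directory for stage outputs.
#' @param seed top-level integer seed.
#' @param species species to analyse.
#' @param woodland_threshold,min_periods,min_years,first_brood_window
#'   analysis thresholds (see the stage functions).
#' @param window_min_len,window_max_len,window_horizon cloud-window scan
#'   bounds.
#' @param female_re include female random intercepts in the mixed models.
#' @param simulate_observations have the simulate stage emit the
#'   look-level multispectral table (needed by the `evi` stage).
#' @param sim named list of [sim_config()] overrides applied by the
#'   simulate stage (e.g. a smaller grid for quick runs); the seed always
#'   comes from the pipeline seed.
#' @param verbose log filter counts with `message()`.
#' @return list of class `phenosync_pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir = file.path(data_dir, "out"),
                            seed = 1,
                            species = c("great_tit", "blue_tit"),
                            woodland_threshold = 0.5, min_periods = 20,
                            min_years = 6, first_brood_window = 30,
                            window_min_len = 3, window_max_len = 15,
                            window_horizon = 15, female_re = FALSE,
                            simulate_observations = TRUE,
                            sim = list(),
                            verbose = FALSE) {
  structure(as.list(environment()), class = "phenosync_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config a `phenosync_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_stages <- c("simulate", "evi", "greenup", "nestbox", "prepare",
                     "annual", "lmm", "synchrony", "mantel", "cloudscan")

# which stage produces each artifact, for actionable missing-input errors
artifact_producer <- c(
  observations.csv = "simulate", grid.csv = "simulate",
  nestboxes.csv = "simulate", breeding.csv = "simulate",
  cloud.csv = "simulate", halffall.csv = "simulate",
  compartments.csv = "simulate", overlay.csv = "simulate",
  evi_series.csv = "evi", greenup.csv = "greenup",
  nestbox_greenup.csv = "nestbox", analysis_table.csv = "prepare")

require_artifact <- function(config, file) {
  dir <- if (file %in% c("observations.csv", "grid.csv", "nestboxes.csv",
                         "breeding.csv", "cloud.csv", "halffall.csv",
                         "compartments.csv", "overlay.csv"))
    config$data_dir else config$out_dir
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stage <- artifact_producer[[file]]
    stop("missing artifact '", file, "': run stage '", stage, "' first",
         call. = FALSE)
  }
  path
}

log_count <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
  invisible(NULL)
}

write_manifest <- function(config, stage, inputs, outputs, counts = list()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    stage = stage,
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = outputs,
    counts = counts,
    package_version = as.character(utils::packageVersion("phenosync")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate all inputs), `evi` (observations to 8-day
#' EVI2 series), `greenup` (series to green-up map), `nestbox` (map to
#' nestbox green-up), `prepare` (breeding records to analysis table),
#' `annual` (annual summaries and correlations), `lmm` (individual-level
#' mixed models), `synchrony` (pixel synchrony map, habitat regressions,
#' species comparison), `mantel` (spatial correlograms), `cloudscan`
#' (window scan), or `all`. Outputs are written atomically and each stage
#' leaves a JSON manifest recording its inputs' checksums, the
#' configuration, the seed and the filter counts.
#'
#' @param stage stage name.
#' @param config a `phenosync_pipeline_config` or path to its YAML file.
#' @return invisibly, a list of the stage's main outputs.
#' @export
run_stage <- function(stage, config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "phenosync_pipeline_config"))
  if (identical(stage, "all")) {
    res <- lapply(pipeline_stages, run_stage, config = config)
    names(res) <- pipeline_stages
    return(invisible(res))
  }
  if (!stage %in% pipeline_stages) {
    stop("unknown stage '", stage, "'; stages are: ",
         paste(c(pipeline_stages, "all"), collapse = ", "), call. = FALSE)
  }
  fn <- switch(stage,
               simulate = stage_simulate, evi = stage_evi,
               greenup = stage_greenup, nestbox = stage_nestbox,
               prepare = stage_prepare, annual = stage_annual,
               lmm = stage_lmm, synchrony = stage_synchrony,
               mantel = stage_mantel, cloudscan = stage_cloudscan)
  invisible(fn(config))
}

stage_simulate <- function(config) {
  args <- config$sim
  args$seed <- config$seed
  sim_cfg <- do.call(sim_config, args)
  sim <- simulate_phenology_data(sim_cfg,
                                 observations = config$simulate_observations)
  paths <- write_simulation(sim, config$data_dir)
  write_manifest(config, "simulate", character(0), as.list(paths),
                 counts = list(n_records = nrow(sim$records),
                               n_pixels = nrow(sim$grid)))
  list(paths = paths)
}

stage_evi <- function(config) {
  obs_path <- require_artifact(config, "observations.csv")
  obs <- read_csv_checked(obs_path,
                          c("pixel_id", "date", "red", "nir", "cloudy"))
  series <- aggregate_periods(obs)
  out <- file.path(config$out_dir, "evi_series.csv")
  write_csv_atomic(series, out)
  log_count(config, "evi: ", nrow(obs), " observations -> ",
            nrow(series), " period rows")
  write_manifest(config, "evi", obs_path, out,
                 counts = list(n_obs = nrow(obs), n_rows = nrow(series)))
  list(series = series)
}

stage_greenup <- function(config) {
  ser_path <- require_artifact(config, "evi_series.csv")
  series <- read_csv_checked(ser_path, c("pixel_id", "year", "period",
                                         "midpoint_day", "evi2", "n_clear"))
  map <- extract_greenup_map(series, min_periods = config$min_periods)
  out <- file.path(config$out_dir, "greenup.csv")
  write_csv_atomic(map, out)
  dropped <- sum(map$status != "ok")
  log_count(config, "greenup: ", nrow(map), " pixel-years, ", dropped,
            " dropped (", paste(unique(map$status[map$status != "ok"]),
                                collapse = ", "), ")")
  write_manifest(config, "greenup", ser_path, out,
                 counts = list(n_pixel_years = nrow(map),
                               n_dropped = dropped))
  list(map = map)
}

stage_nestbox <- function(config) {
  gu_path <- require_artifact(config, "greenup.csv")
  nb_path <- require_artifact(config, "nestboxes.csv")
  grid_path <- require_artifact(config, "grid.csv")
  map <- utils::read.csv(gu_path, stringsAsFactors = FALSE)
  nb <- read_csv_checked(nb_path, c("box_id", "x", "y"))
  grid <- read_csv_checked(grid_path, c("pixel_id", "x_center", "y_center",
                                        "woodland_fraction"))
  tab <- nestbox_greenup_table(nb, map, grid)
  out <- file.path(config$out_dir, "nestbox_greenup.csv")
  write_csv_atomic(tab, out)
  n_na <- sum(tab$status == "NotAssignable")
  log_count(config, "nestbox: ", nrow(tab), " box-years, ", n_na,
            " not assignable")
  write_manifest(config, "nestbox", c(gu_path, nb_path, grid_path), out,
                 counts = list(n_box_years = nrow(tab),
                               n_not_assignable = n_na))
  list(table = tab)
}

stage_prepare <- function(config) {
  br_path <- require_artifact(config, "breeding.csv")
  nb_path <- require_artifact(config, "nestboxes.csv")
  gu_path <- file.path(config$out_dir, "nestbox_greenup.csv")
  if (!file.exists(gu_path)) require_artifact(config, "nestbox_greenup.csv")
  rec <- read_csv_checked(br_path, c("box_id", "year", "species"))
  nb <- utils::read.csv(nb_path, stringsAsFactors = FALSE)
  gu <- utils::read.csv(gu_path, stringsAsFactors = FALSE)

  if (!"laying_day" %in% names(rec)) {
    rec$laying_day <- infer_laying_date(rec$observation_day,
                                        rec$eggs_observed)
  }
  n_in <- nrow(rec)
  rec <- filter_first_broods(rec, window_days = config$first_brood_window)
  n_excluded <- attr(rec, "n_excluded")
  j <- join_covariates(rec, nb, gu)
  tab <- j$table
  out <- file.path(config$out_dir, "analysis_table.csv")
  out_rej <- file.path(config$out_dir, "rejects.csv")
  write_csv_atomic(tab, out)
  write_csv_atomic(j$rejects, out_rej)
  log_count(config, "prepare: ", n_in, " records in, ", n_excluded,
            " excluded (late broods), ", nrow(j$rejects), " rejected, ",
            nrow(tab), " retained")
  write_manifest(config, "prepare", c(br_path, nb_path, gu_path),
                 c(out, out_rej),
                 counts = list(n_in = n_in, n_excluded = n_excluded,
                               n_rejected = nrow(j$rejects),
                               n_retained = nrow(tab)))
  list(table = tab, rejects = j$rejects)
}

stage_annual <- function(config) {
  tab_path <- require_artifact(config, "analysis_table.csv")
  gu_path <- require_artifact(config, "greenup.csv")
  grid_path <- require_artifact(config, "grid.csv")
  hf_path <- file.path(config$data_dir, "halffall.csv")
  tab <- utils::read.csv(tab_path, stringsAsFactors = FALSE)
  map <- utils::read.csv(gu_path, stringsAsFactors = FALSE)
  grid <- utils::read.csv(grid_path, stringsAsFactors = FALSE)
  hf <- if (file.exists(hf_path))
    utils::read.csv(hf_path, stringsAsFactors = FALSE) else NULL
  ann <- annual_phenology(map, grid, tab, halffall = hf,
                          woodland_threshold = config$woodland_threshold)
  out <- file.path(config$out_dir, "annual_phenology.csv")
  write_csv_atomic(ann, out)

  cors <- list()
  for (sp in intersect(config$species, unique(ann$species))) {
    a <- ann[ann$species == sp, , drop = FALSE]
    cors[[sp]] <- list(
      laying = tryCatch(annual_correlation(a$mean_greenup, a$mean_laying),
                        error = function(e) NULL),
      halffall = if (!is.null(hf))
        tryCatch(annual_correlation(a$mean_greenup, a$halffall_day),
                 error = function(e) NULL) else NULL)
  }
  out_json <- file.path(config$out_dir, "annual_correlations.json")
  jsonlite::write_json(cors, out_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  write_manifest(config, "annual", c(tab_path, gu_path, grid_path),
                 c(out, out_json))
  list(annual = ann, correlations = cors)
}

stage_lmm <- function(config) {
  tab_path <- require_artifact(config, "analysis_table.csv")
  tab <- utils::read.csv(tab_path, stringsAsFactors = FALSE)
  fits <- list()
  for (sp in intersect(config$species, unique(tab$species))) {
    s <- tab[tab$species == sp, , drop = FALSE]
    for (cov in c("minimal", "full")) {
      f <- fit_breeding_lmm(s, response = "laying_day", covariates = cov,
                            female_re = config$female_re)
      fits[[paste(sp, cov, sep = ".")]] <-
        list(coefficients = f$coefficients,
             ranef_sd = as.list(f$ranef_sd), n = f$n,
             singular = f$singular)
    }
  }
  out <- file.path(config$out_dir, "model_fits.json")
  jsonlite::write_json(fits, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  write_manifest(config, "lmm", tab_path, out)
  list(fits = fits)
}

stage_synchrony <- function(config) {
  tab_path <- require_artifact(config, "analysis_table.csv")
  gu_path <- require_artifact(config, "greenup.csv")
  grid_path <- require_artifact(config, "grid.csv")
  comp_path <- require_artifact(config, "compartments.csv")
  over_path <- require_artifact(config, "overlay.csv")
  tab <- utils::read.csv(tab_path, stringsAsFactors = FALSE)
  map <- utils::read.csv(gu_path, stringsAsFactors = FALSE)
  grid <- utils::read.csv(grid_path, stringsAsFactors = FALSE)
  comp <- utils::read.csv(comp_path, stringsAsFactors = FALSE)
  over <- utils::read.csv(over_path, stringsAsFactors = FALSE)

  habitat <- habitat_overlay(over, comp)
  maps <- list()
  regs <- list()
  for (sp in intersect(config$species, unique(tab$species))) {
    s <- tab[tab$species == sp, , drop = FALSE]
    sm <- pixel_synchrony(s, map, grid, min_years = config$min_years,
                          woodland_threshold = config$woodland_threshold)
    sm$species <- sp
    maps[[sp]] <- sm
    rg <- synchrony_habitat_regression(sm, habitat)
    rg$species <- sp
    regs[[sp]] <- rg
  }
  sync_all <- do.call(rbind, maps)
  regs_all <- do.call(rbind, regs)
  out_map <- file.path(config$out_dir, "synchrony_map.csv")
  out_reg <- file.path(config$out_dir, "habitat_regressions.csv")
  write_csv_atomic(sync_all, out_map)
  write_csv_atomic(regs_all, out_reg)

  comparison <- NULL
  if (length(maps) == 2) {
    comparison <- compare_species_synchrony(maps[[1]], maps[[2]])
    jsonlite::write_json(comparison,
                         file.path(config$out_dir,
                                   "species_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log_count(config, "synchrony: ",
            sum(sync_all$included), " pixels included of ",
            nrow(sync_all))
  write_manifest(config, "synchrony",
                 c(tab_path, gu_path, grid_path, comp_path, over_path),
                 c(out_map, out_reg))
  list(map = sync_all, regressions = regs_all, comparison = comparison)
}

stage_mantel <- function(config) {
  tab_path <- require_artifact(config, "analysis_table.csv")
  tab <- utils::read.csv(tab_path, stringsAsFactors = FALSE)
  out_rows <- list()
  for (sp in intersect(config$species, unique(tab$species))) {
    s <- tab[tab$species == sp, , drop = FALSE]
    # correct laying dates for annual (and optional female) effects, then
    # average residuals per box
    res <- laying_residuals(s, female_re = config$female_re)
    agg <- stats::aggregate(res$resid,
                            by = list(box_id = res$box_id), FUN = mean)
    names(agg)[2] <- "resid_mean"
    xy <- stats::aggregate(cbind(x, y) ~ box_id, data = s, FUN = mean)
    m <- merge(agg, xy, by = "box_id")
    if (nrow(m) < 4) next
    cg <- mantel_correlogram(m[c("x", "y")], m$resid_mean,
                             seed = config$seed + 7L)
    cg$species <- sp
    out_rows[[sp]] <- cg
  }
  cg_all <- do.call(rbind, out_rows)
  out <- file.path(config$out_dir, "correlogram.csv")
  write_csv_atomic(as.data.frame(cg_all), out)
  write_manifest(config, "mantel", tab_path, out)
  list(correlogram = cg_all)
}

stage_cloudscan <- function(config) {
  tab_path <- require_artifact(config, "analysis_table.csv")
  cloud_path <- require_artifact(config, "cloud.csv")
  tab <- utils::read.csv(tab_path, stringsAsFactors = FALSE)
  cloud <- read_csv_checked(cloud_path,
                            c("year", "period", "cloud_fraction"))
  windows <- enumerate_windows(config$window_min_len,
                               config$window_max_len,
                               config$window_horizon)
  scans <- list()
  syncs <- list()
  for (sp in intersect(config$species, unique(tab$species))) {
    s <- tab[tab$species == sp, , drop = FALSE]
    sync <- annual_synchrony_series(s)
    sync$species <- sp
    syncs[[sp]] <- sync
    sc <- scan_windows(windows, cloud, sync)
    sc$species <- sp
    scans[[sp]] <- sc
  }
  out_scan <- file.path(config$out_dir, "window_scan.csv")
  out_sync <- file.path(config$out_dir, "annual_synchrony.csv")
  write_csv_atomic(do.call(rbind, scans), out_scan)
  write_csv_atomic(do.call(rbind, syncs), out_sync)
  write_manifest(config, "cloudscan", c(tab_path, cloud_path),
                 c(out_scan, out_sync))
  list(scan = do.call(rbind, scans), synchrony = do.call(rbind, syncs))
}

# Residual laying dates after removing annual (and optionally female)
# effects, via random-intercept mixed models; these are the adjusted
# values fed to the spatial correlograms.
laying_residuals <- function(table, female_re = FALSE) {
  tab <- table
  if (female_re) {
    tab <- tab[!is.na(tab$female_id) & tab$female_id != "", , drop = FALSE]
  }
  rand <- "(1 | year)"
  if (female_re) rand <- paste(rand, "+ (1 | female_id)")
  fml <- stats::as.formula(paste("laying_day ~ 1 +", rand))
  fit <- lme4::lmer(fml, data = tab, REML = TRUE)
  data.frame(box_id = tab$box_id, resid = stats::residuals(fit))
}
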