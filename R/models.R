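#' Pearson correlation between two annual series
#'
#' Correlates two yearly series on complete pairs, returning the Pearson
#' coefficient with its two-sided p-value. Used for the annual-scale
#' comparisons (green-up vs caterpillar half-fall, mean laying, mean
#' hatching).
#'
#' @param x,y numeric vectors of equal length (typically one value per
#'   year); pairs with a missing member are dropped.
#' @return list with `r`, `p`, `n`.
#' @export
annual_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete year pairs", call. = FALSE)
  if (stats::sd(x[ok]) < 1e-12 || stats::sd(y[ok]) < 1e-12) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Partition a predictor into between-year and within-year components
#'
#' Within-subject/between-subject centring: the between-year component of
#' each record's green-up date is its year's mean; the within-year
#' component is the deviation from that mean. The two sum back to the
#' observed value exactly, and in a balanced design the components are
#' empirically uncorrelated, so a mixed model can separate the
#' cross-sectional (between-year) from the longitudinal (within-year)
#' response of laying date to green-up.
#'
#' @param values numeric vector (e.g. nestbox green-up dates).
#' @param year grouping vector, same length.
#' @return data frame with `between` (year mean, repeated per record) and
#'   `within` (deviation).
#' @export
partition_within_between <- function(values, year) {
  between <- stats::ave(values, year, FUN = function(v) mean(v, na.rm = TRUE))
  data.frame(between = between, within = values - between)
}

#' Linear mixed model for individual breeding phenology
#'
#' Fits, by REML, a linear mixed model of laying (or hatch) date on
#' nestbox green-up partitioned into within- and between-year components,
#' with random intercepts for year and nestbox. The minimal model has no
#' further fixed effects; the full model controls for altitude, distance
#' from the woodland edge, and local oak density. Optionally female
#' identity is added as a third random intercept, which restricts the
#' data to attempts with a known female.
#'
#' Coefficient p-values are a large-sample normal approximation on the
#' t-values (the point estimates and SEs are the quantities of interest;
#' no MCMC-based inference is attempted).
#'
#' @param table analysis table from [join_covariates()]; must contain the
#'   response, `nestbox_greenup`, `year`, `box_id`, and for the full model
#'   `altitude`, `edge_distance`, `oak_density_75m`.
#' @param response `"laying_day"` or `"hatch_day"`.
#' @param covariates `"minimal"` or `"full"`.
#' @param random random-intercept set: `"year_box"` (default) or
#'   `"year"`. With a year-only random effect the within-year coefficient
#'   is algebraically invariant to year-constant shifts of the green-up
#'   values (the centred predictor has zero year sums, so its normal
#'   equations decouple); the crossed nestbox intercept couples the
#'   columns across years and makes that invariance approximate.
#' @param female_re include a female random intercept (drops rows with
#'   missing `female_id`).
#' @return object of class `phenosync_lmm`: list with `coefficients`
#'   (data frame: estimate, se, t, p), `ranef_sd`, `n`, `singular`,
#'   `model` (the `lme4` fit).
#' @export
fit_breeding_lmm <- function(table, response = "laying_day",
                             covariates = c("minimal", "full"),
                             random = c("year_box", "year"),
                             female_re = FALSE) {
  covariates <- match.arg(covariates)
  random <- match.arg(random)
  tab <- table
  if (female_re) {
    tab <- tab[!is.na(tab$female_id) & tab$female_id != "", , drop = FALSE]
  }
  pw <- partition_within_between(tab$nestbox_greenup, tab$year)
  tab$gu_within <- pw$within
  tab$gu_between <- pw$between
  fixed <- c("gu_within", "gu_between")
  if (covariates == "full") {
    fixed <- c(fixed, "altitude", "edge_distance", "oak_density_75m")
  }
  rand <- if (random == "year_box") c("(1 | year)", "(1 | box_id)") else
    "(1 | year)"
  if (female_re) rand <- c(rand, "(1 | female_id)")
  fml <- stats::as.formula(paste(response, "~",
                                 paste(c(fixed, rand), collapse = " + ")))
  ok <- stats::complete.cases(tab[c(response, fixed, "year", "box_id")])
  tab <- tab[ok, , drop = FALSE]
  if (length(unique(tab$year)) < 2 || length(unique(tab$box_id)) < 2) {
    stop("need >= 2 levels for each random factor", call. = FALSE)
  }
  fit <- lme4::lmer(fml, data = tab, REML = TRUE)
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"], t = cf[, "t value"],
                      p = 2 * stats::pnorm(-abs(cf[, "t value"])),
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_sd <- stats::setNames(vc$sdcor, paste0(vc$grp,
                                               ifelse(is.na(vc$var1), "",
                                                      "")))
  structure(list(coefficients = coefs, ranef_sd = ranef_sd,
                 n = nrow(tab), singular = lme4::isSingular(fit),
                 response = response, covariates = covariates,
                 female_re = female_re, model = fit),
            class = "phenosync_lmm")
}

#' @export
print.phenosync_lmm <- function(x, ...) {
  cat("Linear mixed model:", x$response, "(", x$covariates, "fixed effects",
      if (x$female_re) "+ female RE" else "", ")\n")
  cat("n =", x$n, if (x$singular) " [singular fit]" else "", "\n\n")
  print(x$coefficients, digits = 4)
  cat("\nRandom-effect SDs:\n")
  print(round(x$ranef_sd, 3))
  invisible(x)
}

#' Annual mean green-up date over woodland pixels
#'
#' The study-site-level green-up date for a year: the unweighted mean
#' over pixels whose woodland fraction strictly exceeds the threshold
#' (default 0.5) and that have a valid green-up date, excluding
#' farmland-contaminated border pixels.
#'
#' @param greenup_map data frame with `pixel_id`, `year`, `greenup_day`.
#' @param grid pixel grid with `pixel_id`, `woodland_fraction`.
#' @param year the year to summarize.
#' @param woodland_threshold strict lower bound on woodland fraction.
#' @return mean day of year (scalar).
#' @export
annual_mean_greenup <- function(greenup_map, grid, year,
                                woodland_threshold = 0.5) {
  m <- merge(greenup_map[greenup_map$year == year, , drop = FALSE],
             grid[c("pixel_id", "woodland_fraction")], by = "pixel_id")
  sel <- m$woodland_fraction > woodland_threshold & is.finite(m$greenup_day)
  if (!any(sel)) stop("no qualifying woodland pixel in year ", year,
                      call. = FALSE)
  mean(m$greenup_day[sel])
}

#' Annual phenology summary table
#'
#' One row per year: woodland-pixel mean green-up, per-species mean
#' laying and hatch dates with standard errors, and (if supplied) the
#' caterpillar half-fall date.
#'
#' @param greenup_map,grid as in [annual_mean_greenup()].
#' @param analysis_table individual analysis table (needs `year`,
#'   `species`, `laying_day`, optionally `hatch_day`).
#' @param halffall optional data frame `year`, `halffall_day`.
#' @param woodland_threshold passed to [annual_mean_greenup()].
#' @return data frame keyed by year and species.
#' @export
annual_phenology <- function(greenup_map, grid, analysis_table,
                             halffall = NULL, woodland_threshold = 0.5) {
  years <- sort(unique(analysis_table$year))
  species <- sort(unique(analysis_table$species))
  rows <- list()
  se <- function(v) stats::sd(v) / sqrt(length(v))
  for (yr in years) {
    gmean <- tryCatch(annual_mean_greenup(greenup_map, grid, yr,
                                          woodland_threshold),
                      error = function(e) NA_real_)
    for (sp in species) {
      sel <- analysis_table$year == yr & analysis_table$species == sp
      lay <- analysis_table$laying_day[sel]
      hat <- if ("hatch_day" %in% names(analysis_table))
        analysis_table$hatch_day[sel] else numeric(0)
      rows[[length(rows) + 1L]] <- data.frame(
        year = yr, species = sp, mean_greenup = gmean,
        mean_laying = if (length(lay)) mean(lay) else NA_real_,
        se_laying = if (length(lay) > 1) se(lay) else NA_real_,
        mean_hatch = if (length(hat)) mean(hat, na.rm = TRUE) else NA_real_,
        n_attempts = sum(sel))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(halffall)) {
    out <- merge(out, halffall, by = "year", all.x = TRUE)
  }
  out[order(out$species, out$year), , drop = FALSE]
}
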