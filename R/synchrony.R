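#' Pixel-level phenological synchrony map
#'
#' For each pixel the across-year Pearson correlation between the pixel's
#' annual mean laying date (over breeding attempts in nestboxes inside
#' that pixel) and the pixel's annual green-up date. Pixels are included
#' only when their woodland fraction strictly exceeds the threshold and
#' they have at least `min_years` year-points; low-support and
#' farmland-contaminated pixels carry too little information for a
#' meaningful correlation.
#'
#' @param analysis_table individual analysis table with `pixel_id`,
#'   `year`, `laying_day` (pixel assignment = pixel containing the
#'   nestbox).
#' @param greenup_map data frame `pixel_id`, `year`, `greenup_day`.
#' @param grid pixel grid with `pixel_id`, `woodland_fraction`.
#' @param min_years minimum number of year-points (default 6).
#' @param woodland_threshold strict lower bound on woodland fraction.
#' @return data frame per pixel: `pixel_id`, `r`, `n_years`,
#'   `n_attempts`, `woodland_fraction`, `included`, `exclude_reason`.
#' @export
pixel_synchrony <- function(analysis_table, greenup_map, grid,
                            min_years = 6, woodland_threshold = 0.5) {
  stopifnot("pixel_id" %in% names(analysis_table))
  rows <- lapply(grid$pixel_id, function(px) {
    wf <- grid$woodland_fraction[grid$pixel_id == px]
    att <- analysis_table[analysis_table$pixel_id == px, , drop = FALSE]
    gu <- greenup_map[greenup_map$pixel_id == px &
                        is.finite(greenup_map$greenup_day), , drop = FALSE]
    if (nrow(att) == 0L) {
      return(data.frame(pixel_id = px, r = NA_real_, n_years = 0L,
                        n_attempts = 0L, woodland_fraction = wf,
                        included = FALSE, exclude_reason = "no_attempts"))
    }
    yl <- tapply(att$laying_day, att$year, mean)
    ydf <- data.frame(year = as.integer(names(yl)), mean_laying = as.numeric(yl))
    m <- merge(ydf, gu[c("year", "greenup_day")], by = "year")
    n_years <- nrow(m)
    n_att <- nrow(att)
    reason <- ""
    r <- NA_real_
    if (wf <= woodland_threshold) {
      reason <- "non_woodland"
    } else if (n_years < min_years) {
      reason <- "too_few_years"
    } else if (stats::sd(m$mean_laying) < 1e-12 ||
               stats::sd(m$greenup_day) < 1e-12) {
      reason <- "zero_variance"
    } else {
      r <- stats::cor(m$mean_laying, m$greenup_day)
    }
    data.frame(pixel_id = px, r = r, n_years = n_years,
               n_attempts = n_att, woodland_fraction = wf,
               included = reason == "", exclude_reason = reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pixel habitat composition from compartment overlays
#'
#' Habitat surveys record canopy and understory species proportions per
#' management compartment; pixel-level values are the
#' intersection-area-weighted averages of the overlapping compartments,
#' with area shares renormalized over the covered part of each pixel.
#' Intersection areas are consumed precomputed (polygon overlay is out of
#' scope here).
#'
#' @param overlay data frame with `pixel_id`, `compartment_id`, `area`
#'   (intersection area, any consistent unit).
#' @param compartments data frame keyed by `compartment_id` whose
#'   remaining numeric columns are habitat proportions (e.g. `canopy_oak`,
#'   `under_hazel`).
#' @return data frame keyed by `pixel_id` with the area-weighted habitat
#'   columns; pixels with zero covered area are omitted.
#' @export
habitat_overlay <- function(overlay, compartments) {
  hab_cols <- setdiff(names(compartments), "compartment_id")
  m <- merge(overlay, compartments, by = "compartment_id")
  pixels <- unique(m$pixel_id)
  rows <- lapply(pixels, function(px) {
    s <- m[m$pixel_id == px & m$area > 0, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    w <- s$area / sum(s$area)
    vals <- vapply(hab_cols, function(cl) sum(w * s[[cl]]), numeric(1))
    cbind(data.frame(pixel_id = px), as.data.frame(as.list(vals)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress pixel synchrony on habitat composition
#'
#' One weighted least-squares regression per habitat variable (the
#' variables are mutually dependent proportions, so they are tested
#' separately), of the pixel correlation coefficient on the habitat
#' proportion, weighted by the total number of breeding attempts per
#' pixel to reflect the varying confidence in the pixel coefficients.
#'
#' @param synchrony_map output of [pixel_synchrony()].
#' @param pixel_habitat output of [habitat_overlay()].
#' @param habitat_vars character vector of habitat columns to test; by
#'   default every habitat column present.
#' @param use_weights weight by `n_attempts` (default TRUE).
#' @param included_only restrict to pixels with a defined r; pixels
#'   excluded for low support are dropped automatically since their r is
#'   undefined.
#' @return data frame: `habitat_var`, `slope`, `se`, `t`, `p`,
#'   `n_pixels`.
#' @export
synchrony_habitat_regression <- function(synchrony_map, pixel_habitat,
                                         habitat_vars = NULL,
                                         use_weights = TRUE,
                                         included_only = TRUE) {
  if (is.null(habitat_vars)) {
    habitat_vars <- setdiff(names(pixel_habitat), "pixel_id")
  }
  d <- merge(synchrony_map, pixel_habitat, by = "pixel_id")
  d <- d[is.finite(d$r), , drop = FALSE]
  if (included_only) d <- d[d$included, , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 pixels with defined synchrony",
                        call. = FALSE)
  w <- if (use_weights) d$n_attempts else rep(1, nrow(d))
  rows <- lapply(habitat_vars, function(v) {
    if (stats::sd(d[[v]]) < 1e-12) {
      return(data.frame(habitat_var = v, slope = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, n_pixels = nrow(d)))
    }
    fit <- stats::lm(d$r ~ d[[v]], weights = w)
    # an exactly linear planted structure triggers summary.lm's
    # perfect-fit warning; the zero-SE rows it produces are correct
    cf <- suppressWarnings(summary(fit)$coefficients)
    data.frame(habitat_var = v, slope = cf[2, 1], se = cf[2, 2],
               t = cf[2, 3], p = cf[2, 4], n_pixels = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare pixel-level synchrony between two species
#'
#' Welch two-sample t-test on the included pixel correlation coefficients
#' of two synchrony maps, plus the Pearson correlation between the two
#' species' coefficients over the pixels common to both maps.
#'
#' @param map_a,map_b outputs of [pixel_synchrony()] for the two species.
#' @return list: `t`, `df`, `p`, `mean_a`, `se_a`, `n_a`, `mean_b`,
#'   `se_b`, `n_b`, `paired_r`, `paired_n`, `degenerate` (TRUE when both
#'   samples have zero variance and the t statistic is undefined).
#' @export
compare_species_synchrony <- function(map_a, map_b) {
  a <- map_a$r[map_a$included & is.finite(map_a$r)]
  b <- map_b$r[map_b$included & is.finite(map_b$r)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each map needs >= 2 included pixels", call. = FALSE)
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))
  degenerate <- stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12
  if (degenerate) {
    tt <- list(statistic = c(t = Inf * sign(mean(a) - mean(b))),
               parameter = c(df = NA_real_), p.value = NA_real_)
  } else {
    tt <- stats::t.test(a, b)
  }
  common <- merge(map_a[map_a$included, c("pixel_id", "r")],
                  map_b[map_b$included, c("pixel_id", "r")],
                  by = "pixel_id")
  common <- common[is.finite(common$r.x) & is.finite(common$r.y), ,
                   drop = FALSE]
  paired_r <- if (nrow(common) >= 3 && stats::sd(common$r.x) > 1e-12 &&
                  stats::sd(common$r.y) > 1e-12) {
    stats::cor(common$r.x, common$r.y)
  } else NA_real_
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), se_a = se(a), n_a = length(a),
       mean_b = mean(b), se_b = se(b), n_b = length(b),
       paired_r = paired_r, paired_n = nrow(common),
       degenerate = degenerate)
}
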