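#' Fit a penalized-spline smooth to one pixel-year EVI2 series
#'
#' A cubic penalized regression spline (shrinkage basis, dimension 30) of
#' EVI2 on midpoint day, with the smoothing parameter chosen by
#' generalized cross-validation. The deliberately generous basis with GCV
#' shrinkage imposes no prior shape on the green-up curve, so the same
#' smoother handles logistic-like spring rises and flat or double-peaked
#' series alike. A coarser basis localizes the derivative maximum poorly
#' (knot-phase errors of several days on 8-day-sampled series); dimension
#' 30 lets GCV interpolate clean series while still damping noisy ones.
#'
#' @param series data frame for a single pixel-year as produced by
#'   [aggregate_periods()] (columns `midpoint_day`, `evi2`; missing
#'   periods allowed).
#' @param min_periods minimum number of non-missing periods required to
#'   attempt a fit (default 20); series with fewer are flagged
#'   non-converged and dropped downstream.
#' @param k spline basis dimension.
#' @return an object of class `greenup_smooth`: list with the `mgcv` fit
#'   (`gam`), `n_used`, and `converged`.
#' @export
fit_smooth_curve <- function(series, min_periods = 20, k = 30) {
  ok <- is.finite(series$evi2) & is.finite(series$midpoint_day)
  n_used <- sum(ok)
  if (n_used < min_periods) {
    return(structure(list(gam = NULL, n_used = n_used, converged = FALSE),
                     class = "greenup_smooth"))
  }
  dat <- data.frame(day = series$midpoint_day[ok], evi2 = series$evi2[ok])
  fit <- mgcv::gam(evi2 ~ s(day, k = k, bs = "cs"), data = dat,
                   method = "GCV.Cp")
  structure(list(gam = fit, n_used = n_used, converged = TRUE),
            class = "greenup_smooth")
}

#' Evaluate a fitted smooth and its first derivative on a day grid
#'
#' The derivative is a central finite difference of the spline prediction
#' (step 0.5 day), adequate for locating the derivative maximum on an
#' integer-day grid.
#'
#' @param smooth a `greenup_smooth` from [fit_smooth_curve()].
#' @param days numeric vector of days of year.
#' @return data frame with `day`, `value`, `deriv`.
#' @export
evaluate_smooth <- function(smooth, days) {
  stopifnot(inherits(smooth, "greenup_smooth"), smooth$converged)
  h <- 0.5
  pred <- function(d) as.numeric(
    mgcv::predict.gam(smooth$gam, newdata = data.frame(day = d)))
  data.frame(day = days,
             value = pred(days),
             deriv = (pred(days + h) - pred(days - h)) / (2 * h))
}

#' Extract the green-up date from a fitted smooth
#'
#' Green-up is the day, on an integer-day grid within the evaluation
#' window, at which the first derivative of the smooth is maximal -- the
#' day of the fastest increase in canopy greenness, a proxy for deciduous
#' bud-burst. Ties are broken to the earliest day. A non-positive maximum
#' derivative means the series never rises within the window; such fits
#' are flagged (`status = "NoGreenUp"`) and excluded downstream.
#'
#' @param smooth a `greenup_smooth`.
#' @param window integer vector `c(first, last)` day of year delimiting
#'   the search (default `c(30, 250)`, avoiding boundary artifacts of the
#'   spline).
#' @return list with `greenup_day`, `max_derivative`, `n_periods_used`,
#'   `converged`, `status` (`"ok"`, `"NoGreenUp"`, `"NotEstimable"`).
#' @export
extract_greenup_date <- function(smooth, window = c(30, 250)) {
  if (!smooth$converged) {
    return(list(greenup_day = NA_real_, max_derivative = NA_real_,
                n_periods_used = smooth$n_used, converged = FALSE,
                status = "NotEstimable"))
  }
  days <- seq(as.integer(window[1]), as.integer(window[2]))
  ev <- evaluate_smooth(smooth, days)
  i <- which.max(ev$deriv) # which.max returns the first (earliest) maximum
  if (!is.finite(ev$deriv[i]) || ev$deriv[i] <= 1e-9) {
    return(list(greenup_day = NA_real_, max_derivative = ev$deriv[i],
                n_periods_used = smooth$n_used, converged = TRUE,
                status = "NoGreenUp"))
  }
  list(greenup_day = ev$day[i], max_derivative = ev$deriv[i],
       n_periods_used = smooth$n_used, converged = TRUE, status = "ok")
}

#' Green-up map for many pixel-years
#'
#' Applies [fit_smooth_curve()] + [extract_greenup_date()] to every
#' pixel-year of an EVI2 series table.
#'
#' @param evi_series data frame from [aggregate_periods()].
#' @inheritParams fit_smooth_curve
#' @inheritParams extract_greenup_date
#' @return data frame (one row per pixel-year): `pixel_id`, `year`,
#'   `greenup_day`, `max_derivative`, `n_periods_used`, `converged`,
#'   `status`.
#' @export
extract_greenup_map <- function(evi_series, min_periods = 20,
                                window = c(30, 250), k = 30) {
  keys <- unique(evi_series[c("pixel_id", "year")])
  keys <- keys[order(keys$pixel_id, keys$year), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- evi_series$pixel_id == keys$pixel_id[i] &
      evi_series$year == keys$year[i]
    sm <- fit_smooth_curve(evi_series[sel, , drop = FALSE],
                           min_periods = min_periods, k = k)
    g <- extract_greenup_date(sm, window = window)
    data.frame(pixel_id = keys$pixel_id[i], year = keys$year[i],
               greenup_day = g$greenup_day,
               max_derivative = g$max_derivative,
               n_periods_used = g$n_periods_used,
               converged = g$converged, status = g$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Z-transform a green-up map within years
#'
#' Centres each year's pixel green-up dates by the annual mean and scales
#' by the annual standard deviation (sample sd), so maps from different
#' years share a common scale for display and comparison. Years with zero
#' variance return all zeros with a warning.
#'
#' @param greenup_map data frame with `pixel_id`, `year`, `greenup_day`.
#' @return the input with an added `greenup_z` column.
#' @export
z_transform_map <- function(greenup_map) {
  out <- greenup_map
  out$greenup_z <- NA_real_
  for (yr in unique(out$year)) {
    sel <- out$year == yr & is.finite(out$greenup_day)
    if (sum(sel) < 2) next
    v <- out$greenup_day[sel]
    s <- stats::sd(v)
    if (s < 1e-12) {
      warning("zero variance in year ", yr, "; z-scores set to 0")
      out$greenup_z[sel] <- 0
    } else {
      out$greenup_z[sel] <- (v - mean(v)) / s
    }
  }
  out
}
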