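#' Two-band enhanced vegetation index (EVI2)
#'
#' EVI2 = 2.5 * (NIR - Red) / (NIR + 2.4 * Red + 1), a two-band variant of
#' the enhanced vegetation index that needs no blue band and is robust to
#' soil background. With reflectances in \[0, 1\] the index is bounded in
#' \[-0.74, 1.25\] and is monotonically increasing in NIR at fixed Red.
#'
#' @param red,nir surface reflectances in \[0, 1\]; vectors are recycled
#'   in the usual way.
#' @return numeric vector of index values.
#' @examples
#' compute_evi2(0.05, 0.40) # 0.5757
#' compute_evi2(0.3, 0.3)   # 0 whenever nir == red
#' @export
compute_evi2 <- function(red, nir) {
  if (any(!is.finite(red)) || any(!is.finite(nir)) ||
      any(red < 0 | red > 1) || any(nir < 0 | nir > 1)) {
    stop("reflectances must be finite and within [0, 1]", call. = FALSE)
  }
  2.5 * (nir - red) / (nir + 2.4 * red + 1)
}

# Inverse of compute_evi2 at fixed red: the NIR reflectance giving a target
# index value. Used by the synthetic generator only; the map is monotone so
# the inversion is exact.
evi2_to_nir <- function(evi2, red = 0.05) {
  (evi2 * (2.4 * red + 1) + 2.5 * red) / (2.5 - evi2)
}

#' Midpoint day of an 8-day compositing period
#'
#' Periods partition the year into 46 blocks of 8 days anchored at day 1
#' (the final block holds days 361-365/366). The "middle day" of days
#' d..d+7 has no integer centre; the convention here is the 4th day,
#' `8 * (index - 1) + 4`, within half a day of the true centre.
#'
#' @param period_index integer period index in 1..46.
#' @return integer day of year.
#' @examples
#' period_midpoint(1)  # 4
#' period_midpoint(15) # 116
#' @export
period_midpoint <- function(period_index) {
  if (any(period_index < 1 | period_index > 46 |
          period_index != round(period_index))) {
    stop("period_index must be an integer in 1..46", call. = FALSE)
  }
  8L * (as.integer(period_index) - 1L) + 4L
}

# Period containing a given day of year (1..366); days 361-366 fall in
# period 46.
day_to_period <- function(doy) {
  pmin(ceiling(doy / 8), 46L)
}

#' Aggregate cloud-flagged observations into 8-day EVI2 series
#'
#' For every pixel-year, the EVI2 value of each 8-day period is the
#' arithmetic mean over the period's cloud-free observations; cloudy looks
#' never contribute. Periods with no clear look are reported missing
#' (`evi2 = NA`, `n_clear = 0`). All 46 periods are emitted for every
#' pixel-year present in the input, so series are rectangular.
#'
#' @param obs data frame with columns `pixel_id`, `date` (Date or
#'   ISO-8601 string), `red`, `nir`, `cloudy` (0/1 or logical).
#' @return data frame with columns `pixel_id`, `year`, `period`,
#'   `midpoint_day`, `evi2`, `n_clear`.
#' @export
aggregate_periods <- function(obs) {
  stopifnot(all(c("pixel_id", "date", "red", "nir", "cloudy") %in% names(obs)))
  date <- as.Date(obs$date)
  year <- as.integer(format(date, "%Y"))
  doy <- as.integer(format(date, "%j"))
  period <- day_to_period(doy)
  cloudy <- as.logical(obs$cloudy)

  if (nrow(obs) == 0L) {
    return(data.frame(pixel_id = character(0), year = integer(0),
                      period = integer(0), midpoint_day = integer(0),
                      evi2 = numeric(0), n_clear = integer(0)))
  }
  clear <- !cloudy
  evi <- rep(NA_real_, nrow(obs))
  evi[clear] <- compute_evi2(obs$red[clear], obs$nir[clear])

  # flat coding (pixel-year block) x period, aggregated in one pass
  py <- paste(obs$pixel_id, year, sep = "\r")
  keys <- unique(data.frame(pixel_id = obs$pixel_id, year = year, py = py))
  keys <- keys[order(keys$pixel_id, keys$year), , drop = FALSE]
  ipy <- match(py, keys$py)
  code <- (ipy - 1L) * 46L + period
  ncell <- nrow(keys) * 46L
  n_clear <- tabulate(code[clear], nbins = ncell)
  sums <- numeric(ncell)
  if (any(clear)) {
    rs <- rowsum(evi[clear], code[clear])
    sums[as.integer(rownames(rs))] <- rs[, 1]
  }
  out <- data.frame(
    pixel_id = rep(keys$pixel_id, each = 46L),
    year = rep(keys$year, each = 46L),
    period = rep(1:46, times = nrow(keys)),
    midpoint_day = rep(period_midpoint(1:46), times = nrow(keys)),
    evi2 = ifelse(n_clear > 0, sums / pmax(n_clear, 1L), NA_real_),
    n_clear = n_clear)
  rownames(out) <- NULL
  out
}
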