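#' Enumerate sliding windows of 8-day periods
#'
#' All contiguous windows of `min_len` to `max_len` periods fitting
#' within the first `horizon` periods of the year. With the defaults
#' (3-15 periods within the first 15 periods, i.e. 24-120 days within the
#' first 120 days of the year) there are exactly 91 windows.
#'
#' @param min_len,max_len window length bounds in periods.
#' @param horizon number of periods available (default 15).
#' @return data frame with `start`, `length` (and `end`).
#' @export
enumerate_windows <- function(min_len = 3, max_len = 15, horizon = 15) {
  if (min_len > horizon) {
    warning("min_len exceeds horizon; no windows")
    return(data.frame(start = integer(0), length = integer(0),
                      end = integer(0)))
  }
  if (!(1 <= min_len && min_len <= max_len && max_len <= horizon)) {
    stop("need 1 <= min_len <= max_len <= horizon", call. = FALSE)
  }
  rows <- list()
  for (len in seq(min_len, max_len)) {
    starts <- seq_len(horizon - len + 1)
    rows[[length(rows) + 1L]] <- data.frame(start = starts, length = len)
  }
  out <- do.call(rbind, rows)
  out$end <- out$start + out$length - 1L
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annual synchrony between individual laying and nestbox green-up
#'
#' For each year, the Pearson correlation between individual laying dates
#' and the nestbox-specific green-up dates of the attempts in that year:
#' an annual measure of how tightly the birds track the local vegetation
#' signal. Years with fewer than `min_pairs` usable attempts are missing.
#'
#' @param analysis_table rows with `year`, `laying_day`,
#'   `nestbox_greenup`.
#' @param min_pairs minimum attempts per year (default 3).
#' @return data frame `year`, `r`, `n`.
#' @export
annual_synchrony_series <- function(analysis_table, min_pairs = 3) {
  years <- sort(unique(analysis_table$year))
  rows <- lapply(years, function(yr) {
    s <- analysis_table[analysis_table$year == yr, , drop = FALSE]
    ok <- is.finite(s$laying_day) & is.finite(s$nestbox_greenup)
    n <- sum(ok)
    r <- if (n >= min_pairs &&
             stats::sd(s$laying_day[ok]) > 1e-12 &&
             stats::sd(s$nestbox_greenup[ok]) > 1e-12) {
      stats::cor(s$laying_day[ok], s$nestbox_greenup[ok])
    } else NA_real_
    data.frame(year = yr, r = r, n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan cloudiness windows against annual synchrony
#'
#' For every window, the mean cloud fraction over the window's periods is
#' computed per year and regressed (ordinary least squares) against the
#' annual synchrony series, pairing years present in both and dropping
#' missing years pairwise. Windows are ranked by |r| descending (the
#' strongest associations are negative -- cloudier early springs thin the
#' satellite record and weaken the apparent synchrony -- so magnitude
#' ordering puts them first); a signed-r ranking is also emitted. Ties
#' break by (start, length) ascending. Windows whose mean cloudiness does
#' not vary across years have no defined regression and are excluded from
#' the ranking with a flag.
#'
#' @param windows data frame from [enumerate_windows()].
#' @param cloud data frame `year`, `period`, `cloud_fraction` (percent,
#'   0-100).
#' @param synchrony data frame `year`, `r` from
#'   [annual_synchrony_series()].
#' @return data frame per window: `start`, `length`, `slope`,
#'   `intercept`, `se`, `t`, `p`, `r`, `n_years`, `excluded`,
#'   `rank_abs`, `rank_signed`.
#' @export
scan_windows <- function(windows, cloud, synchrony) {
  if (any(cloud$cloud_fraction < 0 | cloud$cloud_fraction > 100,
          na.rm = TRUE)) {
    stop("cloud fractions must be percentages in [0, 100]", call. = FALSE)
  }
  sync <- synchrony[is.finite(synchrony$r), , drop = FALSE]
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    st <- windows$start[i]; len <- windows$length[i]
    per <- seq(st, st + len - 1)
    cw <- cloud[cloud$period %in% per, , drop = FALSE]
    mc <- tapply(cw$cloud_fraction, cw$year, mean)
    mdf <- data.frame(year = as.integer(names(mc)),
                      mean_cloud = as.numeric(mc))
    m <- merge(sync, mdf, by = "year")
    n <- nrow(m)
    base <- data.frame(start = st, length = len, slope = NA_real_,
                       intercept = NA_real_, se = NA_real_, t = NA_real_,
                       p = NA_real_, r = NA_real_, n_years = n,
                       excluded = TRUE)
    if (n < 3) return(base)
    if (stats::sd(m$mean_cloud) < 1e-12) return(base)
    fit <- stats::lm(r ~ mean_cloud, data = m)
    cf <- suppressWarnings(summary(fit)$coefficients) # exact fits allowed
    rr <- if (stats::sd(m$r) < 1e-12) NA_real_ else
      stats::cor(m$mean_cloud, m$r)
    data.frame(start = st, length = len, slope = cf[2, 1],
               intercept = cf[1, 1], se = cf[2, 2], t = cf[2, 3],
               p = cf[2, 4], r = rr, n_years = n,
               excluded = !is.finite(rr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  rank_within <- function(score) {
    r <- rep(NA_integer_, nrow(out))
    ok <- !out$excluded & is.finite(score)
    # ties broken by (start, length) ascending via stable ordering
    idx <- which(ok)[order(-score[ok], out$start[ok], out$length[ok])]
    r[idx] <- seq_along(idx)
    r
  }
  out$rank_abs <- rank_within(abs(out$r))
  out$rank_signed <- rank_within(out$r)
  out
}
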