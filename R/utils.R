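#' Convert between day-of-April and day-of-year
#'
#' Laying and hatch dates are handled internally on a day-of-April scale
#' (1 = 1 April, 0 = 31 March, negative values reach further into March),
#' the conventional scale for tit breeding data. Day-of-year 91 is 1 April
#' in non-leap years, 92 in leap years.
#'
#' @param x numeric vector of days on the source scale.
#' @param year calendar year (scalar or vector recycled against `x`);
#'   determines leap-year offset.
#' @return numeric vector on the target scale.
#' @examples
#' april_to_doy(1, 2001)  # 91
#' doy_to_april(91, 2001) # 1
#' @export
april_to_doy <- function(x, year) {
  x + 90 + as.integer(is_leap_year(year))
}

#' @rdname april_to_doy
#' @export
doy_to_april <- function(x, year) {
  x - 90 - as.integer(is_leap_year(year))
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Gaussian-smoothed random field on a regular grid
#'
#' White noise smoothed with a separable Gaussian kernel and standardized
#' to mean 0, sd 1. The kernel bandwidth (in metres) divided by the pixel
#' size gives the smoothing sigma in pixel units; a bandwidth of 0 returns
#' (standardized) white noise, i.e. no spatial autocorrelation.
#'
#' Used by the synthetic-data generators for habitat composition, altitude
#' and the spatial component of green-up. Draws from the current RNG
#' stream; seed management is the caller's responsibility.
#'
#' @param rows,cols grid dimensions.
#' @param range_m kernel bandwidth in metres (>= 0).
#' @param pixel_size pixel edge length in metres.
#' @return a `rows` x `cols` matrix with mean 0 and sd 1.
#' @export
smooth_field <- function(rows, cols, range_m, pixel_size = 240) {
  stopifnot(rows >= 1, cols >= 1, range_m >= 0, pixel_size > 0)
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  sigma <- range_m / pixel_size
  if (sigma > 1e-8) {
    half <- max(1L, as.integer(ceiling(3 * sigma)))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    smooth_vec <- function(v) {
      n <- length(v)
      out <- numeric(n)
      for (i in seq_len(n)) {
        idx <- (i - half):(i + half)
        ok <- idx >= 1L & idx <= n
        w <- k[ok]
        out[i] <- sum(w * v[idx[ok]]) / sum(w)
      }
      out
    }
    z <- apply(z, 2, smooth_vec)
    z <- t(apply(z, 1, smooth_vec))
    z <- matrix(z, rows, cols)
  }
  if (stats::sd(z) < 1e-12) return(matrix(0, rows, cols))
  (z - mean(z)) / stats::sd(z)
}

# Atomic CSV write: write to a temporary file in the same directory, then
# rename over the target, so partially written outputs are never visible.
write_csv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
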