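#' Infer laying date from a clutch observation
#'
#' Tits lay one egg per day, so the first-egg (laying) date is the
#' observation date minus (eggs observed - 1) days: a nest with 3 eggs on
#' 3 April began laying on 1 April.
#'
#' @param observation_day numeric day (any consistent scale, e.g.
#'   day-of-April) on which the clutch was counted.
#' @param eggs_observed integer egg count, >= 1.
#' @return laying day on the same scale as `observation_day`.
#' @examples
#' infer_laying_date(3, 3) # 1  (3 eggs on 3 April -> 1 April)
#' @export
infer_laying_date <- function(observation_day, eggs_observed) {
  if (any(eggs_observed < 1 | eggs_observed != round(eggs_observed))) {
    stop("eggs_observed must be an integer >= 1", call. = FALSE)
  }
  observation_day - (eggs_observed - 1)
}

#' Keep first broods only
#'
#' Second breeding attempts are excluded by keeping, within each year and
#' species, only clutches laid within 30 days (inclusive) of the first
#' clutch of that year. The year's earliest clutch is always retained.
#'
#' @param records data frame with `year`, `species`, `laying_day`.
#' @param window_days inclusive window after the first clutch (default 30).
#' @param by_species reference the first clutch per species (default TRUE)
#'   rather than pooled across species.
#' @return the retained subset, with attribute `n_excluded`.
#' @export
filter_first_broods <- function(records, window_days = 30,
                                by_species = TRUE) {
  grp <- if (by_species) {
    interaction(records$year, records$species, drop = TRUE)
  } else {
    factor(records$year)
  }
  first <- stats::ave(records$laying_day, grp, FUN = min)
  keep <- records$laying_day <= first + window_days
  out <- records[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Join breeding records with nestbox covariates and green-up dates
#'
#' Produces the individual-level analysis table: one row per breeding
#' attempt carrying laying/hatch dates, the nestbox-specific green-up day
#' for that year, and the site covariates (altitude, woodland-edge
#' distance, local oak density). Records at unknown boxes and records
#' whose box-year has no assignable green-up are returned in a rejects
#' table rather than silently dropped; retained + rejected counts always
#' sum to the input size.
#'
#' @param records breeding records: `box_id`, `year`, `species`,
#'   `laying_day`, optionally `hatch_day`, `female_id`.
#' @param nestboxes nestbox table: `box_id`, `x`, `y`, `altitude`,
#'   `edge_distance`, `oak_density_75m`.
#' @param nestbox_greenup table from [nestbox_greenup_table()].
#' @return list with `table` (analysis rows) and `rejects` (rows with a
#'   `reject_reason` column).
#' @export
join_covariates <- function(records, nestboxes, nestbox_greenup) {
  rec <- records
  rec$.row <- seq_len(nrow(rec))
  m <- merge(rec, nestboxes, by = "box_id", all.x = TRUE)
  gu <- nestbox_greenup[c("box_id", "year", "greenup_day", "status")]
  names(gu)[3] <- "nestbox_greenup"
  m <- merge(m, gu, by = c("box_id", "year"), all.x = TRUE)
  m <- m[order(m$.row), , drop = FALSE]

  unknown_box <- is.na(m$x)
  no_greenup <- !unknown_box & !is.finite(m$nestbox_greenup)
  ok <- !unknown_box & !no_greenup

  rejects <- m[!ok, , drop = FALSE]
  rejects$reject_reason <- ifelse(unknown_box[!ok], "unknown_box",
                                  "no_nestbox_greenup")
  tab <- m[ok, , drop = FALSE]
  tab$.row <- NULL
  rejects$.row <- NULL
  rownames(tab) <- rownames(rejects) <- NULL
  list(table = tab, rejects = rejects)
}
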