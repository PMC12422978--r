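#' Daytime evaporative fraction for one day
#'
#' EF = LE / (LE + H), the fraction of turbulent energy going to
#' evapotranspiration, averaged over daytime half hours. EF near 1 means
#' energy-limited (wet) conditions, near 0 water-limited (dry) conditions,
#' which makes the daily daytime EF a soil-water-availability and rewetting
#' proxy at sites without soil moisture sensors. Half hours where `le + h`
#' is not positive are excluded (EF is an energy fraction); each half-hourly
#' ratio is clipped to [0, 1] before averaging.
#'
#' @param le latent heat flux (W m-2), half-hourly vector for one day.
#' @param h sensible heat flux (W m-2).
#' @param sw_in incoming shortwave radiation (W m-2).
#' @param sw_threshold daytime cut: half hours with `sw_in >= sw_threshold`.
#' @return scalar EF in [0, 1], or `NA` if no qualifying half hour.
#' @export
daytime_ef <- function(le, h, sw_in, sw_threshold = 50) {
  ok <- !is.na(le) & !is.na(h) & !is.na(sw_in) &
    sw_in >= sw_threshold & (le + h) > 0
  if (!any(ok)) return(NA_real_)
  mean(pmin(1, pmax(0, le[ok] / (le[ok] + h[ok]))))
}

#' Antecedent (prepulse) mean of a daily series
#'
#' Mean of a daily series over the `window_days` days strictly before an
#' event start, the antecedent water-availability index when applied to
#' daytime EF (a low prepulse EF marks a dry antecedent period) and the
#' antecedent-productivity index when applied to daily mean NEE.
#'
#' @param daily a daily table with a `date` column (see [to_daily()]).
#' @param event_start `Date`, the event (rain) start day.
#' @param column which daily column to average.
#' @param window_days antecedent window length (default 15 days; 14 is the
#'   other conventional choice).
#' @param min_days minimum valid days required; fewer gives `NA`.
#' @return the antecedent mean, with attribute `truncated = TRUE` when the
#'   window extends before the start of record.
#' @export
prepulse_mean <- function(daily, event_start, column = "ef_daytime",
                          window_days = 15, min_days = 5) {
  stopifnot(window_days >= 1)
  event_start <- as.Date(event_start)
  win <- daily$date >= event_start - window_days & daily$date < event_start
  x <- daily[[column]][win]
  truncated <- min(daily$date) > event_start - window_days
  out <- if (sum(!is.na(x)) >= min_days) mean(x, na.rm = TRUE) else NA_real_
  attr(out, "truncated") <- truncated
  out
}

#' @rdname prepulse_mean
#' @export
prepulse_ef <- function(daily, event_start, window_days = 15, min_days = 5) {
  prepulse_mean(daily, event_start, "ef_daytime", window_days, min_days)
}

#' Rewetting intensity of an event
#'
#' Difference between the 2-day mean after and the 2-day mean before the
#' rain day: `mean(day, day + 1) - mean(day - 2, day - 1)`, where the rain
#' (event start) day counts as the first "after" day. Applied to daily EF it
#' gives the EF-based rewetting intensity; applied to daily precipitation
#' the precipitation-based one; applied to daily mean NEE the pulse
#' intensity.
#'
#' @param daily daily table with `date`.
#' @param event_start `Date` of the event start.
#' @param column daily column to difference (e.g. `"ef_daytime"`,
#'   `"p_total"`, `"nee_daily_mean"`).
#' @return after-minus-before difference; `NA` if either side has no valid
#'   day.
#' @export
rewetting_intensity <- function(daily, event_start, column = "ef_daytime") {
  event_start <- as.Date(event_start)
  after <- daily[[column]][daily$date %in% (event_start + 0:1)]
  before <- daily[[column]][daily$date %in% (event_start - 2:1)]
  if (all(is.na(after)) || all(is.na(before))) return(NA_real_)
  mean(after, na.rm = TRUE) - mean(before, na.rm = TRUE)
}
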