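T_REF_K <- 288.15
T0_K <- 227.13

# Lloyd-Taylor temperature factor at r_ref = 1.
lt_factor <- function(tair_c, e0, t_ref = T_REF_K, t0 = T0_K) {
  tk <- tair_c + 273.15
  out <- exp(e0 * (1 / (t_ref - t0) - 1 / (tk - t0)))
  out[!is.na(tk) & tk <= t0] <- NA_real_
  out
}

#' Lloyd-Taylor respiration model
#'
#' Ecosystem respiration as an Arrhenius-type exponential function of air
#' temperature: `r_ref * exp(e0 * (1/(T_ref - T0) - 1/(T_air - T0)))` with
#' the fixed constants `T_ref = 288.15 K` and `T0 = 227.13 K`. At
#' `T_air = T_ref` (15 degC) the output equals `r_ref` exactly; for
#' `e0 > 0` it is strictly increasing in temperature. Temperatures at or
#' below `T0` give a missing value.
#'
#' @param tair_c air temperature (degC), vectorized.
#' @param r_ref reference respiration at `T_ref` (umol CO2 m-2 s-1).
#' @param e0 temperature sensitivity (K).
#' @return respiration (umol CO2 m-2 s-1).
#' @export
lloyd_taylor <- function(tair_c, r_ref, e0) {
  r_ref * lt_factor(tair_c, e0)
}

night_rows <- function(t, night_sw = 20) {
  !is.na(t$sw_in) & t$sw_in < night_sw & !is.na(t$nee) & !is.na(t$tair)
}

#' Estimate the temperature sensitivity E0 from night-time data
#'
#' Fits the Lloyd-Taylor model to night-time NEE (assumed to equal
#' ecosystem respiration in the absence of photosynthesis) over short
#' sliding windows, then aggregates the accepted window estimates into one
#' site-level E0 as their uncertainty-weighted mean. A window is accepted
#' when the fit converges, spans at least `min_t_range` degC of temperature
#' and the relative standard error of E0 is below `max_rse`. The final E0
#' is bounded to [30, 450] K.
#'
#' @param t a `flux_table` (already QC-filtered as desired).
#' @param night_sw radiation threshold defining night (W m-2).
#' @param window_days sliding-window length (days).
#' @param step_days window step (days).
#' @param min_obs minimum valid night half hours per window.
#' @param min_t_range minimum within-window temperature range (degC).
#' @param max_rse acceptance bound on `se(E0)/E0`.
#' @return scalar E0 (K) with attribute `n_windows` (accepted windows).
#' @export
fit_e0 <- function(t, night_sw = 20, window_days = 15, step_days = 5,
                   min_obs = 20, min_t_range = 5, max_rse = 0.5) {
  night <- night_rows(t, night_sw)
  day <- as.Date(t$timestamp, tz = "UTC")
  d0 <- min(day); d1 <- max(day)
  starts <- seq(d0, d1, by = step_days)
  est <- matrix(NA_real_, length(starts), 2)
  for (w in seq_along(starts)) {
    in_w <- night & day >= starts[w] & day < starts[w] + window_days
    tair <- t$tair[in_w]; nee <- t$nee[in_w]
    if (sum(in_w) < min_obs) next
    if (diff(range(tair)) < min_t_range) next
    fit <- tryCatch(
      minpack.lm::nlsLM(nee ~ rref * lt_factor(tair, e0),
                        start = list(rref = max(mean(nee), 0.1), e0 = 100),
                        lower = c(0, 30), upper = c(Inf, 450),
                        data = data.frame(nee = nee, tair = tair)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- summary(fit)$coefficients
    e0 <- cf["e0", "Estimate"]; se <- cf["e0", "Std. Error"]
    if (!is.finite(se) || se / e0 > max_rse) next
    est[w, ] <- c(e0, max(se, 1e-6)) # exact fits get a tiny floor so the
    # inverse-variance weights stay finite
  }
  ok <- is.finite(est[, 1])
  if (!any(ok)) {
    # isothermal or data-poor record: temperature range precondition unmet
    stop("E0 estimation failed: no window with enough night data spanning >= ",
         min_t_range, " degC")
  }
  w <- 1 / est[ok, 2]^2
  e0 <- min(max(sum(est[ok, 1] * w) / sum(w), 30), 450)
  attr(e0, "n_windows") <- sum(ok)
  e0
}

#' Moving-window reference respiration
#'
#' With E0 fixed, estimates the reference respiration `r_ref` per short
#' moving window of night-time data by least squares (closed form, since
#' the model is linear in `r_ref`), floors it at zero, and interpolates
#' linearly between window centres to every half hour. Windows with fewer
#' than `min_obs` valid night half hours are skipped; half hours farther
#' than `max_gap_days` from any accepted window centre get a missing
#' `r_ref`. The standard night-time method uses 4-day windows stepped by 2
#' days; the prepulse refit uses 2-day windows.
#'
#' @param t a `flux_table`.
#' @param e0 fixed temperature sensitivity (K).
#' @param window_days window length (days).
#' @param step_days window step (days).
#' @param night_sw night radiation threshold (W m-2).
#' @param min_obs minimum night half hours per window.
#' @param max_gap_days interpolation reach beyond which `r_ref` is missing.
#' @return list with `windows` (data frame: `center`, `r_ref`, `n`) and
#'   `rref_interp` (per half hour of `t`).
#' @export
fit_rref_windows <- function(t, e0, window_days = 4, step_days = 2,
                             night_sw = 20, min_obs = 10, max_gap_days = 14) {
  night <- night_rows(t, night_sw)
  day <- as.Date(t$timestamp, tz = "UTC")
  d0 <- min(day); d1 <- max(day)
  starts <- seq(d0, d1, by = step_days)
  centers <- numeric(0); rrefs <- numeric(0); ns <- integer(0)
  for (w in seq_along(starts)) {
    in_w <- night & day >= starts[w] & day < starts[w] + window_days
    n <- sum(in_w)
    if (n < min_obs) next
    f <- lt_factor(t$tair[in_w], e0)
    y <- t$nee[in_w]
    ok <- is.finite(f)
    if (!any(ok)) next
    rref <- max(sum(y[ok] * f[ok]) / sum(f[ok]^2), 0)
    centers <- c(centers, as.numeric(starts[w]) + (window_days - 1) / 2)
    rrefs <- c(rrefs, rref); ns <- c(ns, n)
  }
  if (!length(centers)) stop("no window with enough night data to fit r_ref")
  tnum <- as.numeric(day) + (as.numeric(t$timestamp) %% 86400) / 86400
  interp <- if (length(centers) == 1) rep(rrefs, nrow(t)) else
    stats::approx(centers, rrefs, xout = tnum, rule = 2)$y
  gap <- vapply(tnum, function(x) min(abs(x - centers)), 1.0)
  interp[gap > max_gap_days] <- NA_real_
  list(windows = data.frame(center = as.Date(round(centers), origin = "1970-01-01"),
                            center_num = centers, r_ref = rrefs, n = ns),
       rref_interp = interp)
}

#' Night-time-method flux partitioning
#'
#' Evaluates the Lloyd-Taylor model at every half hour with the fitted E0
#' and the interpolated moving-window `r_ref` to get the night-time-method
#' ecosystem respiration `reco_nt` (floored at 0), then partitions by
#' `NEE = Reco - GPP`: `gpp_nt = reco_nt - nee`. GPP may be negative where
#' the model under-predicts respiration (a known symptom during pulse
#' events); it is missing wherever NEE is missing while `reco_nt` is still
#' produced from temperature alone.
#'
#' @param t a `flux_table`.
#' @param e0 temperature sensitivity (K), from [fit_e0()].
#' @param rref result of [fit_rref_windows()] (or a numeric vector of
#'   per-half-hour `r_ref`).
#' @return object of class `partition_nt`: list with half-hourly `reco_nt`,
#'   `gpp_nt`, `rref_interp`, scalar `e0` and the `windows` table.
#' @export
partition_nt <- function(t, e0, rref) {
  rref_interp <- if (is.list(rref)) rref$rref_interp else rref
  reco <- pmax(rref_interp * lt_factor(t$tair, e0), 0)
  gpp <- reco - t$nee
  structure(list(reco_nt = reco, gpp_nt = gpp, rref_interp = rref_interp,
                 e0 = as.numeric(e0),
                 windows = if (is.list(rref)) rref$windows else NULL),
            class = "partition_nt")
}

#' Prepulse refit of reference respiration
#'
#' The moving 4-day `r_ref` window of the night-time method overlaps the
#' pulse period in the days just before an event, biasing prepulse
#' respiration. For each event, this refits `r_ref` with 2-day windows over
#' the prepulse period (the `n` days before the start, `n` = event length)
#' and replaces the night-time-method respiration there. Prepulse periods
#' that overlap a previous event are skipped and flagged.
#'
#' @param t a `flux_table`.
#' @param part a `partition_nt` result to correct.
#' @param events event catalog (chronological, one site).
#' @param window_days refit window length (2 days).
#' @param night_sw,min_obs as in [fit_rref_windows()].
#' @return list with updated `reco_nt`, `gpp_nt`, logical `prepulse_mask`
#'   per half hour, and per-event `refitted` flags.
#' @export
refit_prepulse <- function(t, part, events, window_days = 2,
                           night_sw = 20, min_obs = 4) {
  day <- as.Date(t$timestamp, tz = "UTC")
  reco <- part$reco_nt; gpp <- part$gpp_nt
  mask <- logical(nrow(t))
  refitted <- logical(nrow(events))
  ord <- order(as.Date(events$start_date))
  events <- events[ord, , drop = FALSE]
  for (r in seq_len(nrow(events))) {
    s <- as.Date(events$start_date[r]); e <- as.Date(events$end_date[r])
    len <- as.integer(e - s) + 1L
    pre0 <- s - len; pre1 <- s - 1
    overlap <- r > 1 && any(as.Date(events$end_date[seq_len(r - 1)]) >= pre0)
    if (overlap) next
    in_pre <- day >= pre0 & day <= pre1
    if (!any(in_pre)) next
    sub <- t[in_pre, , drop = FALSE]
    rr <- tryCatch(
      fit_rref_windows(sub, part$e0, window_days = window_days,
                       step_days = 1, night_sw = night_sw, min_obs = min_obs,
                       max_gap_days = len),
      error = function(err) NULL)
    if (is.null(rr)) next
    new_reco <- pmax(rr$rref_interp * lt_factor(sub$tair, part$e0), 0)
    keep <- !is.na(new_reco)
    idx <- which(in_pre)[keep]
    reco[idx] <- new_reco[keep]
    gpp[idx] <- reco[idx] - t$nee[idx]
    mask[idx] <- TRUE
    refitted[ord[r]] <- TRUE
  }
  list(reco_nt = reco, gpp_nt = gpp, prepulse_mask = mask, refitted = refitted)
}

#' Export a partitioning result as CSV
#'
#' Writes `reco_nt`, `gpp_nt` and the interpolated `r_ref` aligned to the
#' input timestamps.
#'
#' @param t the `flux_table` the partition was computed on.
#' @param part a `partition_nt` object.
#' @param path output CSV path.
#' @export
write_partition <- function(t, part, path) {
  out <- data.frame(TIMESTAMP_START = format(t$timestamp, "%Y%m%d%H%M"),
                    reco_nt = part$reco_nt, gpp_nt = part$gpp_nt,
                    rref_interp = part$rref_interp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
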