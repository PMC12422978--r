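p98 <- function(x) stats::quantile(x, 0.98, na.rm = TRUE, names = FALSE,
                                   type = 7)

#' Build the decaying correction factor for one event
#'
#' The daily correction factor is
#' `beta_i = (NEE_p98_day1 / RecoNT_p98_day1) * exp(-k * (i - 1))`, where
#' the two 98th percentiles are taken over all valid half hours of the
#' event's first day (day and night pooled; the 98th percentile stands in
#' for the daily maximum). Day 1 therefore anchors the corrected
#' respiration to the observed maximum NEE: where the night-time-method
#' respiration equals its day-1 98th percentile, the corrected value equals
#' the NEE 98th percentile exactly. Events without an emission signal
#' (`NEE_p98 <= 0`) or without a positive respiration percentile are
#' skipped. When the night-time method already exceeds NEE on day 1
#' (`beta_1 < 1`) the event is still corrected but flagged.
#'
#' @param nee_day1 half-hourly NEE on event day 1.
#' @param reco_nt_day1 half-hourly night-time-method respiration on day 1.
#' @param k decay rate (day-1), from [event_decay_rate()].
#' @param n_days event length.
#' @param min_halfhours minimum valid half hours for the percentiles.
#' @param k_source provenance label stored with the state.
#' @return object of class `correction_state`: list with `nee_p98_day1`,
#'   `reco_nt_p98_day1`, `k_used`, `k_source`, `beta_by_day`,
#'   `flag_beta1_lt_1`; or `NULL` with attribute `reason` when the event is
#'   skipped.
#' @export
build_beta <- function(nee_day1, reco_nt_day1, k, n_days,
                       min_halfhours = 10, k_source = NA_character_) {
  skip <- function(reason) structure(list(), class = "correction_skip",
                                     reason = reason)
  if (sum(!is.na(nee_day1)) < min_halfhours ||
      sum(!is.na(reco_nt_day1)) < min_halfhours)
    return(skip("too few valid day-1 half hours"))
  if (is.na(k)) return(skip("no decay rate"))
  nee98 <- p98(nee_day1)
  reco98 <- p98(reco_nt_day1)
  if (!is.finite(reco98) || reco98 <= 0)
    return(skip("day-1 NT respiration percentile not positive"))
  if (!is.finite(nee98) || nee98 <= 0)
    return(skip("no emission pulse to correct (day-1 NEE percentile <= 0)"))
  i <- seq_len(n_days)
  beta <- (nee98 / reco98) * exp(-k * (i - 1))
  structure(list(nee_p98_day1 = nee98, reco_nt_p98_day1 = reco98,
                 k_used = k, k_source = k_source, beta_by_day = beta,
                 flag_beta1_lt_1 = beta[1] < 1),
            class = "correction_state")
}

#' Apply the correction factor over an event
#'
#' Multiplies every half hour of event day i by `beta_i`:
#' `reco_fp = beta_i * reco_nt`, then re-partitions with
#' `gpp_fp = reco_fp - nee`. No floor other than `reco_fp >= 0` is applied;
#' late in an event `beta < 1` may bring corrected respiration below the
#' night-time-method value, as the decay form implies.
#'
#' @param state a `correction_state` from [build_beta()].
#' @param reco_nt half-hourly NT respiration over the event days.
#' @param nee half-hourly NEE over the event days.
#' @param day_index event-day index (1-based) per half hour.
#' @return list with `reco_fp` and `gpp_fp` over the event half hours.
#' @export
apply_correction <- function(state, reco_nt, nee, day_index) {
  beta <- state$beta_by_day[day_index]
  reco_fp <- pmax(beta * reco_nt, 0)
  list(reco_fp = reco_fp, gpp_fp = reco_fp - nee)
}

#' Fit the pulse-corrected partitioning model
#'
#' The main entry point: runs the full correction pipeline on one site's
#' half-hourly record. Steps: (optional) QC filtering to original
#' measurements; daily aggregation; event cataloguing (a supplied catalog,
#' or the rule-based screen when `events = NULL`) with per-event
#' characteristics; night-time-method partitioning (E0 from night windows,
#' moving-window `r_ref`); the prepulse `r_ref` refit with 2-day windows;
#' and the per-event decaying correction anchored to day-1 maximum NEE.
#' Outside corrected half hours the corrected series equal the
#' night-time-method ones.
#'
#' @param t a `flux_table` (see [read_halfhourly()]).
#' @param events event catalog (`site_id`, `start_date`, `end_date`) or
#'   `NULL` to screen candidates from the daily record.
#' @param config list of tuning parameters, see [fp_config()].
#' @return object of class `fluxpulse` with components `data`, `daily`,
#'   `events` (characterized catalog with correction metadata), `partition`
#'   (`partition_nt`), `reco_fp`, `gpp_fp`, `mask` (per half hour:
#'   `"pulse"`, `"prepulse"` or `"untouched"`), `states` (per-event
#'   `correction_state`s) and `config`.
#' @export
fluxpulse <- function(t, events = NULL, config = fp_config()) {
  t <- validate_flux_table(t)
  if (isTRUE(config$qc_filter)) {
    has_qc <- vapply(c("nee", "le", "h"), function(v) {
      qc <- t[[paste0("qc_", v)]]
      !is.null(qc) && !all(is.na(qc))
    }, TRUE)
    if (any(has_qc))
      t <- filter_original(t, names(has_qc)[has_qc], qc_max = config$qc_max)
  }
  daily <- to_daily(t, sw_threshold = config$sw_daytime,
                    night_sw = config$sw_night, min_valid = config$min_valid)
  site_id <- config$site_id %||% "site"
  if (is.null(events)) {
    events <- rule_screen(daily, nee_jump = config$nee_jump,
                          ef_jump = config$ef_jump,
                          rain_window = config$rain_window,
                          require_rain = config$require_rain,
                          end_tol = config$end_tol,
                          max_length = config$max_length, site_id = site_id)
  } else {
    events <- events[order(as.Date(events$start_date)), , drop = FALSE]
  }
  events <- characterize_events(events, daily,
                                window_days = config$prepulse_window)
  e0 <- fit_e0(t, night_sw = config$sw_night,
               window_days = config$e0_window, step_days = config$e0_step,
               min_obs = config$e0_min_obs)
  rr <- fit_rref_windows(t, e0, window_days = config$rref_window,
                         step_days = config$rref_step,
                         night_sw = config$sw_night,
                         min_obs = config$rref_min_obs)
  part <- partition_nt(t, e0, rr)
  reco_fp <- part$reco_nt
  gpp_fp <- part$gpp_nt
  mask <- rep("untouched", nrow(t))
  if (isTRUE(config$prepulse_correct) && nrow(events)) {
    pp <- refit_prepulse(t, part, events,
                         window_days = config$prepulse_rref_window,
                         night_sw = config$sw_night)
    reco_fp <- pp$reco_nt
    gpp_fp <- pp$gpp_nt
    mask[pp$prepulse_mask] <- "prepulse"
    events$prepulse_refitted <- pp$refitted
  }
  day <- as.Date(t$timestamp, tz = "UTC")
  states <- vector("list", nrow(events))
  events$k_used <- rep(NA_real_, nrow(events))
  events$k_source <- rep(NA_character_, nrow(events))
  events$corrected <- rep(FALSE, nrow(events))
  events$skip_reason <- rep(NA_character_, nrow(events))
  for (r in seq_len(nrow(events))) {
    s <- as.Date(events$start_date[r]); e <- as.Date(events$end_date[r])
    len <- as.integer(e - s) + 1L
    kd <- event_decay_rate(t, events[r, ], events, p_sig = config$k_p_sig)
    in_ev <- day >= s & day <= e
    mask[in_ev] <- "pulse" # event half hours, corrected or not
    d1 <- day == s
    st <- build_beta(t$nee[d1], part$reco_nt[d1], kd$k, len,
                     min_halfhours = config$p98_min_halfhours,
                     k_source = kd$k_source)
    states[[r]] <- st
    if (inherits(st, "correction_skip")) {
      events$skip_reason[r] <- attr(st, "reason")
      next
    }
    idx <- as.integer(day[in_ev] - s) + 1L
    corr <- apply_correction(st, part$reco_nt[in_ev], t$nee[in_ev], idx)
    reco_fp[in_ev] <- corr$reco_fp
    gpp_fp[in_ev] <- corr$gpp_fp
    events$k_used[r] <- st$k_used
    events$k_source[r] <- st$k_source
    events$corrected[r] <- TRUE
  }
  structure(list(data = t, daily = daily, events = events, partition = part,
                 reco_fp = reco_fp, gpp_fp = gpp_fp, mask = mask,
                 states = states, config = config),
            class = "fluxpulse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Central defaults for the correction pipeline. Radiation thresholds are in
#' W m-2, windows in days, flux thresholds in umol CO2 m-2 s-1.
#'
#' @param ... named overrides of any default.
#' @return named list of parameters.
#' @export
fp_config <- function(...) {
  cfg <- list(
    site_id = "site",
    qc_filter = TRUE, qc_max = 0,
    sw_daytime = 50, sw_night = 20, min_valid = 10,
    nee_jump = 1.0, ef_jump = 0.08, rain_window = 1, require_rain = TRUE,
    end_tol = 0.25, max_length = 26,
    prepulse_window = 15,
    e0_window = 15, e0_step = 5, e0_min_obs = 20,
    rref_window = 4, rref_step = 2, rref_min_obs = 10,
    prepulse_correct = TRUE, prepulse_rref_window = 2,
    k_p_sig = 0.1, p98_min_halfhours = 10
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys override [fp_config()]
#'   defaults.
#' @return configuration list.
#' @export
read_config <- function(path) {
  do.call(fp_config, yaml::read_yaml(path))
}

#' Night-time validation of corrected respiration
#'
#' At night, NEE approximates ecosystem respiration (no photosynthesis), so
#' the corrected and night-time-method respiration can both be scored
#' against observed night NEE during events. Only events longer than
#' `min_length_gt` days are used, to limit random-error leverage. Half
#' hours are first aggregated to daily night means (valid night coverage is
#' very uneven across event days, so raw half-hourly sums would weight the
#' event tail by data density rather than by flux); the per-event percent
#' bias is then `100 * (sum(reco_daymeans) - sum(nee_daymeans)) /
#' sum(nee_daymeans)` over event days with at least `min_night_obs` valid
#' night half hours. The one-tailed paired t-test asks whether the
#' corrected method reduces the absolute bias relative to the night-time
#' method.
#'
#' @param fit a `fluxpulse` object.
#' @param min_length_gt events must be strictly longer than this (days).
#' @param min_events minimum qualifying events for the test.
#' @param min_night_obs minimum valid night half hours for a day to count.
#' @param min_days minimum qualifying days per event.
#' @return list with `per_event` (data frame of paired biases),
#'   `median_bias_nt`, `median_bias_fp` (percent), `p_value` (one-tailed
#'   paired t-test) and `n_events`.
#' @export
validate_night <- function(fit, min_length_gt = 3, min_events = 2,
                           min_night_obs = 2, min_days = 3) {
  t <- fit$data
  day <- as.Date(t$timestamp, tz = "UTC")
  night <- !is.na(t$sw_in) & t$sw_in < fit$config$sw_night
  ev <- fit$events[fit$events$corrected &
                     fit$events$length_days > min_length_gt, , drop = FALSE]
  rows <- lapply(seq_len(nrow(ev)), function(r) {
    s <- as.Date(ev$start_date[r]); e <- as.Date(ev$end_date[r])
    dm <- vapply(seq(s, e, by = "day"), function(d) {
      m <- night & day == d & !is.na(t$nee) & !is.na(fit$reco_fp) &
        !is.na(fit$partition$reco_nt)
      if (sum(m) < min_night_obs) return(c(NA_real_, NA_real_, NA_real_))
      c(mean(t$nee[m]), mean(fit$partition$reco_nt[m]), mean(fit$reco_fp[m]))
    }, numeric(3))
    ok <- !is.na(dm[1, ])
    if (sum(ok) < min_days || sum(dm[1, ok]) <= 0) return(NULL)
    sn <- sum(dm[1, ok])
    data.frame(start_date = s,
               bias_nt = 100 * (sum(dm[2, ok]) - sn) / sn,
               bias_fp = 100 * (sum(dm[3, ok]) - sn) / sn)
  })
  per_event <- do.call(rbind, rows)
  if (is.null(per_event) || nrow(per_event) < min_events)
    return(list(per_event = per_event, median_bias_nt = NA_real_,
                median_bias_fp = NA_real_, p_value = NA_real_,
                n_events = if (is.null(per_event)) 0L else nrow(per_event)))
  tt <- stats::t.test(abs(per_event$bias_nt), abs(per_event$bias_fp),
                      paired = TRUE, alternative = "greater")
  list(per_event = per_event,
       median_bias_nt = stats::median(per_event$bias_nt),
       median_bias_fp = stats::median(per_event$bias_fp),
       p_value = tt$p.value, n_events = nrow(per_event))
}

#' Pulse-event contribution to annual fluxes
#'
#' Contribution (%) of pulse events to a flux:
#' `100 * sum(x during events) / sum(x over the whole record)`, computed
#' for corrected respiration and for NEP (= -NEE). Missing half hours are
#' excluded from both sums.
#'
#' @param fit a `fluxpulse` object.
#' @return list with `reco_contribution_pct` and `nep_contribution_pct`.
#' @export
contribution_stats <- function(fit) {
  in_pulse <- fit$mask == "pulse"
  reco <- fit$reco_fp
  nep <- -fit$data$nee
  share <- function(x, m) {
    tot <- sum(x, na.rm = TRUE)
    if (!is.finite(tot) || tot == 0) return(NA_real_)
    100 * sum(x[m], na.rm = TRUE) / tot
  }
  list(reco_contribution_pct = share(reco, in_pulse),
       nep_contribution_pct = share(nep, in_pulse))
}

#' Flux underestimation of an alternative partitioner
#'
#' Compares an externally produced half-hourly flux series against the
#' corrected one over pulse-event half hours:
#' `100 * (sum(x) - sum(y)) / sum(x)` with `x` the corrected flux and `y`
#' the alternative. Positive values mean the alternative underestimates the
#' flux, negative values overestimation.
#'
#' @param fit a `fluxpulse` object.
#' @param alt_series half-hourly alternative flux aligned to `fit$data`.
#' @param flux which corrected flux to compare: `"reco"` or `"gpp"`.
#' @return percent underestimation.
#' @export
underestimation_stats <- function(fit, alt_series, flux = c("reco", "gpp")) {
  flux <- match.arg(flux)
  if (length(alt_series) != nrow(fit$data))
    stop("alternative series not aligned: expected ", nrow(fit$data),
         " half hours, got ", length(alt_series))
  x <- if (flux == "reco") fit$reco_fp else fit$gpp_fp
  m <- fit$mask == "pulse" & !is.na(x) & !is.na(alt_series)
  sx <- sum(x[m])
  if (sx == 0) return(NA_real_)
  100 * (sx - sum(alt_series[m])) / sx
}

#' Export corrected fluxes as CSV
#'
#' Half-hourly corrected respiration and GPP aligned to the input
#' timestamps, with the correction mask.
#'
#' @param fit a `fluxpulse` object.
#' @param path output CSV path.
#' @export
write_fluxpulse <- function(fit, path) {
  out <- data.frame(TIMESTAMP_START = format(fit$data$timestamp, "%Y%m%d%H%M"),
                    nee = fit$data$nee, reco_nt = fit$partition$reco_nt,
                    gpp_nt = fit$partition$gpp_nt, reco_fp = fit$reco_fp,
                    gpp_fp = fit$gpp_fp, mask = fit$mask)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
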