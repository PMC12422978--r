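#' First-order kinetic decay fit
#'
#' Fits `y = alpha * exp(-k * i)` by nonlinear least squares, the
#' first-order kinetic form used for pulse decay (day 1 is the rain day).
#' Starting values come from a log-linear regression on the positive points;
#' the parameter p-value for `k` is the Wald test from the least-squares
#' covariance.
#'
#' @param y response (e.g. per-day maxima of daily mean NEE,
#'   umol CO2 m-2 s-1).
#' @param day_index day index `i` (1 = event/rain start day).
#' @param scope label: `"event"`, `"site"` or `"universal"`.
#' @return object of class `decay_fit`: list with `alpha`, `k`, `alpha_se`,
#'   `k_se`, `p_value_k`, `n_points`, `scope`, `converged`, `fitted`.
#' @export
fit_decay <- function(y, day_index = seq_along(y), scope = "event") {
  ok <- !is.na(y) & !is.na(day_index)
  y <- y[ok]; i <- day_index[ok]
  failed <- function() structure(list(alpha = NA_real_, k = NA_real_,
    alpha_se = NA_real_, k_se = NA_real_, p_value_k = NA_real_,
    n_points = length(y), scope = scope, converged = FALSE, fitted = NULL),
    class = "decay_fit")
  if (length(y) < 3) return(failed())
  pos <- y > 0
  if (sum(pos) >= 2) {
    st <- stats::coef(stats::lm(log(y[pos]) ~ i[pos]))
    start <- list(alpha = exp(st[[1]]), k = max(-st[[2]], 1e-3))
  } else {
    start <- list(alpha = max(abs(y)), k = 0.1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ alpha * exp(-k * i),
                      start = start, data = data.frame(y = y, i = i),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- summary(fit)$coefficients
  structure(list(
    alpha = cf["alpha", "Estimate"], k = cf["k", "Estimate"],
    alpha_se = cf["alpha", "Std. Error"], k_se = cf["k", "Std. Error"],
    p_value_k = cf["k", "Pr(>|t|)"], n_points = length(y), scope = scope,
    converged = TRUE, fitted = stats::fitted(fit)), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("First-order kinetic decay fit (scope:", x$scope, ")\n")
  if (!x$converged) {
    cat("  did not converge (n =", x$n_points, ")\n")
  } else {
    cat(sprintf("  alpha = %.4g (se %.3g)   k = %.4g /day (se %.3g, p = %.3g)\n",
                x$alpha, x$alpha_se, x$k, x$k_se, x$p_value_k))
    cat("  n =", x$n_points, "day points\n")
  }
  invisible(x)
}

#' Rule-based screening of pulse-event candidates
#'
#' Proposes event start dates where the manual-labelling conditions hold on
#' the daily record: (1) the day-over-day jump in daily mean NEE exceeds
#' `nee_jump`; (2) NEE decays for at least 2 subsequent days (each below the
#' start-day mean), separating pulses from single-day noise; (3) the EF jump
#' against the 2 prior days exceeds `ef_jump`; (4) positive precipitation
#' within `rain_window` days of the start (waivable via `require_rain`,
#' since tipping-bucket rain gauges under-report). The event ends on the
#' first day whose night-time mean NEE returns within `end_tol` (relative)
#' of the prepulse night-time mean, capped at `max_length` days; candidates
#' starting inside an accepted event are skipped, so events never overlap.
#'
#' @param daily daily table from [to_daily()].
#' @param nee_jump minimum day-over-day increase in daily mean NEE
#'   (umol CO2 m-2 s-1).
#' @param ef_jump minimum EF rise against the mean of the 2 prior days.
#' @param rain_window tolerance (days) for locating positive precipitation.
#' @param require_rain enforce condition (4)?
#' @param end_tol relative tolerance for night-NEE return to prepulse level.
#' @param max_length event-length cap in days.
#' @param min_length minimum event length (2 days).
#' @param site_id site label carried into the catalog.
#' @return data frame of candidate events (`site_id`, `start_date`,
#'   `end_date`, `source = "rule"`); empty if none.
#' @export
rule_screen <- function(daily, nee_jump = 1.0, ef_jump = 0.08,
                        rain_window = 1, require_rain = TRUE,
                        end_tol = 0.25, max_length = 26, min_length = 2,
                        site_id = "site") {
  n <- nrow(daily)
  empty <- data.frame(site_id = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      source = character(0), stringsAsFactors = FALSE)
  if (n < 4) return(empty)
  nee <- daily$nee_daily_mean
  ef <- daily$ef_daytime
  p <- daily$p_total
  starts <- integer(0); ends <- integer(0)
  t <- 2L
  while (t <= n - 2L) {
    ok <- !is.na(nee[t]) && !is.na(nee[t - 1]) &&
      (nee[t] - nee[t - 1]) > nee_jump
    if (ok) { # gradual decay over >= 2 subsequent days: declining, but the
      # first decay day still elevated above the pre-jump level (a one-day
      # spike back to baseline is noise, not a pulse)
      ok <- !is.na(nee[t + 1]) && !is.na(nee[t + 2]) &&
        nee[t + 1] < nee[t] && nee[t + 2] <= nee[t + 1] &&
        nee[t + 1] > nee[t - 1]
    }
    if (ok) { # EF surge against the 2 prior days
      ef_before <- mean(ef[max(1, t - 2):(t - 1)], na.rm = TRUE)
      ok <- !is.na(ef[t]) && is.finite(ef_before) &&
        (ef[t] - ef_before) > ef_jump
    }
    if (ok && require_rain) {
      win <- max(1, t - rain_window):min(n, t + rain_window)
      ok <- any(!is.na(p[win]) & p[win] > 0)
    }
    if (ok) {
      e <- event_end_day(daily, t, end_tol, max_length, min_length)
      starts <- c(starts, t); ends <- c(ends, e)
      t <- e + 1L
    } else t <- t + 1L
  }
  if (!length(starts)) return(empty)
  data.frame(site_id = site_id, start_date = daily$date[starts],
             end_date = daily$date[ends], source = "rule",
             stringsAsFactors = FALSE)
}

# End day: first day after the peak whose night-time mean NEE is back within
# end_tol of the prepulse night-time level, capped at max_length.
event_end_day <- function(daily, t, end_tol, max_length, min_length) {
  n <- nrow(daily)
  night <- daily$nee_night_mean
  pre <- night[max(1, t - 5):(t - 1)]
  pre_level <- if (any(!is.na(pre))) mean(pre, na.rm = TRUE) else NA_real_
  last <- min(n, t + max_length - 1L)
  e <- last
  if (!is.na(pre_level)) {
    tol <- max(abs(pre_level) * end_tol, 0.25)
    for (d in (t + min_length - 1L):last) {
      if (!is.na(night[d]) && abs(night[d] - pre_level) <= tol) { e <- d; break }
    }
  }
  max(e, t + min_length - 1L)
}

#' Attach per-event characteristics
#'
#' Completes an event catalog with the four descriptive pulse
#' characteristics plus the hydrologic indices: length (days from start to
#' end inclusive), intensity (change in daily mean NEE between the mean of
#' the first 2 event days and the mean of the 2 days before the start),
#' size (sum of daily mean NEE over the event, umol CO2 m-2 s-1), the EF
#' rewetting intensity `delta_ef`, the precipitation rewetting intensity
#' `delta_p`, and the antecedent means `prepulse_ef` and `prepulse_nee`.
#' When one of the two pre-start days is missing, the single valid day is
#' used and the event is flagged in `partial_pre`.
#'
#' @param events catalog with `start_date`, `end_date`.
#' @param daily daily table from [to_daily()].
#' @param window_days antecedent window for the prepulse means.
#' @return the catalog with characteristic columns appended.
#' @export
characterize_events <- function(events, daily, window_days = 15) {
  n <- nrow(events)
  add <- data.frame(length_days = integer(n),
                    intensity_delta_nee = rep(NA_real_, n),
                    size = rep(NA_real_, n), delta_ef = rep(NA_real_, n),
                    delta_p = rep(NA_real_, n),
                    prepulse_ef = rep(NA_real_, n),
                    prepulse_nee = rep(NA_real_, n),
                    partial_pre = rep(FALSE, n))
  for (r in seq_len(n)) {
    s <- as.Date(events$start_date[r]); e <- as.Date(events$end_date[r])
    add$length_days[r] <- as.integer(e - s) + 1L
    pre <- daily$nee_daily_mean[daily$date %in% (s - 2:1)]
    post <- daily$nee_daily_mean[daily$date >= s & daily$date <= min(e, s + 1)]
    if (any(!is.na(pre)) && any(!is.na(post))) {
      add$intensity_delta_nee[r] <- mean(post, na.rm = TRUE) -
        mean(pre, na.rm = TRUE)
      add$partial_pre[r] <- anyNA(pre) || length(pre) < 2
    }
    ev <- daily$nee_daily_mean[daily$date >= s & daily$date <= e]
    if (any(!is.na(ev))) add$size[r] <- sum(ev, na.rm = TRUE)
    add$delta_ef[r] <- rewetting_intensity(daily, s, "ef_daytime")
    add$delta_p[r] <- rewetting_intensity(daily, s, "p_total")
    add$prepulse_ef[r] <- as.numeric(prepulse_ef(daily, s, window_days))
    add$prepulse_nee[r] <- as.numeric(
      prepulse_mean(daily, s, "nee_daily_mean", window_days))
  }
  cbind(events[setdiff(names(events), names(add))], add)
}

# Per-site series of day-indexed maxima of daily mean NEE across events.
site_day_maxima <- function(events, daily) {
  if (!nrow(events)) return(numeric(0))
  max_len <- 0L
  per_event <- lapply(seq_len(nrow(events)), function(r) {
    s <- as.Date(events$start_date[r]); e <- as.Date(events$end_date[r])
    daily$nee_daily_mean[match(seq(s, e, by = "day"), daily$date)]
  })
  max_len <- max(vapply(per_event, length, 1L))
  vapply(seq_len(max_len), function(i) {
    v <- unlist(lapply(per_event, function(x) if (length(x) >= i) x[i] else NA))
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, 1.0)
}

#' Site-specific pulse intensity and decay rate
#'
#' For each day index i (day 1 = rain day), takes the maximum of the daily
#' mean NEE over all the site's pulse events, then fits the first-order
#' kinetic curve `NEE_i = alpha_s * exp(-k_s * i)`. `alpha_s` is the
#' site-specific pulse intensity and `k_s` the site-specific decay rate; the
#' fit is flagged significant when the Wald p-value of `k_s` is below
#' `p_sig` (0.05).
#'
#' @param events the site's event catalog.
#' @param daily the site's daily table.
#' @param p_sig significance level for `k_s`.
#' @return a `decay_fit` (scope `"site"`) with extra fields `series` (the
#'   day-indexed maxima) and `significant`.
#' @export
site_decay_fit <- function(events, daily, p_sig = 0.05) {
  series <- site_day_maxima(events, daily)
  fit <- fit_decay(series, seq_along(series), scope = "site")
  fit$series <- series
  fit$significant <- isTRUE(fit$converged && !is.na(fit$p_value_k) &&
                              fit$p_value_k < p_sig)
  fit
}

#' Pooled (universal) decay curve across sites
#'
#' Normalizes each site's day-indexed maxima by its fitted site intensity
#' `alpha_s`, pools the normalized points from all sites with significant
#' site fits, and fits a single `y = a * exp(-k * x)`. Convergence of the
#' pooled `k` across sites is the universal-decay result.
#'
#' @param site_fits list of `decay_fit` objects from [site_decay_fit()]
#'   (each carrying its `series`).
#' @return a `decay_fit` with scope `"universal"` and field `n_sites`.
#' @export
universal_decay <- function(site_fits) {
  usable <- Filter(function(f) isTRUE(f$significant) && f$alpha > 0, site_fits)
  if (length(usable) < 2)
    stop("universal decay needs >= 2 sites with significant site fits")
  x <- unlist(lapply(usable, function(f) seq_along(f$series)))
  y <- unlist(lapply(usable, function(f) f$series / f$alpha))
  fit <- fit_decay(y, x, scope = "universal")
  fit$n_sites <- length(usable)
  fit
}

#' Empirical per-event decay rate with site fallback
#'
#' Estimates the decay rate `k` used in the correction factor. First fits
#' the kinetic curve to the array of per-day 68th percentiles of half-hourly
#' NEE over the event days (the 68th percentile reflects values within one
#' standard deviation of the mean); if that fit is statistically significant
#' (p < `p_sig`, default 0.1) its `k` is accepted. Otherwise the same curve
#' is fitted to the site-level array of per-day means of half-hourly NEE
#' pooled over all the site's events, and that `k` is used instead. Events
#' shorter than 3 days skip the per-event fit.
#'
#' @param t the site's half-hourly `flux_table`.
#' @param event one catalog row (needs `start_date`, `end_date`).
#' @param site_events the site's full catalog (for the fallback array).
#' @param p_sig acceptance p-value for the per-event fit.
#' @return list with `k`, `k_source` (`"event"`, `"site"` or `NA`) and the
#'   underlying `fit`.
#' @export
event_decay_rate <- function(t, event, site_events, p_sig = 0.1) {
  s <- as.Date(event$start_date); e <- as.Date(event$end_date)
  len <- as.integer(e - s) + 1L
  day <- as.Date(t$timestamp, tz = "UTC")
  if (len >= 3) {
    p68 <- vapply(seq(s, e, by = "day"), function(d) {
      x <- t$nee[day == d]
      if (sum(!is.na(x)) < 5) NA_real_
      else stats::quantile(x, 0.68, na.rm = TRUE, names = FALSE, type = 7)
    }, 1.0)
    fit <- fit_decay(p68, seq_along(p68), scope = "event")
    if (fit$converged && !is.na(fit$p_value_k) && fit$p_value_k < p_sig &&
        fit$k > 0)
      return(list(k = fit$k, k_source = "event", fit = fit))
  }
  # site fallback: day-indexed means of half-hourly NEE pooled over events
  max_len <- max(as.integer(as.Date(site_events$end_date) -
                              as.Date(site_events$start_date)) + 1L)
  pooled <- vapply(seq_len(max_len), function(i) {
    x <- unlist(lapply(seq_len(nrow(site_events)), function(r) {
      d <- as.Date(site_events$start_date[r]) + (i - 1L)
      if (d > as.Date(site_events$end_date[r])) return(numeric(0))
      t$nee[day == d]
    }))
    if (sum(!is.na(x)) < 5) NA_real_ else mean(x, na.rm = TRUE)
  }, 1.0)
  fit <- fit_decay(pooled, seq_along(pooled), scope = "site")
  if (fit$converged && fit$k > 0)
    return(list(k = fit$k, k_source = "site", fit = fit))
  list(k = NA_real_, k_source = NA_character_, fit = fit)
}

#' Event-catalog I/O
#'
#' CSV catalogs with ISO-8601 dates and columns `site_id`, `start_date`,
#' `end_date`, `source`, plus any derived characteristic columns.
#'
#' @param path CSV path.
#' @return `read_events`: the catalog data frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "start_date", "end_date")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event catalog missing columns: ",
                         paste(miss, collapse = ", "))
  ev$start_date <- as.Date(ev$start_date)
  ev$end_date <- as.Date(ev$end_date)
  if (!("source" %in% names(ev))) ev$source <- "manual"
  bad <- ev$end_date < ev$start_date + 1
  if (any(bad)) stop("events shorter than 2 days at rows: ",
                     paste(which(bad), collapse = ", "))
  ev
}

#' @param events catalog data frame.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
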