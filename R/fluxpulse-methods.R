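#' @export
print.fluxpulse <- function(x, ...) {
  n_corr <- sum(x$events$corrected)
  cat("Pulse-corrected flux partitioning (night-time baseline)\n")
  cat(sprintf("  record: %s to %s (%d half hours)\n",
              format(min(x$data$timestamp), "%Y-%m-%d"),
              format(max(x$data$timestamp), "%Y-%m-%d"), nrow(x$data)))
  cat(sprintf("  E0 = %.1f K; %d r_ref windows\n", x$partition$e0,
              nrow(x$partition$windows)))
  cat(sprintf("  events: %d catalogued, %d corrected\n",
              nrow(x$events), n_corr))
  invisible(x)
}

#' @export
summary.fluxpulse <- function(object, ...) {
  contrib <- contribution_stats(object)
  val <- validate_night(object)
  out <- list(
    n_halfhours = nrow(object$data),
    e0 = object$partition$e0,
    n_events = nrow(object$events),
    n_corrected = sum(object$events$corrected),
    median_k = stats::median(object$events$k_used, na.rm = TRUE),
    median_intensity = stats::median(object$events$intensity_delta_nee,
                                     na.rm = TRUE),
    reco_contribution_pct = contrib$reco_contribution_pct,
    nep_contribution_pct = contrib$nep_contribution_pct,
    median_bias_nt = val$median_bias_nt,
    median_bias_fp = val$median_bias_fp,
    bias_p_value = val$p_value
  )
  class(out) <- "summary.fluxpulse"
  out
}

#' @export
print.summary.fluxpulse <- function(x, ...) {
  cat("Pulse-corrected flux partitioning - summary\n")
  cat(sprintf("  half hours: %d   E0: %.1f K\n", x$n_halfhours, x$e0))
  cat(sprintf("  events: %d catalogued, %d corrected\n",
              x$n_events, x$n_corrected))
  cat(sprintf("  median decay rate k: %.3f /day   median intensity: %.2f umol m-2 s-1\n",
              x$median_k, x$median_intensity))
  cat(sprintf("  pulse contribution: %.1f%% of respiration, %.1f%% of NEP\n",
              x$reco_contribution_pct, x$nep_contribution_pct))
  if (!is.na(x$median_bias_nt))
    cat(sprintf("  night bias (median): %.1f%% (NT) -> %.1f%% (corrected), one-tailed p = %.3g\n",
                x$median_bias_nt, x$median_bias_fp, x$bias_p_value))
  invisible(x)
}

#' @export
coef.fluxpulse <- function(object, ...) {
  c(e0 = object$partition$e0,
    rref_mean = mean(object$partition$windows$r_ref),
    median_k = stats::median(object$events$k_used, na.rm = TRUE))
}

#' Model respiration at new temperatures
#'
#' Evaluates the fitted Lloyd-Taylor curve (site E0, mean moving-window
#' reference respiration) at new air temperatures.
#'
#' @param object a `fluxpulse` fit.
#' @param newdata data frame with a `tair` column (degC), or `NULL` to
#'   return the fitted half-hourly corrected respiration.
#' @param ... unused.
#' @export
predict.fluxpulse <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$reco_fp)
  lloyd_taylor(newdata$tair, mean(object$partition$windows$r_ref),
               object$partition$e0)
}

#' Night-time respiration residuals
#'
#' Corrected respiration minus observed NEE over night half hours, where
#' NEE approximates respiration; the diagnostic used for the night-time
#' validation.
#'
#' @param object a `fluxpulse` fit.
#' @param ... unused.
#' @export
residuals.fluxpulse <- function(object, ...) {
  night <- !is.na(object$data$sw_in) &
    object$data$sw_in < object$config$sw_night
  r <- object$reco_fp - object$data$nee
  r[!night] <- NA_real_
  r
}

#' Plot a corrected record
#'
#' Daily mean NEE with the night-time-method and corrected respiration
#' overlaid; catalogued events shaded.
#'
#' @param x a `fluxpulse` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fluxpulse <- function(x, ...) {
  day <- as.Date(x$data$timestamp, tz = "UTC")
  agg <- function(v) tapply(v, day, mean, na.rm = TRUE)
  d <- as.Date(names(agg(x$data$nee)))
  graphics::plot(d, agg(x$data$nee), type = "l", col = "grey40",
                 xlab = "date", ylab = "flux (umol CO2 m-2 s-1)", ...)
  if (nrow(x$events)) {
    usr <- graphics::par("usr")
    graphics::rect(as.numeric(as.Date(x$events$start_date)), usr[3],
                   as.numeric(as.Date(x$events$end_date)), usr[4],
                   col = grDevices::adjustcolor("skyblue", 0.25), border = NA)
  }
  graphics::lines(d, agg(x$partition$reco_nt), col = "blue")
  graphics::lines(d, agg(x$reco_fp), col = "red")
  graphics::legend("topright", legend = c("NEE", "NT Reco", "corrected Reco"),
                   col = c("grey40", "blue", "red"), lty = 1, bty = "n")
  invisible(x)
}
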