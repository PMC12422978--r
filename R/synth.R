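#' Synthetic-tower configuration
#'
#' Parameters of the synthetic dryland flux-tower generator. Defaults
#' describe a warm semi-arid grassland-like site: seasonal Lloyd-Taylor
#' baseline respiration, light-response photosynthesis gated by soil-water
#' availability (tracked through the evaporative fraction), sporadic rain
#' events (about 1.2 per month, exponential depths around 8 mm) that raise
#' EF stepwise and trigger additive respiration pulses on dry soil, pulse
#' amplitudes of a few umol CO2 m-2 s-1 decaying at 0.15-0.35 per day over
#' 4-12 days (within the observed 2-26 day range), and modest additive
#' Gaussian noise on the measured fluxes.
#'
#' @param n_years record length (years).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param rref_base,rref_amp baseline reference respiration: mean and
#'   seasonal amplitude (umol CO2 m-2 s-1).
#' @param e0_true Lloyd-Taylor temperature sensitivity (K).
#' @param gpp_max light-saturated GPP (umol CO2 m-2 s-1).
#' @param light_half_sat light-response half saturation (W m-2).
#' @param rain_per_month mean rain events per month.
#' @param rain_depth_mean mean event depth (mm).
#' @param pulse_alpha_range uniform range of day-1 pulse amplitude
#'   (umol CO2 m-2 s-1); daily amplitude is `alpha * exp(-k * (day - 1))`.
#' @param pulse_k_range uniform range of the true decay rate (day-1).
#' @param pulse_len_range event-length range (days), within [2, 26].
#' @param pulse_min_depth minimum rain depth (mm) to trigger a pulse.
#' @param pulse_max_ef driest prepulse EF still triggering a pulse.
#' @param ef_dry,ef_wet EF dry floor and wet ceiling.
#' @param ef_tau EF dry-down e-folding time (days).
#' @param gpp_lag_days vegetation response time to rewetting (days): the
#'   water-availability factor driving GPP is an exponentially smoothed
#'   version of the EF state with this e-folding time, so green-up after
#'   rain is gradual while the microbial pulse is immediate.
#' @param noise_nee,noise_le,noise_h additive Gaussian noise sd per flux.
#' @param tair_mean,tair_seasonal_amp,tair_diel_amp air-temperature
#'   climatology (degC).
#' @param sw_max clear-sky noon shortwave (W m-2).
#' @param rain_temp_drop air-temperature drop on a rain day (degC),
#'   recovering with e-folding `rain_temp_tau` days: rain arrives with cold
#'   fronts, which is one reason a temperature-response respiration model
#'   misses rewetting pulses.
#' @param rain_temp_tau recovery e-folding time of the cold drop (days).
#' @param qc_night_frac,qc_day_frac fraction of night/day half hours
#'   flagged gap-filled (QC > 0), emulating friction-velocity screening and
#'   routine quality loss in ONEFlux products.
#' @param qc_rain_frac flagged fraction on rain days (sensor degradation in
#'   rain).
#' @param qc_night_wet_frac flagged fraction for night half hours while the
#'   soil is wet (calm, humid post-rain nights fail the turbulence screen
#'   almost wholesale, which is what leaves the moving-window baseline
#'   largely blind to the pulse).
#' @param wet_threshold relative EF wetness above which a night counts as
#'   post-rain wet.
#' @return named list (class `synth_config`).
#' @export
synth_config <- function(n_years = 2, seed = 1,
                         rref_base = 1.2, rref_amp = 0.5, e0_true = 150,
                         gpp_max = 6, light_half_sat = 250,
                         rain_per_month = 1.2, rain_depth_mean = 8,
                         pulse_alpha_range = c(3, 8),
                         pulse_k_range = c(0.15, 0.35),
                         pulse_len_range = c(4, 12),
                         pulse_min_depth = 3, pulse_max_ef = 0.35,
                         ef_dry = 0.1, ef_wet = 0.7, ef_tau = 8,
                         gpp_lag_days = 5,
                         noise_nee = 0.5, noise_le = 8, noise_h = 8,
                         tair_mean = 16, tair_seasonal_amp = 9,
                         tair_diel_amp = 6, sw_max = 850,
                         rain_temp_drop = 5, rain_temp_tau = 2,
                         qc_night_frac = 0.4, qc_day_frac = 0.1,
                         qc_rain_frac = 0.6, qc_night_wet_frac = 0.92,
                         wet_threshold = 0.35) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_years >= 1, cfg$ef_tau > 0,
            all(c(cfg$noise_nee, cfg$noise_le, cfg$noise_h) >= 0),
            cfg$rain_per_month >= 0, cfg$rain_depth_mean > 0,
            cfg$ef_dry < cfg$ef_wet)
  if (cfg$pulse_len_range[1] < 2 || cfg$pulse_len_range[2] > 26)
    stop("pulse lengths must lie in [2, 26] days")
  class(cfg) <- c("synth_config", "list")
  cfg
}

#' Generate a synthetic half-hourly tower record
#'
#' Builds a half-hourly dryland record with a known
#' respiration/photosynthesis split and injected rewetting pulses, the
#' ground truth against which every other stage of the pipeline can be
#' scored. Baseline respiration follows the Lloyd-Taylor curve with a
#' seasonal reference respiration; GPP follows a rectangular-hyperbola
#' light response gated by lagged soil-water availability; rain events
#' raise the daily EF stepwise (exponential dry-down in between); each
#' pulse adds `alpha * exp(-k * (day - 1))` (daily mean amplitude) to
#' respiration, modulated diurnally by the Lloyd-Taylor temperature factor
#' so that night NEE during events tracks true respiration. Latent and
#' sensible heat are generated so the daily daytime EF matches the EF
#' state. Pulses trigger only on sufficiently wet rain days falling on
#' sufficiently dry soil, and never overlap.
#'
#' @param cfg a [synth_config()].
#' @return list with `flux` (a `flux_table`, QC flags all 0) and `truth`
#'   (list: half-hourly `reco_true`, `gpp_true`, `pulse_component`,
#'   `ef_state` per day, and `events` - data frame with `site_id`,
#'   `start_date`, `end_date`, `alpha_true`, `k_true`).
#' @export
generate_site <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n_days <- round(cfg$n_years * 365)
  dates <- as.Date("2015-01-01") + 0:(n_days - 1)
  ts <- seq(as.POSIXct("2015-01-01 00:00", tz = "UTC"),
            by = 1800, length.out = n_days * 48)
  doy <- as.numeric(format(ts, "%j"))
  hod <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  day_i <- rep(seq_len(n_days), each = 48)

  seasonal <- cos(2 * pi * (doy - 200) / 365)
  sw_in <- pmax(0, cfg$sw_max * (0.7 + 0.3 * seasonal) *
                  sin(pi * (hod - 6) / 12)) * (hod >= 6 & hod <= 18)

  # rain: Bernoulli day with exponential depth, dumped into 4 half hours
  rain_day <- stats::runif(n_days) < cfg$rain_per_month / 30
  depth <- ifelse(rain_day, stats::rexp(n_days, 1 / cfg$rain_depth_mean), 0)

  # cold front with each rain event, relaxing over a few days
  cold <- numeric(n_days)
  carry <- 0
  for (d in seq_len(n_days)) {
    carry <- carry * exp(-1 / cfg$rain_temp_tau)
    if (rain_day[d]) carry <- cfg$rain_temp_drop
    cold[d] <- carry
  }
  tair <- cfg$tair_mean + cfg$tair_seasonal_amp * seasonal +
    cfg$tair_diel_amp * sin(2 * pi * (hod - 9) / 24) - cold[day_i]

  # daily EF state: exponential dry-down plus stepwise rewetting
  ef_state <- numeric(n_days)
  ef <- cfg$ef_dry + 0.05
  decay <- exp(-1 / cfg$ef_tau)
  for (d in seq_len(n_days)) {
    ef <- cfg$ef_dry + (ef - cfg$ef_dry) * decay
    if (depth[d] > 0)
      ef <- min(cfg$ef_wet, ef + max(0.1, 0.035 * depth[d]))
    ef_state[d] <- ef
  }

  # pulse events: dry-soil rain days, non-overlapping
  ev_start <- integer(0); ev_end <- integer(0)
  ev_alpha <- numeric(0); ev_k <- numeric(0)
  last_end <- 0L
  for (d in seq_len(n_days)) {
    if (!rain_day[d] || depth[d] < cfg$pulse_min_depth) next
    pre_ef <- if (d == 1) cfg$ef_dry else ef_state[d - 1]
    if (pre_ef > cfg$pulse_max_ef) next
    if (d <= last_end + 2L) next
    len <- sample(cfg$pulse_len_range[1]:cfg$pulse_len_range[2], 1)
    if (d + len - 1 > n_days) next
    ev_start <- c(ev_start, d); ev_end <- c(ev_end, d + len - 1L)
    ev_alpha <- c(ev_alpha, stats::runif(1, cfg$pulse_alpha_range[1],
                                         cfg$pulse_alpha_range[2]))
    ev_k <- c(ev_k, stats::runif(1, cfg$pulse_k_range[1],
                                 cfg$pulse_k_range[2]))
    last_end <- d + len - 1L
  }

  rref_t <- cfg$rref_base + cfg$rref_amp * seasonal
  ltf <- lt_factor(tair, cfg$e0_true)
  reco_base <- pmax(rref_t, 0.05) * ltf
  # diel modulation normalized to a daily mean of 1 so the daily mean of
  # the pulse component equals the prescribed amplitude
  ltf_daymean <- stats::ave(ltf, day_i)
  diel <- ltf / ltf_daymean
  pulse <- numeric(length(ts))
  for (e in seq_along(ev_start)) {
    for (i in 0:(ev_end[e] - ev_start[e])) {
      hh <- which(day_i == ev_start[e] + i)
      pulse[hh] <- pulse[hh] + ev_alpha[e] * exp(-ev_k[e] * i) * diel[hh]
    }
  }
  reco_true <- reco_base + pulse

  # GPP: light response gated by smoothed (vegetation-lagged) water
  # availability - green-up is gradual, unlike the microbial pulse
  wet_now <- (ef_state - cfg$ef_dry) / (cfg$ef_wet - cfg$ef_dry)
  veg_wet <- numeric(n_days)
  gain <- 1 - exp(-1 / cfg$gpp_lag_days)
  vw <- wet_now[1]
  for (d in seq_len(n_days)) {
    vw <- vw + (wet_now[d] - vw) * gain
    veg_wet[d] <- vw
  }
  wet <- pmin(pmax(veg_wet[day_i], 0.05), 1)
  gpp_true <- cfg$gpp_max * sw_in / (sw_in + cfg$light_half_sat) * wet

  nee <- reco_true - gpp_true + stats::rnorm(length(ts), 0, cfg$noise_nee)

  # turbulent energy split so the daytime EF matches the EF state
  avail <- 0.65 * sw_in + 15
  ef_hh <- ef_state[day_i]
  le <- ef_hh * avail + stats::rnorm(length(ts), 0, cfg$noise_le)
  h <- (1 - ef_hh) * avail + stats::rnorm(length(ts), 0, cfg$noise_h)

  p_era <- numeric(length(ts))
  for (d in which(depth > 0)) {
    hh <- which(day_i == d)[seq(19, 25, by = 2)] # morning rain
    p_era[hh] <- depth[d] / length(hh)
  }

  # QC provenance: routine night (u*-screening) and day losses, heavier on
  # rain days; flagged half hours carry a model-based fill (as gap-filled
  # products do) and QC flag 1
  night_hh <- sw_in < 20
  p_flag <- ifelse(night_hh, cfg$qc_night_frac, cfg$qc_day_frac)
  wetness <- (ef_state[day_i] - cfg$ef_dry) / (cfg$ef_wet - cfg$ef_dry)
  wet_night <- night_hh & wetness > cfg$wet_threshold
  p_flag[wet_night] <- cfg$qc_night_wet_frac
  p_flag[rain_day[day_i]] <- pmax(p_flag[rain_day[day_i]], cfg$qc_rain_frac)
  flagged <- stats::runif(length(ts)) < p_flag
  fill <- reco_base - gpp_true + stats::rnorm(length(ts), 0, cfg$noise_nee)
  nee[flagged] <- fill[flagged]
  qc <- as.numeric(flagged)

  flux <- validate_flux_table(data.frame(
    timestamp = ts, nee = nee, le = le, h = h, tair = tair, sw_in = sw_in,
    p_tower = p_era * 0.7, p_era = p_era,
    qc_nee = qc, qc_le = qc, qc_h = qc))
  events <- data.frame(site_id = rep(paste0("SYN-", cfg$seed),
                                     length(ev_start)),
                       start_date = dates[ev_start], end_date = dates[ev_end],
                       alpha_true = ev_alpha, k_true = ev_k,
                       source = rep("truth", length(ev_start)),
                       stringsAsFactors = FALSE)
  list(flux = flux,
       truth = list(reco_true = reco_true, gpp_true = gpp_true,
                    pulse_component = pulse, ef_state = ef_state,
                    dates = dates, events = events))
}

#' Ground-truth pulse contributions
#'
#' Exact contributions of the injected pulses computed from the generated
#' components: the share of the additive pulse component in total
#' respiration, and the share of event-window respiration and NEP in the
#' record totals (the quantity the empirical contribution statistic
#' estimates).
#'
#' @param site output of [generate_site()].
#' @return list with `pulse_component_pct` (additive component share of
#'   respiration), `reco_event_window_pct` and `nep_event_window_pct`
#'   (event-window shares).
#' @export
truth_report <- function(site) {
  truth <- site$truth
  day <- as.Date(site$flux$timestamp, tz = "UTC")
  in_ev <- rep(FALSE, length(day))
  for (r in seq_len(nrow(truth$events))) {
    in_ev <- in_ev | (day >= truth$events$start_date[r] &
                        day <= truth$events$end_date[r])
  }
  nep <- -(truth$reco_true - truth$gpp_true)
  list(pulse_component_pct = 100 * sum(truth$pulse_component) /
         sum(truth$reco_true),
       reco_event_window_pct = 100 * sum(truth$reco_true[in_ev]) /
         sum(truth$reco_true),
       nep_event_window_pct = 100 * sum(nep[in_ev]) / sum(nep))
}
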