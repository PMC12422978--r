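test_that("Lloyd-Taylor anchors exactly at the reference temperature", {
  r_ref <- 2.7
  expect_identical(lloyd_taylor(15, r_ref, e0 = 185), r_ref)
  # zero temperature sensitivity -> flat response
  expect_equal(lloyd_taylor(c(-5, 10, 30), 2, e0 = 0), rep(2, 3))
  # direct numeric evaluation at 25 degC
  expect_equal(lloyd_taylor(25, 2, 200),
               2 * exp(200 * (1 / 61.02 - 1 / 71.02)), tolerance = 1e-12)
  expect_equal(lloyd_taylor(25, 2, 200), 3.17294, tolerance = 1e-5)
  # below T0 the model is undefined
  expect_true(is.na(lloyd_taylor(-50, 2, 200)))
})

test_that("Lloyd-Taylor is strictly increasing in temperature for E0 > 0", {
  tt <- seq(-20, 45, by = 0.5)
  for (e0 in c(50, 150, 400)) {
    v <- lloyd_taylor(tt, 1.5, e0)
    expect_true(all(diff(v) > 0))
  }
})

# night-only synthetic record generated exactly from the model
make_nt_flux <- function(n_days, r_ref = 2, e0 = 150, noise = 0,
                         tair_amp = 10, seed = 1) {
  set.seed(seed)
  t <- make_flux(n_days = n_days, tair = 0)
  hod <- as.numeric(format(t$timestamp, "%H"))
  doy <- as.numeric(format(t$timestamp, "%j"))
  t$tair <- 12 + tair_amp * sin(2 * pi * doy / 60) + 4 * sin(2 * pi * (hod - 9) / 24)
  rr <- if (length(r_ref) == 1) rep(r_ref, nrow(t)) else r_ref
  reco <- lloyd_taylor(t$tair, rr, e0)
  t$nee <- reco + rnorm(nrow(t), 0, noise)
  t$nee[t$sw_in >= 20] <- reco[t$sw_in >= 20] # day NEE unused at night
  t
}

test_that("E0 is recovered from exact and noisy night-time data", {
  t <- make_nt_flux(60, r_ref = 2, e0 = 150)
  e0 <- fit_e0(t)
  expect_equal(as.numeric(e0), 150, tolerance = 1e-3)
  tn <- make_nt_flux(60, r_ref = 2, e0 = 150, noise = 0.3, seed = 2)
  e0n <- fit_e0(tn)
  expect_lt(abs(e0n - 150), 20)
  # grid-search oracle on one window of night data
  night <- tn$sw_in < 20
  win <- night & as.Date(tn$timestamp) < as.Date("2020-06-16")
  grid <- expand.grid(rref = seq(1.5, 2.5, 0.01), e0 = seq(80, 250, 1))
  ss <- mapply(function(r, e) sum((tn$nee[win] - lloyd_taylor(tn$tair[win], r, e))^2),
               grid$rref, grid$e0)
  e0_oracle <- grid$e0[which.min(ss)]
  expect_lt(abs(e0_oracle - 150), 20) # oracle agrees the truth is recoverable
  # isothermal nights violate the temperature-range precondition
  iso <- make_flux(n_days = 30, nee = 2, tair = 15)
  expect_error(fit_e0(iso), "temperature range|no window")
})

test_that("moving-window r_ref estimation and interpolation behave as specified", {
  # constant night NEE at the reference temperature -> every window r_ref
  t <- make_flux(n_days = 12, nee = 1.8, tair = 15)
  rr <- fit_rref_windows(t, e0 = 150, window_days = 4, step_days = 2,
                         min_obs = 5)
  expect_true(all(abs(rr$windows$r_ref - 1.8) < 1e-9))
  expect_true(all(abs(rr$rref_interp - 1.8) < 1e-9))
  # two window levels: midpoint interpolation halves the step
  t2 <- make_flux(n_days = 8, nee = c(rep(1, 4 * 48), rep(2, 4 * 48)),
                  tair = 15)
  rr2 <- fit_rref_windows(t2, e0 = 150, window_days = 4, step_days = 4,
                          min_obs = 5)
  expect_equal(nrow(rr2$windows), 2)
  mid <- mean(rr2$windows$center_num)
  tnum <- as.numeric(as.Date(t2$timestamp)) +
    (as.numeric(t2$timestamp) %% 86400) / 86400
  j <- which.min(abs(tnum - mid))
  expect_equal(rr2$rref_interp[j], 1.5, tolerance = 0.01)
})

test_that("seasonally varying r_ref is tracked within 10% of its amplitude", {
  n_days <- 120
  doy <- rep(1:n_days, each = 48)
  rref_true <- 2 + 1 * sin(2 * pi * doy / 120)
  t <- make_nt_flux(n_days, r_ref = rref_true, e0 = 150)
  rr <- fit_rref_windows(t, e0 = 150, min_obs = 5)
  night <- t$sw_in < 20
  err <- abs(rr$rref_interp[night] - rref_true[night])
  expect_lt(max(err, na.rm = TRUE), 0.1 * 1)
})

test_that("partitioning preserves NEE = Reco - GPP and propagates missingness", {
  t <- make_nt_flux(30, r_ref = 2, e0 = 150)
  t$nee[100:150] <- NA
  e0 <- fit_e0(t)
  part <- partition_nt(t, e0, fit_rref_windows(t, e0, min_obs = 5))
  ok <- !is.na(part$gpp_nt)
  expect_equal(t$nee[ok], part$reco_nt[ok] - part$gpp_nt[ok], tolerance = 1e-12)
  expect_true(all(is.na(part$gpp_nt[100:150])))
  expect_true(all(!is.na(part$reco_nt[100:150]))) # reco from temperature alone
  expect_true(all(part$reco_nt >= 0, na.rm = TRUE))
  # night NEE equals modelled respiration by construction -> night GPP ~ 0
  night <- t$sw_in < 20 & !is.na(part$gpp_nt)
  expect_lt(stats::median(abs(part$gpp_nt[night])), 0.05)
})

test_that("pulse-free synthetic data give high-fidelity partitioning", {
  site <- generate_site(synth_config(n_years = 1, seed = 2, rain_per_month = 0,
                                     noise_nee = 0, qc_night_frac = 0,
                                     qc_day_frac = 0, qc_rain_frac = 0,
                                     qc_night_wet_frac = 0))
  t <- site$flux
  e0 <- fit_e0(t)
  part <- partition_nt(t, e0, fit_rref_windows(t, e0))
  truth <- site$truth$reco_true
  ok <- !is.na(part$reco_nt)
  rmse <- sqrt(mean((part$reco_nt[ok] - truth[ok])^2))
  expect_lt(rmse, 0.15 * mean(truth))
  expect_gt(stats::cor(part$reco_nt[ok], truth[ok])^2, 0.95)
})

test_that("the prepulse refit uses the event-length window and skips overlaps", {
  t <- make_nt_flux(40, r_ref = 2, e0 = 150)
  e0 <- 150
  part <- partition_nt(t, e0, fit_rref_windows(t, e0, min_obs = 5))
  d0 <- as.Date(t$timestamp[1], tz = "UTC")
  events <- data.frame(site_id = "A",
                       start_date = c(d0 + 10, d0 + 18),
                       end_date = c(d0 + 14, d0 + 23))
  pp <- refit_prepulse(t, part, events)
  # first event: 5-day prepulse (days 5-9) refitted
  day <- as.Date(t$timestamp, tz = "UTC")
  expect_true(any(pp$prepulse_mask[day >= d0 + 5 & day <= d0 + 9]))
  expect_true(pp$refitted[1])
  # second event: its 6-day prepulse (days 12-17) overlaps event 1 -> skipped
  expect_false(pp$refitted[2])
  expect_false(any(pp$prepulse_mask[day >= d0 + 15 & day <= d0 + 17]))
})

test_that("2-day prepulse windows track a step change better than 4-day ones", {
  # r_ref steps up 3 days before the "event" (rising respiration toward rain)
  n_days <- 30
  rref_true <- rep(c(1, 2), c(24 * 48, 6 * 48))
  t <- make_nt_flux(n_days, r_ref = rref_true, e0 = 150, noise = 0.05, seed = 4)
  rmse_for <- function(w) {
    rr <- fit_rref_windows(t, 150, window_days = w, step_days = 1, min_obs = 4)
    sub <- as.Date(t$timestamp, tz = "UTC") >= as.Date(t$timestamp[1]) + 22
    sqrt(mean((rr$rref_interp[sub] - rref_true[sub])^2, na.rm = TRUE))
  }
  expect_lt(rmse_for(2), rmse_for(4))
})
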