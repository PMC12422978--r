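test_that("the correction factor follows the day-1 percentile ratio and decay", {
  nee1 <- rep(seq(0, 6, length.out = 24), 2) # p98 ~ 6
  reco1 <- rep(seq(0, 3, length.out = 24), 2)
  st0 <- build_beta(nee1, reco1, k = 0, n_days = 4)
  ratio <- st0$nee_p98_day1 / st0$reco_nt_p98_day1
  expect_equal(st0$beta_by_day, rep(ratio, 4)) # k = 0 limit: constant beta
  st <- build_beta(nee1, reco1, k = 0.16, n_days = 5)
  expect_equal(st$beta_by_day[3], ratio * exp(-0.32), tolerance = 1e-12)
  # worked value with exact percentiles 6 and 3
  expect_equal(2 * exp(-0.32), 1.4523, tolerance = 1e-4)
  # identical percentiles -> beta_1 = 1 (baseline already unbiased on day 1)
  st1 <- build_beta(nee1, nee1, k = 0.2, n_days = 3)
  expect_equal(st1$beta_by_day[1], 1)
  expect_true(st1$flag_beta1_lt_1 == FALSE)
})

test_that("events without a usable day-1 signal are skipped with a reason", {
  noemit <- build_beta(rep(-2, 48), rep(2, 48), k = 0.2, n_days = 3)
  expect_s3_class(noemit, "correction_skip")
  expect_match(attr(noemit, "reason"), "no emission pulse")
  noreco <- build_beta(rep(2, 48), rep(0, 48), k = 0.2, n_days = 3)
  expect_match(attr(noreco, "reason"), "not positive")
  few <- build_beta(c(rep(2, 5), rep(NA, 43)), rep(2, 48), k = 0.2, n_days = 3)
  expect_match(attr(few, "reason"), "too few")
})

test_that("beta decays strictly for k > 0 and the day-1 identity is exact", {
  set.seed(9)
  for (rep in 1:15) {
    nee1 <- rnorm(48, 5, 2); reco1 <- abs(rnorm(48, 2, 0.5))
    k <- runif(1, 0.05, 0.6)
    st <- build_beta(nee1, reco1, k = k, n_days = 10)
    if (inherits(st, "correction_skip")) next
    expect_true(all(diff(st$beta_by_day) < 0))
    # beta_1 * Reco98 = NEE98 (exact up to one floating-point rounding)
    expect_equal(st$beta_by_day[1] * st$reco_nt_p98_day1, st$nee_p98_day1,
                 tolerance = 1e-14)
  }
})

test_that("applying the correction scales days and preserves the identity", {
  st <- build_beta(rep(c(3, 6), 24), rep(c(1.5, 3), 24), k = 0.2, n_days = 3)
  reco_nt <- rep(3, 144); nee <- rep(2, 144)
  day_index <- rep(1:3, each = 48)
  out <- apply_correction(st, reco_nt, nee, day_index)
  expect_equal(out$reco_fp[1:48], rep(st$beta_by_day[1] * 3, 48))
  expect_equal(out$gpp_fp, out$reco_fp - nee)
  # at the day-1 half hour where reco_nt equals its 98th percentile the
  # corrected value equals the NEE 98th percentile
  r98 <- st$reco_nt_p98_day1
  out2 <- apply_correction(st, rep(r98, 48), nee[1:48], rep(1L, 48))
  expect_equal(out2$reco_fp[1], st$nee_p98_day1, tolerance = 1e-12)
})

test_that("the full pipeline corrects a synthetic site and anchors day 1", {
  site <- generate_site(synth_config(n_years = 2, seed = 7))
  fit <- fluxpulse(site$flux,
                   events = site$truth$events[c("site_id", "start_date",
                                                "end_date")])
  expect_s3_class(fit, "fluxpulse")
  day <- as.Date(fit$data$timestamp, tz = "UTC")
  corrected <- which(fit$events$corrected)
  expect_gt(length(corrected), 3)
  for (r in corrected) {
    st <- fit$states[[r]]
    s <- as.Date(fit$events$start_date[r])
    d1 <- day == s & !is.na(fit$partition$reco_nt)
    # day-1 98th percentile of corrected reco equals beta_1 * NT percentile
    p98 <- function(x) stats::quantile(x, 0.98, na.rm = TRUE, names = FALSE)
    expect_equal(p98(fit$reco_fp[d1]), st$nee_p98_day1, tolerance = 1e-9)
    expect_true(all(diff(st$beta_by_day) < 0))
  }
  # untouched half hours are bit-identical to the NT output
  un <- fit$mask == "untouched"
  expect_identical(fit$reco_fp[un], fit$partition$reco_nt[un])
  expect_identical(fit$gpp_fp[un], fit$partition$gpp_nt[un])
  # conservation wherever NEE is defined
  ok <- !is.na(fit$gpp_fp) & !is.na(fit$reco_fp) & !is.na(fit$data$nee)
  expect_equal(fit$gpp_fp[ok] - fit$reco_fp[ok], -fit$data$nee[ok],
               tolerance = 1e-12)
})

test_that("a constructed event is corrected closer to truth than a flat baseline", {
  # a pulse decaying onto a baseline the temperature model holds flat
  set.seed(17)
  n_days <- 8
  day_index <- rep(1:n_days, each = 48)
  hod <- rep(seq(0, 23.5, by = 0.5), n_days)
  night <- hod < 6 | hod > 18
  truth <- 2 + 5 * exp(-0.3 * (day_index - 1))
  nee <- truth + rnorm(n_days * 48, 0, 0.3)
  reco_nt <- rep(2, n_days * 48) # flat baseline misses the pulse
  p68 <- vapply(1:n_days, function(i)
    stats::quantile(nee[day_index == i], 0.68, names = FALSE), 1.0)
  kfit <- fit_decay(p68, 1:n_days)
  st <- build_beta(nee[day_index == 1], reco_nt[day_index == 1],
                   k = kfit$k, n_days = n_days)
  out <- apply_correction(st, reco_nt, nee, day_index)
  err_fp <- abs(out$reco_fp[night] - truth[night])
  err_nt <- abs(reco_nt[night] - truth[night])
  expect_lt(stats::median(err_fp), stats::median(err_nt))
})

test_that("contribution statistics are exact share computations", {
  site <- generate_site(synth_config(n_years = 1, seed = 3))
  fit <- fluxpulse(site$flux,
                   events = site$truth$events[c("site_id", "start_date",
                                                "end_date")])
  cs <- contribution_stats(fit)
  in_p <- fit$mask == "pulse"
  expect_equal(cs$reco_contribution_pct,
               100 * sum(fit$reco_fp[in_p], na.rm = TRUE) /
                 sum(fit$reco_fp, na.rm = TRUE))
  # no events -> zero contribution
  quiet <- generate_site(synth_config(n_years = 1, seed = 3,
                                      rain_per_month = 0))
  fq <- fluxpulse(quiet$flux, events = quiet$truth$events[
    c("site_id", "start_date", "end_date")])
  expect_equal(contribution_stats(fq)$reco_contribution_pct, 0)
})

test_that("underestimation of an alternative partitioner has the stated sign", {
  site <- generate_site(synth_config(n_years = 1, seed = 5))
  fit <- fluxpulse(site$flux,
                   events = site$truth$events[c("site_id", "start_date",
                                                "end_date")])
  # y identical to x -> 0%
  expect_equal(underestimation_stats(fit, fit$reco_fp), 0)
  # y = 0.8 x -> 20% underestimation; y = 1.25 x -> -25% (overestimation)
  expect_equal(underestimation_stats(fit, 0.8 * fit$reco_fp), 20)
  expect_equal(underestimation_stats(fit, 1.25 * fit$reco_fp), -25)
  expect_error(underestimation_stats(fit, 1:10), "not aligned")
})

test_that("night validation detects a constructed bias reduction", {
  site <- generate_site(synth_config(n_years = 2, seed = 13))
  fit <- fluxpulse(site$flux,
                   events = site$truth$events[c("site_id", "start_date",
                                                "end_date")])
  v <- validate_night(fit)
  expect_gt(v$n_events, 2)
  # perfect corrected series -> zero bias by construction
  fit2 <- fit
  night <- fit2$data$sw_in < 20
  fit2$reco_fp[night] <- fit2$data$nee[night]
  v2 <- validate_night(fit2)
  expect_equal(v2$median_bias_fp, 0, tolerance = 1e-9)
  # baseline scaled to ~0.8x night NEE -> ~-20% bias, reduction detected
  set.seed(1)
  fit3 <- fit2
  scale <- 0.8 + rnorm(length(night), 0, 0.02)
  fit3$partition$reco_nt <- scale * fit2$data$nee
  fit3$partition$reco_nt[!night] <- fit2$partition$reco_nt[!night]
  v3 <- validate_night(fit3)
  expect_equal(v3$median_bias_nt, -20, tolerance = 0.05)
  expect_lt(v3$p_value, 0.05)
})
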