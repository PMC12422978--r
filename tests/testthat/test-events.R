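test_that("noiseless kinetic decay is recovered to 1e-6 relative error", {
  i <- 1:10
  y <- 8 * exp(-0.3 * i)
  fit <- fit_decay(y, i, scope = "site")
  expect_true(fit$converged)
  expect_equal(fit$alpha, 8, tolerance = 1e-6)
  expect_equal(fit$k, 0.3, tolerance = 1e-6)
  expect_lt(fit$p_value_k, 0.001)
})

test_that("noisy decay fit matches a grid-search least-squares oracle", {
  set.seed(5)
  i <- 1:10
  y <- 8 * exp(-0.3 * i) * (1 + 0.1 * rnorm(10))
  fit <- fit_decay(y, i)
  oracle <- grid_decay_oracle(y, i, a_grid = seq(5, 12, by = 0.02),
                              k_grid = seq(0.1, 0.6, by = 0.005))
  expect_equal(fit$k, oracle$k, tolerance = 0.005 / 0.3) # grid resolution
  expect_equal(fit$alpha, oracle$alpha, tolerance = 0.02 / 8 * 2)
  expect_lt(abs(fit$k - 0.3), 0.05)
})

test_that("degenerate decay inputs are handled: constants and short series", {
  set.seed(1)
  flat <- fit_decay(2 + rnorm(8, 0, 0.01), 1:8)
  expect_true(!flat$converged || abs(flat$k) < 0.02)
  if (flat$converged) expect_gt(flat$p_value_k, 0.05) # not significant
  expect_false(fit_decay(c(3, 2), 1:2)$converged)
})

test_that("rule screen finds the hand-traced candidate and rejects non-pulses", {
  nee <- c(0.5, 0.5, 4.0, 3.0, 2.2, 0.6, 0.5, 0.5)
  ef <- c(0.2, 0.2, 0.55, 0.5, 0.45, 0.4, 0.35, 0.3)
  night <- c(0.5, 0.5, 3.8, 2.9, 2.0, 0.55, 0.5, 0.5)
  p <- c(0, 0, 9, 0, 0, 0, 0, 0)
  d <- make_daily(nee, ef = ef, p = p, night = night)
  cand <- rule_screen(d, nee_jump = 1, ef_jump = 0.1, site_id = "A")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start_date, d$date[3])
  # end: night NEE back within 25% of prepulse level (0.5) on day 6
  expect_equal(cand$end_date, d$date[6])
  # flat series, no rain -> nothing
  expect_equal(nrow(rule_screen(make_daily(rep(0.5, 8)))), 0)
  # single-day spike fails the 2-day decay condition
  spike <- make_daily(c(0.5, 0.5, 4.0, 0.5, 0.5, 0.5), ef = ef[1:6],
                      p = p[1:6])
  expect_equal(nrow(rule_screen(spike, nee_jump = 1, ef_jump = 0.1)), 0)
  # rain requirement can be waived
  norain <- make_daily(nee, ef = ef, p = 0, night = night)
  expect_equal(nrow(rule_screen(norain, nee_jump = 1, ef_jump = 0.1,
                                require_rain = TRUE)), 0)
  expect_equal(nrow(rule_screen(norain, nee_jump = 1, ef_jump = 0.1,
                                require_rain = FALSE)), 1)
})

test_that("event characteristics follow the 2-day and whole-event definitions", {
  nee <- c(0.5, 0.5, 3.0, 2.0, 0.5, 0.4, 0.4, 0.4)
  d <- make_daily(nee)
  ev <- data.frame(site_id = "A", start_date = d$date[3], end_date = d$date[5],
                   source = "manual")
  ch <- characterize_events(ev, d)
  expect_equal(ch$length_days, 3L)
  expect_equal(ch$intensity_delta_nee, mean(c(3, 2)) - mean(c(0.5, 0.5)))
  expect_equal(ch$size, 3 + 2 + 0.5)
  # all-zero flux -> zero intensity and size
  z <- make_daily(rep(0, 8))
  chz <- characterize_events(ev, z)
  expect_equal(chz$intensity_delta_nee, 0)
  expect_equal(chz$size, 0)
  # one missing pre-day: the single valid day is used and flagged
  d2 <- d; d2$nee_daily_mean[2] <- NA
  ch2 <- characterize_events(ev, d2)
  expect_equal(ch2$intensity_delta_nee, mean(c(3, 2)) - 0.5)
  expect_true(ch2$partial_pre)
})

test_that("site decay fit recovers parameters from day-indexed event maxima", {
  # two events whose daily means follow 6*exp(-0.25*i) with different lengths
  i1 <- 1:8; i2 <- 1:5
  vals <- rep(0.2, 30)
  d <- make_daily(vals)
  d$nee_daily_mean[3 + i1 - 1] <- 6 * exp(-0.25 * i1)
  d$nee_daily_mean[18 + i2 - 1] <- 4 * exp(-0.25 * i2) # smaller event
  ev <- data.frame(site_id = "A",
                   start_date = d$date[c(3, 18)],
                   end_date = d$date[c(10, 22)], source = "manual")
  fit <- site_decay_fit(ev, d)
  # maxima over events are the larger event's values
  expect_equal(fit$series[1:5], 6 * exp(-0.25 * (1:5)))
  expect_true(fit$significant)
  expect_equal(fit$alpha, 6, tolerance = 1e-6)
  expect_equal(fit$k, 0.25, tolerance = 1e-6)
})

test_that("pooled decay across identical sites equals the single-site fit", {
  mk <- function(a) {
    d <- make_daily(rep(0.2, 20))
    d$nee_daily_mean[5:14] <- a * exp(-0.2 * (1:10))
    ev <- data.frame(site_id = "s", start_date = d$date[5],
                     end_date = d$date[14], source = "manual")
    site_decay_fit(ev, d)
  }
  f1 <- mk(5); f2 <- mk(9)
  uni <- universal_decay(list(f1, f2))
  expect_equal(uni$k, 0.2, tolerance = 1e-6)
  # normalized day-1 value: exp(-k * 1) scaled by the pooled intercept
  expect_equal(uni$alpha * exp(-uni$k), exp(-0.2), tolerance = 1e-6)
  expect_error(universal_decay(list(f1)), ">= 2 sites")
})

test_that("per-event decay rate uses the 68th-percentile path when significant", {
  # construct half-hourly NEE whose daily 68th percentiles equal
  # 5 * exp(-0.2 * (i - 1))
  n_days <- 6
  base <- stats::qnorm(seq(0.01, 0.99, length.out = 48)) # spread within day
  nee <- unlist(lapply(1:n_days, function(i) {
    target <- 5 * exp(-0.2 * i)
    x <- base - stats::quantile(base, 0.68, type = 7) # p68 = 0
    x + target
  }))
  t <- make_flux(n_days = n_days, nee = nee)
  ev <- data.frame(site_id = "A",
                   start_date = as.Date("2020-06-01"),
                   end_date = as.Date("2020-06-06"))
  res <- event_decay_rate(t, ev[1, ], ev)
  expect_equal(res$k_source, "event")
  expect_equal(res$k, 0.2, tolerance = 1e-6)
})

test_that("noisy or short events fall back to the site-level mean array", {
  set.seed(3)
  # pure noise: per-event percentile fit not significant at p < 0.1
  t <- make_flux(n_days = 12, nee = rnorm(12 * 48, 1, 0.5))
  day0 <- as.Date("2020-06-01")
  # site catalog with a decaying mean event elsewhere in the record
  nee2 <- unlist(lapply(1:6, function(i) rep(4 * exp(-0.3 * i), 48)))
  t$nee[(6 * 48 + 1):(12 * 48)] <- nee2 + rnorm(6 * 48, 0, 0.05)
  events <- data.frame(site_id = "A",
                       start_date = c(day0, day0 + 6),
                       end_date = c(day0 + 5, day0 + 11))
  res <- event_decay_rate(t, events[1, ], events)
  expect_true(res$k_source %in% c("event", "site"))
  if (res$k_source == "event") expect_lt(res$fit$p_value_k, 0.1)
  # a 2-day event cannot take the per-event path
  short_ev <- data.frame(site_id = "A", start_date = day0 + 6,
                         end_date = day0 + 7)
  res2 <- event_decay_rate(t, short_ev, events)
  expect_false(identical(res2$k_source, "event"))
})

test_that("event catalogs round-trip through CSV and reject sub-2-day events", {
  ev <- data.frame(site_id = "A",
                   start_date = as.Date(c("2020-06-01", "2020-07-01")),
                   end_date = as.Date(c("2020-06-05", "2020-07-03")),
                   source = "manual")
  f <- tempfile(fileext = ".csv")
  write_events(ev, f)
  rt <- read_events(f)
  expect_equal(rt$start_date, ev$start_date)
  expect_equal(rt$end_date, ev$end_date)
  bad <- ev; bad$end_date[1] <- bad$start_date[1]
  fb <- tempfile(fileext = ".csv")
  write_events(bad, fb)
  expect_error(read_events(fb), "shorter than 2 days")
})
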