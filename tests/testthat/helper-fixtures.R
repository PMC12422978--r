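# Fixture builders used across the suite. All data are generated in code.

# Half-hourly flux table covering n_days from a given start, with constant
# or per-half-hour values.
make_flux <- function(n_days = 1, start = "2020-06-01", nee = 1, le = 100,
                      h = 100, tair = 15, sw_in = NULL, p_era = 0,
                      qc_nee = 0, qc_le = 0, qc_h = 0) {
  n <- n_days * 48
  ts <- seq(as.POSIXct(paste(start, "00:00"), tz = "UTC"), by = 1800,
            length.out = n)
  hod <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  if (is.null(sw_in))
    sw_in <- pmax(0, 600 * sin(pi * (hod - 6) / 12)) * (hod >= 6 & hod <= 18)
  rep_n <- function(x) if (length(x) == n) x else rep_len(x, n)
  validate_flux_table(data.frame(
    timestamp = ts, nee = rep_n(nee), le = rep_n(le), h = rep_n(h),
    tair = rep_n(tair), sw_in = rep_n(sw_in), p_tower = rep_n(p_era),
    p_era = rep_n(p_era), qc_nee = rep_n(qc_nee), qc_le = rep_n(qc_le),
    qc_h = rep_n(qc_h)))
}

# Daily table shortcut for event/hydro tests.
make_daily <- function(nee, ef = 0.3, p = 0, night = NULL,
                       start = "2020-06-01") {
  n <- length(nee)
  data.frame(date = as.Date(start) + 0:(n - 1),
             nee_daily_mean = nee,
             nee_daily_max = nee,
             nee_p68 = nee, nee_p98 = nee,
             nee_night_mean = if (is.null(night)) nee else rep_len(night, n),
             ef_daytime = rep_len(ef, n),
             p_total = rep_len(p, n),
             n_valid_halfhours = 48L)
}

# Independent grid-search least-squares oracle for y = a * exp(-k * i).
grid_decay_oracle <- function(y, i, a_grid, k_grid) {
  best <- c(NA, NA, Inf)
  for (a in a_grid) for (k in k_grid) {
    ss <- sum((y - a * exp(-k * i))^2)
    if (ss < best[3]) best <- c(a, k, ss)
  }
  list(alpha = best[1], k = best[2], ss = best[3])
}

# Brute-force maximum one-to-one matching within tolerance (for catalogs
# small enough to enumerate all injective assignments).
brute_force_matches <- function(pred, truth, tol = 2) {
  pred <- as.numeric(as.Date(pred)); truth <- as.numeric(as.Date(truth))
  np <- length(pred); nt <- length(truth)
  if (np == 0 || nt == 0) return(0L)
  best <- 0L
  assign_next <- function(p_idx, used, count) {
    if (count + (np - p_idx + 1) <= best) return()
    if (p_idx > np) { best <<- max(best, count); return() }
    assign_next(p_idx + 1, used, count) # leave unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && abs(pred[p_idx] - truth[j]) <= tol) {
        used[j] <- TRUE
        assign_next(p_idx + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, logical(nt), 0L)
  best
}

# Exact LMG by enumeration over all orderings (p small). Subset R^2 values
# come from plain lm() fits, cached by subset key.
enum_lmg <- function(X, y) {
  X <- as.matrix(X); p <- ncol(X)
  cache <- new.env(parent = emptyenv())
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    key <- paste(sort(cols), collapse = ",")
    if (is.null(cache[[key]]))
      cache[[key]] <- summary(stats::lm(y ~ X[, cols, drop = FALSE]))$r.squared
    cache[[key]]
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  shares <- numeric(p)
  ords <- perms(seq_len(p))
  for (o in ords) {
    for (pos in seq_along(o)) {
      j <- o[pos]
      before <- if (pos == 1) integer(0) else o[seq_len(pos - 1)]
      shares[j] <- shares[j] + r2(c(before, j)) - r2(before)
    }
  }
  shares / length(ords)
}
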