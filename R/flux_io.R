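FP_SENTINEL <- -9999

#' Default ONEFlux/FLUXNET column mapping
#'
#' Maps canonical internal variable names to the column names used by
#' ONEFlux/FLUXNET half-hourly products. Override entries to read files with
#' different headers (e.g. a different NEE quality variant).
#'
#' @param ... named overrides, e.g. `nee = "NEE_CUT_REF"`.
#' @return named list mapping canonical names to file column names.
#' @export
fp_variable_map <- function(...) {
  map <- list(
    timestamp = "TIMESTAMP_START",
    nee       = "NEE_VUT_REF",
    le        = "LE_F_MDS",
    h         = "H_F_MDS",
    tair      = "TA_F_MDS",
    sw_in     = "SW_IN_F_MDS",
    p_tower   = "P",
    p_era     = "P_ERA",
    qc_nee    = "NEE_VUT_REF_QC",
    qc_le     = "LE_F_MDS_QC",
    qc_h      = "H_F_MDS_QC"
  )
  dots <- list(...)
  map[names(dots)] <- dots
  map
}

fp_mandatory_vars <- c("timestamp", "nee", "le", "h", "tair", "sw_in")

#' Read a half-hourly flux-tower table
#'
#' Reads an ONEFlux/FLUXNET-style CSV (comma separated, header row,
#' `TIMESTAMP_START` in `YYYYMMDDHHMM`, -9999 missing-value sentinel) into a
#' validated `flux_table`: a data frame with canonical columns `timestamp`
#' (POSIXct, local standard time), `nee`, `le`, `h`, `tair`, `sw_in`,
#' `p_tower`, `p_era` and the QC flag columns `qc_nee`, `qc_le`, `qc_h`
#' (0 = original measurement, > 0 = gap-filled). NEE keeps the
#' micrometeorological sign convention: positive = flux to the atmosphere.
#'
#' @param path CSV file path.
#' @param variable_map mapping from canonical names to file columns, see
#'   [fp_variable_map()]. Optional variables (`p_tower`, `p_era`, QC flags)
#'   may be absent from the file; mandatory ones must be present.
#' @return a `flux_table` data frame.
#' @export
read_halfhourly <- function(path, variable_map = fp_variable_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (v in fp_mandatory_vars) {
    col <- variable_map[[v]]
    if (is.null(col) || !(col %in% names(raw)))
      stop("mandatory column missing from ", path, ": ", v,
           " (expected file column '", col, "')")
  }
  out <- data.frame(
    timestamp = parse_oneflux_timestamp(raw[[variable_map$timestamp]])
  )
  for (v in setdiff(names(fp_variable_map()), "timestamp")) {
    col <- variable_map[[v]]
    if (!is.null(col) && col %in% names(raw)) {
      x <- as.numeric(raw[[col]])
      x[x == FP_SENTINEL] <- NA_real_
      out[[v]] <- x
    } else {
      out[[v]] <- NA_real_
    }
  }
  validate_flux_table(out)
}

parse_oneflux_timestamp <- function(x) {
  ts <- as.POSIXct(strptime(as.character(x), "%Y%m%d%H%M", tz = "UTC"))
  if (anyNA(ts)) stop("unparseable TIMESTAMP_START value at row ",
                      which(is.na(ts))[1])
  ts
}

#' Validate a half-hourly flux table
#'
#' Checks the `flux_table` invariants: strictly increasing timestamps with
#' exact 30-minute spacing and no duplicates.
#'
#' @param t data frame with at least a `timestamp` column.
#' @return the validated `flux_table` (classed).
#' @export
validate_flux_table <- function(t) {
  stopifnot(is.data.frame(t), "timestamp" %in% names(t))
  d <- diff(as.numeric(t$timestamp))
  if (any(d == 0)) {
    i <- which(d == 0)[1]
    stop("duplicated timestamp: ", format(t$timestamp[i], "%Y-%m-%d %H:%M"))
  }
  if (any(d < 0)) {
    stop("non-monotone timestamps: first offending row index ",
         which(d < 0)[1] + 1L)
  }
  if (any(d != 1800)) {
    stop("timestamps not on a 30-min grid: first gap after row ",
         which(d != 1800)[1])
  }
  class(t) <- unique(c("flux_table", class(t)))
  t
}

#' Write a half-hourly flux table
#'
#' Inverse of [read_halfhourly()]: writes the canonical columns back to an
#' ONEFlux-style CSV with `TIMESTAMP_START` and -9999 sentinels, so a
#' read/write round trip reproduces finite values bit-identically.
#'
#' @param t a `flux_table`.
#' @param path output CSV path.
#' @param variable_map column naming, see [fp_variable_map()].
#' @return `path`, invisibly.
#' @export
write_halfhourly <- function(t, path, variable_map = fp_variable_map()) {
  out <- data.frame(format(t$timestamp, "%Y%m%d%H%M"))
  names(out) <- variable_map$timestamp
  for (v in setdiff(names(fp_variable_map()), "timestamp")) {
    x <- t[[v]]
    x[is.na(x)] <- FP_SENTINEL
    out[[variable_map[[v]]]] <- x
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only original (non-gap-filled) measurements
#'
#' Sets flux values whose QC flag exceeds `qc_max` (default 0, i.e. anything
#' gap-filled) to missing. Row count is never changed and the operation is
#' idempotent. Values whose QC flag is itself missing are treated as
#' non-original and removed.
#'
#' @param t a `flux_table`.
#' @param flux_vars canonical flux variables to filter (must each have a
#'   `qc_<var>` column with at least one non-missing flag).
#' @param qc_max largest QC flag still considered an original measurement.
#' @return the filtered `flux_table`.
#' @export
filter_original <- function(t, flux_vars = c("nee", "le", "h"), qc_max = 0) {
  for (v in flux_vars) {
    qc_col <- paste0("qc_", v)
    if (!(qc_col %in% names(t)) || all(is.na(t[[qc_col]])))
      stop("no QC flag column for variable '", v, "'")
    bad <- is.na(t[[qc_col]]) | t[[qc_col]] > qc_max
    t[[v]][bad] <- NA_real_
  }
  t
}

#' Dryland site qualification
#'
#' Applies the site gate used for pulse analysis: aridity index (P/PET) below
#' `max_aridity` (0.65, the common dryland definition), at least `min_years`
#' years of record (default 4), and a short/sparse-vegetation IGBP class
#' (grasslands, savannas, woody savannas, open and closed shrublands).
#'
#' @param m one-row data frame or list with `aridity_index`,
#'   `years_of_record`, `igbp_class`.
#' @param min_years minimum record length in years.
#' @param max_aridity aridity-index (P/PET) upper bound, exclusive.
#' @param allowed_igbp admissible IGBP classes.
#' @return list with `qualified` (logical) and `reasons` (character vector of
#'   failed criteria; empty when qualified).
#' @export
qualify_site <- function(m, min_years = 4, max_aridity = 0.65,
                         allowed_igbp = c("GRA", "SAV", "OSH", "CSH", "WSA")) {
  reasons <- character(0)
  chk <- function(x) !is.null(x) && length(x) == 1 && !is.na(x)
  if (!chk(m$aridity_index)) reasons <- c(reasons, "aridity missing")
  else if (!(m$aridity_index < max_aridity)) reasons <- c(reasons, "aridity")
  if (!chk(m$years_of_record)) reasons <- c(reasons, "years missing")
  else if (m$years_of_record < min_years) reasons <- c(reasons, "years")
  if (!chk(m$igbp_class)) reasons <- c(reasons, "igbp missing")
  else if (!(as.character(m$igbp_class) %in% allowed_igbp))
    reasons <- c(reasons, "igbp")
  list(qualified = length(reasons) == 0, reasons = reasons)
}

#' Read a site-metadata table
#'
#' One CSV row per site with columns `site_id`, `aridity_index`,
#' `years_of_record`, `igbp_class`, `map_mm`, `mat_c`, `soil_ph`, `clay_pct`,
#' `soc_g_kg`, `annual_gpp`.
#'
#' @param path CSV path.
#' @return data frame of site metadata.
#' @export
read_site_meta <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("site_id" %in% names(m))) stop("site metadata needs a site_id column")
  m
}

#' Aggregate a half-hourly record to daily summaries
#'
#' Produces one row per local calendar day with the daily mean, maximum and
#' 68th/98th percentiles of half-hourly NEE, the night-time mean NEE, the
#' daytime evaporative fraction, total precipitation and the count of valid
#' (non-missing NEE) half hours. Percentiles use the linear-interpolation
#' (type 7) definition throughout. Days with fewer valid half hours than
#' `min_valid` have their NEE aggregates set missing; EF and precipitation
#' are computed from whatever is available.
#'
#' @param t a `flux_table`.
#' @param sw_threshold daytime definition: `sw_in >= sw_threshold` (W m-2).
#' @param night_sw night definition: `sw_in < night_sw` (W m-2).
#' @param min_valid minimum valid NEE half hours for daily NEE aggregates.
#' @return data frame (`daily_table`) with columns `date`, `nee_daily_mean`,
#'   `nee_daily_max`, `nee_p68`, `nee_p98`, `nee_night_mean`, `ef_daytime`,
#'   `p_total`, `n_valid_halfhours`.
#' @export
to_daily <- function(t, sw_threshold = 50, night_sw = 20, min_valid = 10) {
  if (nrow(t) == 0) {
    return(data.frame(date = as.Date(character(0)), nee_daily_mean = numeric(0),
                      nee_daily_max = numeric(0), nee_p68 = numeric(0),
                      nee_p98 = numeric(0), nee_night_mean = numeric(0),
                      ef_daytime = numeric(0), p_total = numeric(0),
                      n_valid_halfhours = integer(0)))
  }
  day <- as.Date(t$timestamp, tz = "UTC")
  idx <- split(seq_len(nrow(t)), day)
  agg <- lapply(idx, function(i) {
    nee <- t$nee[i]
    valid <- sum(!is.na(nee))
    night <- !is.na(t$sw_in[i]) & t$sw_in[i] < night_sw
    data.frame(
      nee_daily_mean = if (valid >= min_valid) mean(nee, na.rm = TRUE) else NA_real_,
      nee_daily_max = if (valid >= min_valid) max(nee, na.rm = TRUE) else NA_real_,
      nee_p68 = if (valid >= min_valid)
        stats::quantile(nee, 0.68, na.rm = TRUE, names = FALSE, type = 7) else NA_real_,
      nee_p98 = if (valid >= min_valid)
        stats::quantile(nee, 0.98, na.rm = TRUE, names = FALSE, type = 7) else NA_real_,
      nee_night_mean = if (any(night & !is.na(nee)))
        mean(nee[night], na.rm = TRUE) else NA_real_,
      ef_daytime = daytime_ef(t$le[i], t$h[i], t$sw_in[i], sw_threshold),
      p_total = if (all(is.na(t$p_era[i]))) NA_real_
                else sum(t$p_era[i], na.rm = TRUE),
      n_valid_halfhours = valid
    )
  })
  out <- do.call(rbind, agg)
  out <- cbind(date = as.Date(names(idx)), out)
  rownames(out) <- NULL
  out
}
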