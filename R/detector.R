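#' Build a per-day feature table for pulse detection
#'
#' One row per site-day with the detection features: daily mean NEE, the
#' daytime EF, the antecedent-window means of NEE and EF (`prepulse_nee`,
#' `prepulse_ef`), the day-over-2-prior-day jumps (`delta_nee`,
#' `delta_ef`), daily precipitation and calendar month. Rolling features
#' use only the current and past days, so a fitted detector never sees the
#' future. Days inside a catalogued event get `label = "pulse"`. Rows whose
#' features are all missing are dropped (count in attribute `n_dropped`).
#'
#' @param daily_by_site named list of daily tables (one per site, from
#'   [to_daily()]), or a single daily table.
#' @param events event catalog with `site_id`, `start_date`, `end_date`;
#'   `NULL` for unlabelled feature rows.
#' @param window_days antecedent window for the prepulse means.
#' @return data frame of feature rows with `site_id`, `date`, the features
#'   and (when `events` given) a `label` factor.
#' @export
build_features <- function(daily_by_site, events = NULL, window_days = 15) {
  if (is.data.frame(daily_by_site)) daily_by_site <- list(site = daily_by_site)
  past_mean <- function(x, from, to) {
    # mean of x[t-from .. t-to] for each t, past-only
    n <- length(x)
    vapply(seq_len(n), function(t) {
      w <- x[max(1, t - from):max(1, min(t - to, n))]
      if (t - to < 1) return(NA_real_)
      if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    }, 1.0)
  }
  rows <- lapply(names(daily_by_site), function(sid) {
    d <- daily_by_site[[sid]]
    nee <- d$nee_daily_mean; ef <- d$ef_daytime
    out <- data.frame(
      site_id = sid, date = d$date,
      nee_daily_mean = nee,
      ef = ef,
      prepulse_nee = past_mean(nee, window_days, 1),
      prepulse_ef = past_mean(ef, window_days, 1),
      delta_nee = nee - past_mean(nee, 2, 1),
      delta_ef = ef - past_mean(ef, 2, 1),
      p_era_daily = d$p_total,
      month = as.integer(format(d$date, "%m")),
      stringsAsFactors = FALSE)
    out
  })
  feat <- do.call(rbind, rows)
  fcols <- detector_feature_names()
  all_missing <- rowSums(!is.na(feat[fcols])) == 0
  feat <- feat[!all_missing, , drop = FALSE]
  if (!is.null(events)) {
    feat$label <- factor("nonpulse", levels = c("nonpulse", "pulse"))
    for (r in seq_len(nrow(events))) {
      hit <- feat$site_id == events$site_id[r] &
        feat$date >= as.Date(events$start_date[r]) &
        feat$date <= as.Date(events$end_date[r])
      feat$label[hit] <- "pulse"
    }
  }
  attr(feat, "n_dropped") <- sum(all_missing)
  rownames(feat) <- NULL
  feat
}

detector_feature_names <- function() {
  c("nee_daily_mean", "ef", "prepulse_nee", "prepulse_ef",
    "delta_nee", "delta_ef", "p_era_daily", "month")
}

#' Train/validation/test split for the detector
#'
#' Keeps sites with at least `min_years` of data and `min_events`
#' catalogued events; per site the last `test_years` calendar years form
#' the test set and the remaining rows are split at random into training
#' and validation at `1 - val_frac` : `val_frac` under a fixed seed. A
#' qualifying site with no calendar year left for training is dropped with
#' a warning.
#'
#' @param features labelled feature table from [build_features()].
#' @param events the event catalog (for the per-site event counts).
#' @param min_years,min_events site-qualification gates.
#' @param test_years length of the per-site test tail (calendar years).
#' @param val_frac validation fraction of the non-test rows.
#' @param seed RNG seed for the random split.
#' @return list of data frames `train`, `val`, `test`, plus
#'   `sites` (qualifying site ids).
#' @export
split_sites <- function(features, events, min_years = 5, min_events = 20,
                        test_years = 3, val_frac = 0.2, seed = 1) {
  keep <- character(0)
  for (sid in unique(features$site_id)) {
    d <- features$date[features$site_id == sid]
    yrs <- length(unique(format(d, "%Y")))
    nev <- sum(events$site_id == sid)
    if (yrs >= min_years && nev >= min_events) keep <- c(keep, sid)
  }
  if (!length(keep)) stop("no site passes the detector qualification gate")
  test_idx <- logical(nrow(features))
  drop_sites <- character(0)
  for (sid in keep) {
    in_site <- features$site_id == sid
    yrs <- sort(unique(as.integer(format(features$date[in_site], "%Y"))))
    test_y <- utils::tail(yrs, test_years)
    if (length(yrs) <= test_years) {
      drop_sites <- c(drop_sites, sid)
      next
    }
    test_idx <- test_idx | (in_site &
      as.integer(format(features$date, "%Y")) %in% test_y)
  }
  if (length(drop_sites)) {
    warning("sites dropped (no training year left after the test tail): ",
            paste(drop_sites, collapse = ", "))
    keep <- setdiff(keep, drop_sites)
  }
  in_keep <- features$site_id %in% keep
  rest <- which(in_keep & !test_idx)
  set.seed(seed)
  val_rows <- sample(rest, size = round(val_frac * length(rest)))
  list(train = features[setdiff(rest, val_rows), , drop = FALSE],
       val = features[val_rows, , drop = FALSE],
       test = features[in_keep & test_idx, , drop = FALSE],
       sites = keep)
}

#' Train the random-forest pulse detector
#'
#' Binary random-forest classification of site-days into pulse /
#' non-pulse, with balanced class weights to counter the strong class
#' imbalance (pulse days are rare). Rows with missing feature values are
#' dropped for training. Gini (impurity-reduction) feature importances are
#' normalized to sum to 1.
#'
#' @param train labelled feature rows.
#' @param num_trees forest size.
#' @param mtry variables per split (`NULL` = ranger default).
#' @param seed RNG seed (fixed seed gives identical forests and
#'   importances).
#' @param class_weights `"balanced"` (inverse class frequency) or a named
#'   numeric vector.
#' @return object of class `pulse_detector`: list with the `ranger` model,
#'   `features` (names) and normalized `importance`.
#' @export
train_forest <- function(train, num_trees = 500, mtry = NULL, seed = 1,
                         class_weights = "balanced") {
  fcols <- detector_feature_names()
  cc <- stats::complete.cases(train[fcols])
  d <- train[cc, c(fcols, "label")]
  tab <- table(d$label)
  if (any(tab == 0)) stop("training set has a single class")
  w <- if (identical(class_weights, "balanced"))
    as.numeric(sum(tab) / (2 * tab)) else as.numeric(class_weights[names(tab)])
  names(w) <- names(tab)
  model <- ranger::ranger(
    label ~ ., data = d, num.trees = num_trees, mtry = mtry,
    importance = "impurity", class.weights = w, seed = seed,
    probability = FALSE)
  imp <- model$variable.importance
  structure(list(model = model, features = fcols,
                 importance = imp / sum(imp)),
            class = "pulse_detector")
}

#' Predict per-day pulse labels
#'
#' @param object a `pulse_detector`.
#' @param newdata feature rows; rows with missing features are predicted
#'   non-pulse.
#' @param ... unused.
#' @return factor of predicted labels aligned to `newdata`.
#' @export
predict.pulse_detector <- function(object, newdata, ...) {
  out <- factor(rep("nonpulse", nrow(newdata)),
                levels = c("nonpulse", "pulse"))
  cc <- stats::complete.cases(newdata[object$features])
  if (any(cc)) {
    pr <- stats::predict(object$model,
                         data = newdata[cc, object$features])$predictions
    out[cc] <- pr
  }
  out
}

#' Reconstruct predicted events from day labels
#'
#' Maximal runs of at least 2 consecutive pulse-labelled days become
#' predicted events (start = first day of the run); runs separated by a
#' single non-pulse day are merged when `merge_gap = 1`.
#'
#' @param labels per-day labels (`"pulse"`/`"nonpulse"` factor or logical).
#' @param dates the matching `Date` vector (one site, increasing).
#' @param min_run minimum run length in days.
#' @param merge_gap merge runs separated by up to this many non-pulse days.
#' @return data frame with `start_date`, `end_date` per predicted event.
#' @export
reconstruct_events <- function(labels, dates, min_run = 2, merge_gap = 1) {
  is_pulse <- if (is.logical(labels)) labels else labels == "pulse"
  is_pulse[is.na(is_pulse)] <- FALSE
  r <- rle(is_pulse)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(runs)) return(data.frame(start_date = as.Date(character(0)),
                                     end_date = as.Date(character(0))))
  if (merge_gap > 0 && nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap_days <- as.numeric(dates[runs$start[i]] -
                               dates[merged$end[nrow(merged)]]) - 1
      if (gap_days <= merge_gap)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  len <- as.numeric(dates[runs$end] - dates[runs$start]) + 1
  runs <- runs[len >= min_run, , drop = FALSE]
  data.frame(start_date = dates[runs$start], end_date = dates[runs$end])
}

#' Score event detection against a reference catalog
#'
#' One-to-one start-date matching within `tolerance` days: true starts are
#' taken in chronological order and each matches the earliest unmatched
#' predicted start inside its tolerance window. Because every tolerance
#' window has the same width, this greedy scheme attains the maximum
#' one-to-one matching (the bipartite graph is convex), so the scores are
#' order-invariant and agree with brute-force optimal matching. Precision
#' is TP / (TP + FP); recall is TP / (TP + FN). With true event sizes
#' supplied, recall is additionally binned by pulse size (bins of width
#' `bin_width` umol CO2 m-2 s-1 spanning `bin_range`).
#'
#' @param predicted_starts `Date` vector of predicted event starts.
#' @param true_starts `Date` vector of reference starts.
#' @param tolerance matching tolerance in days.
#' @param true_sizes optional event sizes aligned to `true_starts`.
#' @param bin_width,bin_range size-bin layout.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`, `matched`
#'   (logical per true event) and, when sizes are given, `recall_by_size`
#'   (data frame with bin edges, n and recall).
#' @export
score_detection <- function(predicted_starts, true_starts, tolerance = 2,
                            true_sizes = NULL, bin_width = 5,
                            bin_range = c(-20, 20)) {
  predicted_starts <- sort(as.Date(predicted_starts))
  ord <- order(as.Date(true_starts))
  true_starts <- as.Date(true_starts)[ord]
  if (!is.null(true_sizes)) true_sizes <- true_sizes[ord]
  matched <- logical(length(true_starts))
  pred_used <- logical(length(predicted_starts))
  tp <- 0L
  for (j in seq_along(true_starts)) {
    d <- as.numeric(predicted_starts - true_starts[j])
    cand <- which(!pred_used & abs(d) <= tolerance)
    if (length(cand)) {
      matched[j] <- TRUE
      pred_used[cand[1]] <- TRUE # earliest available prediction
      tp <- tp + 1L
    }
  }
  fp <- length(predicted_starts) - tp
  fn <- sum(!matched)
  precision <- if (length(predicted_starts)) tp / (tp + fp) else NA_real_
  recall <- if (length(true_starts)) tp / (tp + fn) else NA_real_
  out <- list(precision = precision, recall = recall, tp = tp, fp = fp,
              fn = fn, matched = matched)
  if (!is.null(true_sizes)) {
    edges <- seq(bin_range[1], bin_range[2], by = bin_width)
    bin <- cut(true_sizes, edges, include.lowest = TRUE, right = FALSE)
    out$recall_by_size <- do.call(rbind, lapply(levels(bin), function(b) {
      in_b <- !is.na(bin) & bin == b
      data.frame(bin = b, n = sum(in_b),
                 recall = if (any(in_b)) mean(matched[in_b]) else NA_real_)
    }))
  }
  out
}

#' Persist and restore a trained detector
#'
#' The forest is written with [saveRDS()] next to a JSON sidecar recording
#' the feature names, hyperparameters and seed.
#'
#' @param object a `pulse_detector`.
#' @param path `.rds` path for the model (sidecar gets `.json`).
#' @export
save_detector <- function(object, path) {
  saveRDS(object, path)
  sidecar <- list(features = object$features,
                  num_trees = object$model$num.trees,
                  mtry = object$model$mtry,
                  importance = as.list(object$importance))
  jsonlite::write_json(sidecar, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @param path `.rds` path written by [save_detector()].
#' @export
load_detector <- function(path) readRDS(path)
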