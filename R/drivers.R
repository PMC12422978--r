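# R^2 of the regression of standardized y on the predictor subset S,
# computed from the correlation matrix.
subset_r2 <- function(Rxx, rxy, S) {
  if (!length(S)) return(0)
  b <- solve(Rxx[S, S, drop = FALSE], rxy[S])
  sum(b * rxy[S])
}

#' LMG relative importance decomposition
#'
#' Decomposes the R-squared of a linear regression over its predictors by
#' the Lindeman-Merenda-Gold method: each predictor's share is its
#' incremental R-squared averaged over all p! orderings of predictor entry,
#' which is robust to multicollinearity. Computed exactly via the 2^p
#' subset decomposition (each subset's R-squared weighted by
#' `s!(p-s-1)!/p!`), so it is exact and fast for the p <= 15 designs used
#' for site-level drivers. Shares are nonnegative up to numerical error and
#' sum to the full-model R-squared. Predictors are standardized internally;
#' shares are invariant to that.
#'
#' @param X numeric predictor matrix or data frame (n sites x p).
#' @param y numeric response (e.g. site pulse intensity `alpha_s` or decay
#'   rate `k_s`).
#' @return object of class `lmg_importance`: list with `shares` (named, sum
#'   = `total_r2`), `total_r2`, `n`, `p`.
#' @export
lmg_importance <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (n <= p + 1) stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X)
  qrz <- qr(Z)
  if (qrz$rank < p) {
    dep <- colnames(X)[-qrz$pivot[seq_len(qrz$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  Rxx <- stats::cor(X)
  rxy <- as.numeric(stats::cor(X, y))
  # weight of a subset of size s when adding one more predictor
  wt <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) -
              lfactorial(p))
  shares <- numeric(p)
  subsets <- 0:(2^p - 1)
  bits <- matrix(vapply(subsets,
                        function(s) as.logical(bitwAnd(s, 2^(0:(p - 1)))),
                        logical(p)), nrow = p)
  r2 <- vapply(subsets + 1L, function(i) {
    subset_r2(Rxx, rxy, which(bits[, i]))
  }, 1.0)
  for (j in seq_len(p)) {
    without_j <- which(!bits[j, ])
    for (i in without_j) {
      S <- bits[, i]
      with_j <- i + 2^(j - 1)
      shares[j] <- shares[j] + wt[sum(S) + 1] * (r2[with_j] - r2[i])
    }
  }
  names(shares) <- colnames(X)
  structure(list(shares = shares, total_r2 = r2[2^p], n = n, p = p),
            class = "lmg_importance")
}

#' @export
print.lmg_importance <- function(x, ...) {
  cat("LMG relative importance (total R^2 =", round(x$total_r2, 4), ")\n")
  print(round(sort(x$shares, decreasing = TRUE), 4))
  invisible(x)
}

#' Bootstrap spread of LMG shares
#'
#' Resamples sites with replacement (`n_boot` draws, default 100),
#' recomputes the LMG decomposition on each draw, and reports the
#' per-predictor standard deviation. Rank-deficient draws are redrawn (up
#' to 10 retries each) and counted.
#'
#' @param X,y as in [lmg_importance()].
#' @param n_boot bootstrap draws.
#' @param seed RNG seed.
#' @return list with `sd` (named per-predictor), `n_boot`, `n_redrawn`.
#' @export
bootstrap_importance <- function(X, y, n_boot = 100, seed = 1) {
  X <- as.matrix(X)
  set.seed(seed)
  n <- nrow(X)
  redrawn <- 0L
  draws <- matrix(NA_real_, n_boot, ncol(X))
  for (b in seq_len(n_boot)) {
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(lmg_importance(X[idx, , drop = FALSE], y[idx]),
                      error = function(e) NULL)
      if (!is.null(res)) break
      redrawn <- redrawn + 1L
    }
    if (is.null(res)) stop("bootstrap draw ", b, " rank-deficient after 10 retries")
    draws[b, ] <- res$shares
  }
  list(sd = stats::setNames(apply(draws, 2, stats::sd), colnames(X)),
       n_boot = n_boot, n_redrawn = redrawn)
}

#' Partial-dependence curve
#'
#' Mean model prediction over the data with one feature fixed to each grid
#' value in turn, marginalizing over the joint distribution of the other
#' features (so confounding between predictors is accounted for without
#' assuming linearity). Works with any fitted model through `predict_fun`.
#'
#' @param model fitted model (e.g. `lm`, `ranger`, or a random-forest
#'   regressor fitted to the site table).
#' @param data data frame the model was fitted on.
#' @param feature feature name to vary.
#' @param grid grid values; default 25 points across the observed range.
#' @param predict_fun function `(model, data) -> numeric`; default handles
#'   `lm`-likes and `ranger`.
#' @return data frame with `grid`, `pd` and logical `extrapolated` (grid
#'   value outside the observed range).
#' @export
partial_dependence <- function(model, data, feature, grid = NULL,
                               predict_fun = NULL) {
  obs <- data[[feature]]
  if (is.null(grid))
    grid <- seq(min(obs, na.rm = TRUE), max(obs, na.rm = TRUE), length.out = 25)
  if (is.null(predict_fun)) {
    predict_fun <- function(m, d) {
      if (inherits(m, "ranger")) stats::predict(m, data = d)$predictions
      else as.numeric(stats::predict(m, newdata = d))
    }
  }
  pd <- vapply(grid, function(g) {
    d <- data
    d[[feature]] <- g
    mean(predict_fun(model, d), na.rm = TRUE)
  }, 1.0)
  data.frame(grid = grid, pd = pd,
             extrapolated = grid < min(obs, na.rm = TRUE) |
               grid > max(obs, na.rm = TRUE))
}
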