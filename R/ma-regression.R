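#' Model II major-axis regression
#'
#' Fits the major axis (the first principal axis of the joint scatter) of
#' `y` on `x`, appropriate when both variables are measured in the same
#' units and both are subject to error. The slope is
#' `(s_yy - s_xx + sqrt((s_yy - s_xx)^2 + 4 s_xy^2)) / (2 s_xy)`, the
#' intercept passes the axis through the means, and `r` is the Pearson
#' correlation. Confidence intervals come from the classical major-axis
#' angle bound (a t/F-quantile on the rotation angle that decorrelates the
#' data; see [ma_confidence()]); the permutation test permutes `y` against
#' `x` and compares `|r|` ([permutation_test()]). The fit also reports
#' whether the axis departs from the 1:1 identity line (slope CI excluding 1
#' or intercept CI excluding 0).
#'
#' @param x,y Numeric vectors (current and future index values across
#'   parks/species), length >= 3, neither constant.
#' @param alpha Confidence level is `1 - alpha`.
#' @param n_perm Number of permutations (0 skips the test; needs n >= 5).
#' @param seed Optional integer seed for the permutation test.
#' @return Object of class `ma_fit` with elements `slope`, `intercept`, `r`,
#'   `slope_ci`, `intercept_ci`, `p_perm`, `n_perm`,
#'   `departs_from_identity`, `n`, `means`, `data`.
#' @examples
#' fit <- ma_fit(1:10, 2 * (1:10), n_perm = 99, seed = 1)
#' coef(fit)
#' @export
ma_fit <- function(x, y, alpha = 0.05, n_perm = 999L, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop("x and y must be finite")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  sxx <- stats::var(x)
  syy <- stats::var(y)
  sxy <- stats::cov(x, y)
  if (sxx == 0 || syy == 0) stop("x and y must not be constant")
  if (sxy == 0 && sxx == syy)
    stop("major axis undefined: zero covariance with equal variances")
  slope <- if (sxy == 0) {
    if (syy > sxx) Inf else 0
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  mx <- mean(x)
  my <- mean(y)
  intercept <- if (is.finite(slope)) my - slope * mx else NA_real_
  r <- stats::cor(x, y)
  ci <- ma_confidence(x, y, slope, alpha = alpha)
  p_perm <- if (n_perm > 0 && n >= 5)
    permutation_test(x, y, n_perm = n_perm, seed = seed) else NA_real_
  departs <- isTRUE(ci$slope_ci[1] > 1 || ci$slope_ci[2] < 1 ||
                      ci$intercept_ci[1] > 0 || ci$intercept_ci[2] < 0)
  structure(list(slope = slope, intercept = intercept, r = r,
                 slope_ci = ci$slope_ci, intercept_ci = ci$intercept_ci,
                 alpha = alpha, p_perm = p_perm,
                 n_perm = if (is.na(p_perm)) 0L else as.integer(n_perm),
                 departs_from_identity = departs, n = n,
                 means = c(x = mx, y = my), data = list(x = x, y = y),
                 call = match.call()),
            class = "ma_fit")
}

#' Confidence intervals for a major-axis fit
#'
#' The slope CI uses the angle formulation: with covariance eigenvalues
#' `l1 >= l2`, `H = F(1 - alpha; 1, n - 2) / ((l1/l2 + l2/l1 - 2) (n-2) / 4)`
#' and the slope limits are `tan(atan(slope) +/- 0.5 asin(sqrt(H)))`. When
#' `H >= 1` the data do not constrain the axis direction at this level and
#' the interval is unbounded. A perfect fit (`l2 = 0`) gives zero-width
#' intervals. The intercept CI is propagated through the means.
#'
#' @param x,y The data.
#' @param fit An `ma_fit` object or the fitted slope.
#' @param alpha Significance level.
#' @return List with `slope_ci` and `intercept_ci` (each `c(low, high)`).
#' @export
ma_confidence <- function(x, y, fit, alpha = 0.05) {
  slope <- if (inherits(fit, "ma_fit")) fit$slope else fit
  n <- length(x)
  S <- stats::cov(cbind(x, y))
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  mx <- mean(x)
  my <- mean(y)
  if (lam[2] <= lam[1] * 1e-12) {  # perfect linear relation
    slope_ci <- c(slope, slope)
    intercept_ci <- rep(my - slope * mx, 2)
    return(list(slope_ci = slope_ci, intercept_ci = intercept_ci))
  }
  H <- stats::qf(1 - alpha, 1, n - 2) /
    ((lam[1] / lam[2] + lam[2] / lam[1] - 2) * (n - 2) / 4)
  if (H >= 1)
    return(list(slope_ci = c(-Inf, Inf), intercept_ci = c(-Inf, Inf)))
  phi <- 0.5 * asin(sqrt(H))
  theta <- atan(slope)
  lo <- if (theta - phi <= -pi / 2) -Inf else tan(theta - phi)
  hi <- if (theta + phi >= pi / 2) Inf else tan(theta + phi)
  slope_ci <- c(lo, hi)
  intercept_ci <- if (mx == 0) rep(my, 2) else sort(my - slope_ci * mx)
  list(slope_ci = slope_ci, intercept_ci = intercept_ci)
}

#' Permutation test of association for the major-axis comparison
#'
#' Permutes `y` against `x` `n_perm` times and compares the absolute Pearson
#' correlation with the observed one;
#' `p = (1 + #permuted |r| >= observed |r|) / (n_perm + 1)`. Two-tailed on
#' `|r|`; the smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param x,y Numeric vectors, length >= 5.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return Permutation p-value in (0, 1].
#' @export
permutation_test <- function(x, y, n_perm = 999L, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 5) stop("need at least 5 observations")
  if (!is.null(seed)) set.seed(seed)
  robs <- abs(stats::cor(x, y))
  xc <- x - mean(x)
  denom_x <- sqrt(sum(xc^2))
  yc <- y - mean(y)
  denom_y <- sqrt(sum(yc^2))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    rp <- abs(sum(xc * sample(yc)) / (denom_x * denom_y))
    if (rp >= robs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' @export
print.ma_fit <- function(x, digits = 4, ...) {
  cat("Model II major-axis regression (n =", x$n, ")\n")
  cat(sprintf("  slope     %s  [%s, %s]\n",
              format(x$slope, digits = digits),
              format(x$slope_ci[1], digits = digits),
              format(x$slope_ci[2], digits = digits)))
  cat(sprintf("  intercept %s  [%s, %s]\n",
              format(x$intercept, digits = digits),
              format(x$intercept_ci[1], digits = digits),
              format(x$intercept_ci[2], digits = digits)))
  cat(sprintf("  r = %s", format(x$r, digits = digits)))
  if (!is.na(x$p_perm))
    cat(sprintf(", permutation p = %s (%d permutations)",
                format(x$p_perm, digits = digits), x$n_perm))
  cat("\n  departs from 1:1 line:",
      if (x$departs_from_identity) "yes" else "no", "\n")
  invisible(x)
}

#' @export
summary.ma_fit <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
coef.ma_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.ma_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$data$x else
    if (is.list(newdata)) newdata$x else newdata
  object$intercept + object$slope * xv
}

#' @export
fitted.ma_fit <- function(object, ...) predict(object)

#' @export
residuals.ma_fit <- function(object, ...) object$data$y - fitted(object)

#' @export
confint.ma_fit <- function(object, parm = c("slope", "intercept"),
                           level = NULL, ...) {
  if (!is.null(level) && abs((1 - level) - object$alpha) > 1e-12)
    return(ma_confidence(object$data$x, object$data$y, object,
                         alpha = 1 - level)[paste0(parm, "_ci")])
  out <- rbind(slope = object$slope_ci, intercept = object$intercept_ci)
  out[parm, , drop = FALSE]
}

#' @export
plot.ma_fit <- function(x, xlab = "current", ylab = "future", ...) {
  graphics::plot(x$data$x, x$data$y, xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, 1, lty = 2)
  if (is.finite(x$slope)) graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}

#' Major-axis regression table for future vs current index values
#'
#' One fit per index x season, shaped like the headline regression table:
#' slope and intercept with confidence limits, correlation, permutation p
#' and the 1:1-departure flag. Rows with fewer than 3 pairs or a degenerate
#' fit are reported with `NA` estimates and a warning.
#'
#' @param values Data frame with columns `index`, `season`, `current`,
#'   `future` (one row per park or species).
#' @param n_perm Permutations per test.
#' @param alpha Significance level.
#' @param seed Base seed; each fit uses `seed + i` for reproducibility.
#' @return Data frame, one row per index x season.
#' @export
ma_regression_table <- function(values, n_perm = 999L, alpha = 0.05,
                                seed = 1L) {
  combos <- unique(values[c("index", "season")])
  combos <- combos[order(combos$index, combos$season), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    g <- values[values$index == combos$index[i] &
                  values$season == combos$season[i], , drop = FALSE]
    g <- g[is.finite(g$current) & is.finite(g$future), , drop = FALSE]
    fit <- tryCatch(
      ma_fit(g$current, g$future, alpha = alpha, n_perm = n_perm,
             seed = seed + i),
      error = function(e) {
        warning("MA fit failed for ", combos$index[i], "/",
                combos$season[i], ": ", conditionMessage(e))
        NULL
      })
    rows[[i]] <- data.frame(
      index = combos$index[i], season = combos$season[i],
      n = nrow(g),
      slope = if (is.null(fit)) NA_real_ else fit$slope,
      slope_lo = if (is.null(fit)) NA_real_ else fit$slope_ci[1],
      slope_hi = if (is.null(fit)) NA_real_ else fit$slope_ci[2],
      intercept = if (is.null(fit)) NA_real_ else fit$intercept,
      intercept_lo = if (is.null(fit)) NA_real_ else fit$intercept_ci[1],
      intercept_hi = if (is.null(fit)) NA_real_ else fit$intercept_ci[2],
      r = if (is.null(fit)) NA_real_ else fit$r,
      p_perm = if (is.null(fit)) NA_real_ else fit$p_perm,
      departs_from_identity = if (is.null(fit)) NA else
        fit$departs_from_identity,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
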