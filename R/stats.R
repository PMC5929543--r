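#' No-intercept regression with R-squared and the L-squared identity metric
#'
#' Validation of automatic against reference (e.g. manual expert) counts uses
#' simple linear regression without the intercept term, `y = kx`: in the
#' absence of cells both counts must be zero, so no systematic shift term is
#' allowed. The least-squares slope is `k = sum(x*y) / sum(x^2)`.
#'
#' Two goodness measures are reported. `R^2 = 1 - SS_res / SS_tot` with
#' `SS_res = sum((y - f)^2)`, `SS_tot = sum((y - mean(y))^2)` and fitted
#' points `f = k*x`, measures how well the data follow the fitted line.
#' `L^2 = 1 - sum((f - x)^2) / SS_tot` measures how close the *fitted line*
#' is to the ideal identity line `y = x`: it equals 1 exactly when `k = 1`.
#'
#' Neither coefficient is clamped: despite the usual description of both as
#' ranging over \[0, 1\], the formulas can produce negative values (a fitted
#' line far from the identity makes `L^2` arbitrarily negative), and raw
#' values are reported.
#'
#' @param x Reference (abscissa) values, e.g. manual counts.
#' @param y Estimated (ordinate) values, same length, `n >= 2`.
#' @return Object of class `origin_fit` with fields `k`, `x`, `y`, `fitted`,
#'   `y_bar`, `f_bar`, `ss_tot`, `ss_res_r2`, `ss_res_l2`, `r2`, `l2`, `n`.
#'   `r2`/`l2` are `NA` when `ss_tot = 0` (degenerate ordinate variance).
#' @examples
#' fit <- fit_no_intercept(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' coef(fit)
#' summary(fit)
#' @export
fit_no_intercept <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 paired points")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  sxx <- sum(x^2)
  if (sxx == 0) stop("degenerate abscissa: all x are zero, slope undefined")
  k <- sum(x * y) / sxx
  fitted <- k * x
  y_bar <- mean(y)
  f_bar <- mean(fitted)
  ss_tot <- sum((y - y_bar)^2)
  ss_res_r2 <- sum((y - fitted)^2)
  ss_res_l2 <- sum((fitted - x)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res_r2 / ss_tot else NA_real_
  l2 <- if (ss_tot > 0) 1 - ss_res_l2 / ss_tot else NA_real_
  structure(list(k = k, x = x, y = y, fitted = fitted, y_bar = y_bar,
                 f_bar = f_bar, ss_tot = ss_tot, ss_res_r2 = ss_res_r2,
                 ss_res_l2 = ss_res_l2, r2 = r2, l2 = l2, n = length(x)),
            class = "origin_fit")
}

#' Regress estimated counts on a reference
#'
#' Convenience wrapper for validation harnesses: fits
#' `estimates = k * reference` through the origin.
#'
#' @param estimates Estimated per-image values (ordinate).
#' @param reference Reference per-image values (abscissa), same length.
#' @return An `origin_fit`; see [fit_no_intercept()].
#' @export
compare_to_reference <- function(estimates, reference) {
  fit_no_intercept(x = reference, y = estimates)
}

#' @export
coef.origin_fit <- function(object, ...) c(k = object$k)

#' @export
residuals.origin_fit <- function(object, ...) object$y - object$fitted

#' @export
predict.origin_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$k * x
}

#' @export
print.origin_fit <- function(x, digits = 4, ...) {
  cat("No-intercept regression y = k * x\n")
  cat(sprintf("  k  = %s  (n = %d)\n", format(x$k, digits = digits), x$n))
  cat(sprintf("  R2 = %s   L2 = %s\n", format(x$r2, digits = digits),
              format(x$l2, digits = digits)))
  invisible(x)
}

#' @export
summary.origin_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.origin_fit")
}

#' @export
print.summary.origin_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  SS_tot = %g, SS_res(R2) = %g, SS_res(L2) = %g\n",
              f$ss_tot, f$ss_res_r2, f$ss_res_l2))
  cat(sprintf("  residual range [%g, %g]\n", min(f$y - f$fitted),
              max(f$y - f$fitted)))
  if (!is.na(f$l2) && f$l2 < 0)
    cat("  note: L2 < 0 - the fitted line deviates strongly from y = x\n")
  invisible(x)
}

#' @export
plot.origin_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "reference count",
                 ylab = "estimated count", ...)
  graphics::abline(0, x$k, lwd = 2)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft",
                   legend = c(sprintf("fit y = %.3f x", x$k), "ideal y = x"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  invisible(x)
}
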