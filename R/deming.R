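#' Deming (errors-in-variables) regression
#'
#' Fits a straight line allowing for measurement error in both variables.
#' With delta the ratio of the y-error variance to the x-error variance,
#' the closed-form slope is
#'
#'   b = (s_yy - delta * s_xx + sqrt((s_yy - delta * s_xx)^2 +
#'        4 * delta * s_xy^2)) / (2 * s_xy)
#'
#' and the intercept is `mean(y) - b * mean(x)`. `delta = 1` gives
#' orthogonal regression. Unlike ordinary least squares of y on x, the
#' slope is not attenuated by noise in x.
#'
#' @param data A data frame.
#' @param x,y Column names (strings) of the predictor-like and
#'   response-like variables.
#' @param variance_ratio delta, the assumed y/x error-variance ratio
#'   (default 1).
#' @return An object of class `deming_fit` with elements `slope`,
#'   `intercept`, `variance_ratio`, `n`. Has [tidy()] and [glance()]
#'   methods.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' deming_regression(d, "x", "y")
#' @export
deming_regression <- function(data, x, y, variance_ratio = 1) {
  xv <- data[[x]]
  yv <- data[[y]]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3) {
    abort("Deming regression needs at least 3 complete points",
          class = "parattc_validation_error")
  }
  s_xx <- var(xv)
  s_yy <- var(yv)
  s_xy <- stats::cov(xv, yv)
  if (s_xx == 0) {
    abort("no variance in x", class = "parattc_validation_error")
  }
  if (s_xy == 0) {
    abort("x and y are uncorrelated; Deming slope undefined",
          class = "parattc_undefined_slope_error")
  }
  delta <- variance_ratio
  slope <- (s_yy - delta * s_xx +
              sqrt((s_yy - delta * s_xx)^2 + 4 * delta * s_xy^2)) /
    (2 * s_xy)
  structure(
    list(
      slope = slope,
      intercept = mean(yv) - slope * mean(xv),
      variance_ratio = delta,
      n = length(xv)
    ),
    class = "deming_fit"
  )
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "Deming regression (delta = %g, n = %d)\n  slope: %.4f  intercept: %.4f\n",
    x$variance_ratio, x$n, x$slope, x$intercept
  ))
  invisible(x)
}

#' @rdname deming_regression
#' @param x A `deming_fit` object.
#' @param ... Unused.
#' @method tidy deming_fit
#' @export
tidy.deming_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname deming_regression
#' @method glance deming_fit
#' @export
glance.deming_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    variance_ratio = x$variance_ratio,
    nobs = x$n
  )
}
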