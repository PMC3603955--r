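#' Scaling-law fit objects
#'
#' Container for a fitted scaling exponent: a least-squares fit on log-log
#' (power law) or semi-log (exponential) axes, carrying the exponent
#' magnitude, its standard error, and the points used.
#'
#' @param exponent Fitted exponent magnitude.
#' @param stderr Standard error of the exponent.
#' @param points Tibble of the (x, y) pairs used.
#' @param model `"powerlaw"` or `"exponential"`.
#' @param quantity Short label of what the exponent measures (e.g. `"d_B"`).
#' @param extra Named list of auxiliary values (e.g. `k0`, `gamma_pred`).
#' @return An object of class `scaling_fit`.
#' @keywords internal
new_scaling_fit <- function(exponent, stderr, points, model, quantity,
                            extra = list()) {
  stopifnot(model %in% c("powerlaw", "exponential"))
  structure(
    list(exponent = exponent, stderr = stderr,
         points = tibble::as_tibble(points), model = model,
         quantity = quantity, extra = extra),
    class = "scaling_fit"
  )
}

# unweighted least squares of y on x; returns slope, stderr, r2
ls_slope <- function(x, y) {
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(
    slope = unname(coef(fit)[2]),
    stderr = unname(sm$coefficients[2, 2]),
    r2 = sm$r.squared,
    intercept = unname(coef(fit)[1])
  )
}

# log-log power-law fit: y ~ x^(sign * exponent); exponent reported positive
fit_power_scaling <- function(x, y, quantity, sign = -1) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 3) {
    abort(sprintf("need >= 3 usable points to fit %s (got %d)",
                  quantity, sum(ok)))
  }
  f <- ls_slope(log(x[ok]), log(y[ok]))
  new_scaling_fit(
    exponent = sign * f$slope, stderr = f$stderr,
    points = tibble::tibble(x = x[ok], y = y[ok]),
    model = "powerlaw", quantity = quantity,
    extra = list(r_squared = f$r2, raw_slope = f$slope)
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s = %.4g (se %.3g, %s, %d points)\n",
              x$quantity, x$exponent, x$stderr, x$model,
              nrow(x$points)))
  invisible(x)
}

#' @rdname new_scaling_fit
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(
    term = x$quantity,
    estimate = x$exponent,
    std.error = x$stderr,
    model = x$model
  )
}

#' @rdname new_scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(
    quantity = x$quantity,
    exponent = x$exponent,
    stderr = x$stderr,
    model = x$model,
    n_points = nrow(x$points),
    r.squared = x$extra$r_squared %||% NA_real_
  )
}

#' @rdname new_scaling_fit
#' @param object A `scaling_fit`.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$points, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s = %.3g ± %.2g", object$quantity,
                      object$exponent, object$stderr)
    )
  if (object$model == "powerlaw") {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  } else {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}
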