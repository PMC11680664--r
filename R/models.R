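#' The five retention function families
#'
#' Character vector of the five two-parameter families used throughout the
#' package, in their canonical reporting order (the four classic curvilinear
#' loss functions, then linear). The order is also the documented tie-break
#' order in [best_fit()].
#'
#' Each family maps a retention delay `t` (seconds) to a proportion
#' remembered `M` via a scale parameter `a` and a rate parameter `b`:
#'
#' * `logarithmic`: `M = a - b * ln(t)`
#' * `power`: `M = a * t^b`
#' * `exponential_power`: `M = a * exp(-b * sqrt(t))`
#' * `hyperbolic_power`: `M = 1 / (a + b * sqrt(t))`
#' * `linear`: `M = b * t + a`
#'
#' @format Character vector of length 5.
#' @export
retention_families <- c(
  "logarithmic", "power", "exponential_power", "hyperbolic_power", "linear"
)

#' Construct a retention curve
#'
#' A retention curve is a function family together with its scale parameter
#' `a` and rate parameter `b`. For all families except `hyperbolic_power`,
#' `a` lives on the proportion-correct scale; for `hyperbolic_power` it is an
#' intercept on the reciprocal scale.
#'
#' @param family One of [retention_families].
#' @param a Scale parameter (finite numeric scalar).
#' @param b Rate parameter (finite numeric scalar).
#' @return An object of class `retention_curve`.
#' @examples
#' retention_curve("power", a = 0.8, b = -0.2)
#' @export
retention_curve <- function(family, a, b) {
  family <- match.arg(family, retention_families)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a)) {
    stop("`a` must be a finite numeric scalar", call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b)) {
    stop("`b` must be a finite numeric scalar", call. = FALSE)
  }
  structure(
    list(family = family, a = as.numeric(a), b = as.numeric(b)),
    class = "retention_curve"
  )
}

#' @export
print.retention_curve <- function(x, ...) {
  eqn <- switch(x$family,
    logarithmic       = "M = a - b ln(t)",
    power             = "M = a t^b",
    exponential_power = "M = a exp(-b sqrt(t))",
    hyperbolic_power  = "M = 1 / (a + b sqrt(t))",
    linear            = "M = b t + a"
  )
  cat(sprintf("<retention_curve> %s  [%s]  a = %.6g, b = %.6g\n",
              x$family, eqn, x$a, x$b))
  invisible(x)
}

# Raw family formula, no clamping, no domain checks. Vectorized over t.
family_value <- function(family, a, b, t) {
  switch(family,
    logarithmic       = a - b * log(t),
    power             = a * t^b,
    exponential_power = a * exp(-b * sqrt(t)),
    hyperbolic_power  = 1 / (a + b * sqrt(t)),
    linear            = b * t + a,
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Evaluate a retention curve at given delays
#'
#' Evaluates the curve's formula at delays `t` (seconds). With
#' `clamp = TRUE` (the default) predictions are truncated into `[0, 1]`:
#' logarithmic and linear curves eventually predict negative retention, so a
#' boundary constraint is required for them, and the same truncation is
#' applied uniformly to every family. Fitting uses `clamp = FALSE`
#' internally so residuals are taken against the raw formula.
#'
#' @param curve A [retention_curve()].
#' @param t Numeric vector of delays in seconds, all `> 0`.
#' @param clamp Truncate predictions into `[0, 1]`?
#' @return Numeric vector of predicted proportions, same length as `t`.
#' @examples
#' evaluate_curve(retention_curve("logarithmic", 0.9, 0.1), t = 1)
#' @export
evaluate_curve <- function(curve, t, clamp = TRUE) {
  stopifnot(inherits(curve, "retention_curve"))
  if (length(t) == 0L || !is.numeric(t)) {
    stop("`t` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("all delays `t` must be finite and > 0", call. = FALSE)
  }
  if (curve$family == "hyperbolic_power" && !clamp) {
    denom <- curve$a + curve$b * sqrt(t)
    if (any(denom <= 0)) {
      stop("hyperbolic_power denominator a + b*sqrt(t) is <= 0 over `t`",
           call. = FALSE)
    }
  }
  m <- family_value(curve$family, curve$a, curve$b, t)
  if (clamp) m <- pmin(1, pmax(0, m))
  m
}

#' Sample a retention curve on a time grid
#'
#' Element-wise [evaluate_curve()] with `clamp = TRUE`, returned as a tidy
#' data frame suitable for plotting typical curves.
#'
#' @param curve A [retention_curve()].
#' @param times Strictly increasing numeric vector of delays, all `> 0`.
#' @return A data frame with columns `t` and `M`, one row per grid point.
#' @export
curve_grid <- function(curve, times) {
  if (length(times) == 0L) stop("`times` must be non-empty", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  data.frame(t = times, M = evaluate_curve(curve, times, clamp = TRUE))
}

#' Serialize / deserialize retention curves
#'
#' Curves round-trip through a plain `{family, a, b}` record, usable as a
#' one-row data frame (CSV) or via [jsonlite::toJSON()].
#'
#' @param curve A [retention_curve()].
#' @param record A list or one-row data frame with `family`, `a`, `b`.
#' @return `curve_record()` returns a one-row data frame;
#'   `curve_from_record()` returns a `retention_curve`.
#' @export
curve_record <- function(curve) {
  stopifnot(inherits(curve, "retention_curve"))
  data.frame(family = curve$family, a = curve$a, b = curve$b,
             stringsAsFactors = FALSE)
}

#' @rdname curve_record
#' @export
curve_from_record <- function(record) {
  retention_curve(as.character(record$family), as.numeric(record$a),
                  as.numeric(record$b))
}

#' Default log-spaced delay grid
#'
#' Log-spaced grid from 1 second to 68 years (the longest retention interval
#' represented in the kinds of corpora this package targets), used for
#' typical-curve rendering.
#'
#' @param n Number of grid points.
#' @param from,to Grid endpoints in seconds.
#' @return Strictly increasing numeric vector of length `n`.
#' @export
default_time_grid <- function(n = 200, from = 1, to = 68 * 31536000) {
  exp(seq(log(from), log(to), length.out = n))
}
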