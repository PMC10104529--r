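#' Derive the Gaussian-limb scale parameter of a thermal performance curve
#'
#' Laboratory studies rarely report the scale of the ascending (sub-optimal)
#' limb of a thermal performance curve directly. It is therefore derived from
#' the critical thermal minimum and the thermal optimum as
#' \deqn{\sigma = (T_{opt} - CT_{min}) / 4,}
#' which places \eqn{CT_{min}} four Gaussian scale units below the optimum, so
#' the curve has essentially vanished (\eqn{e^{-4} \approx 0.018}) at the
#' critical minimum.
#'
#' @param t_opt Thermal optimum, degrees C.
#' @param ct_min Critical thermal minimum, degrees C. Must be strictly below
#'   `t_opt`.
#' @return The scale parameter sigma in degrees C. Vectorized over both
#'   arguments.
#' @examples
#' derive_sigma(28, 4) # 6
#' @seealso [thermal_curve()], [performance()]
#' @export
derive_sigma <- function(t_opt, ct_min) {
  if (any(!is.finite(t_opt)) || any(!is.finite(ct_min))) {
    stop_pga("t_opt and ct_min must be finite")
  }
  if (any(t_opt <= ct_min)) {
    stop_pga("invalid trait ordering: t_opt must be strictly greater than ct_min")
  }
  (t_opt - ct_min) / 4
}

#' Construct a thermal performance curve
#'
#' A thermal performance curve maps water temperature to a relative
#' performance scalar in \[0, 1\]: a Gaussian ascending limb rising to 1 at the
#' thermal optimum `t_opt`, a quadratic decline from `t_opt` to 0 at the
#' critical thermal maximum `ct_max`, and 0 above `ct_max`. When `sigma` is
#' not supplied it is derived from `t_opt` and `ct_min` via [derive_sigma()].
#'
#' Note the Gaussian limb applies to all temperatures at or below `t_opt`, so
#' the curve is small but not exactly zero at `ct_min`
#' (\eqn{P(CT_{min}) = e^{-4} \approx 0.018} under the derived sigma).
#'
#' @param ct_min Critical thermal minimum, degrees C.
#' @param t_opt Thermal optimum, degrees C.
#' @param ct_max Critical thermal maximum, degrees C.
#' @param sigma Scale of the Gaussian ascending limb, degrees C; derived from
#'   the other traits when `NULL`.
#' @return An object of class `thermal_curve`.
#' @examples
#' cv <- thermal_curve(ct_min = 4, t_opt = 22, ct_max = 30)
#' performance(c(10, 22, 26, 31), cv)
#' @export
thermal_curve <- function(ct_min, t_opt, ct_max, sigma = NULL) {
  if (any(!is.finite(c(ct_min, t_opt, ct_max)))) {
    stop_pga("curve parameters must be finite")
  }
  if (!(ct_min < t_opt && t_opt < ct_max)) {
    stop_pga("curve parameters must satisfy ct_min < t_opt < ct_max")
  }
  if (is.null(sigma)) sigma <- derive_sigma(t_opt, ct_min)
  if (!is.finite(sigma)) stop_pga("curve parameters must be finite")
  if (sigma <= 0) stop_pga("sigma must be positive")
  structure(
    list(ct_min = ct_min, t_opt = t_opt, ct_max = ct_max, sigma = sigma),
    class = "thermal_curve"
  )
}

#' Evaluate a thermal performance curve
#'
#' Piecewise evaluation of the performance scalar:
#' \deqn{P(T) = \exp(-((T - T_{opt})/(2\sigma))^2)} for \eqn{T \le T_{opt}},
#' \deqn{P(T) = 1 - ((T - T_{opt})/(T_{opt} - CT_{max}))^2} for
#' \eqn{T_{opt} < T \le CT_{max}}, and 0 above \eqn{CT_{max}}.
#'
#' @param temp Numeric vector of temperatures, degrees C. Any real value is
#'   accepted.
#' @param curve A [thermal_curve()].
#' @return Numeric vector of performance values in \[0, 1\].
#' @export
performance <- function(temp, curve) {
  stopifnot(inherits(curve, "thermal_curve"))
  p <- numeric(length(temp))
  lo <- temp <= curve$t_opt
  mid <- temp > curve$t_opt & temp <= curve$ct_max
  p[lo] <- exp(-((temp[lo] - curve$t_opt) / (2 * curve$sigma))^2)
  p[mid] <- 1 - ((temp[mid] - curve$t_opt) / (curve$t_opt - curve$ct_max))^2
  # temp > ct_max stays 0
  p[is.na(temp)] <- NA_real_
  p
}

#' Tabulate a thermal performance curve over a temperature grid
#'
#' Convenience export of (temperature, performance) pairs, e.g. for plotting
#' or writing to CSV.
#'
#' @param curve A [thermal_curve()].
#' @param from,to Grid limits, degrees C; default spans the curve with margin.
#' @param by Grid step, degrees C.
#' @return A data.frame with columns `temperature` and `performance`.
#' @export
curve_table <- function(curve, from = curve$ct_min - 2, to = curve$ct_max + 2,
                        by = 0.1) {
  temperature <- seq(from, to, by = by)
  data.frame(temperature = temperature,
             performance = performance(temperature, curve))
}

#' @export
print.thermal_curve <- function(x, ...) {
  cat(sprintf(
    "Thermal performance curve: CT_min = %.2f, T_opt = %.2f, CT_max = %.2f, sigma = %.3f (degC)\n",
    x$ct_min, x$t_opt, x$ct_max, x$sigma
  ))
  invisible(x)
}

#' @export
plot.thermal_curve <- function(x, from = x$ct_min - 2, to = x$ct_max + 2, ...,
                               xlab = "Temperature (°C)",
                               ylab = "Performance", type = "l") {
  tab <- curve_table(x, from, to)
  graphics::plot(tab$temperature, tab$performance, type = type,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
as.data.frame.thermal_curve <- function(x, ...) {
  data.frame(ct_min = x$ct_min, t_opt = x$t_opt, ct_max = x$ct_max,
             sigma = x$sigma)
}
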