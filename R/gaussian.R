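#' Gaussian rate function parameters
#'
#' The age profile of both incidence and remission is modelled as a single
#' Gaussian bump
#' \deqn{g(a) = A \exp\{-((a - \mu)/w)^2\},}
#' with amplitude \eqn{A} (rate per person-year at the mode), location
#' \eqn{\mu} (age in years of the mode) and width \eqn{w > 0} (years).  The
#' amplitude may be negative while the parameters are being optimized;
#' negative rates are truncated to zero only at reporting time (see
#' [rates_table()]).
#'
#' @param amplitude Rate per person-year at the mode.  May be negative
#'   during optimization.
#' @param location Age (years) at which the rate peaks.
#' @param width Width of the bump in years; strictly positive.
#' @return An object of class `gaussian_rate`.
#' @examples
#' inc <- gaussian_rate_params(0.004, 20, 18)
#' gaussian_rate(20, inc)   # equals the amplitude at the mode
#' @seealso [gaussian_rate()], [rate_parameter_set()]
#' @export
gaussian_rate_params <- function(amplitude, location, width) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(location), length(location) == 1L,
            is.numeric(width), length(width) == 1L)
  if (!is.finite(width) || width <= 0) {
    stop("'width' must be strictly positive, got ", width, call. = FALSE)
  }
  structure(list(amplitude = amplitude, location = location, width = width),
            class = "gaussian_rate")
}

#' @export
print.gaussian_rate <- function(x, ...) {
  cat(sprintf("Gaussian rate: amplitude %.6g /PY at age %.4g (width %.4g y)\n",
              x$amplitude, x$location, x$width))
  invisible(x)
}

#' Evaluate a Gaussian rate function
#'
#' @param age Numeric vector of ages in years.
#' @param g A [gaussian_rate_params()] object.
#' @return Rates per person-year, same length as `age`.
#' @export
gaussian_rate <- function(age, g) {
  if (!inherits(g, "gaussian_rate")) {
    g <- do.call(gaussian_rate_params, as.list(g)[c("amplitude", "location", "width")])
  }
  if (g$width <= 0) stop("'width' must be strictly positive", call. = FALSE)
  g$amplitude * exp(-((age - g$location) / g$width)^2)
}

#' Incidence/remission parameter set
#'
#' Bundles the six coefficients that the least-squares step estimates: one
#' Gaussian for incidence (susceptible to diseased) and one for remission
#' (diseased back to susceptible).
#'
#' @param incidence,remission [gaussian_rate_params()] objects.
#' @return An object of class `rate_parameter_set`.
#' @export
rate_parameter_set <- function(incidence, remission) {
  stopifnot(inherits(incidence, "gaussian_rate"),
            inherits(remission, "gaussian_rate"))
  structure(list(incidence = incidence, remission = remission),
            class = "rate_parameter_set")
}

#' @export
print.rate_parameter_set <- function(x, ...) {
  cat("Illness-death rate parameters\n  incidence: ")
  cat(sprintf("%.6g /PY at age %.4g (width %.4g y)\n",
              x$incidence$amplitude, x$incidence$location, x$incidence$width))
  cat("  remission: ")
  cat(sprintf("%.6g /PY at age %.4g (width %.4g y)\n",
              x$remission$amplitude, x$remission$location, x$remission$width))
  invisible(x)
}

# theta = (inc_amp, inc_loc, log inc_width, rem_amp, rem_loc, log rem_width);
# widths live on the log scale during optimization so positivity needs no bounds
.theta_from_params <- function(params) {
  c(params$incidence$amplitude, params$incidence$location, log(params$incidence$width),
    params$remission$amplitude, params$remission$location, log(params$remission$width))
}

.params_from_theta <- function(theta) {
  theta <- unname(theta)
  rate_parameter_set(
    gaussian_rate_params(theta[1L], theta[2L], exp(theta[3L])),
    gaussian_rate_params(theta[4L], theta[5L], exp(theta[6L]))
  )
}

.gauss_eval <- function(age, amp, loc, wid) amp * exp(-((age - loc) / wid)^2)
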