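#' Rate estimates with symmetric 95% confidence intervals and units
#'
#' Every derived quantity in the kinetic-race analysis — dwell times, off-rates,
#' run lengths, step counts, tethered-head attachment rates, dissociation
#' constants — is a nonnegative value with a symmetric 95% confidence interval
#' and a unit tag. `rate_estimate()` builds such a value; products, quotients
#' and reciprocals propagate the interval by first-order relative-error
#' quadrature (the relative CI of a product or quotient is the root sum of
#' squares of the inputs' relative CIs) and track the unit algebra, so that
#' e.g. micromolar times per-micromolar-per-second yields per-second, and any
#' combination without a recognised unit tag is an error rather than a silent
#' number.
#'
#' @param value nonnegative numeric scalar.
#' @param ci95 nonnegative half-width of the 95% confidence interval, in the
#'   same unit as `value`. Default 0 (treated as exactly known).
#' @param unit one of `"per_second"`, `"per_micromolar_per_second"`,
#'   `"micromolar"`, `"micrometer"`, `"second"`, `"dimensionless"`.
#' @return an object of class `rate_estimate`.
#' @examples
#' dwell <- rate_estimate(1.8, 0.08, "second")
#' re_reciprocal(dwell)  # off-rate, 0.56 +/- 0.02 s^-1
#' @export
rate_estimate <- function(value, ci95 = 0, unit = "dimensionless") {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) || value < 0) {
    kr_stop("`value` must be a single nonnegative number",
            "kinrace_domain_error")
  }
  if (!is.numeric(ci95) || length(ci95) != 1 || is.na(ci95) || ci95 < 0) {
    kr_stop("`ci95` must be a single nonnegative number",
            "kinrace_domain_error")
  }
  unit <- match.arg(unit, names(.unit_exponents))
  structure(list(value = as.numeric(value), ci95 = as.numeric(ci95),
                 unit = unit),
            class = "rate_estimate")
}

# unit tags as exponent triples over (second, micromolar, micrometer)
.unit_exponents <- list(
  per_second                = c(s = -1, uM =  0, um = 0),
  per_micromolar_per_second = c(s = -1, uM = -1, um = 0),
  micromolar                = c(s =  0, uM =  1, um = 0),
  micrometer                = c(s =  0, uM =  0, um = 1),
  second                    = c(s =  1, uM =  0, um = 0),
  dimensionless             = c(s =  0, uM =  0, um = 0)
)

.unit_from_exponents <- function(expo) {
  for (nm in names(.unit_exponents)) {
    if (all(.unit_exponents[[nm]] == expo)) return(nm)
  }
  kr_stop(sprintf("no unit tag for exponents (s^%d uM^%d um^%d)",
                  expo[["s"]], expo[["uM"]], expo[["um"]]),
          "kinrace_unit_error")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%g +/- %g [%s]\n", x$value, x$ci95, x$unit))
  invisible(x)
}

#' @export
format.rate_estimate <- function(x, digits = 3, ...) {
  sprintf("%s +/- %s [%s]",
          format(round_half_up(x$value, digits)),
          format(round_half_up(x$ci95, digits)), x$unit)
}

#' Relative 95% confidence interval of a rate estimate
#'
#' @param x a `rate_estimate`.
#' @return `ci95 / value`, or 0 when the value is 0 and the interval is 0.
#' @export
re_rel_ci <- function(x) {
  stopifnot(inherits(x, "rate_estimate"))
  if (x$value == 0) {
    if (x$ci95 == 0) return(0)
    kr_stop("relative CI undefined for zero value with nonzero ci95",
            "kinrace_domain_error")
  }
  x$ci95 / x$value
}

.as_re <- function(x) {
  if (inherits(x, "rate_estimate")) return(x)
  if (is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0) {
    return(rate_estimate(x, 0, "dimensionless"))
  }
  kr_stop("operands must be rate_estimate or nonnegative scalars",
          "kinrace_domain_error")
}

#' Multiply two rate estimates
#'
#' Value multiplies; relative CIs combine in quadrature; unit exponents add.
#'
#' @param a,b `rate_estimate` objects (bare nonnegative scalars are promoted
#'   to dimensionless estimates with zero CI).
#' @return a `rate_estimate`.
#' @export
re_multiply <- function(a, b) {
  a <- .as_re(a); b <- .as_re(b)
  expo <- .unit_exponents[[a$unit]] + .unit_exponents[[b$unit]]
  unit <- .unit_from_exponents(expo)
  value <- a$value * b$value
  rel <- sqrt(re_rel_ci(a)^2 + re_rel_ci(b)^2)
  rate_estimate(value, value * rel, unit)
}

#' Divide two rate estimates
#'
#' @inheritParams re_multiply
#' @return a `rate_estimate`; dividing by a zero-valued estimate is an error.
#' @export
re_divide <- function(a, b) {
  a <- .as_re(a); b <- .as_re(b)
  if (b$value <= 0) {
    kr_stop("division by a nonpositive rate estimate", "kinrace_domain_error")
  }
  expo <- .unit_exponents[[a$unit]] - .unit_exponents[[b$unit]]
  unit <- .unit_from_exponents(expo)
  value <- a$value / b$value
  rel <- sqrt(re_rel_ci(a)^2 + re_rel_ci(b)^2)
  rate_estimate(value, value * rel, unit)
}

#' Reciprocal of a rate estimate
#'
#' The relative CI is preserved (first-order propagation); unit exponents
#' negate, so the reciprocal of a dwell time in seconds is a rate per second.
#'
#' @param x a positive `rate_estimate`.
#' @return a `rate_estimate`.
#' @export
re_reciprocal <- function(x) {
  x <- .as_re(x)
  if (x$value <= 0) {
    kr_stop("reciprocal requires a positive value", "kinrace_domain_error")
  }
  unit <- .unit_from_exponents(-.unit_exponents[[x$unit]])
  value <- 1 / x$value
  rate_estimate(value, value * re_rel_ci(x), unit)
}

#' Scale a rate estimate by an exact factor
#'
#' Both the value and the CI half-width scale; the unit is unchanged (the
#' factor is treated as a pure number, e.g. a unit conversion).
#'
#' @param x a `rate_estimate`.
#' @param factor positive scalar.
#' @return a `rate_estimate`.
#' @export
re_scale <- function(x, factor) {
  stopifnot(inherits(x, "rate_estimate"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 0) {
    kr_stop("`factor` must be a nonnegative scalar", "kinrace_domain_error")
  }
  rate_estimate(x$value * factor, x$ci95 * factor, x$unit)
}

#' @export
Ops.rate_estimate <- function(e1, e2) {
  switch(.Generic,
    "*" = re_multiply(e1, e2),
    "/" = re_divide(e1, e2),
    kr_stop(sprintf("operation `%s` not defined for rate_estimate", .Generic),
            "kinrace_unit_error")
  )
}
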