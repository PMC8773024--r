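# Canonical term names of the two-factor quadratic response model:
# y = b0 + b1*P + b2*Q + b11*P^2 + b22*Q^2 + b12*P*Q
quad_terms <- c("intercept", "pressure", "co2_flow",
                "pressure2", "co2_flow2", "pressure:co2_flow")

# full 6-vector with zeros for absent terms
complete_beta <- function(beta) {
  unknown <- setdiff(names(beta), quad_terms)
  if (length(unknown)) {
    stop_input(paste0("Unknown term(s): ", paste(unknown, collapse = ", "),
                      ". Valid terms: ", paste(quad_terms, collapse = ", "), "."))
  }
  out <- setNames(numeric(6), quad_terms)
  out[names(beta)] <- beta
  out
}

#' Define a quadratic response surface from known coefficients
#'
#' Wraps a set of coefficients of the two-factor quadratic model
#' \eqn{y = \beta_0 + \beta_1 P + \beta_2 Q + \beta_{11} P^2 + \beta_{22} Q^2
#' + \beta_{12} P Q} (pressure `P` in bar, CO2 flow `Q` in g/min) so that
#' published coefficient tables can be evaluated, analysed for stationary
#' points, and optimized exactly like a fitted model.
#'
#' @param coefficients Named numeric vector using the term names
#'   `intercept`, `pressure`, `co2_flow`, `pressure2`, `co2_flow2`,
#'   `pressure:co2_flow`; omitted terms are zero.
#' @param response Optional response label.
#' @param bounds Optional factor bounds, a list like
#'   `list(pressure = c(80, 160), co2_flow = c(10, 60))`; evaluations outside
#'   them are flagged as extrapolation.
#' @return An object of class `quad_surface`.
#' @examples
#' s <- quad_surface(c(intercept = 242.6, pressure = -2.343, co2_flow = -3.835,
#'                     pressure2 = 0.00717, co2_flow2 = 0.00812,
#'                     `pressure:co2_flow` = 0.0252))
#' predict_surface(s, pressure = 120, co2_flow = 35)
#' @export
quad_surface <- function(coefficients, response = NULL, bounds = NULL) {
  check_number(coefficients, "coefficients")
  beta <- complete_beta(coefficients)
  structure(
    list(beta = beta, active = names(coefficients),
         response = response, bounds = bounds),
    class = "quad_surface"
  )
}

#' @export
print.quad_surface <- function(x, ...) {
  cat("Quadratic surface",
      if (!is.null(x$response)) paste0("for `", x$response, "`"), "\n")
  print(x$beta[x$active])
  invisible(x)
}

#' Full natural-unit coefficient vector of a surface or fit
#'
#' @param x A [quad_surface()] or a fit from [fit_response_surface()].
#' @return Named numeric vector over all six quadratic-model terms
#'   (inactive terms as 0), in natural units (bar, g/min).
#' @export
natural_coefficients <- function(x) UseMethod("natural_coefficients")

#' @export
natural_coefficients.quad_surface <- function(x) x$beta

eval_quad <- function(beta, pressure, co2_flow) {
  beta[["intercept"]] +
    beta[["pressure"]] * pressure +
    beta[["co2_flow"]] * co2_flow +
    beta[["pressure2"]] * pressure^2 +
    beta[["co2_flow2"]] * co2_flow^2 +
    beta[["pressure:co2_flow"]] * pressure * co2_flow
}

surface_bounds <- function(x) {
  if (inherits(x, "quad_surface")) x$bounds else x$data_bounds
}

#' Evaluate a response surface at given conditions
#'
#' @param object A [quad_surface()] or [fit_response_surface()] result.
#' @param pressure,co2_flow Conditions (bar, g/min); vectorized.
#' @param warn_extrapolation Warn when a point lies outside the surface's
#'   known factor bounds (the fitted data range, or `bounds` of a
#'   [quad_surface()]).
#' @return Numeric vector of predicted response values.
#' @export
predict_surface <- function(object, pressure, co2_flow,
                            warn_extrapolation = TRUE) {
  check_number(pressure, "pressure")
  check_number(co2_flow, "co2_flow")
  b <- surface_bounds(object)
  if (warn_extrapolation && !is.null(b)) {
    out <- pressure < b$pressure[1] | pressure > b$pressure[2] |
      co2_flow < b$co2_flow[1] | co2_flow > b$co2_flow[2]
    if (any(out)) {
      warn(sprintf("%d point(s) outside the factor bounds: extrapolating.",
                   sum(out)))
    }
  }
  eval_quad(natural_coefficients(object), pressure, co2_flow)
}

#' Stationary point of a quadratic surface
#'
#' Solves the linear gradient system of the quadratic polynomial and
#' classifies the critical point by the eigenvalues of its Hessian.
#' Surfaces whose Hessian is singular (relative to its norm, tolerance
#' 1e-10) are reported as degenerate without a located point.
#'
#' @inheritParams predict_surface
#' @return A one-row tibble with `pressure_bar`, `co2_flow_g_min`,
#'   `classification` (`"maximum"`, `"minimum"`, `"saddle"` or
#'   `"degenerate"`) and the predicted `value` at the point (`NA` for
#'   degenerate surfaces).
#' @examples
#' stationary_point(quad_surface(c(pressure2 = -1, co2_flow2 = -1))) # maximum at origin
#' @export
stationary_point <- function(object) {
  beta <- natural_coefficients(object)
  active <- object$active
  if (!any(c("pressure2", "co2_flow2", "pressure:co2_flow") %in% active)) {
    stop_input("Surface has no active quadratic terms; no stationary point.")
  }
  H <- matrix(c(2 * beta[["pressure2"]], beta[["pressure:co2_flow"]],
                beta[["pressure:co2_flow"]], 2 * beta[["co2_flow2"]]), 2, 2)
  g <- c(beta[["pressure"]], beta[["co2_flow"]])
  scale <- max(abs(H))
  if (scale == 0 || abs(det(H)) <= 1e-10 * scale^2) {
    return(tibble(pressure_bar = NA_real_, co2_flow_g_min = NA_real_,
                  classification = "degenerate", value = NA_real_))
  }
  theta <- solve(H, -g)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  cls <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
  tibble(
    pressure_bar = theta[1], co2_flow_g_min = theta[2],
    classification = cls,
    value = eval_quad(beta, theta[1], theta[2])
  )
}

#' Evaluate a surface on a rectangular lattice
#'
#' Numeric backing for contour maps of a response over the operating window:
#' an evenly spaced `resolution` x `resolution` lattice including both
#' bounds, evaluated row-by-row (pressure varies slowest).
#'
#' @inheritParams predict_surface
#' @param bounds List with elements `pressure` and `co2_flow`, each a
#'   length-2 numeric range with distinct endpoints.
#' @param resolution Number of lattice points per axis (>= 2).
#' @return A tibble with columns `pressure_bar`, `co2_flow_g_min`, `value`,
#'   in row-major order.
#' @export
contour_grid <- function(object,
                         bounds = list(pressure = c(80, 160),
                                       co2_flow = c(10, 60)),
                         resolution = 41) {
  check_number(resolution, "resolution", min = 2)
  for (nm in c("pressure", "co2_flow")) {
    r <- bounds[[nm]]
    if (is.null(r) || length(r) != 2 || anyNA(r) || r[1] >= r[2]) {
      stop_input(sprintf("`bounds$%s` must be an increasing length-2 range.", nm))
    }
  }
  grid <- tidyr::expand_grid(
    pressure_bar = seq(bounds$pressure[1], bounds$pressure[2],
                       length.out = resolution),
    co2_flow_g_min = seq(bounds$co2_flow[1], bounds$co2_flow[2],
                         length.out = resolution)
  )
  grid$value <- predict_surface(object, grid$pressure_bar,
                                grid$co2_flow_g_min,
                                warn_extrapolation = FALSE)
  grid
}
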