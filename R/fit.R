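resolve_terms <- function(terms) {
  presets <- list(
    full = quad_terms,
    no_q2 = setdiff(quad_terms, "co2_flow2"),
    no_interaction = setdiff(quad_terms, "pressure:co2_flow")
  )
  if (length(terms) == 1 && terms %in% names(presets)) {
    return(presets[[terms]])
  }
  unknown <- setdiff(terms, quad_terms)
  if (length(unknown)) {
    stop_input(paste0(
      "Unknown term(s): ", paste(unknown, collapse = ", "),
      ". Use a preset (full, no_q2, no_interaction) or names among: ",
      paste(quad_terms, collapse = ", "), "."))
  }
  union("intercept", terms)
}

# model-matrix columns for the active non-intercept terms
term_columns <- function(pressure, co2_flow) {
  list(
    pressure = pressure,
    co2_flow = co2_flow,
    pressure2 = pressure^2,
    co2_flow2 = co2_flow^2,
    `pressure:co2_flow` = pressure * co2_flow
  )
}

#' Fit a quadratic response surface by ordinary least squares
#'
#' Fits the two-factor quadratic model
#' \eqn{y = \beta_0 + \beta_1 P + \beta_2 Q + \beta_{11} P^2 +
#' \beta_{22} Q^2 + \beta_{12} P Q} to experimental runs by OLS, with a
#' user-chosen term set (responses for which some terms were dropped are
#' refit with exactly the reduced set; no automatic elimination is
#' performed). Standard errors use the unbiased residual variance and
#' p-values are two-sided t-tests on the residual degrees of freedom.
#'
#' The default fits in natural units (bar, g/min). With `units = "coded"`
#' the factors are first affinely centred and scaled using a design
#' specification (coded value = (natural - center) / step, step being the
#' distance from the center to the factorial level); predictions and
#' [natural_coefficients()] are identical in both parametrizations.
#'
#' @param data Data frame with columns `pressure_bar`, `co2_flow_g_min` and
#'   the response.
#' @param response Name of the response column (string).
#' @param terms `"full"`, `"no_q2"` (drop the quadratic flow term),
#'   `"no_interaction"` (drop the cross term), or a character vector of term
#'   names among `pressure`, `co2_flow`, `pressure2`, `co2_flow2`,
#'   `pressure:co2_flow`. The intercept is always included.
#' @param units `"natural"` (default) or `"coded"`.
#' @param spec A [ccd_spec()] supplying center and step for
#'   `units = "coded"`; defaults to [calendula_design()].
#' @return An object of class `saf_rsm`; see [tidy()], [glance()],
#'   [predict_surface()], [stationary_point()], [autoplot()].
#' @examples
#' runs <- calendula_runs()
#' fit <- fit_response_surface(runs, "y_saf_pct")
#' tidy(fit)
#' glance(fit)
#' @export
fit_response_surface <- function(data, response, terms = "full",
                                 units = c("natural", "coded"),
                                 spec = NULL) {
  units <- match.arg(units)
  data <- as_tibble(data)
  needed <- c("pressure_bar", "co2_flow_g_min", response)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop_input(paste0("`data` is missing column(s): ",
                      paste(missing, collapse = ", "), "."))
  }
  active <- resolve_terms(terms)
  y <- data[[response]]
  check_number(y, response)
  P <- data$pressure_bar
  Q <- data$co2_flow_g_min
  check_number(P, "pressure_bar")
  check_number(Q, "co2_flow_g_min")

  transform <- NULL
  if (units == "coded") {
    if (is.null(spec)) spec <- calendula_design()
    if (!inherits(spec, "ccd_spec")) stop_input("`spec` must be a `ccd_spec`.")
    center <- vapply(spec$levels, `[[`, numeric(1), 3)
    step <- vapply(spec$levels, `[[`, numeric(1), 4) - center
    transform <- list(center = center, step = step)
    P <- (P - center[["pressure_bar"]]) / step[["pressure_bar"]]
    Q <- (Q - center[["co2_flow_g_min"]]) / step[["co2_flow_g_min"]]
  }

  cols <- term_columns(P, Q)[setdiff(active, "intercept")]
  k <- length(cols) + 1
  if (length(y) <= k) {
    stop_input(sprintf(
      "Need more observations (%d) than coefficients (%d).", length(y), k))
  }
  df <- tibble(.y = y, !!!cols)
  names(df) <- c(".y", paste0(".x", seq_along(cols)))
  fit <- lm(.y ~ ., data = df)
  if (anyNA(coef(fit))) {
    bad <- setdiff(active, "intercept")[is.na(coef(fit)[-1])]
    abort(paste0("Design is rank deficient; collinear term(s): ",
                 paste(bad, collapse = ", "), "."),
          class = "safskin_fit_error")
  }
  names(fit$coefficients) <- active

  structure(
    list(
      fit = fit, response = response, active = active, units = units,
      transform = transform,
      data = data[needed],
      data_bounds = list(pressure = range(data$pressure_bar),
                         co2_flow = range(data$co2_flow_g_min))
    ),
    class = "saf_rsm"
  )
}

#' @export
print.saf_rsm <- function(x, ...) {
  cat(sprintf("Quadratic response-surface fit for `%s` (%s units)\n",
              x$response, x$units))
  print(tidy(x), n = Inf)
  g <- glance(x)
  cat(sprintf("R2 = %.2f%%, s = %.4g on %d residual df\n",
              g$r.squared.pct, g$sigma, g$df.residual))
  invisible(x)
}

#' @describeIn fit_response_surface Coefficient table: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, in the units of the fit.
#' @param x,object A `saf_rsm` fit.
#' @param ... Unused.
#' @export
tidy.saf_rsm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = x$active,
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @describeIn fit_response_surface One-row model summary: `r.squared`
#'   (0-1), `r.squared.pct` (0-100), `sigma` (residual standard deviation,
#'   response units), `df.residual`, `nobs`.
#' @export
glance.saf_rsm <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    response = x$response,
    r.squared = s$r.squared,
    r.squared.pct = 100 * s$r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    nobs = length(x$fit$residuals)
  )
}

#' @export
natural_coefficients.saf_rsm <- function(x) {
  beta <- complete_beta(coef(x$fit))
  if (x$units == "natural") return(beta)
  c1 <- x$transform$center[["pressure_bar"]]
  c2 <- x$transform$center[["co2_flow_g_min"]]
  s1 <- x$transform$step[["pressure_bar"]]
  s2 <- x$transform$step[["co2_flow_g_min"]]
  b <- beta
  out <- setNames(numeric(6), quad_terms)
  out[["pressure2"]] <- b[["pressure2"]] / s1^2
  out[["co2_flow2"]] <- b[["co2_flow2"]] / s2^2
  out[["pressure:co2_flow"]] <- b[["pressure:co2_flow"]] / (s1 * s2)
  out[["pressure"]] <- b[["pressure"]] / s1 -
    2 * b[["pressure2"]] * c1 / s1^2 -
    b[["pressure:co2_flow"]] * c2 / (s1 * s2)
  out[["co2_flow"]] <- b[["co2_flow"]] / s2 -
    2 * b[["co2_flow2"]] * c2 / s2^2 -
    b[["pressure:co2_flow"]] * c1 / (s1 * s2)
  out[["intercept"]] <- b[["intercept"]] -
    b[["pressure"]] * c1 / s1 - b[["co2_flow"]] * c2 / s2 +
    b[["pressure2"]] * (c1 / s1)^2 + b[["co2_flow2"]] * (c2 / s2)^2 +
    b[["pressure:co2_flow"]] * c1 * c2 / (s1 * s2)
  out
}

#' @export
predict.saf_rsm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  predict_surface(object, newdata$pressure_bar, newdata$co2_flow_g_min,
                  warn_extrapolation = FALSE)
}

#' Contour map of a fitted response surface
#'
#' @param object A `saf_rsm` fit or [quad_surface()].
#' @param bounds,resolution Passed to [contour_grid()]; `bounds` defaults to
#'   the fitted data range (or the surface's own bounds).
#' @param ... Unused.
#' @return A ggplot: filled contours of the predicted response, with the
#'   design points overlaid for fitted models.
#' @export
autoplot.saf_rsm <- function(object, bounds = NULL, resolution = 101, ...) {
  if (is.null(bounds)) bounds <- surface_bounds(object)
  grid <- contour_grid(object, bounds = bounds, resolution = resolution)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$pressure_bar,
                                          .data$co2_flow_g_min)) +
    ggplot2::geom_contour_filled(ggplot2::aes(z = .data$value)) +
    ggplot2::labs(x = "Pressure (bar)", y = expression(CO[2]~flow~(g/min)),
                  fill = if (inherits(object, "saf_rsm")) object$response
                         else object$response %||% "response")
  if (inherits(object, "saf_rsm")) {
    p <- p + ggplot2::geom_point(data = object$data, colour = "white")
  }
  p
}

#' @export
autoplot.quad_surface <- autoplot.saf_rsm

`%||%` <- function(a, b) if (is.null(a)) b else a
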