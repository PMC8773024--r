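#' Specify a desirability transform for one response
#'
#' Derringer-Suich ramp desirabilities map a response value onto a
#' unitless score in \[0, 1\]. For `goal = "maximize"` the score is 0 at or
#' below `low`, 1 at or above the target (which equals `high`), and
#' `((y - low)/(high - low))^weight` between; `"minimize"` mirrors this;
#' `"target"` ramps up from `low` to `target` and back down to `high`.
#'
#' @param goal `"maximize"`, `"minimize"` or `"target"`.
#' @param low,high Lower and upper anchors (`low < high`), in response
#'   units. Typical practice when no specification limits exist is to use
#'   the observed response range.
#' @param target Target value; defaults to `high` when maximizing and `low`
#'   when minimizing; required (strictly inside `(low, high)`) for
#'   `goal = "target"`.
#' @param weight Positive ramp exponent; 1 (default) is linear, larger
#'   values demand being close to the target.
#' @return An object of class `desirability_spec`.
#' @examples
#' d <- desirability("maximize", low = 31.1, high = 73.7)
#' desirability_score(c(31.1, 52.4, 73.7), d)
#' @export
desirability <- function(goal = c("maximize", "minimize", "target"),
                         low, high, target = NULL, weight = 1) {
  goal <- match.arg(goal)
  check_number(low, "low")
  check_number(high, "high")
  check_number(weight, "weight", min = 0, strict = TRUE)
  if (low >= high) {
    abort("`low` must be strictly less than `high`.",
          class = "safskin_spec_error")
  }
  if (is.null(target)) {
    target <- switch(goal, maximize = high, minimize = low,
                     abort("`target` is required for goal = \"target\".",
                           class = "safskin_spec_error"))
  }
  check_number(target, "target")
  if (goal == "target" && (target <= low || target >= high)) {
    abort("`target` must lie strictly between `low` and `high`.",
          class = "safskin_spec_error")
  }
  structure(list(goal = goal, low = low, high = high, target = target,
                 weight = weight),
            class = "desirability_spec")
}

#' @export
print.desirability_spec <- function(x, ...) {
  cat(sprintf("desirability: %s on [%g, %g], target %g, weight %g\n",
              x$goal, x$low, x$high, x$target, x$weight))
  invisible(x)
}

#' Individual desirability of response values
#'
#' @param value Numeric vector of response values.
#' @param spec A [desirability()] specification.
#' @return Scores in \[0, 1\], same length as `value`.
#' @export
desirability_score <- function(value, spec) {
  if (!inherits(spec, "desirability_spec")) {
    stop_input("`spec` must come from desirability().")
  }
  check_number(value, "value")
  ramp_up <- function(y, a, b) {
    pmin(1, pmax(0, (y - a) / (b - a)))^spec$weight
  }
  switch(spec$goal,
    maximize = ramp_up(value, spec$low, spec$target),
    minimize = ramp_up(-value, -spec$high, -spec$target),
    target = {
      d <- ifelse(value <= spec$target,
                  ramp_up(value, spec$low, spec$target),
                  ramp_up(-value, -spec$high, -spec$target))
      ifelse(value <= spec$low | value >= spec$high, 0, d)
    }
  )
}

#' Composite desirability of several responses
#'
#' Equal-weight geometric mean of the individual desirabilities; it is zero
#' whenever any individual score is zero, so no response can be traded away
#' entirely.
#'
#' @param values Named numeric vector (or list) of response values.
#' @param specs Named list of [desirability()] specifications with the same
#'   names.
#' @return Composite desirability in \[0, 1\].
#' @examples
#' composite_desirability(
#'   c(a = 5, b = 10),
#'   list(a = desirability("maximize", 0, 10),
#'        b = desirability("maximize", 0, 10)))
#' @export
composite_desirability <- function(values, specs) {
  values <- unlist(values)
  if (is.null(names(values)) || is.null(names(specs)) ||
      !setequal(names(values), names(specs))) {
    stop_input("`values` and `specs` must carry the same response names.")
  }
  d <- vapply(names(values),
              function(nm) desirability_score(values[[nm]], specs[[nm]]),
              numeric(1))
  if (any(d == 0)) return(0)
  exp(mean(log(d)))
}

#' Find operating conditions maximizing composite desirability
#'
#' Deterministic two-stage search over the operating window: a dense grid
#' scan (at least 201 x 201 points by default) locates the best cell, then a
#' bounded quasi-Newton polish (L-BFGS-B) refines it. No randomness is
#' involved, so results are exactly reproducible.
#'
#' @param fits Named list of fitted surfaces ([fit_response_surface()] or
#'   [quad_surface()]), one per response.
#' @param specs Named list of [desirability()] specifications, same names.
#' @param bounds Operating window, `list(pressure = c(lo, hi),
#'   co2_flow = c(lo, hi))`.
#' @param resolution Grid points per axis for the scan.
#' @param polish Run the local refinement after the grid scan.
#' @return An object of class `saf_optimum`: a list with `optimum` (one-row
#'   tibble: `pressure_bar`, `co2_flow_g_min`, `D`), `responses` (per-response
#'   predicted value and desirability at the optimum), `degenerate` (`TRUE`
#'   when D = 0 everywhere on the grid) and the search settings.
#' @examples
#' fit <- fit_response_surface(calendula_runs(), "y_saf_pct")
#' opt <- optimize_desirability(
#'   list(y_saf_pct = fit),
#'   list(y_saf_pct = desirability("maximize", 31.1, 73.7)))
#' opt
#' @export
optimize_desirability <- function(fits, specs,
                                  bounds = list(pressure = c(80, 160),
                                                co2_flow = c(10, 60)),
                                  resolution = 201, polish = TRUE) {
  if (is.null(names(fits)) || !setequal(names(fits), names(specs))) {
    stop_input("`fits` and `specs` must carry the same response names.")
  }
  check_number(resolution, "resolution", min = 2)
  betas <- lapply(fits, natural_coefficients)

  d_all <- function(p, q) {
    vapply(names(fits), function(nm) {
      desirability_score(eval_quad(betas[[nm]], p, q), specs[[nm]])
    }, numeric(length(p)))
  }
  D_of <- function(p, q) {
    d <- d_all(p, q)
    if (is.null(dim(d))) d <- matrix(d, nrow = 1)
    apply(d, 1, function(row) if (any(row == 0)) 0 else exp(mean(log(row))))
  }

  grid <- tidyr::expand_grid(
    pressure_bar = seq(bounds$pressure[1], bounds$pressure[2],
                       length.out = resolution),
    co2_flow_g_min = seq(bounds$co2_flow[1], bounds$co2_flow[2],
                         length.out = resolution)
  )
  D_grid <- D_of(grid$pressure_bar, grid$co2_flow_g_min)
  best <- which.max(D_grid)
  pt <- c(grid$pressure_bar[best], grid$co2_flow_g_min[best])
  D_best <- D_grid[best]
  degenerate <- D_best == 0

  if (polish && !degenerate) {
    # derivative-free polish: the composite is continuous but kinked where a
    # ramp saturates, so a simplex search is more reliable than a gradient one
    clamp <- function(par) {
      c(min(max(par[1], bounds$pressure[1]), bounds$pressure[2]),
        min(max(par[2], bounds$co2_flow[1]), bounds$co2_flow[2]))
    }
    res <- optim(pt, function(par) {
      par <- clamp(par)
      -D_of(par[1], par[2])
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-12, maxit = 2000))
    if (-res$value >= D_best) {
      pt <- clamp(res$par)
      D_best <- -res$value
    }
  }

  pred <- vapply(betas, eval_quad, numeric(1), pressure = pt[1],
                 co2_flow = pt[2])
  dind <- vapply(names(fits),
                 function(nm) desirability_score(pred[[nm]], specs[[nm]]),
                 numeric(1))
  structure(
    list(
      optimum = tibble(pressure_bar = pt[1], co2_flow_g_min = pt[2],
                       D = D_best),
      responses = tibble(response = names(fits), predicted = unname(pred),
                         desirability = unname(dind)),
      degenerate = degenerate,
      bounds = bounds, resolution = resolution
    ),
    class = "saf_optimum"
  )
}

#' @export
print.saf_optimum <- function(x, ...) {
  with(x$optimum, cat(sprintf(
    "Composite-desirability optimum: %.1f bar, %.1f g/min (D = %.3f)%s\n",
    pressure_bar, co2_flow_g_min, D,
    if (x$degenerate) " [degenerate: D = 0 everywhere]" else "")))
  print(x$responses)
  invisible(x)
}

#' @describeIn optimize_desirability Per-response breakdown at the optimum.
#' @param x A `saf_optimum`.
#' @param ... Unused.
#' @export
tidy.saf_optimum <- function(x, ...) {
  dplyr::bind_cols(x$responses, x$optimum[rep(1, nrow(x$responses)), ])
}

#' @describeIn optimize_desirability Map of the composite desirability over
#'   the operating window with the optimum marked.
#' @param object A `saf_optimum`; recomputes D on a display grid, so supply
#'   the same `fits`/`specs` used for the optimization.
#' @param fits,specs As in `optimize_desirability()`.
#' @export
autoplot.saf_optimum <- function(object, fits, specs, ...) {
  grid <- tidyr::expand_grid(
    pressure_bar = seq(object$bounds$pressure[1], object$bounds$pressure[2],
                       length.out = 101),
    co2_flow_g_min = seq(object$bounds$co2_flow[1], object$bounds$co2_flow[2],
                         length.out = 101)
  )
  betas <- lapply(fits, natural_coefficients)
  d <- sapply(names(fits), function(nm) {
    desirability_score(eval_quad(betas[[nm]], grid$pressure_bar,
                                 grid$co2_flow_g_min), specs[[nm]])
  })
  grid$D <- apply(d, 1, function(row) {
    if (any(row == 0)) 0 else exp(mean(log(row)))
  })
  ggplot2::ggplot(grid, ggplot2::aes(.data$pressure_bar,
                                     .data$co2_flow_g_min)) +
    ggplot2::geom_contour_filled(ggplot2::aes(z = .data$D)) +
    ggplot2::geom_point(data = object$optimum, colour = "red", size = 3) +
    ggplot2::labs(x = "Pressure (bar)", y = expression(CO[2]~flow~(g/min)),
                  fill = "D")
}
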