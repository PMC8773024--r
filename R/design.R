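#' Specify a two-factor central composite design
#'
#' A rotatable-style central composite design (CCD) for two factors is built
#' from four factorial points (coded (+/-1, +/-1)), four axial points at the
#' star level, and replicated center points. Natural factor levels are given
#' verbatim per coded level rather than derived from a star distance, so
#' designs whose published level tables round the axial settings are
#' reproduced exactly as printed.
#'
#' @param pressure,co2_flow Numeric vectors of length 5: the natural levels
#'   of each factor at the coded levels in `coded_levels`, strictly
#'   increasing.
#' @param coded_levels The five coded levels, low star to high star.
#' @param center_replicates Number of center-point replicates.
#' @return An object of class `ccd_spec`.
#' @seealso [generate_ccd()], [calendula_design()]
#' @export
ccd_spec <- function(pressure, co2_flow,
                     coded_levels = c(-1.44, -1, 0, 1, 1.44),
                     center_replicates = 5) {
  levels <- list(pressure_bar = pressure, co2_flow_g_min = co2_flow)
  if (length(coded_levels) != 5 || is.unsorted(coded_levels, strictly = TRUE)) {
    stop_input("`coded_levels` must be 5 strictly increasing values.")
  }
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    if (length(lv) != 5 || anyNA(lv)) {
      stop_input(sprintf("`%s` must map all five coded levels.", nm))
    }
    if (is.unsorted(lv, strictly = TRUE)) {
      stop_input(sprintf("`%s` levels must be strictly increasing.", nm))
    }
  }
  check_number(center_replicates, "center_replicates", min = 1)
  structure(
    list(levels = levels, coded_levels = coded_levels,
         center_replicates = as.integer(center_replicates)),
    class = "ccd_spec"
  )
}

#' @export
print.ccd_spec <- function(x, ...) {
  cat("Central composite design (2 factors)\n")
  tab <- rbind(coded = x$coded_levels,
               pressure_bar = x$levels$pressure_bar,
               co2_flow_g_min = x$levels$co2_flow_g_min)
  print(tab)
  cat(x$center_replicates, "center replicate(s);",
      4 + 4 + x$center_replicates, "runs total\n")
  invisible(x)
}

#' The pressure / CO2-flow design of the calendula fractionation study
#'
#' Factor levels of the 13-run CCD used to map antisolvent-fractionation
#' yields and enrichments: pressure 80-160 bar, CO2 flow 10-60 g/min, five
#' center replicates at (120 bar, 35 g/min).
#'
#' @return A [ccd_spec()] object.
#' @export
calendula_design <- function() {
  ccd_spec(pressure = c(80, 92, 120, 148, 160),
           co2_flow = c(10, 17, 35, 53, 60))
}

#' Generate the run table of a central composite design
#'
#' Expands a [ccd_spec()] into its run list: 4 factorial + 4 axial +
#' center replicates, in a run order shuffled deterministically by `seed`
#' (experiments are conventionally executed in random order to guard
#' against drift).
#'
#' @param spec A [ccd_spec()].
#' @param seed Integer seed for the run-order shuffle, or `NULL` to keep the
#'   systematic order (factorial, axial, center).
#' @return A tibble with columns `run_id`, `coded_pressure`, `coded_co2_flow`,
#'   `pressure_bar`, `co2_flow_g_min`.
#' @examples
#' generate_ccd(calendula_design(), seed = 1)
#' @export
generate_ccd <- function(spec, seed = NULL) {
  if (!inherits(spec, "ccd_spec")) stop_input("`spec` must be a `ccd_spec`.")
  cl <- spec$coded_levels
  lo <- cl[1]; m1 <- cl[2]; ct <- cl[3]; p1 <- cl[4]; hi <- cl[5]
  pts <- rbind(
    expand.grid(c1 = c(m1, p1), c2 = c(m1, p1)),                 # factorial
    data.frame(c1 = c(lo, hi, ct, ct), c2 = c(ct, ct, lo, hi)),  # axial
    data.frame(c1 = rep(ct, spec$center_replicates),
               c2 = rep(ct, spec$center_replicates))             # center
  )
  nat <- function(code, factor) {
    spec$levels[[factor]][match(code, cl)]
  }
  tab <- tibble(
    coded_pressure = pts$c1,
    coded_co2_flow = pts$c2,
    pressure_bar = nat(pts$c1, "pressure_bar"),
    co2_flow_g_min = nat(pts$c2, "co2_flow_g_min")
  )
  ord <- seq_len(nrow(tab))
  if (!is.null(seed)) {
    ord <- withr::with_seed(as.integer(seed), sample(ord))
  }
  tab <- tab[ord, ]
  tab$run_id <- seq_len(nrow(tab))
  dplyr::relocate(tab, "run_id")
}
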