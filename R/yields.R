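#' Extraction yield from collected masses
#'
#' Total recovery of an extraction step, expressed as a weight percentage of
#' the material charged into the extractor. Covers both the single-collector
#' case (one extract mass) and processes that split the extract over several
#' collection vessels.
#'
#' @param collected_masses Numeric vector of collected masses (g), one per
#'   collection vessel. All must be non-negative.
#' @param load_mass Mass (g) of dried plant material (or extract) charged;
#'   must be strictly positive.
#' @return Yield in wt% (0-100 scale): `100 * sum(collected_masses) / load_mass`.
#' @examples
#' extraction_yield(c(4.15, 4.15), 100) # 8.3 wt%
#' @export
extraction_yield <- function(collected_masses, load_mass) {
  check_number(collected_masses, "collected_masses", min = 0)
  check_number(load_mass, "load_mass", min = 0, strict = TRUE)
  100 * sum(collected_masses) / load_mass
}

#' Fraction recovery yield
#'
#' Mass recovery of a single fractionation vessel (precipitation or
#' downstream) relative to the mass of extract contained in the feed
#' solution processed.
#'
#' @param fraction_mass Collected mass (g) in the vessel; non-negative.
#'   Vectorized.
#' @param fs_extract_mass Mass (g) of extract in the feed solution; strictly
#'   positive.
#' @return Yield in wt%: `100 * fraction_mass / fs_extract_mass`.
#' @export
fraction_yield <- function(fraction_mass, fs_extract_mass) {
  check_number(fraction_mass, "fraction_mass", min = 0)
  check_number(fs_extract_mass, "fs_extract_mass", min = 0, strict = TRUE)
  100 * fraction_mass / fs_extract_mass
}

#' Overall fractionation yield
#'
#' The overall recovery of the antisolvent fractionation step is the sum of
#' the precipitation-vessel and downstream-vessel yields.
#'
#' @param y_pv,y_dv Vessel yields in wt%; non-negative. Vectorized.
#' @return `y_pv + y_dv` in wt%.
#' @examples
#' overall_yield(30.9, 42.8) # 73.7
#' @export
overall_yield <- function(y_pv, y_dv) {
  check_number(y_pv, "y_pv", min = 0)
  check_number(y_dv, "y_dv", min = 0)
  y_pv + y_dv
}

#' Compound concentration in a fraction
#'
#' @param mass_compound Mass (g) of the compound contained in the fraction;
#'   must lie in `[0, mass_fraction]`.
#' @param mass_fraction Mass (g) of the fraction; strictly positive.
#' @return Concentration in wt%.
#' @export
concentration <- function(mass_compound, mass_fraction) {
  check_number(mass_compound, "mass_compound", min = 0)
  check_number(mass_fraction, "mass_fraction", min = 0, strict = TRUE)
  if (any(mass_compound > mass_fraction)) {
    stop_domain("`mass_compound` cannot exceed `mass_fraction`.")
  }
  100 * mass_compound / mass_fraction
}

#' Enrichment ratio of a compound in a fraction
#'
#' Concentration of a compound in a collected fraction divided by its
#' concentration in the feed solution. Values above 1 indicate enrichment,
#' below 1 depletion.
#'
#' @param c_fraction Concentration (wt%) in the fraction; non-negative.
#' @param c_fs Concentration (wt%) in the feed solution; strictly positive.
#' @return Dimensionless ratio. Vectorized.
#' @export
enrichment_ratio <- function(c_fraction, c_fs) {
  check_number(c_fraction, "c_fraction", min = 0)
  check_number(c_fs, "c_fs", min = 0, strict = TRUE)
  c_fraction / c_fs
}

#' Joint enrichment ratio of several compounds
#'
#' Ratio of the summed concentrations of a set of compounds in a fraction to
#' their summed concentrations in the feed solution. This is the
#' concentration-weighted mean of the individual enrichment ratios, so it
#' always lies between their minimum and maximum.
#'
#' @param c_fraction Named numeric vector of per-compound concentrations
#'   (wt%) in the fraction.
#' @param c_fs Named numeric vector of per-compound feed-solution
#'   concentrations (wt%); same names as `c_fraction`, summing to > 0.
#' @return Dimensionless ratio `sum(c_fraction) / sum(c_fs)`.
#' @examples
#' total_enrichment(c(A = 3, B = 1, C = 0), c(A = 1, B = 1, C = 2)) # 1
#' @export
total_enrichment <- function(c_fraction, c_fs) {
  if (is.null(names(c_fraction)) || is.null(names(c_fs)) ||
      !setequal(names(c_fraction), names(c_fs)) ||
      anyDuplicated(names(c_fraction)) || anyDuplicated(names(c_fs))) {
    stop_input("`c_fraction` and `c_fs` must carry the same compound names.")
  }
  c_fs <- c_fs[names(c_fraction)]
  check_number(c_fraction, "c_fraction", min = 0)
  check_number(c_fs, "c_fs", min = 0)
  if (sum(c_fs) <= 0) {
    stop_domain("Feed-solution concentrations must sum to > 0.")
  }
  sum(c_fraction) / sum(c_fs)
}

#' Check run tables for yield mass-balance violations
#'
#' Flags runs whose reported overall yield disagrees with the sum of the
#' vessel yields by more than `tolerance`. The default tolerance of 0.05 wt%
#' is one half-unit of the last digit at which yields are customarily
#' reported (0.1 wt%).
#'
#' @param runs A data frame with columns `y_pv_pct`, `y_dv_pct`, `y_saf_pct`
#'   (and typically `run_id`), e.g. from [read_saf_runs()].
#' @param tolerance Allowed absolute discrepancy in wt%.
#' @return A tibble of the violating rows with an extra `discrepancy` column
#'   (signed, `y_saf_pct - (y_pv_pct + y_dv_pct)`); zero rows when the table
#'   balances.
#' @export
validate_mass_balance <- function(runs, tolerance = 0.05) {
  runs <- as_tibble(runs)
  needed <- c("y_pv_pct", "y_dv_pct", "y_saf_pct")
  missing <- setdiff(needed, names(runs))
  if (length(missing)) {
    stop_input(paste0("`runs` is missing column(s): ",
                      paste(missing, collapse = ", "), "."))
  }
  check_number(tolerance, "tolerance", min = 0)
  runs |>
    dplyr::mutate(discrepancy = .data$y_saf_pct -
                    (.data$y_pv_pct + .data$y_dv_pct)) |>
    dplyr::filter(abs(.data$discrepancy) > tolerance)
}
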