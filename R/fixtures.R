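extdata <- function(file) {
  path <- system.file("extdata", file, package = "safskin")
  if (path == "") {
    abort(paste0("Packaged data file not found: ", file),
          class = "safskin_input_error")
  }
  path
}

#' The 13-run calendula fractionation dataset
#'
#' Pressure and CO2 flow conditions, vessel and overall yields (wt%) and
#' precipitate enrichment ratios of chlorogenic (CHA), caffeic (CAF) and
#' ferulic (FA) acid for every run of the packaged central-composite
#' campaign on a defatted *Calendula officinalis* ethanolic extract.
#' `run_order` records the randomized order in which the experiments were
#' executed.
#'
#' @return A 13-row tibble; see [read_saf_runs()] for the columns.
#' @export
calendula_runs <- function() {
  read_saf_runs(extdata("saf_runs.csv"))
}

#' Epidermal resistance profiles of the three tracked antioxidants
#'
#' Per-compartment intercellular and transcellular resistances (s/m) of
#' caffeic, chlorogenic and ferulic acid in the four-layer epidermis model,
#' as computed by a continuum-solvation membrane method (aqueous vehicle,
#' fully hydrated skin).
#'
#' @return A 12-row tibble in the [skin_permeability()] input layout.
#' @export
calendula_profiles <- function() {
  read_resistance_profiles(extdata("resistance_profiles.csv"))
}

#' Published model summaries for the calendula study
#'
#' Reference values used by [reproduce_report()] to document how closely the
#' package's refits reproduce the published analysis: `reported_rsm()`
#' returns the published quadratic-model coefficients, p-values, R2 and
#' residual standard deviations per response (long format; `value` is `NA`
#' for terms excluded from a response's model), and
#' `reported_permeability()` the published combined resistances,
#' permeability coefficients and the reference log Kp values (calculated
#' epidermis and Caco-2 measurements) per compound.
#'
#' @return A tibble.
#' @export
reported_rsm <- function() {
  df <- read_csv_strict(extdata("reported_rsm.csv"))
  df$value <- parse_numeric_column(df$value, "value", allow_na = TRUE)
  df$p_value <- parse_numeric_column(df$p_value, "p_value", allow_na = TRUE)
  df
}

#' @rdname reported_rsm
#' @export
reported_permeability <- function() {
  df <- read_csv_strict(extdata("reported_permeability.csv"))
  for (col in setdiff(names(df), "compound")) {
    df[[col]] <- parse_numeric_column(df[[col]], col, allow_na = TRUE)
  }
  df
}

# published joint optimum of the yield/enrichment desirability search
reported_optimum <- function() {
  tibble(pressure_bar = 153, co2_flow_g_min = 42, D = 0.673)
}

# term sets with which each published response model was fit
reported_term_sets <- function() {
  list(
    y_pv_pct = "no_q2",
    y_dv_pct = "full",
    y_saf_pct = "full",
    e_cha_pv = "no_interaction",
    e_fa_pv = "no_interaction",
    e_all_pv = "no_interaction"
  )
}
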