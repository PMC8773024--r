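# published quadratic coefficients used as known inputs in several tests

published_y_saf <- function() {
  quad_surface(c(intercept = 242.6, pressure = -2.343, co2_flow = -3.835,
                 pressure2 = 0.00717, co2_flow2 = 0.00812,
                 `pressure:co2_flow` = 0.0252),
               response = "y_saf_pct")
}

published_e_all <- function() {
  quad_surface(c(intercept = -3.840, pressure = 0.0802, co2_flow = 0.0166,
                 pressure2 = -0.000308, co2_flow2 = -0.000264),
               response = "e_all_pv")
}

all_quad_terms <- c("intercept", "pressure", "co2_flow",
                    "pressure2", "co2_flow2", "pressure:co2_flow")

# expand a partial coefficient vector to all six terms (zeros elsewhere)
complete_beta_for_test <- function(beta) {
  out <- stats::setNames(numeric(6), all_quad_terms)
  out[names(beta)] <- beta
  out
}

# run table loaded once, without the (intentional) mass-balance warnings
fixture_runs <- function() {
  suppressWarnings(calendula_runs())
}
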