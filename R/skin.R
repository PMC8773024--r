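# epidermal compartments, outermost to innermost
skin_compartments <- c("SC", "SG", "SS", "SB")

#' Combine the two permeation pathways of one compartment
#'
#' Each epidermal compartment is crossed either between the cells
#' (intercellular) or through them (transcellular); the two routes act in
#' parallel, so their resistances combine harmonically. A blocked pathway is
#' represented by an infinite resistance.
#'
#' @param r_inter,r_trans Pathway resistances (s/m), strictly positive;
#'   `Inf` allowed. Vectorized.
#' @return Combined compartment resistance (s/m), never larger than either
#'   arm.
#' @examples
#' combine_pathways(1.26e8, 1.34e7) # stratum granulosum, caffeic acid
#' @export
combine_pathways <- function(r_inter, r_trans) {
  check_number(r_inter, "r_inter", min = 0, strict = TRUE, allow_inf = TRUE)
  check_number(r_trans, "r_trans", min = 0, strict = TRUE, allow_inf = TRUE)
  1 / (1 / r_inter + 1 / r_trans)
}

#' Serial resistance of the stratified cell layers
#'
#' The four epidermal compartments (stratum corneum, granulosum, spinosum,
#' basale) are crossed in sequence, so their combined resistances add.
#'
#' @param r_sc,r_sg,r_ss,r_sb Combined compartment resistances (s/m),
#'   strictly positive; `Inf` allowed. Vectorized.
#' @return Total stratified-cells resistance (s/m).
#' @export
stratified_resistance <- function(r_sc, r_sg, r_ss, r_sb) {
  for (nm in c("r_sc", "r_sg", "r_ss", "r_sb")) {
    check_number(get(nm), nm, min = 0, strict = TRUE, allow_inf = TRUE)
  }
  r_sc + r_sg + r_ss + r_sb
}

#' Total skin resistance including the shunt pathway
#'
#' Hair follicles and glands offer a parallel route past the stratified cell
#' layers, modeled as a fixed conductance.
#'
#' @param r_cells Stratified-cells resistance (s/m), strictly positive.
#' @param shunt_conductance Shunt conductance `1/R_shunt` (m/s),
#'   non-negative; default `2e-11` m/s.
#' @return Overall skin resistance (s/m), never larger than `r_cells`.
#' @export
skin_resistance <- function(r_cells, shunt_conductance = 2e-11) {
  check_number(r_cells, "r_cells", min = 0, strict = TRUE, allow_inf = TRUE)
  check_number(shunt_conductance, "shunt_conductance", min = 0)
  1 / (1 / r_cells + shunt_conductance)
}

#' Log permeability coefficient from a resistance
#'
#' The permeability coefficient is the reciprocal of the resistance; with
#' resistances in s/m this gives m/s, which is converted to the customary
#' cm/s before taking the base-10 logarithm: `log10(100 / r)`.
#'
#' @param r Resistance (s/m), strictly positive. Vectorized.
#' @return log10 permeability in cm/s.
#' @examples
#' log_permeability(7.74e7) # about -5.89
#' @export
log_permeability <- function(r) {
  check_number(r, "r", min = 0, strict = TRUE, allow_inf = TRUE)
  log10(100 / r)
}

#' Offset-corrected log permeability
#'
#' Predicted epidermal permeabilities carry a constant systematic offset
#' relative to measured values; the correction is additive on the log scale
#' (default `-1.12` log10 cm/s units).
#'
#' @param logkp_pred Predicted log10 permeability (cm/s). Vectorized.
#' @param offset Additive offset (log10 cm/s).
#' @return Corrected log10 permeability (cm/s).
#' @export
corrected_log_permeability <- function(logkp_pred, offset = -1.12) {
  check_number(logkp_pred, "logkp_pred")
  check_number(offset, "offset")
  logkp_pred + offset
}

#' Deviation of a reference permeability from a prediction
#'
#' Signed difference `reference - logkp_corrected`: positive when the
#' reference system is more permeable than predicted for skin.
#'
#' @param logkp_corrected Corrected predicted log10 permeability (cm/s).
#' @param reference Reference log10 permeability (cm/s), e.g. a Caco-2 or
#'   calculated-epidermis value. Vectorized.
#' @return Dimensionless deviation.
#' @export
deviation_vs_reference <- function(logkp_corrected, reference) {
  check_number(logkp_corrected, "logkp_corrected")
  if (!is.numeric(reference)) {
    stop_input("`reference` must be numeric.") # NA allowed: missing reference
  }
  reference - logkp_corrected
}

#' Default parameter set of the epidermal resistance model
#'
#' @param shunt_conductance Shunt conductance (m/s).
#' @param offset Log-scale correction applied to predictions (log10 cm/s).
#' @param log_kd Desquamation rate coefficient (log10 m/s): skin turnover
#'   against which a permeant's corrected permeability is compared.
#' @param log_k_vehicle_water Log partition coefficient of the vehicle
#'   against water (0 for aqueous vehicles); shifts the predicted log
#'   permeability additively.
#' @param vehicle Vehicle label.
#' @return Named list of model constants.
#' @export
skin_params <- function(shunt_conductance = 2e-11, offset = -1.12,
                        log_kd = -9, log_k_vehicle_water = 0,
                        vehicle = "water") {
  check_number(shunt_conductance, "shunt_conductance", min = 0)
  check_number(offset, "offset")
  check_number(log_kd, "log_kd")
  check_number(log_k_vehicle_water, "log_k_vehicle_water")
  list(shunt_conductance = shunt_conductance, offset = offset,
       log_kd = log_kd, log_k_vehicle_water = log_k_vehicle_water,
       vehicle = vehicle)
}

#' Full epidermal permeability analysis of resistance profiles
#'
#' Composes the compartmental network for each compound: parallel
#' inter/transcellular combination per compartment, serial stacking of the
#' four compartments, parallel shunt, conversion to a log permeability
#' coefficient, and the constant offset correction. Alongside the numbers it
#' reports, per compound, the rate-limiting compartment (largest combined
#' resistance; ties go to the outermost layer, which the permeant meets
#' first), the preferred pathway of each compartment (the arm with the
#' smaller resistance; ties count as intercellular), and a safety
#' classification: permeants stopped at the stratum corneum are
#' `"retained in SC"`; ones that penetrate deeper but whose corrected
#' permeability (converted to m/s) stays below the desquamation rate
#' coefficient are `"safe - below desquamation"` since shedding outpaces
#' penetration; anything faster is `"flag for review"`.
#'
#' @param profiles Data frame with columns `compound`, `compartment`
#'   (`"SC"`, `"SG"`, `"SS"`, `"SB"`), `r_inter_s_per_m`,
#'   `r_trans_s_per_m`; exactly one row per compound and compartment.
#'   `Inf` marks a blocked pathway. See [read_resistance_profiles()].
#' @param params Model constants from [skin_params()].
#' @return A tibble of class `skin_permeability`, one row per compound:
#'   `compound`, `r_cells`, `r_skin` (s/m), `log_kp_pred`,
#'   `log_kp_corrected` (log10 cm/s), `rate_limiting`,
#'   `rate_limiting_pathway`, `classification`, and a `layers` list-column
#'   of per-compartment tibbles (`compartment`, `r_inter`, `r_trans`,
#'   `r_combined`, `log_perm_layer` in log10 cm/s, `preferred_pathway`).
#' @examples
#' skin_permeability(calendula_profiles())
#' @export
skin_permeability <- function(profiles, params = skin_params()) {
  profiles <- as_tibble(profiles)
  needed <- c("compound", "compartment", "r_inter_s_per_m", "r_trans_s_per_m")
  missing <- setdiff(needed, names(profiles))
  if (length(missing)) {
    stop_input(paste0("`profiles` is missing column(s): ",
                      paste(missing, collapse = ", "), "."))
  }
  bad <- setdiff(unique(profiles$compartment), skin_compartments)
  if (length(bad)) {
    stop_input(paste0("Unknown compartment(s): ", paste(bad, collapse = ", "),
                      "; expected ", paste(skin_compartments, collapse = ", "), "."))
  }

  one <- function(df) {
    if (!setequal(df$compartment, skin_compartments) ||
        nrow(df) != length(skin_compartments)) {
      stop_input(sprintf(
        "Compound `%s` must have exactly one row per compartment (%s).",
        df$compound[1], paste(skin_compartments, collapse = ", ")))
    }
    df <- df[match(skin_compartments, df$compartment), ]
    layers <- tibble(
      compartment = skin_compartments,
      r_inter = df$r_inter_s_per_m,
      r_trans = df$r_trans_s_per_m,
      r_combined = combine_pathways(df$r_inter_s_per_m, df$r_trans_s_per_m),
      log_perm_layer = log_permeability(
        combine_pathways(df$r_inter_s_per_m, df$r_trans_s_per_m)),
      preferred_pathway = ifelse(df$r_inter_s_per_m <= df$r_trans_s_per_m,
                                 "inter", "trans")
    )
    r_cells <- stratified_resistance(layers$r_combined[1],
                                     layers$r_combined[2],
                                     layers$r_combined[3],
                                     layers$r_combined[4])
    r_skin <- skin_resistance(r_cells, params$shunt_conductance)
    log_kp_pred <- log_permeability(r_skin) + params$log_k_vehicle_water
    log_kp_corr <- corrected_log_permeability(log_kp_pred, params$offset)
    rl <- which.max(layers$r_combined) # first max = outermost on ties
    classification <- if (skin_compartments[rl] == "SC") {
      "retained in SC"
    } else if (log_kp_corr - 2 < params$log_kd) {
      # corrected value is in cm/s; -2 converts to m/s for the comparison
      "safe - below desquamation"
    } else {
      "flag for review"
    }
    tibble(
      compound = df$compound[1],
      r_cells = r_cells, r_skin = r_skin,
      log_kp_pred = log_kp_pred, log_kp_corrected = log_kp_corr,
      rate_limiting = skin_compartments[rl],
      rate_limiting_pathway = layers$preferred_pathway[rl],
      classification = classification,
      layers = list(layers)
    )
  }

  out <- profiles |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_split() |>
    purrr::map(one) |>
    purrr::list_rbind()
  # preserve input compound order
  out <- out[match(unique(profiles$compound), out$compound), ]
  class(out) <- c("skin_permeability", class(out))
  out
}

#' @describeIn skin_permeability Long per-compartment table (one row per
#'   compound and layer) with the compound-level summaries joined on.
#' @param x A `skin_permeability` result.
#' @param ... Unused.
#' @export
tidy.skin_permeability <- function(x, ...) {
  x |>
    as_tibble() |>
    dplyr::select("compound", "layers") |>
    tidyr::unnest("layers")
}

#' @describeIn skin_permeability Per-layer resistance chart (log10 scale) by
#'   compound.
#' @param object A `skin_permeability` result.
#' @export
autoplot.skin_permeability <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::mutate(compartment = factor(.data$compartment,
                                       levels = skin_compartments))
  ggplot2::ggplot(long, ggplot2::aes(.data$compartment,
                                     log10(.data$r_combined),
                                     fill = .data$preferred_pathway)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~compound) +
    ggplot2::labs(x = "Compartment", y = "log10 resistance (s/m)",
                  fill = "pathway")
}
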