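# strict numeric parsing for file ingest: normalizes unicode minus signs,
# accepts `inf`/blank as infinity/NA where allowed, and reports the first
# offending row on failure.
parse_numeric_column <- function(x, col, allow_na = FALSE, allow_inf = FALSE) {
  x <- trimws(gsub("−", "-", x))
  out <- rep(NA_real_, length(x))
  blank <- is.na(x) | x == ""
  isinf <- !blank & tolower(x) %in% c("inf", "infinite", "∞")
  num <- suppressWarnings(as.numeric(x))
  out[!blank & !isinf] <- num[!blank & !isinf]
  out[isinf] <- Inf
  bad <- !blank & !isinf & is.na(num)
  if (any(bad)) {
    abort(sprintf("Column `%s`, row %d: cannot parse \"%s\" as a number.",
                  col, which(bad)[1], x[which(bad)[1]]),
          class = "safskin_parse_error")
  }
  if (!allow_na && any(blank)) {
    abort(sprintf("Column `%s`, row %d: value is missing.",
                  col, which(blank)[1]),
          class = "safskin_parse_error")
  }
  if (!allow_inf && any(isinf)) {
    abort(sprintf("Column `%s`, row %d: infinite value not allowed.",
                  col, which(isinf)[1]),
          class = "safskin_parse_error")
  }
  out
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "safskin_input_error")
  }
  df <- tryCatch(
    suppressWarnings(readr::read_csv(
      path, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE)),
    error = function(e) {
      abort(paste0("Cannot parse `", path, "`: ", conditionMessage(e)),
            class = "safskin_parse_error")
    })
  if (ncol(df) == 0 || nrow(df) == 0) {
    abort(paste0("`", path, "` contains no data rows."),
          class = "safskin_parse_error")
  }
  df
}

#' Read a fractionation run table
#'
#' Reads a CSV run table with columns `run_id`, `pressure_bar`,
#' `co2_flow_g_min`, `y_pv_pct`, `y_dv_pct`, `y_saf_pct` and the enrichment
#' columns `e_cha_pv`, `e_caf_pv`, `e_fa_pv`, `e_all_pv` (blank enrichment
#' cells are allowed and read as `NA`). The yield mass balance is checked on
#' load and any violation is reported as a warning, never an error.
#'
#' @param path Path to the CSV file.
#' @param tolerance Mass-balance tolerance (wt%) passed to
#'   [validate_mass_balance()].
#' @return A tibble, one row per run.
#' @examples
#' runs <- read_saf_runs(system.file("extdata", "saf_runs.csv",
#'                                   package = "safskin"))
#' @export
read_saf_runs <- function(path, tolerance = 0.05) {
  df <- read_csv_strict(path)
  required <- c("run_id", "pressure_bar", "co2_flow_g_min",
                "y_pv_pct", "y_dv_pct", "y_saf_pct")
  enrich <- c("e_cha_pv", "e_caf_pv", "e_fa_pv", "e_all_pv")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Run table is missing column(s): ",
                 paste(missing, collapse = ", "), "."),
          class = "safskin_parse_error")
  }
  for (col in intersect(c(required, enrich, "run_order"), names(df))) {
    df[[col]] <- parse_numeric_column(df[[col]], col,
                                      allow_na = col %in% enrich)
  }
  viol <- validate_mass_balance(df, tolerance = tolerance)
  if (nrow(viol)) {
    warn(sprintf(
      "Mass-balance violation in run(s) %s: |y_saf - (y_pv + y_dv)| > %g wt%%.",
      paste(viol$run_id, collapse = ", "), tolerance))
  }
  df
}

#' Write a fractionation run table
#'
#' @param runs Run tibble as returned by [read_saf_runs()].
#' @param path Output CSV path.
#' @return `runs`, invisibly.
#' @export
write_saf_runs <- function(runs, path) {
  readr::write_csv(as_tibble(runs), path, na = "")
  invisible(runs)
}

#' Read compartmental resistance profiles
#'
#' Reads a CSV with columns `compound`, `compartment` (SC, SG, SS, SB),
#' `r_inter_s_per_m`, `r_trans_s_per_m`. A blank cell or the token `inf`
#' marks a blocked pathway (infinite resistance).
#'
#' @param path Path to the CSV file.
#' @return A tibble suitable for [skin_permeability()].
#' @export
read_resistance_profiles <- function(path) {
  df <- read_csv_strict(path)
  required <- c("compound", "compartment", "r_inter_s_per_m",
                "r_trans_s_per_m")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Profile table is missing column(s): ",
                 paste(missing, collapse = ", "), "."),
          class = "safskin_parse_error")
  }
  for (col in c("r_inter_s_per_m", "r_trans_s_per_m")) {
    x <- parse_numeric_column(df[[col]], col, allow_na = TRUE,
                              allow_inf = TRUE)
    x[is.na(x)] <- Inf
    df[[col]] <- x
  }
  df
}

#' Write compartmental resistance profiles
#'
#' Infinite resistances are written as the token `inf`.
#'
#' @param profiles Profile tibble.
#' @param path Output CSV path.
#' @return `profiles`, invisibly.
#' @export
write_resistance_profiles <- function(profiles, path) {
  out <- as_tibble(profiles)
  for (col in c("r_inter_s_per_m", "r_trans_s_per_m")) {
    out[[col]] <- ifelse(is.infinite(out[[col]]), "inf",
                         format(out[[col]], digits = 15, trim = TRUE,
                                scientific = NA))
  }
  readr::write_csv(out, path, na = "")
  invisible(profiles)
}

#' Read skin-model constants from JSON
#'
#' @param path Path to a JSON object with any of the fields of
#'   [skin_params()]; absent fields keep their defaults.
#' @return A [skin_params()] list.
#' @export
read_skin_params <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "safskin_input_error")
  }
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(skin_params, vals[intersect(names(vals), names(formals(skin_params)))])
}

#' Serialize a response-surface fit to JSON
#'
#' Writes term names, coefficient estimates with standard errors and
#' p-values (in the units of the fit), the natural-unit coefficient vector,
#' and the fit summaries, so a fit can be re-used for prediction and
#' optimization without the raw data.
#'
#' @param fit A [fit_response_surface()] result.
#' @param path Output JSON path.
#' @return `fit`, invisibly.
#' @export
write_rsm_fit <- function(fit, path) {
  if (!inherits(fit, "saf_rsm")) stop_input("`fit` must be an `saf_rsm`.")
  co <- tidy(fit)
  g <- glance(fit)
  obj <- list(
    response = fit$response,
    units = fit$units,
    terms = co$term,
    coefficients = setNames(as.list(co$estimate), co$term),
    std_error = setNames(as.list(co$std.error), co$term),
    p_value = setNames(as.list(co$p.value), co$term),
    natural_coefficients = as.list(natural_coefficients(fit)),
    r2_pct = g$r.squared.pct,
    s = g$sigma,
    df_residual = g$df.residual
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(fit)
}

#' Read a serialized response-surface fit
#'
#' @param path JSON path written by [write_rsm_fit()].
#' @return A [quad_surface()] carrying the natural-unit coefficients (only
#'   the terms that were active in the fit).
#' @export
read_rsm_fit <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "safskin_input_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$natural_coefficients)
  quad_surface(beta[obj$terms], response = obj$response)
}
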