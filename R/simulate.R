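#' Simulate a fractionation run table from a known surface
#'
#' Emulates the measurement model behind a CCD campaign: the response at
#' each design point is the quadratic surface mean plus independent
#' homoscedastic Gaussian noise. Simulated yields that come out negative are
#' clipped to zero (a mass fraction cannot be negative) and flagged.
#'
#' @param truth A [quad_surface()] (or named coefficient vector) giving the
#'   true response surface.
#' @param sigma Noise standard deviation (response units), >= 0.
#' @param spec Design to simulate over, a [ccd_spec()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param response Name for the simulated response column.
#' @return A tibble with `run_id`, `pressure_bar`, `co2_flow_g_min`, the
#'   response column, and `clipped` (logical).
#' @examples
#' truth <- quad_surface(c(intercept = 242.6, pressure = -2.343,
#'                         co2_flow = -3.835, pressure2 = 0.00717,
#'                         co2_flow2 = 0.00812, `pressure:co2_flow` = 0.0252))
#' simulate_saf_table(truth, sigma = 2.66, seed = 7)
#' @export
simulate_saf_table <- function(truth, sigma, spec = calendula_design(),
                               seed = 1, response = "y_sim") {
  if (is.numeric(truth)) truth <- quad_surface(truth)
  if (!inherits(truth, "quad_surface")) {
    stop_input("`truth` must be a quad_surface or named coefficient vector.")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    stop_input("`sigma` must be a single non-negative number.")
  }
  design <- generate_ccd(spec)
  mu <- predict_surface(truth, design$pressure_bar, design$co2_flow_g_min,
                        warn_extrapolation = FALSE)
  y <- withr::with_seed(as.integer(seed), mu + rnorm(length(mu), sd = sigma))
  clipped <- y < 0
  if (any(clipped)) {
    warn(sprintf("%d simulated value(s) were negative and clipped to 0.",
                 sum(clipped)))
    y[clipped] <- 0
  }
  design |>
    dplyr::select("run_id", "pressure_bar", "co2_flow_g_min") |>
    dplyr::mutate(!!response := y, clipped = clipped)
}

#' Simulate random layered resistance profiles
#'
#' Draws intercellular and transcellular resistances independently and
#' log-uniformly within per-compartment ranges — a broad, scale-free prior
#' over physically plausible layered barriers, useful for property testing
#' of the resistance network.
#'
#' @param n Number of profiles.
#' @param ranges Named list with one `c(lower, upper)` range (s/m, both
#'   > 0) per compartment `SC`, `SG`, `SS`, `SB`; the same range is used for
#'   both pathways of the compartment.
#' @param seed Integer seed.
#' @return A tibble in the [skin_permeability()] input layout (`compound`
#'   is `"sim_001"`, ... ), `4 * n` rows.
#' @export
simulate_profiles <- function(n = 1,
                              ranges = list(SC = c(1e6, 1e12),
                                            SG = c(1e6, 1e12),
                                            SS = c(1e6, 1e12),
                                            SB = c(1e6, 1e12)),
                              seed = 1) {
  check_number(n, "n", min = 1)
  if (!setequal(names(ranges), skin_compartments)) {
    stop_input("`ranges` must name exactly the compartments SC, SG, SS, SB.")
  }
  for (nm in skin_compartments) {
    r <- ranges[[nm]]
    if (length(r) != 2 || anyNA(r) || r[1] <= 0 || r[1] > r[2]) {
      stop_input(sprintf("`ranges$%s` must be 0 < lower <= upper.", nm))
    }
  }
  lo <- log10(vapply(ranges[skin_compartments], `[[`, numeric(1), 1))
  hi <- log10(vapply(ranges[skin_compartments], `[[`, numeric(1), 2))
  base <- tidyr::expand_grid(
    compound = sprintf("sim_%03d", seq_len(n)),
    compartment = skin_compartments
  )
  idx <- match(base$compartment, skin_compartments)
  withr::with_seed(as.integer(seed), {
    base$r_inter_s_per_m <- 10^runif(nrow(base), lo[idx], hi[idx])
    base$r_trans_s_per_m <- 10^runif(nrow(base), lo[idx], hi[idx])
  })
  base
}
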