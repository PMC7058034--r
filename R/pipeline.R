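#' Simulate one plate end to end
#'
#' Samples a colony population at the given concentration and renders it,
#' using an RNG stream derived from the configuration's master seed and the
#' plate index, so any plate of a simulated experiment can be regenerated
#' independently and bit-identically.
#'
#' @param config A [sim_config()] object.
#' @param concentration Concentration (mM); defaults to the lowest grid
#'   value.
#' @param plate_index Index of the plate within the experiment (drives the
#'   derived seed).
#' @param n Number of colonies; defaults to `config$colonies_per_plate`.
#' @param brightfield Render the bright-field channel?
#' @return A `plate_image` with ground-truth sidecar.
#' @export
simulate_plate <- function(config = sim_config(),
                           concentration = config$concentration_grid[1],
                           plate_index = 1L,
                           n = config$colonies_per_plate,
                           brightfield = TRUE) {
  config <- validate_sim_config(config)
  # one stream for the population, an offset stream for rendering noise
  conc_i <- match(concentration, config$concentration_grid)
  if (is.na(conc_i)) conc_i <- 0L
  base <- conc_i * 10000L + plate_index
  pop_seed <- derive_seed(config$seed, base)
  rend_seed <- derive_seed(config$seed, base + 500000L)
  colonies <- sample_colony_population(concentration, n, config,
                                       seed = pop_seed)
  render_plate(colonies, config, seed = rend_seed,
               plate_id = sprintf("c%g_p%d", concentration, plate_index),
               brightfield = brightfield)
}

#' Run the full colony heterogeneity pipeline on simulated plates
#'
#' Convenience wrapper for simulation studies: renders `plates_per_conc`
#' plates at each requested concentration, detects colonies, classifies
#' them with a mixture threshold fitted on the pooled lowest-concentration
#' colonies, and assembles the dose--response table plus the step and
#' exponential-decline fits.
#'
#' @param config A [sim_config()].
#' @param concentrations Concentrations to simulate (defaults to the whole
#'   grid).
#' @param plates_per_conc Plates per concentration.
#' @param params [detect_params()].
#' @param fit_curves Also fit the step and decline curves?
#' @return List with `records` (classified colony records), `threshold`,
#'   `mixture` (the mixture fit), `dose` (dose--response table), and when
#'   `fit_curves` is `TRUE` also `step` and `switch_fit` (the latter `NULL`
#'   when no sectored colony was observed).
#' @export
run_simulation_study <- function(config = sim_config(),
                                 concentrations = config$concentration_grid,
                                 plates_per_conc = 1L,
                                 params = detect_params(),
                                 fit_curves = TRUE) {
  recs <- list()
  for (x in concentrations) {
    for (p in seq_len(plates_per_conc)) {
      plate <- simulate_plate(config, concentration = x, plate_index = p,
                              brightfield = FALSE)
      recs[[length(recs) + 1L]] <- detect_colonies(plate, params)
    }
  }
  records <- do.call(rbind, recs)
  if (nrow(records) == 0L) stop("no colonies detected on any plate")
  low <- records[records$concentration_mM == min(concentrations), ]
  mix <- fit_intensity_mixture(low$mean_fluor, seed = config$seed)
  records <- classify_colonies(records, mix$threshold)
  dose <- dose_response(records)
  out <- list(records = records, threshold = mix$threshold, mixture = mix,
              dose = dose)
  if (fit_curves) {
    out$step <- if (nrow(dose) >= 4L) fit_step(dose) else NULL
    out$switch_fit <- if (any(dose$frac_sectored > 0) && nrow(dose) >= 3L) {
      tryCatch(fit_switch_decline(dose), error = function(e) NULL)
    } else NULL
  }
  out
}
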