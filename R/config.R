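#' Simulation configuration for synthetic plate experiments
#'
#' Builds the parameter set that defines a simulated colony-plating
#' experiment: the methionine concentration grid, the dose--response truth
#' curves for the fraction of reporter-positive (GFP+) colonies and for the
#' probability of a sectored (phenotype-switched) colony, the per-phenotype
#' colony intensity and diameter models, and the plate-rendering parameters.
#'
#' The defaults emulate the colony-level heterogeneity of a methionine
#' auxotroph carrying a *met*-promoter GFP reporter: roughly 45% of colonies
#' are GFP+ at the lowest methionine concentrations, none at the highest,
#' with a steep decline between; sectored colonies are rare (about 2.5% at
#' the lowest concentration) and their probability decays exponentially with
#' concentration.  GFP+ colonies are slightly larger than GFP- colonies at
#' low methionine.
#'
#' @param concentration_grid Methionine concentrations (mM), strictly
#'   positive and sorted ascending.
#' @param colonies_per_plate Number of colonies placed on one plate.
#' @param truth_plateau Low-concentration probability that a colony is GFP+
#'   (dimensionless, in \[0, 1\]).
#' @param truth_x0 Concentration (mM) at which the GFP+ probability has
#'   fallen to half the plateau.
#' @param truth_k Steepness of the GFP+ decline (per mM).
#' @param sector_alpha Exponential decay rate of the sector probability
#'   (per mM).
#' @param sector_beta Offset (mM) of the sector-probability curve
#'   `exp(-sector_alpha * (x - sector_beta))`.
#' @param sector_pmax Upper clamp on the sector probability.
#' @param intensity_model Named list with elements `gfp_neg` and `gfp_pos`,
#'   each `c(log_mean, log_sd)` of the log-normal colony mean fluorescence
#'   (arbitrary units on a 16-bit scale).
#' @param diameter_model Named list with elements `gfp_neg_base` (mm),
#'   `gfp_neg_conc_gain` (mm; saturating increase of GFP- diameter with
#'   concentration), `gfp_pos` (mm) and `sd` (mm).
#' @param artifact_rate Expected number of irregular non-colony blobs per
#'   plate (Poisson mean).
#' @param noise_sd Additive Gaussian pixel noise (a.u.).
#' @param background_level Background fluorescence level (a.u.).
#' @param background_gradient Fractional linear increase of the background
#'   across the image columns (dimensionless).
#' @param pixel_size Physical pixel size (mm per px).
#' @param image_size Side length of the square plate raster (px).
#' @param min_center_distance Minimum distance between colony centers (px);
#'   must exceed twice the largest expected colony radius so that colonies
#'   never merge.
#' @param sector_arc_range Range (degrees) from which the angular size of a
#'   sector wedge is drawn.
#' @param edge_width_frac Width of the cosine-tapered colony edge as a
#'   fraction of the colony radius.
#' @param bf_background,bf_colony Bright-field background and colony levels
#'   (a.u.).
#' @param seed Master RNG seed; per-plate streams are derived from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [dose_response_truth()], [sample_colony_population()],
#'   [render_plate()]
#' @export
#' @examples
#' cfg <- sim_config()
#' cfg$concentration_grid
sim_config <- function(concentration_grid = c(0.025, 0.05, 0.1, 0.25, 0.5,
                                              0.75, 1, 2.5, 5, 10),
                       colonies_per_plate = 80,
                       truth_plateau = 0.45,
                       truth_x0 = 0.75,
                       truth_k = 10,
                       sector_alpha = 1.34,
                       sector_beta = -2.7279,
                       sector_pmax = 0.03,
                       intensity_model = list(
                         gfp_neg = c(log_mean = log(10000), log_sd = 0.12),
                         gfp_pos = c(log_mean = log(20000), log_sd = 0.12)),
                       diameter_model = list(
                         gfp_neg_base = 1.8,
                         gfp_neg_conc_gain = 0.4,
                         gfp_pos = 2.0,
                         sd = 0.12),
                       artifact_rate = 3,
                       noise_sd = 200,
                       background_level = 500,
                       background_gradient = 0.2,
                       pixel_size = 0.05,
                       image_size = 1200,
                       min_center_distance = 60,
                       sector_arc_range = c(40, 180),
                       edge_width_frac = 0.15,
                       bf_background = 30000,
                       bf_colony = 45000,
                       seed = 1L) {
  cfg <- list(concentration_grid = as.numeric(concentration_grid),
              colonies_per_plate = as.integer(colonies_per_plate),
              truth_plateau = truth_plateau,
              truth_x0 = truth_x0,
              truth_k = truth_k,
              sector_alpha = sector_alpha,
              sector_beta = sector_beta,
              sector_pmax = sector_pmax,
              intensity_model = intensity_model,
              diameter_model = diameter_model,
              artifact_rate = artifact_rate,
              noise_sd = noise_sd,
              background_level = background_level,
              background_gradient = background_gradient,
              pixel_size = pixel_size,
              image_size = as.integer(image_size),
              min_center_distance = min_center_distance,
              sector_arc_range = sector_arc_range,
              edge_width_frac = edge_width_frac,
              bf_background = bf_background,
              bf_colony = bf_colony,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- cfg$concentration_grid
  if (length(x) < 1L) stop("concentration grid must be non-empty")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("concentrations must be finite and strictly positive")
  }
  if (is.unsorted(x, strictly = TRUE)) {
    stop("concentration grid must be sorted strictly ascending")
  }
  probs <- c(cfg$truth_plateau, cfg$sector_pmax)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  sds <- c(cfg$intensity_model$gfp_neg["log_sd"],
           cfg$intensity_model$gfp_pos["log_sd"],
           cfg$diameter_model$sd, cfg$noise_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  if (cfg$colonies_per_plate < 0) stop("colonies_per_plate must be >= 0")
  # overlap guard: min_center_distance must exceed twice the largest radius
  # any colony can realistically reach (mean + 4 sd, plus the taper overhang)
  max_diam <- max(cfg$diameter_model$gfp_pos,
                  cfg$diameter_model$gfp_neg_base +
                    cfg$diameter_model$gfp_neg_conc_gain) +
    4 * cfg$diameter_model$sd
  max_r_px <- (max_diam / 2 / cfg$pixel_size) * (1 + cfg$edge_width_frac / 2)
  if (cfg$min_center_distance <= 2 * max_r_px) {
    stop("min_center_distance must exceed twice the maximum expected ",
         "colony radius (", round(2 * max_r_px, 1), " px)")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic plate simulation configuration\n")
  cat("  concentrations (mM): ", paste(x$concentration_grid, collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  colonies/plate: %d   image: %d x %d px (%.3f mm/px)\n",
              x$colonies_per_plate, x$image_size, x$image_size, x$pixel_size))
  cat(sprintf("  GFP+ truth: plateau %.3f, midpoint %.3g mM, steepness %.3g/mM\n",
              x$truth_plateau, x$truth_x0, x$truth_k))
  cat(sprintf("  sector truth: exp(-%.3g (x - %.4g)), clamped at %.3g\n",
              x$sector_alpha, x$sector_beta, x$sector_pmax))
  cat(sprintf("  master seed: %d\n", x$seed))
  invisible(x)
}

# Derive an independent, reproducible sub-seed for stream `index` from a
# master seed.  Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 1000003) %%
               2147483647)
}
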