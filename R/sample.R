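#' Sample a ground-truth colony population for one plate
#'
#' Draws the latent state of every colony on a plate: phenotype (i.i.d.
#' Bernoulli with the concentration-dependent GFP+ probability), log-normal
#' mean fluorescence per phenotype, normal diameter per phenotype truncated
#' at > 0, Bernoulli sector flags, and non-overlapping center positions
#' obtained by rejection sampling with a hard minimum center distance.
#'
#' @param concentration Methionine concentration (mM).
#' @param n Number of colonies (>= 0).
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed; when given the draw is fully
#'   reproducible.
#' @return A data frame of class `colony_truth` with one row per colony and
#'   columns `center_row`, `center_col` (px, 0-based, fractional),
#'   `radius_px`, `diameter_mm`, `phenotype` (`"GFP+"`/`"GFP-"`),
#'   `mean_fluor` (a.u.), `sectored` (logical), `sector_arc_deg`,
#'   `sector_start_deg`, `sector_fluor` (intensity of the wedge, drawn from
#'   the opposite phenotype's component).  The concentration, the truth
#'   probabilities used, and the realized sector count are attached as
#'   attributes `concentration`, `p_gfp_pos`, `p_sector`, `n_sectored`.
#' @export
sample_colony_population <- function(concentration, n, config = sim_config(),
                                     seed = NULL) {
  config <- validate_sim_config(config)
  stopifnot(length(concentration) == 1L, concentration > 0, n >= 0)
  n <- as.integer(n)
  draw <- function() {
    p_pos <- gfp_pos_prob(concentration, config)
    p_sec <- sector_prob(concentration, config)
    phenotype <- ifelse(stats::rbinom(n, 1L, p_pos) == 1L, "GFP+", "GFP-")
    im <- config$intensity_model
    lm_ <- ifelse(phenotype == "GFP+", im$gfp_pos["log_mean"],
                  im$gfp_neg["log_mean"])
    ls_ <- ifelse(phenotype == "GFP+", im$gfp_pos["log_sd"],
                  im$gfp_neg["log_sd"])
    mean_fluor <- stats::rlnorm(n, lm_, ls_)
    dmn <- diameter_mean(phenotype, concentration, config)
    diameter <- stats::rnorm(n, dmn, config$diameter_model$sd)
    bad <- which(diameter <= 0)
    for (i in bad) {  # truncation at > 0 by redraw
      repeat {
        d <- stats::rnorm(1, dmn[i], config$diameter_model$sd)
        if (d > 0) { diameter[i] <- d; break }
      }
    }
    radius_px <- diameter / 2 / config$pixel_size
    sectored <- stats::rbinom(n, 1L, p_sec) == 1L
    sector_arc <- ifelse(sectored,
                         stats::runif(n, config$sector_arc_range[1],
                                      config$sector_arc_range[2]), 0)
    sector_start <- ifelse(sectored, stats::runif(n, 0, 360), 0)
    lm_opp <- ifelse(phenotype == "GFP+", im$gfp_neg["log_mean"],
                     im$gfp_pos["log_mean"])
    ls_opp <- ifelse(phenotype == "GFP+", im$gfp_neg["log_sd"],
                     im$gfp_pos["log_sd"])
    sector_fluor <- ifelse(sectored, stats::rlnorm(n, lm_opp, ls_opp), NA_real_)

    centers <- place_centers(n, radius_px, config)
    out <- data.frame(center_row = centers$row, center_col = centers$col,
                      radius_px = radius_px, diameter_mm = diameter,
                      phenotype = phenotype, mean_fluor = mean_fluor,
                      sectored = sectored, sector_arc_deg = sector_arc,
                      sector_start_deg = sector_start,
                      sector_fluor = sector_fluor,
                      stringsAsFactors = FALSE)
    attr(out, "concentration") <- concentration
    attr(out, "p_gfp_pos") <- p_pos
    attr(out, "p_sector") <- p_sec
    attr(out, "n_sectored") <- sum(sectored)
    class(out) <- c("colony_truth", "data.frame")
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Rejection-sample n colony centers inside the raster so that no colony
# (including its tapered edge) is clipped by the border and all pairwise
# center distances are >= min_center_distance.  Errors if the plate cannot
# hold n colonies after a bounded number of attempts.
place_centers <- function(n, radius_px, config, extra = NULL,
                          max_tries = 2000L) {
  L <- config$image_size
  rows <- numeric(0); cols <- numeric(0)
  if (!is.null(extra)) { rows <- extra$row; cols <- extra$col }
  n_fixed <- length(rows)
  if (n == 0L) return(list(row = numeric(0), col = numeric(0)))
  overhang <- 1 + config$edge_width_frac / 2
  for (i in seq_len(n)) {
    margin <- radius_px[i] * overhang + 6  # keep clear of the border filter
    if (2 * margin >= L) stop("plate too small to place colony of radius ",
                              round(radius_px[i], 1), " px")
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, margin, L - 1 - margin)
      c_ <- stats::runif(1, margin, L - 1 - margin)
      if (length(rows) == 0 ||
          all((rows - r)^2 + (cols - c_)^2 >=
              config$min_center_distance^2)) {
        rows <- c(rows, r); cols <- c(cols, c_); ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", n, " non-overlapping colonies on a ",
                  L, "x", L, " plate (min_center_distance = ",
                  config$min_center_distance, " px)")
  }
  keep <- seq.int(n_fixed + 1L, length(rows))
  list(row = rows[keep], col = cols[keep], all_row = rows, all_col = cols)
}
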