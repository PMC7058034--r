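#' Probability that a colony is GFP+ at a given concentration
#'
#' Generator truth for the dose--response of the reporter-positive colony
#' fraction: a logistic decline `plateau / (1 + exp(k * (x - x0)))`, equal to
#' the plateau at low concentration and (numerically) zero at the highest.
#'
#' @param x Methionine concentration(s), mM.
#' @param config A [sim_config()] object.
#' @return Probabilities in \[0, 1\], same length as `x`.
#' @export
gfp_pos_prob <- function(x, config = sim_config()) {
  z <- pmin(700, config$truth_k * (x - config$truth_x0))
  config$truth_plateau / (1 + exp(z))
}

#' Probability that a colony is sectored at a given concentration
#'
#' Generator truth for the phenotype-switching (sector) probability: an
#' exponential decline `exp(-alpha * (x - beta))` clamped to
#' \[0, `sector_pmax`\].  Under the default parameters the probability is
#' 2.5% at 0.025 mM and falls below 1e-7 at 10 mM.
#'
#' @inheritParams gfp_pos_prob
#' @return Probabilities in \[0, `sector_pmax`\], same length as `x`.
#' @export
sector_prob <- function(x, config = sim_config()) {
  p <- exp(-config$sector_alpha * (x - config$sector_beta))
  pmin(pmax(p, 0), config$sector_pmax)
}

#' Per-concentration ground-truth dose--response table
#'
#' Evaluates the generator truth curves on the configured concentration
#' grid.  Both the GFP+ probability and the sector probability are monotone
#' non-increasing in concentration.
#'
#' @param config A [sim_config()] object.
#' @return A data frame with columns `concentration_mM`, `p_gfp_pos`,
#'   `p_sector`.
#' @export
#' @examples
#' dose_response_truth(sim_config())
dose_response_truth <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  x <- config$concentration_grid
  data.frame(concentration_mM = x,
             p_gfp_pos = gfp_pos_prob(x, config),
             p_sector = sector_prob(x, config))
}

# Mean colony diameter (mm) for a phenotype at a concentration.  GFP-
# colonies grow larger at high methionine; GFP+ colonies (present only at
# low methionine) are slightly larger than GFP- colonies there.
diameter_mean <- function(phenotype, x, config) {
  dm <- config$diameter_model
  ifelse(phenotype == "GFP+", dm$gfp_pos,
         dm$gfp_neg_base + dm$gfp_neg_conc_gain * x / (x + 1))
}
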