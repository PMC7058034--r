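#' Background-corrected, growth-normalized reporter signal
#'
#' Normalizes a plate-reader fluorescence time series by the matched
#' optical-density series: both signals are corrected for the medium
#' background and the ratio `(RFU - RFU_bg) / (OD - OD_bg)` is returned
#' pointwise.  Points where the corrected OD does not exceed `od_floor`
#' are masked (`NA`) rather than producing unstable ratios.
#'
#' @param rfu Fluorescence series (relative fluorescence units).
#' @param od Optical density series (OD600), aligned with `rfu`.
#' @param rfu_background,od_background Medium background values.
#' @param od_floor Minimum corrected OD for a point to be used.
#' @return Numeric vector of RFU/OD600 values with masked points `NA`.
#' @export
#' @examples
#' normalize_plate_reader(1000, 0.5, rfu_background = 100,
#'                        od_background = 0.05)
normalize_plate_reader <- function(rfu, od, rfu_background = 0,
                                   od_background = 0, od_floor = 0.01) {
  if (length(rfu) != length(od)) {
    stop("rfu and od series must have the same length")
  }
  num <- rfu - rfu_background
  den <- od - od_background
  out <- ifelse(den > od_floor, num / den, NA_real_)
  as.numeric(out)
}
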