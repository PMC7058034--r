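#' Algebraic least-squares circle fit to a region boundary
#'
#' Fits a circle through boundary pixels by the algebraic (Kasa)
#' least-squares method: minimizing the algebraic distance reduces to one
#' linear solve, which is exact for points lying on a true circle and very
#' close to the geometric fit for the near-circular, low-noise boundaries
#' produced by colony segmentation.  Because boundary pixel centers sit on
#' average half a pixel inside the true contour, half a pixel is added to
#' the fitted radius.
#'
#' @param region Either a `region_set` row context -- a two-column matrix of
#'   0-based boundary coordinates `(row, col)` as stored in
#'   `region_set$boundaries` -- or a `region_set` with exactly one region.
#' @param poor_fit_ratio Flag the fit as poor when the radial RMS residual
#'   exceeds this fraction of the radius.
#' @param raster_correction Added to the fitted radius to compensate for
#'   boundary pixel centers lying inside the true contour.  Use 0 when the
#'   input points are exact (non-rasterized) coordinates.
#' @return An object of class `circle_fit`: list with `center` (named,
#'   0-based `(row, col)`, fractional), `radius` (px), `residual` (radial
#'   RMS, px), `n_points`, `poor_fit` (logical).
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 40)[-40]
#' pts <- cbind(row = 20 + 7 * sin(th), col = 30 + 7 * cos(th))
#' fit_circle(pts, raster_correction = 0)
fit_circle <- function(region, poor_fit_ratio = 0.15,
                       raster_correction = 0.5) {
  pts <- if (inherits(region, "region_set")) {
    if (length(region$boundaries) != 1L) {
      stop("region_set must contain exactly one region")
    }
    region$boundaries[[1]]
  } else region
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2)
  pts <- unique(pts)
  y <- pts[, 1]; x <- pts[, 2]
  if (nrow(pts) < 3L) stop("degenerate circle fit: fewer than 3 boundary points")
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3L) stop("degenerate circle fit: boundary points are collinear")
  sol <- qr.coef(qrA, rhs)
  cx <- sol[1]; cy <- sol[2]
  r2 <- sol[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) stop("degenerate circle fit")
  r <- sqrt(r2)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  resid <- sqrt(mean((d - r)^2))
  out <- list(center = c(row = unname(cy), col = unname(cx)),
              radius = unname(r) + raster_correction,
              residual = unname(resid),
              n_points = nrow(pts),
              poor_fit = resid / r > poor_fit_ratio)
  class(out) <- "circle_fit"
  out
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf(
    "circle fit: center (row %.2f, col %.2f), radius %.2f px, RMS %.3f px (%d pts)%s\n",
    x$center["row"], x$center["col"], x$radius, x$residual, x$n_points,
    if (x$poor_fit) " [poor fit]" else ""))
  invisible(x)
}
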