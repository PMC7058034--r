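#' Angular sector score of a colony
#'
#' Scores evidence of a phenotype switch (a sector) within a detected
#' colony.  The disk is divided into `n_bins` angular bins; the score is
#' the Michelson-style contrast `(max bin mean - min bin mean) /
#' (max bin mean + min bin mean)`.  The colony is flagged sectored when the
#' score reaches `s_thresh` *and* the bins above the midline
#' `(max + min)/2` form a single contiguous circular arc covering between
#' `arc_range[1]` and `arc_range[2]` of the circle: a genuine sector is one
#' coherent wedge, not scattered speckle.
#'
#' @param image A `plate_image` or numeric matrix of fluorescence.
#' @param circle A `circle_fit` (or list with `center` `(row, col)` and
#'   `radius`).
#' @param n_bins Number of angular bins.
#' @param s_thresh Minimum score for the sectored flag.
#' @param arc_range Admissible fractional arc coverage of the above-midline
#'   bins.
#' @return List with `score`, `sectored` (logical), `arc_fraction`,
#'   `border_clipped` (logical; when `TRUE` the score is `NA` and no call
#'   is made).
#' @export
sector_score <- function(image, circle, n_bins = 36L, s_thresh = 0.3,
                         arc_range = c(0.1, 0.9)) {
  m <- if (inherits(image, "plate_image")) image$fluor else image
  cr <- circle$center["row"]; cc <- circle$center["col"]; R <- circle$radius
  if (cr - R < 0 || cc - R < 0 ||
      cr + R > nrow(m) - 1 || cc + R > ncol(m) - 1) {
    return(list(score = NA_real_, sectored = NA, arc_fraction = NA_real_,
                border_clipped = TRUE))
  }
  r0 <- max(0, floor(cr - R)); r1 <- min(nrow(m) - 1, ceiling(cr + R))
  c0 <- max(0, floor(cc - R)); c1 <- min(ncol(m) - 1, ceiling(cc + R))
  rr <- r0:r1; cl <- c0:c1
  dr <- outer(rr - cr, rep(1, length(cl)))
  dc <- outer(rep(1, length(rr)), cl - cc)
  d <- sqrt(dr^2 + dc^2)
  inside <- d <= R
  th <- (atan2(dr[inside], dc[inside]) * 180 / pi) %% 360
  bin <- pmin(floor(th / (360 / n_bins)) + 1L, n_bins)
  vals <- m[rr + 1L, cl + 1L, drop = FALSE][inside]
  bm <- rep(NA_real_, n_bins)
  agg <- tapply(vals, bin, mean)
  bm[as.integer(names(agg))] <- agg
  bm <- bm[!is.na(bm)]
  hi <- max(bm); lo <- min(bm)
  score <- if (hi + lo <= 0) 0 else (hi - lo) / (hi + lo)
  above <- bm > (hi + lo) / 2
  arc_frac <- mean(above)
  contiguous <- n_circular_runs(above) == 1L
  sectored <- score >= s_thresh && contiguous &&
    arc_frac >= arc_range[1] && arc_frac <= arc_range[2]
  list(score = unname(score), sectored = sectored,
       arc_fraction = unname(arc_frac), border_clipped = FALSE)
}

# Number of runs of TRUE in a logical vector regarded as circular.
n_circular_runs <- function(x) {
  if (!any(x)) return(0L)
  if (all(x)) return(1L)
  starts <- sum(x & !c(x[length(x)], x[-length(x)]))
  as.integer(starts)
}
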