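#' Render a plate image from a ground-truth colony population
#'
#' Draws each colony as a disk with a flat center and a cosine-tapered edge.
#' The taper spans `edge_width_frac * radius` centered on the nominal
#' radius, so the half-intensity contour of the rendered colony coincides
#' with the ground-truth radius; this makes threshold-based detection
#' unbiased by construction.  Sectored colonies receive an angular wedge at
#' an intensity drawn from the opposite phenotype's component.  A linear
#' background gradient, Gaussian pixel noise, and a Poisson number of
#' irregular random-walk artifact blobs (circularity well below the colony
#' range) are added.  An optional bright-field raster with the same
#' geometry is rendered alongside.
#'
#' @param colonies A `colony_truth` data frame from
#'   [sample_colony_population()].
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed controlling noise and artifacts.
#' @param plate_id Identifier stored in the ground-truth sidecar.
#' @param brightfield Render the bright-field channel too?
#' @return An object of class `plate_image`: a list with integer matrices
#'   `fluor` (and optionally `bf`) in \[0, 65535\], `pixel_size` (mm/px),
#'   `concentration` (mM), `plate_id`, and `truth` (the sidecar: colony
#'   table plus artifact count).
#' @export
render_plate <- function(colonies, config = sim_config(), seed = NULL,
                         plate_id = "plate_1", brightfield = TRUE) {
  config <- validate_sim_config(config)
  stopifnot(inherits(colonies, "data.frame"))
  run <- function() {
    L <- config$image_size
    grad <- config$background_level * config$background_gradient *
      (seq_len(L) - 1) / max(L - 1, 1)
    bg <- matrix(rep(grad, each = L), L, L) + config$background_level
    fluor <- bg
    bf <- if (brightfield) matrix(config$bf_background, L, L) else NULL
    w <- config$edge_width_frac / 2
    for (i in seq_len(nrow(colonies))) {
      cr <- colonies$center_row[i]; cc <- colonies$center_col[i]
      R <- colonies$radius_px[i]
      rout <- R * (1 + w)
      r0 <- max(0L, floor(cr - rout)); r1 <- min(L - 1L, ceiling(cr + rout))
      c0 <- max(0L, floor(cc - rout)); c1 <- min(L - 1L, ceiling(cc + rout))
      rr <- r0:r1; cc_ <- c0:c1
      dr <- outer(rr - cr, rep(1, length(cc_)))
      dc <- outer(rep(1, length(rr)), cc_ - cc)
      d <- sqrt(dr^2 + dc^2)
      prof <- cosine_profile(d, R, w)
      level <- matrix(colonies$mean_fluor[i], length(rr), length(cc_))
      if (isTRUE(colonies$sectored[i]) && colonies$sector_arc_deg[i] > 0) {
        th <- (atan2(dr, dc) * 180 / pi) %% 360
        rel <- (th - colonies$sector_start_deg[i]) %% 360
        level[rel < colonies$sector_arc_deg[i]] <- colonies$sector_fluor[i]
      }
      sub <- fluor[rr + 1L, cc_ + 1L, drop = FALSE]
      fluor[rr + 1L, cc_ + 1L] <- sub + (level - sub) * prof
      if (brightfield) {
        sb <- bf[rr + 1L, cc_ + 1L, drop = FALSE]
        bf[rr + 1L, cc_ + 1L] <- sb + (config$bf_colony - sb) * prof
      }
    }
    n_art <- stats::rpois(1, config$artifact_rate)
    art <- draw_artifacts(n_art, colonies, config)
    if (length(art$idx)) {
      fluor[art$idx] <- art$level
      if (brightfield) bf[art$idx] <- config$bf_colony
    }
    if (config$noise_sd > 0) {
      fluor <- fluor + stats::rnorm(L * L, 0, config$noise_sd)
      if (brightfield) bf <- bf + stats::rnorm(L * L, 0, config$noise_sd)
    }
    clamp16 <- function(m) {
      m <- round(m); m[m < 0] <- 0; m[m > 65535] <- 65535
      storage.mode(m) <- "integer"; m
    }
    truth <- list(plate_id = plate_id,
                  concentration_mM = attr(colonies, "concentration"),
                  pixel_size = config$pixel_size,
                  image_size = L,
                  n_colonies = nrow(colonies),
                  n_sectored = sum(colonies$sectored),
                  n_artifacts = n_art,
                  colonies = as.data.frame(colonies))
    out <- list(fluor = clamp16(fluor),
                bf = if (brightfield) clamp16(bf) else NULL,
                pixel_size = config$pixel_size,
                concentration = attr(colonies, "concentration"),
                plate_id = plate_id,
                truth = truth)
    class(out) <- "plate_image"
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Radial profile: 1 inside R*(1-w), cosine taper to 0 at R*(1+w).  The
# half-intensity point sits exactly at d = R.
cosine_profile <- function(d, R, w) {
  lo <- R * (1 - w); hi <- R * (1 + w)
  p <- matrix(0, nrow(d), ncol(d))
  p[d <= lo] <- 1
  tz <- d > lo & d < hi
  p[tz] <- 0.5 * (1 + cos(pi * (d[tz] - lo) / (hi - lo)))
  p
}

# Irregular bright blobs built from thickened random walks; their
# circularity is far below the colony range, so the shape filter must
# reject them.  Returns linear pixel indices and an intensity.
draw_artifacts <- function(n_art, colonies, config) {
  L <- config$image_size
  if (n_art == 0L) return(list(idx = integer(0), level = numeric(0)))
  idx <- integer(0)
  occupied <- list(row = colonies$center_row, col = colonies$center_col)
  for (a in seq_len(n_art)) {
    ok <- FALSE
    for (try in 1:200) {
      r <- stats::runif(1, 40, L - 41); c_ <- stats::runif(1, 40, L - 41)
      if (!length(occupied$row) ||
          all((occupied$row - r)^2 + (occupied$col - c_)^2 >=
              config$min_center_distance^2)) { ok <- TRUE; break }
    }
    if (!ok) next
    occupied$row <- c(occupied$row, r); occupied$col <- c(occupied$col, c_)
    # persistent-direction walk: an elongated strand, never a compact clump,
    # so artifact circularity stays far below the colony range
    steps <- 150L
    theta <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(steps - 1, 0, 0.25)))
    pr <- pmin(pmax(round(r + cumsum(sin(theta))), round(r) - 22L),
               round(r) + 22L)
    pc <- pmin(pmax(round(c_ + cumsum(cos(theta))), round(c_) - 22L),
               round(c_) + 22L)
    pr <- pmin(pmax(pr, 2L), L - 3L)
    pc <- pmin(pmax(pc, 2L), L - 3L)
    # thicken the trail to a 3x3 brush so the blob has interior area
    off <- expand.grid(or = -1:1, oc = -1:1)
    allr <- rep(pr, each = nrow(off)) + off$or
    allc <- rep(pc, each = nrow(off)) + off$oc
    idx <- c(idx, unique(allr + 1L + allc * L))
  }
  list(idx = unique(idx), level = stats::rlnorm(1, log(12000), 0.2))
}
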