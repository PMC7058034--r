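#' Detection parameters
#'
#' Bundles the tunable parameters of the colony-detection pipeline.  The
#' region filters follow the size-and-shape removal step of the detection
#' algorithm: colonies are large, near-circular regions, so small specks,
#' merged blobs and elongated artifacts are rejected before circle fitting.
#'
#' @param level Optional fixed binarization threshold (normalized \[0, 1\]);
#'   `NULL` selects Otsu's method.
#' @param min_area,max_area Region area bounds (px^2).
#' @param min_circularity Minimum circularity `4*pi*A/P^2`.
#' @param border_margin Minimum distance (px) from the image border.
#' @param poor_fit_ratio Residual/radius ratio above which a circle fit is
#'   flagged poor.
#' @param n_bins,s_thresh,arc_range Sector-score settings, see
#'   [sector_score()].
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(level = NULL, min_area = pi * 5^2,
                          max_area = pi * 150^2, min_circularity = 0.8,
                          border_margin = 5, poor_fit_ratio = 0.15,
                          n_bins = 36L, s_thresh = 0.3,
                          arc_range = c(0.1, 0.9)) {
  structure(list(level = level, min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 border_margin = border_margin,
                 poor_fit_ratio = poor_fit_ratio, n_bins = n_bins,
                 s_thresh = s_thresh, arc_range = arc_range),
            class = "detect_params")
}

#' Detect colonies on a plate image
#'
#' Runs the five-step detection algorithm: (1) binarize the fluorescence
#' image, (2) remove wrongly segmented regions by size, shape and border
#' proximity, (3) fit a circle to each remaining region boundary, (4) score
#' each colony for sectors (phenotype switches) -- manual curation can then
#' be applied with [apply_curation()] -- and (5) summarize each colony:
#' center, radius, diameter in mm, and mean fluorescence over the fitted
#' disk.
#'
#' @param image A `plate_image`.
#' @param params A [detect_params()] object.
#' @return A data frame of colony records with columns `plate_id`,
#'   `colony_id`, `concentration_mM`, `center_row_px`, `center_col_px`,
#'   `radius_px`, `diameter_mm`, `mean_fluor`, `sector_score`, `sectored`,
#'   `qc_flags` (semicolon-separated; empty when clean).
#' @export
detect_colonies <- function(image, params = detect_params()) {
  stopifnot(inherits(image, "plate_image"))
  mask <- binarize(image, level = params$level)
  regions <- extract_regions(mask)
  kept <- filter_regions(regions, min_area = params$min_area,
                         max_area = params$max_area,
                         min_circularity = params$min_circularity,
                         border_margin = params$border_margin)
  tab <- kept$table
  n <- nrow(tab)
  rec <- empty_colony_table()
  if (n == 0L) return(rec)
  m <- image$fluor
  for (i in seq_len(n)) {
    flags <- character(0)
    fit <- tryCatch(
      fit_circle(kept$boundaries[[i]],
                 poor_fit_ratio = params$poor_fit_ratio),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$poor_fit) flags <- c(flags, "poor-fit")
    sc <- sector_score(m, fit, n_bins = params$n_bins,
                       s_thresh = params$s_thresh,
                       arc_range = params$arc_range)
    if (isTRUE(sc$border_clipped)) flags <- c(flags, "border-clipped")
    rr <- refine_radius(m, fit$center["row"], fit$center["col"], fit$radius)
    fit$radius <- rr
    mf <- disk_mean(m, fit$center["row"], fit$center["col"], fit$radius)
    rec <- rbind(rec, data.frame(
      plate_id = image$plate_id,
      colony_id = nrow(rec) + 1L,
      concentration_mM = if (is.null(image$concentration)) NA_real_
                         else image$concentration,
      center_row_px = unname(fit$center["row"]),
      center_col_px = unname(fit$center["col"]),
      radius_px = fit$radius,
      diameter_mm = 2 * fit$radius * image$pixel_size,
      mean_fluor = mf,
      sector_score = sc$score,
      sectored = isTRUE(sc$sectored),
      qc_flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE))
  }
  rec$colony_id <- seq_len(nrow(rec))
  rec
}

empty_colony_table <- function() {
  data.frame(plate_id = character(0), colony_id = integer(0),
             concentration_mM = numeric(0), center_row_px = numeric(0),
             center_col_px = numeric(0), radius_px = numeric(0),
             diameter_mm = numeric(0), mean_fluor = numeric(0),
             sector_score = numeric(0), sectored = logical(0),
             qc_flags = character(0), stringsAsFactors = FALSE)
}

# Refine a colony radius to the half-maximum crossing of its radial
# intensity profile.  The binarization threshold sits somewhere on the
# colony's tapered edge, so the segmented footprint (and hence the circle
# fitted to it) depends on where the threshold fell; the half-intensity
# radius is a threshold-independent convention.  Falls back to r0 when no
# clean crossing is found (e.g. truncated profiles near the border).
refine_radius <- function(m, cr, cc, r0) {
  rmax <- 1.5 * r0
  rr0 <- max(0, floor(cr - rmax)); rr1 <- min(nrow(m) - 1, ceiling(cr + rmax))
  cc0 <- max(0, floor(cc - rmax)); cc1 <- min(ncol(m) - 1, ceiling(cc + rmax))
  rows <- rr0:rr1; cols <- cc0:cc1
  d <- sqrt(outer((rows - cr)^2, rep(1, length(cols))) +
              outer(rep(1, length(rows)), (cols - cc)^2))
  v <- m[rows + 1L, cols + 1L, drop = FALSE]
  sel <- d <= rmax
  bins <- floor(d[sel] / 0.5) + 1L
  prof <- tapply(as.numeric(v[sel]), bins, mean)
  mids <- (as.integer(names(prof)) - 0.5) * 0.5
  plateau <- mean(prof[mids < 0.6 * r0])
  bg <- mean(prof[mids > 1.25 * r0])
  if (!is.finite(plateau) || !is.finite(bg) || plateau <= bg) return(r0)
  half <- (plateau + bg) / 2
  idx <- which(mids >= 0.6 * r0)
  below <- idx[prof[idx] < half]
  if (!length(below)) return(r0)
  j <- below[1]
  if (j == 1L) return(r0)
  # linear interpolation between the bracketing profile bins
  x0 <- mids[j - 1]; x1 <- mids[j]
  y0 <- prof[j - 1]; y1 <- prof[j]
  if (y0 == y1) return(r0)
  unname(x0 + (half - y0) / (y1 - y0) * (x1 - x0))
}

# Mean intensity over the disk of radius R around (cr, cc), 0-based.
disk_mean <- function(m, cr, cc, R) {
  r0 <- max(0, floor(cr - R)); r1 <- min(nrow(m) - 1, ceiling(cr + R))
  c0 <- max(0, floor(cc - R)); c1 <- min(ncol(m) - 1, ceiling(cc + R))
  rr <- r0:r1; cl <- c0:c1
  d2 <- outer((rr - cr)^2, rep(1, length(cl))) +
    outer(rep(1, length(rr)), (cl - cc)^2)
  sub <- m[rr + 1L, cl + 1L, drop = FALSE]
  mean(sub[d2 <= R^2])
}

#' Apply a manual curation file to colony records
#'
#' Reproduces the manual-inspection step of the detection workflow: a
#' curation table lists per-colony overrides -- removing wrongly detected
#' colonies, forcing the sectored flag on or off, or explicitly keeping a
#' colony.  Every override leaves a provenance note in `qc_flags`.
#'
#' @param records Colony records from [detect_colonies()].
#' @param curation Data frame with columns `colony_id`, `action` (one of
#'   `keep`, `remove`, `sector_true`, `sector_false`) and optional `note`,
#'   or a path to such a CSV file.
#' @return The curated records.
#' @export
apply_curation <- function(records, curation) {
  if (is.character(curation)) curation <- utils::read.csv(curation)
  stopifnot(all(c("colony_id", "action") %in% names(curation)))
  if (nrow(curation) == 0L) return(records)
  unknown <- setdiff(curation$colony_id, records$colony_id)
  if (length(unknown)) {
    stop("curation refers to unknown colony id(s): ",
         paste(unknown, collapse = ", "))
  }
  bad <- setdiff(curation$action,
                 c("keep", "remove", "sector_true", "sector_false"))
  if (length(bad)) stop("unknown curation action(s): ",
                        paste(bad, collapse = ", "))
  add_flag <- function(flags, new) {
    ifelse(nchar(flags) == 0, new, paste(flags, new, sep = ";"))
  }
  for (k in seq_len(nrow(curation))) {
    i <- which(records$colony_id == curation$colony_id[k])
    act <- curation$action[k]
    records$qc_flags[i] <- add_flag(records$qc_flags[i],
                                    paste0("curation:", act))
    if (act == "sector_true") records$sectored[i] <- TRUE
    if (act == "sector_false") records$sectored[i] <- FALSE
  }
  drop <- curation$colony_id[curation$action == "remove"]
  out <- records[!records$colony_id %in% drop, , drop = FALSE]
  attr(out, "removed") <- records[records$colony_id %in% drop, , drop = FALSE]
  out
}
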