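#' Binarize a plate image
#'
#' Converts the fluorescence raster to a black-and-white mask of candidate
#' colony regions.  Intensities are normalized to \[0, 1\] by the 16-bit
#' range; a pixel is included iff its normalized intensity is greater than
#' or equal to the threshold.  When no threshold is given it is chosen by
#' Otsu's two-class variance-maximizing histogram method applied to the
#' log-intensity histogram -- fluorescence spans a multiplicative dynamic
#' range, and on the raw histogram the dominant background class can push
#' the two-class optimum into the dim-colony mode -- and the selected
#' threshold is mapped back to the normalized intensity scale.
#'
#' @param image A `plate_image` (from [render_plate()] or
#'   [read_plate_image()]) or a numeric matrix of raw intensities.
#' @param level Optional normalized threshold in \[0, 1\].
#' @return A logical matrix with attribute `level` (the threshold used).
#' @export
binarize <- function(image, level = NULL) {
  m <- if (inherits(image, "plate_image")) image$fluor else image
  stopifnot(is.matrix(m), length(m) > 0)
  norm <- m / 65535
  if (is.null(level)) {
    if (max(norm) - min(norm) < .Machine$double.eps * 4) {
      stop("no threshold separates classes: image is constant")
    }
    lg <- log1p(pmax(m, 0)) / log1p(65535)
    lv_log <- as.numeric(EBImage::otsu(EBImage::Image(lg),
                                       range = c(0, 1), levels = 65536L))
    level <- expm1(lv_log * log1p(65535)) / 65535
  }
  mask <- norm >= level
  attr(mask, "level") <- level
  mask
}

#' Extract labeled regions and their shape measurements from a binary mask
#'
#' Labels 8-connected foreground components and computes per-region area,
#' centroid, bounding box, perimeter and circularity.  The perimeter is
#' measured by tracing the outer boundary (Moore neighborhood) and summing
#' edge-weighted steps: 1 for orthogonal moves, sqrt(2) for diagonal moves.
#' Circularity is `4*pi*A/P^2`, clamped at 1.05 because the digital
#' estimator can slightly exceed 1 on small round shapes.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return An object of class `region_set`: a list with `table` (data frame
#'   of per-region measures; coordinates 0-based `(row, col)`), `labels`
#'   (the integer label matrix) and `boundaries` (list of 0-based boundary
#'   coordinate matrices, one per region).
#' @export
extract_regions <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- label_8connected(m)
  n_reg <- max(lab)
  if (n_reg == 0L) {
    return(structure(list(table = empty_region_table(), labels = lab,
                          boundaries = list()), class = "region_set"))
  }
  fg <- which(lab > 0L)
  rows0 <- (fg - 1L) %% nrow(lab)        # 0-based row
  cols0 <- (fg - 1L) %/% nrow(lab)       # 0-based col
  labv <- lab[fg]
  area <- tabulate(labv, n_reg)
  cen_r <- vapply(split(rows0, labv), mean, 0)
  cen_c <- vapply(split(cols0, labv), mean, 0)
  bb_r0 <- vapply(split(rows0, labv), min, 0)
  bb_r1 <- vapply(split(rows0, labv), max, 0)
  bb_c0 <- vapply(split(cols0, labv), min, 0)
  bb_c1 <- vapply(split(cols0, labv), max, 0)
  boundaries <- vector("list", n_reg)
  perim <- numeric(n_reg)
  for (i in seq_len(n_reg)) {
    tr <- trace_boundary(lab, i, bb_r0[i], bb_r1[i], bb_c0[i], bb_c1[i])
    boundaries[[i]] <- tr$coords
    perim[i] <- tr$perimeter
  }
  circ <- pmin(4 * pi * area / pmax(perim, 1e-9)^2, 1.05)
  tab <- data.frame(region_id = seq_len(n_reg), area = area,
                    perimeter = perim, centroid_row = cen_r,
                    centroid_col = cen_c, bbox_r0 = bb_r0, bbox_r1 = bb_r1,
                    bbox_c0 = bb_c0, bbox_c1 = bb_c1, circularity = circ,
                    row.names = NULL)
  structure(list(table = tab, labels = lab, boundaries = boundaries),
            class = "region_set")
}

empty_region_table <- function() {
  data.frame(region_id = integer(0), area = numeric(0),
             perimeter = numeric(0), centroid_row = numeric(0),
             centroid_col = numeric(0), bbox_r0 = numeric(0),
             bbox_r1 = numeric(0), bbox_c0 = numeric(0),
             bbox_c1 = numeric(0), circularity = numeric(0))
}

# 8-connected labeling.  EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
label_8connected <- function(m) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m)))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal pairs
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, 0L)
    dense <- match(root, sort(unique(root)))
    lab[lab > 0L] <- dense[lab[lab > 0L]]
  }
  lab
}

# Moore-neighbor boundary trace of region `id` within its bounding box.
# Returns 0-based boundary coordinates in traversal order and the
# edge-weighted perimeter (orthogonal step 1, diagonal step sqrt(2)).
trace_boundary <- function(lab, id, r0, r1, c0, c1) {
  # crop with 1-px pad; work 1-based inside the crop
  sub <- lab[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1), drop = FALSE] == id
  nr <- nrow(sub) + 2L; nc <- ncol(sub) + 2L
  m <- matrix(FALSE, nr, nc); m[2:(nr - 1), 2:(nc - 1)] <- sub
  start <- which(m)[1]  # column-major: uppermost pixel of leftmost column
  sr <- (start - 1L) %% nr + 1L; sc <- (start - 1L) %/% nr + 1L
  # clockwise Moore neighborhood, starting west: (dr, dc)
  nbr <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L, 0L, 1L,
                  1L, 1L, 1L, 0L, 1L, -1L), ncol = 2, byrow = TRUE)
  if (sum(m) == 1L) {
    return(list(coords = cbind(row = sr - 2L + r0, col = sc - 2L + c0),
                perimeter = 4))
  }
  path_r <- integer(0); path_c <- integer(0); perim <- 0
  cur_r <- sr; cur_c <- sc
  dir <- 1L  # scan start: the backtrack direction (west of start)
  cap <- 8L * sum(m) + 16L
  repeat {
    path_r <- c(path_r, cur_r); path_c <- c(path_c, cur_c)
    found <- FALSE
    for (k in 0:7) {
      j <- ((dir - 1L + k) %% 8L) + 1L
      nr_ <- cur_r + nbr[j, 1]; nc_ <- cur_c + nbr[j, 2]
      if (m[nr_, nc_]) {
        perim <- perim + if (nbr[j, 1] != 0 && nbr[j, 2] != 0) sqrt(2) else 1
        # resume the clockwise scan just past the new backtrack pixel
        dir <- ((j - 3L) %% 8L) + 1L
        cur_r <- nr_; cur_c <- nc_
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (cannot happen when area > 1)
    if (cur_r == sr && cur_c == sc) break  # closed the contour
    if (length(path_r) > cap) break        # safety cap
  }
  coords <- unique(cbind(row = path_r, col = path_c))
  list(coords = cbind(row = coords[, 1] - 2L + r0,
                      col = coords[, 2] - 2L + c0),
       perimeter = perim)
}

#' Filter regions by size, shape and border proximity
#'
#' Keeps regions whose area lies in `[min_area, max_area]`, whose
#' circularity is at least `min_circularity`, and whose bounding box is at
#' least `border_margin` pixels from every image edge.  The removal reason
#' for each rejected region is recorded.
#'
#' @param regions A `region_set` from [extract_regions()].
#' @param min_area,max_area Area bounds (px^2).
#' @param min_circularity Minimum circularity (`4*pi*A/P^2`).
#' @param border_margin Minimum distance (px) of the bounding box from the
#'   image border.
#' @return A `region_set` containing the retained regions; the data frame
#'   of removed regions with a `removal_reason` column is attached as
#'   attribute `removed`.
#' @export
filter_regions <- function(regions, min_area = pi * 5^2,
                           max_area = pi * 150^2, min_circularity = 0.8,
                           border_margin = 5) {
  stopifnot(inherits(regions, "region_set"), min_area > 0,
            min_area < max_area)
  tab <- regions$table
  if (nrow(tab) == 0L) return(regions)
  nr <- nrow(regions$labels); nc <- ncol(regions$labels)
  reason <- rep(NA_character_, nrow(tab))
  bad_size <- tab$area < min_area | tab$area > max_area
  bad_shape <- tab$circularity < min_circularity
  bad_border <- tab$bbox_r0 < border_margin | tab$bbox_c0 < border_margin |
    tab$bbox_r1 > nr - 1 - border_margin | tab$bbox_c1 > nc - 1 - border_margin
  reason[bad_border] <- "border"
  reason[bad_shape] <- "shape"
  reason[bad_size] <- "size"   # size takes precedence in the log
  keep <- is.na(reason)
  out <- structure(list(table = tab[keep, , drop = FALSE],
                        labels = regions$labels,
                        boundaries = regions$boundaries[tab$region_id[keep]]),
                   class = "region_set")
  removed <- tab[!keep, , drop = FALSE]
  removed$removal_reason <- reason[!keep]
  attr(out, "removed") <- removed
  out
}
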