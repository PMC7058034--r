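# Independent oracles and fixture builders used across the suite.

# Scaled-down simulation config for unit tests (same statistical structure
# as the default, smaller raster).
test_config <- function(...) {
  args <- utils::modifyList(list(image_size = 700L, colonies_per_plate = 30L,
                                 artifact_rate = 2, seed = 1L), list(...))
  do.call(sim_config, args)
}

# Wrap a bare intensity matrix as a plate image.
as_plate <- function(m, pixel_size = 0.05, concentration = NA_real_,
                     plate_id = "test") {
  storage.mode(m) <- "integer"
  structure(list(fluor = m, bf = NULL, pixel_size = pixel_size,
                 concentration = concentration, plate_id = plate_id,
                 truth = NULL),
            class = "plate_image")
}

# Rasterized disk mask: pixels (0-based) with distance <= R from center.
rasterize_disk <- function(nrow, ncol, cr, cc, R) {
  rows <- matrix(0:(nrow - 1), nrow, ncol)
  cols <- matrix(0:(ncol - 1), nrow, ncol, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= R^2
}

# Connected components by breadth-first flood fill (8-connectivity):
# independent of the package's labeling path.
flood_fill_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && !seen[i, j]) {
      n <- n + 1L
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  n
}

# Exact two-tailed Mann-Whitney p by full enumeration of all
# choose(n1+n2, n1) group assignments of the pooled ranks.
enum_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Tie-free samples realizing a target Mann-Whitney U: give the i-th of the
# n1 x-ranks a non-decreasing offset into the y-ranks summing to U.
samples_with_u <- function(n1, n2, U) {
  off <- integer(n1); rem <- U
  for (i in n1:1) { off[i] <- min(n2, rem); rem <- rem - off[i] }
  rx <- seq_len(n1) + off
  list(x = rx, y = setdiff(seq_len(n1 + n2), rx))
}

# Match detected records to ground-truth colonies by nearest center.
match_truth <- function(records, truth, max_dist = 5) {
  if (nrow(records) == 0L || nrow(truth) == 0L) {
    return(list(matched = integer(0), dist = numeric(0),
                n_false = nrow(records)))
  }
  d <- outer(records$center_row_px, truth$center_row, "-")^2 +
    outer(records$center_col_px, truth$center_col, "-")^2
  nearest <- apply(d, 1, which.min)
  mind <- sqrt(apply(d, 1, min))
  ok <- mind <= max_dist
  list(matched = nearest[ok], dist = mind[ok], n_false = sum(!ok),
       detected_of = length(unique(nearest[ok])))
}
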