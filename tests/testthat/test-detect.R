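test_that("binarize applies the >= convention and handles empty/constant images", {
  m <- matrix(1000L, 20, 20)
  # all background, high level: nothing above threshold
  expect_true(!any(binarize(as_plate(m), level = 0.5)))
  # pixel exactly at the threshold is included
  lvl <- 1000 / 65535
  expect_true(all(binarize(as_plate(m), level = lvl)))
  # constant image with unset level cannot be split into two classes
  expect_error(binarize(as_plate(m)), "no threshold")
  # with an explicit level a constant image is fine
  expect_true(all(binarize(as_plate(m), level = 0)))
})

test_that("binarize + labeling recover five disjoint disks", {
  m <- matrix(500L, 220, 220)
  centers <- cbind(c(40, 40, 110, 180, 180), c(40, 180, 110, 40, 180))
  for (i in 1:5) {
    m[rasterize_disk(220, 220, centers[i, 1], centers[i, 2], 15)] <- 20000L
  }
  mask <- binarize(as_plate(m))
  expect_identical(flood_fill_count(mask), 5L)  # independent BFS oracle
  expect_identical(nrow(extract_regions(mask)$table), 5L)
})

test_that("region extraction measures areas and uses 8-connectivity", {
  expect_identical(nrow(extract_regions(matrix(FALSE, 10, 10))$table), 0L)
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  expect_equal(extract_regions(sq)$table$area, 100)
  diagpx <- matrix(FALSE, 6, 6); diagpx[2, 2] <- TRUE; diagpx[3, 3] <- TRUE
  expect_identical(nrow(extract_regions(diagpx)$table), 1L)
})

test_that("filter_regions removes squares, lines and undersized regions with reasons", {
  # large square: digital circularity ~ pi/4, removed at 0.8
  sq <- matrix(FALSE, 220, 220); sq[11:210, 11:210] <- TRUE
  rs <- extract_regions(sq)
  expect_equal(rs$table$circularity, pi / 4, tolerance = 0.015)
  kept <- filter_regions(rs, min_area = 100, max_area = 1e5,
                         min_circularity = 0.8, border_margin = 5)
  expect_identical(nrow(kept$table), 0L)
  expect_identical(attr(kept, "removed")$removal_reason, "shape")

  # 1 x 200 line: circularity far below 0.5
  ln <- matrix(FALSE, 220, 250); ln[100, 21:220] <- TRUE
  rl <- extract_regions(ln)
  expect_lt(rl$table$circularity, 0.1)
  keptl <- filter_regions(rl, min_area = 50, max_area = 1e5,
                          min_circularity = 0.5, border_margin = 5)
  expect_identical(nrow(keptl$table), 0L)

  # undersized region logs reason "size"
  sm <- matrix(FALSE, 60, 60); sm[rasterize_disk(60, 60, 30, 30, 3)] <- TRUE
  keptc <- filter_regions(extract_regions(sm), min_area = pi * 5^2,
                          max_area = 1e4, min_circularity = 0.5,
                          border_margin = 2)
  expect_identical(attr(keptc, "removed")$removal_reason, "size")

  # a clean disk passes all filters
  dk <- matrix(FALSE, 100, 100); dk[rasterize_disk(100, 100, 50, 50, 20)] <- TRUE
  keptd <- filter_regions(extract_regions(dk))
  expect_identical(nrow(keptd$table), 1L)
  expect_gte(keptd$table$circularity, 0.8)
})

test_that("circle fit recovers rasterized disks and exact three-point circles", {
  dk <- matrix(FALSE, 120, 120)
  dk[rasterize_disk(120, 120, 50, 60, 10)] <- TRUE
  fit <- fit_circle(extract_regions(dk))
  expect_lt(abs(fit$center["row"] - 50), 0.5)
  expect_lt(abs(fit$center["col"] - 60), 0.5)
  expect_lt(abs(fit$radius - 10), 0.5)

  # three exact points on a known circle: machine-precision recovery
  th <- c(0.3, 2.0, 4.5)
  pts <- cbind(row = 12 + 7 * sin(th), col = 9 + 7 * cos(th))
  f3 <- fit_circle(pts, raster_correction = 0)
  expect_equal(unname(f3$center), c(12, 9), tolerance = 1e-9)
  expect_equal(f3$radius, 7, tolerance = 1e-9)
  expect_equal(f3$residual, 0, tolerance = 1e-9)

  # collinear points are degenerate
  line <- cbind(row = 1:10, col = 2 * (1:10) + 3)
  expect_error(fit_circle(line), "collinear|degenerate")
  expect_error(fit_circle(cbind(row = 1:2, col = 1:2)), "fewer than 3")
})

test_that("sector score separates uniform disks, half wedges and slivers", {
  build_wedge <- function(arc_deg, base = 10000, wedge = 20000) {
    m <- matrix(500, 101, 101)
    rows <- matrix(0:100, 101, 101); cols <- t(rows)
    d <- sqrt((rows - 50)^2 + (cols - 50)^2)
    th <- (atan2(rows - 50, cols - 50) * 180 / pi) %% 360
    m[d <= 30] <- base
    m[d <= 30 & th < arc_deg] <- wedge
    as_plate(m)
  }
  circ <- list(center = c(row = 50, col = 50), radius = 30)

  uni <- sector_score(build_wedge(0), circ)
  expect_lt(uni$score, 0.05)
  expect_false(isTRUE(uni$sectored))

  half <- sector_score(build_wedge(180), circ)
  expect_equal(half$score, 1 / 3, tolerance = 0.02)  # (2-1)/(2+1)
  expect_true(half$sectored)

  sliver <- sector_score(build_wedge(7.2), circ)  # 2% of the circle
  expect_false(isTRUE(sliver$sectored))

  clipped <- sector_score(build_wedge(180),
                          list(center = c(row = 10, col = 50), radius = 30))
  expect_true(clipped$border_clipped)
  expect_true(is.na(clipped$score))
})

test_that("manual curation applies keep/remove/sector overrides with provenance", {
  rec <- data.frame(plate_id = "p", colony_id = 1:4,
                    concentration_mM = 0.025, center_row_px = 1:4,
                    center_col_px = 1:4, radius_px = 10, diameter_mm = 1,
                    mean_fluor = c(1, 2, 3, 4) * 1000, sector_score = 0,
                    sectored = FALSE, qc_flags = "",
                    stringsAsFactors = FALSE)
  expect_identical(apply_curation(rec, data.frame(colony_id = integer(0),
                                                  action = character(0))),
                   rec)
  cur <- data.frame(colony_id = c(7), action = "remove")
  expect_error(apply_curation(rec, cur), "unknown colony id")
  cur <- data.frame(colony_id = c(2, 3), action = c("remove", "sector_true"))
  out <- apply_curation(rec, cur)
  expect_false(2 %in% out$colony_id)
  expect_true(out$sectored[out$colony_id == 3])
  expect_match(out$qc_flags[out$colony_id == 3], "curation:sector_true")
  expect_identical(attr(out, "removed")$colony_id, 2L)
  expect_error(apply_curation(rec, data.frame(colony_id = 1,
                                              action = "explode")),
               "unknown curation action")
})

test_that("detection on a default synthetic plate finds the colonies and no artifacts", {
  plate <- simulate_plate(sim_config(), plate_index = 1, brightfield = FALSE)
  rec <- detect_colonies(plate)
  mt <- match_truth(rec, plate$truth$colonies)
  expect_gte(mt$detected_of, 78)
  expect_identical(mt$n_false, 0L)
  # matched radii within 1 px of truth
  tr <- plate$truth$colonies
  expect_true(all(abs(rec$radius_px[seq_along(mt$matched)] -
                        tr$radius_px[mt$matched]) <= 1))
  # retained regions all satisfy the circularity floor by construction
  mask <- binarize(plate)
  kept <- filter_regions(extract_regions(mask))
  expect_true(all(kept$table$circularity >= 0.8))
})

test_that("a noiseless single-colony plate yields the oracle disk mean", {
  cfg <- test_config(noise_sd = 0, artifact_rate = 0, background_gradient = 0)
  pop <- sample_colony_population(0.025, 1, cfg, seed = 4)
  plate <- render_plate(pop, cfg, seed = 4, brightfield = FALSE)
  rec <- detect_colonies(plate)
  expect_identical(nrow(rec), 1L)
  # oracle: profile-weighted mean over the truth disk
  w <- cfg$edge_width_frac / 2
  R <- pop$radius_px[1]; cr <- pop$center_row[1]; cc <- pop$center_col[1]
  rows <- matrix(0:(cfg$image_size - 1), cfg$image_size, cfg$image_size)
  cols <- t(rows)
  d <- sqrt((rows - cr)^2 + (cols - cc)^2)
  lo <- R * (1 - w); hi <- R * (1 + w)
  prof <- ifelse(d <= lo, 1, ifelse(d >= hi, 0,
                 0.5 * (1 + cos(pi * (d - lo) / (hi - lo)))))
  oracle <- mean((cfg$background_level +
                    (pop$mean_fluor[1] - cfg$background_level) *
                    prof)[d <= R])
  expect_lt(abs(rec$mean_fluor - oracle) / oracle, 0.01)
})

test_that("a plate holding only artifact blobs yields no colony records", {
  cfg <- test_config(artifact_rate = 8)
  pop <- sample_colony_population(0.025, 0, cfg, seed = 5)
  plate <- render_plate(pop, cfg, seed = 5, brightfield = FALSE)
  rec <- detect_colonies(plate)
  expect_identical(nrow(rec), 0L)
})

test_that("detection is equivariant under integer pixel shifts", {
  cfg <- test_config(artifact_rate = 0)
  pop <- sample_colony_population(0.025, 6, cfg, seed = 6)
  plate <- render_plate(pop, cfg, seed = 6, brightfield = FALSE)
  rec <- detect_colonies(plate)
  # shift the raster by (dr, dc) with background fill
  dr <- 3L; dc <- 5L
  L <- cfg$image_size
  shifted <- matrix(as.integer(round(cfg$background_level)), L, L)
  shifted[(1 + dr):L, (1 + dc):L] <- plate$fluor[1:(L - dr), 1:(L - dc)]
  plate2 <- plate; plate2$fluor <- shifted
  rec2 <- detect_colonies(plate2)
  expect_identical(nrow(rec2), nrow(rec))
  o1 <- order(rec$center_row_px); o2 <- order(rec2$center_row_px)
  expect_equal(rec2$center_row_px[o2], rec$center_row_px[o1] + dr,
               tolerance = 0.2)
  expect_equal(rec2$center_col_px[o2], rec$center_col_px[o1] + dc,
               tolerance = 0.2)
})
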