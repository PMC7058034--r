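test_that("dose-response truth matches the observed plateau and vanishes at high dose", {
  truth <- dose_response_truth(sim_config())
  expect_equal(truth$p_gfp_pos[truth$concentration_mM == 0.025], 0.45,
               tolerance = 1e-3)
  expect_lt(truth$p_gfp_pos[truth$concentration_mM == 10], 1e-12)
  # monotone non-increasing in concentration, both curves
  expect_true(all(diff(truth$p_gfp_pos) <= 0))
  expect_true(all(diff(truth$p_sector) <= 0))
  # sector probability: rare (< 3%) at the lowest concentration
  expect_equal(truth$p_sector[1], 0.025, tolerance = 1e-4)
  expect_true(all(truth$p_sector <= 0.03))
})

test_that("zero plateau gives zero GFP+ probability everywhere", {
  truth <- dose_response_truth(sim_config(truth_plateau = 0))
  expect_true(all(truth$p_gfp_pos == 0))
})

test_that("config validation rejects malformed grids and geometry", {
  expect_error(sim_config(concentration_grid = numeric(0)), "non-empty")
  expect_error(sim_config(concentration_grid = c(1, 0.5)), "ascending")
  expect_error(sim_config(concentration_grid = c(-1, 1)), "positive")
  expect_error(sim_config(truth_plateau = 1.2), "probabilities")
  expect_error(sim_config(min_center_distance = 10), "min_center_distance")
})

test_that("degenerate Bernoulli phenotype draws are all one class", {
  cfg0 <- test_config(truth_plateau = 0)
  pop <- sample_colony_population(0.025, 25, cfg0, seed = 7)
  expect_true(all(pop$phenotype == "GFP-"))
  cfg1 <- test_config(truth_plateau = 1, truth_x0 = 50)
  pop <- sample_colony_population(0.025, 25, cfg1, seed = 7)
  expect_true(all(pop$phenotype == "GFP+"))
})

test_that("pooled GFP+ fraction over 10,000 sampled colonies is within 3 binomial sds", {
  cfg <- sim_config(image_size = 3400L)  # room for 1000 colonies per draw
  p <- gfp_pos_prob(0.025, cfg)
  frac <- vapply(1:10, function(s) {
    pop <- sample_colony_population(0.025, 1000, cfg, seed = s)
    mean(pop$phenotype == "GFP+")
  }, 0)
  n_tot <- 10000
  expect_lt(abs(mean(frac) - p), 3 * sqrt(p * (1 - p) / n_tot))
})

test_that("sampling is seed-deterministic and conserves counts", {
  cfg <- test_config()
  a <- sample_colony_population(0.05, 30, cfg, seed = 11)
  b <- sample_colony_population(0.05, 30, cfg, seed = 11)
  expect_identical(a, b)
  expect_identical(nrow(a), 30L)
  expect_identical(attr(a, "n_sectored"), sum(a$sectored))
  # pairwise center distances respect the hard core
  d <- as.matrix(dist(cbind(a$center_row, a$center_col)))
  expect_true(all(d[upper.tri(d)] >= cfg$min_center_distance))
})

test_that("an overfull plate raises an explicit placement error", {
  cfg <- test_config()
  expect_error(sample_colony_population(0.025, 5000, cfg, seed = 1),
               "could not place|too small")
})

test_that("sampled GFP+ fractions are calibrated to the truth table across seeds", {
  cfg <- test_config()
  n_seeds <- 20L; n <- 40L
  for (x in c(0.025, 0.5, 1)) {
    p <- gfp_pos_prob(x, cfg)
    hits <- sum(vapply(seq_len(n_seeds), function(s) {
      sum(sample_colony_population(x, n, cfg, seed = 100 + s)$phenotype ==
            "GFP+")
    }, 0))
    n_tot <- n_seeds * n
    se <- sqrt(p * (1 - p) / n_tot)
    expect_lt(abs(hits / n_tot - p), 3 * max(se, 1e-6) + 1e-12)
  }
})

test_that("rendering is bit-identical under a fixed seed", {
  cfg <- test_config()
  pop <- sample_colony_population(0.025, 10, cfg, seed = 3)
  a <- render_plate(pop, cfg, seed = 5)
  b <- render_plate(pop, cfg, seed = 5)
  expect_identical(a$fluor, b$fluor)
  expect_identical(a$bf, b$bf)
  expect_identical(a$truth, b$truth)
})

test_that("an empty population renders a background-only plate with an empty sidecar", {
  cfg <- test_config(noise_sd = 0, artifact_rate = 0)
  pop <- sample_colony_population(0.025, 0, cfg, seed = 1)
  plate <- render_plate(pop, cfg, seed = 1, brightfield = FALSE)
  expect_equal(plate$truth$n_colonies, 0)
  expect_equal(nrow(plate$truth$colonies), 0)
  # only background + gradient remain
  expect_lte(max(plate$fluor),
             ceiling(cfg$background_level * (1 + cfg$background_gradient)))
  expect_gte(min(plate$fluor), floor(cfg$background_level))
})

test_that("a noiseless rendered disk reproduces its assigned mean (profile-weighted)", {
  cfg <- test_config(noise_sd = 0, artifact_rate = 0,
                     background_gradient = 0)
  pop <- sample_colony_population(0.025, 1, cfg, seed = 2)
  plate <- render_plate(pop, cfg, seed = 2, brightfield = FALSE)
  R <- pop$radius_px[1]; cr <- pop$center_row[1]; cc <- pop$center_col[1]
  # oracle: profile-weighted expectation over the rasterized disk
  w <- cfg$edge_width_frac / 2
  rows <- matrix(0:(cfg$image_size - 1), cfg$image_size, cfg$image_size)
  cols <- t(rows)
  d <- sqrt((rows - cr)^2 + (cols - cc)^2)
  lo <- R * (1 - w); hi <- R * (1 + w)
  prof <- ifelse(d <= lo, 1,
                 ifelse(d >= hi, 0,
                        0.5 * (1 + cos(pi * (d - lo) / (hi - lo)))))
  inside <- d <= R
  M <- pop$mean_fluor[1]; bg <- cfg$background_level
  expected <- mean(bg + (M - bg) * prof[inside])
  measured <- mean(plate$fluor[inside])
  expect_lt(abs(measured - expected) / expected, 0.01)
  # sidecar conservation
  expect_equal(nrow(plate$truth$colonies), 1)
  # 16-bit range
  expect_true(all(plate$fluor >= 0 & plate$fluor <= 65535))
})

test_that("derived per-plate streams make whole plates independently reproducible", {
  cfg <- test_config()
  p1 <- simulate_plate(cfg, plate_index = 2, brightfield = FALSE)
  p2 <- simulate_plate(cfg, plate_index = 2, brightfield = FALSE)
  expect_identical(p1$fluor, p2$fluor)
  p3 <- simulate_plate(cfg, plate_index = 3, brightfield = FALSE)
  expect_false(identical(p1$fluor, p3$fluor))
})
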