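test_that("dose_response aggregates counts, conserves totals and ignores order", {
  rec <- data.frame(concentration_mM = rep(c(0.025, 1), c(100, 50)),
                    phenotype = c(rep("GFP+", 45), rep("GFP-", 55),
                                  rep("GFP-", 50)),
                    sectored = c(rep(TRUE, 2), rep(FALSE, 148)))
  dr <- dose_response(rec)
  expect_equal(dr$frac_gfp_pos, c(0.45, 0))
  expect_equal(dr$n, c(100, 50))
  expect_equal(dr$n_sectored, c(2, 0))
  # order invariance
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(dose_response(shuf), dr)
  # count conservation per concentration
  expect_equal(dr$n_gfp_pos + (dr$n - dr$n_gfp_pos), dr$n)
  expect_warning(dose_response(rec[0, ]), "empty")
})

test_that("step fit interpolates its own model exactly and handles degenerate data", {
  cfg <- sim_config()
  x <- cfg$concentration_grid
  a_true <- 0.5; b_true <- -0.6
  y <- a_true - a_true / (1 + exp(-100 * (x + b_true)))
  fit <- fit_step(data.frame(concentration_mM = x, frac_gfp_pos = y))
  expect_equal(fit$a, a_true, tolerance = 1e-6)
  # all-zero fractions give a zero plateau
  f0 <- fit_step(data.frame(concentration_mM = x, frac_gfp_pos = 0 * x))
  expect_equal(f0$a, 0, tolerance = 1e-12)
  expect_error(fit_step(data.frame(concentration_mM = x[1:3],
                                   frac_gfp_pos = y[1:3])), "at least 4")
})

test_that("the fitted step plateau equals the low-concentration limit of the curve", {
  cfg <- sim_config()
  x <- cfg$concentration_grid
  set.seed(9)
  y <- rbinom(length(x), 300, gfp_pos_prob(x, cfg)) / 300
  fit <- fit_step(data.frame(concentration_mM = x, frac_gfp_pos = y))
  expect_equal(predict(fit, -1e6), fit$a, tolerance = 1e-12)
  expect_lt(predict(fit, 1e6), 1e-12)
})

test_that("step fit recovers the plateau from binomially sampled fractions", {
  cfg <- sim_config()
  x <- cfg$concentration_grid
  p <- gfp_pos_prob(x, cfg)
  a_hat <- vapply(1:8, function(s) {
    y <- withr::with_seed(s, rbinom(length(x), 300, p) / 300)
    fit_step(data.frame(concentration_mM = x, frac_gfp_pos = y))$a
  }, 0)
  expect_lt(abs(mean(a_hat) - cfg$truth_plateau), 0.02)
  # reported standard error is on the right scale (within a factor ~2 of
  # the sd across replicates)
  se_rep <- fit_step(data.frame(
    concentration_mM = x,
    frac_gfp_pos = withr::with_seed(1, rbinom(length(x), 300, p) / 300)))$se_a
  expect_lt(se_rep, 4 * max(sd(a_hat), 1e-4))
})

test_that("step fit supports alternative axis transforms", {
  x <- c(0.025, 0.05, 0.1, 0.25, 0.5, 1, 2.5, 10)
  t <- log10(x)
  y <- 0.45 - 0.45 / (1 + exp(-100 * (t + 0.3)))
  fit <- fit_step(data.frame(concentration_mM = x, frac_gfp_pos = y),
                  transform = "log10")
  expect_equal(fit$a, 0.45, tolerance = 1e-6)
  expect_identical(fit$transform, "log10")
})

test_that("exponential decline fit interpolates noiseless data to machine precision", {
  x <- seq(5, 10, 0.5)
  a_true <- 1.34; b_true <- 6.41
  y <- exp(-a_true * (x - b_true))
  fit <- fit_switch_decline(data.frame(concentration_mM = x,
                                       frac_sectored = y))
  expect_equal(fit$a, a_true, tolerance = 1e-6)
  expect_equal(fit$b, b_true, tolerance = 1e-6)
})

test_that("exponential decline degenerate inputs behave as specified", {
  x <- 1:6
  expect_error(fit_switch_decline(data.frame(concentration_mM = x,
                                             frac_sectored = rep(0, 6))),
               "no decline")
  flat <- fit_switch_decline(data.frame(concentration_mM = x,
                                        frac_sectored = rep(0.02, 6)))
  expect_equal(flat$a, 0)
  expect_error(fit_switch_decline(data.frame(concentration_mM = rep(1, 5),
                                             frac_sectored = exp(-(1:5)))),
               "x-spread")
  expect_error(fit_switch_decline(data.frame(concentration_mM = x[1:2],
                                             frac_sectored = c(1, 0.5))),
               "at least 3")
})

test_that("exponential decline recovers the rate under moderate noise", {
  x <- seq(5, 10, 0.5)
  a_true <- 1.34; b_true <- 6.41
  mu <- exp(-a_true * (x - b_true))
  a_hat <- vapply(1:25, function(s) {
    y <- withr::with_seed(s, mu + rnorm(length(x), 0, 0.005))
    fit_switch_decline(data.frame(concentration_mM = x,
                                  frac_sectored = y))$a
  }, 0)
  expect_lt(abs(mean(a_hat) - a_true), 0.15)
})
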