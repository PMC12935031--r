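make_pairs <- function(n, alpha = 5, beta = 0.8, sigma = 10, seed = 1) {
  withr::with_seed(seed, {
    g <- runif(n, -40, 90)
    data.frame(site_id = sprintf("P%04d", seq_len(n)),
               gridded = g, field = alpha + beta * g + rnorm(n, 0, sigma))
  })
}

test_that("bias calibration is exact on noiseless pairs and guards its preconditions", {
  p <- make_pairs(9, sigma = 0)
  m <- calibrate_bias(p)
  expect_equal(c(m$alpha, m$beta, m$sigma), c(5, 0.8, 0), tolerance = 1e-9)
  expect_equal(m$n_cal, 9)

  expect_error(calibrate_bias(p[1:2, ]), "insufficient")
  pc <- p; pc$gridded <- 3
  expect_error(calibrate_bias(pc), "zero variance")

  m2 <- calibrate_bias(p, exclusions = "P0001")
  expect_equal(m2$n_cal, 8)
  expect_identical(m2$excluded, "P0001")
})

test_that("bias calibration recovers the generative triplet within sampling error", {
  p <- make_pairs(1000, seed = 5)
  m <- calibrate_bias(p)
  fit <- summary(lm(field ~ gridded, data = p))
  expect_lt(abs(m$alpha - 5), 3 * fit$coefficients[1, 2])
  expect_lt(abs(m$beta - 0.8), 3 * fit$coefficients[2, 2])
  expect_lt(abs(m$sigma - 10), 3 * 10 / sqrt(2 * 998))
})

test_that("imputation draws have the composed variance and degenerate limits", {
  m <- calibrate_bias(make_pairs(200, seed = 2))
  # plug-in recipe: sigma = 0 and se = 0 collapse to a point mass
  m0 <- m; m0$sigma <- 0
  d0 <- draw_imputed(list(mean = 30, se = 0), m0, M = 500, seed = 1,
                     propagate_calibration = FALSE)
  expect_true(all(d0 == m0$alpha + m0$beta * 30))

  d <- draw_imputed(list(mean = 30, se = 6), m, M = 1e5, seed = 2,
                    propagate_calibration = FALSE)
  expect_equal(sd(d), sqrt(m$beta^2 * 36 + m$sigma^2), tolerance = 0.02)

  expect_identical(draw_imputed(list(mean = 30, se = 6), m, 100, seed = 9),
                   draw_imputed(list(mean = 30, se = 6), m, 100, seed = 9))
  expect_error(draw_imputed(list(mean = 1, se = 1), m, M = 0), "M must be")
})

test_that("calibration-uncertainty propagation widens draws at small n but vanishes at large n", {
  site <- list(mean = 30, se = 6)
  m_small <- calibrate_bias(make_pairs(10, seed = 3))
  m_big <- calibrate_bias(make_pairs(5000, seed = 3))
  sd_plug <- sd(draw_imputed(site, m_small, 2e4, seed = 4,
                             propagate_calibration = FALSE))
  sd_prop <- sd(draw_imputed(site, m_small, 2e4, seed = 4,
                             propagate_calibration = TRUE))
  expect_gt(sd_prop, sd_plug)
  sd_plug_b <- sd(draw_imputed(site, m_big, 2e4, seed = 5,
                               propagate_calibration = FALSE))
  sd_prop_b <- sd(draw_imputed(site, m_big, 2e4, seed = 5,
                               propagate_calibration = TRUE))
  expect_equal(sd_prop_b / sd_plug_b, 1, tolerance = 0.03)
})

test_that("measured-site draws match their normal specification", {
  expect_true(all(draw_measured(list(mean = 12, se = 0), 200, seed = 1) == 12))
  d <- draw_measured(list(mean = 40, se = 8), 1e5, seed = 2)
  expect_lt(abs(mean(d) - 40), 4 * 8 / sqrt(1e5))
  d2 <- draw_measured(list(mean = 40, se = 8), 1e5, seed = 3)
  expect_false(identical(d, d2))
  expect_equal(mean(d2), mean(d), tolerance = 0.01)
})

test_that("posterior summaries use interpolated percentiles with the expected limits", {
  meta <- data.frame(site_id = c("A", "B"), ai = c(0.5, 1.5),
                     source = c("field", "gridded"))
  ens <- posterior_ensemble(list(A = rep(7, 100), B = rep(-2, 100)), meta)
  ps <- posterior_summaries(ens)
  expect_equal(ps$lo, ps$hi)
  expect_equal(ps$mean, c(7, -2))

  z <- withr::with_seed(1, rnorm(1e6))
  meta1 <- data.frame(site_id = "Z", ai = 1, source = "field")
  ps2 <- posterior_summaries(posterior_ensemble(list(Z = z), meta1))
  expect_equal(ps2$lo, qnorm(0.025), tolerance = 0.02)
  expect_equal(ps2$hi, qnorm(0.975), tolerance = 0.02)
  ps3 <- posterior_summaries(posterior_ensemble(list(Z = z + 10), meta1))
  expect_equal(ps3$lo - ps2$lo, 10, tolerance = 1e-9)
  expect_equal(ps3$hi - ps2$hi, 10, tolerance = 1e-9)
})

test_that("the ensemble enforces equal draw counts and imputed intervals dominate measured ones", {
  meta <- data.frame(site_id = c("A", "B"), ai = c(1, 2),
                     source = c("field", "gridded"))
  expect_error(posterior_ensemble(list(A = rnorm(100), B = rnorm(99)), meta),
               "exactly M")
  expect_error(posterior_ensemble(list(A = rnorm(50), B = rnorm(50)), meta),
               "M must be >= 100")

  m <- calibrate_bias(make_pairs(50, seed = 6))
  stopifnot(m$sigma > 0)
  se <- 5
  wid <- function(d) diff(quantile(d, c(0.025, 0.975)))
  w_meas <- wid(draw_measured(list(mean = 20, se = se), 2e4, seed = 7))
  w_imp <- wid(draw_imputed(list(mean = 20, se = se), m, 2e4, seed = 7))
  expect_gt(w_imp, w_meas)
})

test_that("posterior regression consumes draws in order and degenerates correctly", {
  meta <- data.frame(site_id = c("A", "B", "C", "D"),
                     ai = c(0.4, 0.9, 1.4, 2.0),
                     source = "field")
  const <- list(A = rep(0, 200), B = rep(10, 200), C = rep(20, 200),
                D = rep(35, 200))
  pr <- posterior_regression(posterior_ensemble(const, meta), n_rep = 50)
  expect_equal(sd(pr$slope), 0)
  expect_equal(sd(pr$r2), 0)
  expect_error(posterior_regression(posterior_ensemble(const, meta),
                                    n_rep = 500), "without replacement")
  expect_error(posterior_regression(
    posterior_ensemble(const[1:2], meta[1:2, ]), n_rep = 10), ">= 3 sites")
})

test_that("end-to-end imputation keeps M draws per site and reproduces itself", {
  cfg <- world_config(n_sites = 8, n_imputed = 3)
  s <- generate_sites(cfg, seed = 31)
  g <- generate_gridded_estimates(s, cfg$bias, seed = 32)
  src <- rep("field", 8); src[c(2, 5, 7)] <- "gridded"
  obs <- withr::with_seed(33, s$true_delta + rnorm(8, 0, cfg$field_se))
  sd_tab <- data.frame(site_id = s$site_id, ai = s$ai, source = src,
                       obs_mean = ifelse(src == "field", obs, NA),
                       obs_se = ifelse(src == "field", cfg$field_se, NA))
  imp <- impute_deltas(sd_tab, g$sites, M = 250, seed = 34)
  expect_equal(unname(lengths(imp$ensemble$draws)), rep(250, 8))
  imp2 <- impute_deltas(sd_tab, g$sites, M = 250, seed = 34)
  expect_identical(imp$ensemble$draws, imp2$ensemble$draws)
})
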