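test_that("pedotransfer fitting recovers exact coefficients and rejects bad designs", {
  set.seed(1)
  cal <- data.frame(soc = runif(20, 0.2, 6), clay = runif(20, 5, 50),
                    silt = runif(20, 10, 60))
  cal$bd_measured <- -0.1 * cal$soc + 0.002 * cal$clay + 0.001 * cal$silt + 1.4
  fit <- fit_pedotransfer(cal)
  expect_equal(c(fit$a, fit$b, fit$c, fit$d),
               c(-0.1, 0.002, 0.001, 1.4), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-8)

  expect_error(fit_pedotransfer(cal[1:3, ]), ">= 4 samples")
  cal$clay <- 20
  expect_error(fit_pedotransfer(cal), "singular")
})

test_that("pedotransfer coefficients are unbiased within sampling error on noisy data", {
  set.seed(7)
  n <- 60
  cal <- data.frame(soc = runif(n, 0.2, 6), clay = runif(n, 5, 50),
                    silt = runif(n, 10, 60))
  cal$bd_measured <- -0.1 * cal$soc + 0.002 * cal$clay + 0.001 * cal$silt +
    1.4 + rnorm(n, 0, 0.08)
  fit <- fit_pedotransfer(cal)
  oracle <- summary(lm(bd_measured ~ soc + clay + silt, data = cal))
  truth <- c(1.4, -0.1, 0.002, 0.001)
  for (i in 1:4) {
    expect_equal(unname(c(fit$d, fit$a, fit$b, fit$c)[i]),
                 unname(oracle$coefficients[i, 1]), tolerance = 1e-10)
    expect_lt(abs(oracle$coefficients[i, 1] - truth[i]),
              3 * oracle$coefficients[i, 2])
  }
})

test_that("pedotransfer predictions are clipped to the physical range", {
  cal <- data.frame(soc = c(0.5, 1, 2, 4, 6), clay = c(10, 20, 30, 25, 15),
                    silt = c(30, 35, 40, 30, 35))
  cal$bd_measured <- -0.1 * cal$soc + 0.002 * cal$clay + 0.001 * cal$silt + 1.4
  fit <- fit_pedotransfer(cal)
  expect_warning(bd <- predict(fit, data.frame(soc = 50, clay = 10, silt = 10)),
                 "clipped")
  expect_equal(as.numeric(bd), 0.2)
  expect_equal(attr(bd, "n_clipped"), 1)
})

test_that("fine-earth bulk density applies the 3% gravel threshold", {
  expect_equal(bulk_density_fine(600, 500), 1.2)
  expect_equal(bulk_density_fine(600, 500, 60, 25), 540 / 475)
  expect_equal(bulk_density_fine(600, 500, 12, 25), 1.2)  # 2% <= 3%: skipped
  expect_error(bulk_density_fine(600, 500, 10, 500), "degenerate")
})

test_that("SOC density follows the unit-checked conversion", {
  expect_equal(soc_density(0, 1.3), 0)
  expect_equal(soc_density(2, 1.25), 0.25)
  expect_equal(soc_density(2, 2.5), 2 * soc_density(2, 1.25))
  expect_error(soc_density(-1, 1), ">= 0")
})

test_that("profile stocks are additive under refinement and reject broken geometry", {
  h <- data.frame(depth_top = 0, depth_bottom = 10, soc = 2,
                  bd_measured = 1.25)
  expect_equal(profile_stock(h)$stock, 2.5)

  h2 <- data.frame(depth_top = c(0, 5), depth_bottom = c(5, 10),
                   soc = 2, bd_measured = 1.25)
  expect_equal(profile_stock(h2)$stock, profile_stock(h)$stock)

  bad <- data.frame(depth_top = c(0, 20), depth_bottom = c(10, 30), soc = 2,
                    bd_measured = 1)
  expect_error(profile_stock(bad), "geometry")
})

test_that("profile stock matches fine-grid quadrature of the generator's density field", {
  cfg <- world_config(soc_noise_sd = 0, geochem_noise_sd = 0,
                      layer_thickness = 12.5, depth_max = 100,
                      bd_measured_frac = 1)
  site <- generate_sites(cfg, seed = 2)[10, ]
  prof <- generate_profiles(site, cfg, seed = 3)
  h <- prof[prof$profile_id == sprintf("%s_control_1", site$site_id), ]
  got <- profile_stock(h)$stock

  f_soc <- terrasoc:::profile_soc_fun(site$ai, "control", cfg$depth_max)
  clay <- h$clay[1]; silt <- h$silt[1]
  f_dens <- function(z) {
    soc <- f_soc(z)
    bd <- -0.1 * soc + 0.002 * clay + 0.001 * silt + 1.4
    soc / 100 * bd * 10
  }
  oracle <- oracle_quad(f_dens, 0, 100)
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("gridded layer harmonization sums whole layers and fractions the straddler", {
  sg <- data.frame(top = c(0, 5, 15, 30, 60, 100),
                   bottom = c(5, 15, 30, 60, 100, 200),
                   stock = c(1, 2, 3, 4, 5, 6))
  expect_equal(harmonize_gridded_profile(sg, 200), 21)
  expect_equal(harmonize_gridded_profile(sg, 30), 6)
  uni <- data.frame(top = c(0, 20, 40, 60, 80, 100, 150),
                    bottom = c(20, 40, 60, 80, 100, 150, 200))
  uni$stock <- 0.1 * (uni$bottom - uni$top)   # uniform density
  expect_equal(harmonize_gridded_profile(uni, 45), 45 / 200 * 20)
  expect_error(harmonize_gridded_profile(sg, 250), "coverage")
})

test_that("relative change reproduces its anchors and antisymmetry closed form", {
  expect_equal(relative_change(5, 5), 0)
  expect_equal(relative_change(1.75, 1), 75)
  expect_equal(relative_change(0.63, 1), -37)
  expect_error(relative_change(1, 0), "baseline")

  for (x in c(-37, 6, 41, 75)) {
    fwd <- relative_change(1 + x / 100, 1)
    back <- relative_change(1, 1 + x / 100)
    expect_equal(back, 100 * (1 / (1 + x / 100) - 1), tolerance = 1e-12)
    expect_equal(fwd, x, tolerance = 1e-12)
  }
})
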