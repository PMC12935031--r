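test_that("world configuration validates its invariants", {
  expect_s3_class(world_config(), "world_config")
  expect_error(world_config(n_sites = 2), "n_sites")
  expect_error(world_config(ai_range = c(0.1, 2)), "extremely arid")
  expect_error(world_config(depth_max = 100, layer_thickness = 7), "divide")
  expect_error(world_config(bias = list(alpha = 0, beta = 1, sigma = -1)),
               "SD")
})

test_that("site generation is seed-deterministic, spans the gradient, and is monotone without noise", {
  cfg <- world_config(n_sites = 14, seed = 1)
  s1 <- generate_sites(cfg, seed = 1)
  s2 <- generate_sites(cfg, seed = 1)
  expect_identical(s1, s2)
  expect_equal(range(s1$ai), cfg$ai_range)
  expect_equal(s1$ai, s1$map / s1$pet, tolerance = 1e-12)

  cfg0 <- world_config(delta_soc_model = list(intercept = -32, slope = 60,
                                              site_sd = 0))
  s0 <- generate_sites(cfg0, seed = 3)
  expect_true(all(diff(s0$true_delta) > 0))
})

test_that("OLS on a large generated gradient recovers the configured aridity slope", {
  cfg <- world_config(n_sites = 500,
                      delta_soc_model = list(intercept = -32, slope = 60,
                                             site_sd = 12))
  s <- generate_sites(cfg, seed = 11)
  fit <- summary(lm(true_delta ~ ai, data = s))
  expect_lt(abs(fit$coefficients["ai", "Estimate"] - 60),
            3 * fit$coefficients["ai", "Std. Error"])
})

test_that("profiles carry the built-in climate contrasts and monotone SOC decay at zero noise", {
  cfg <- world_config(soc_noise_sd = 0, geochem_noise_sd = 0)
  humid <- generate_sites(world_config(n_sites = 3, n_imputed = 1,
                                       ai_range = c(1.9, 2.1)),
                          seed = 1)[1, ]
  arid <- generate_sites(world_config(n_sites = 3, n_imputed = 1,
                                      ai_range = c(0.35, 0.45)),
                         seed = 1)[1, ]
  hp <- generate_profiles(humid, cfg, seed = 2)
  ap <- generate_profiles(arid, cfg, seed = 2)
  expect_gt(mean(hp$Fe_o), mean(ap$Fe_o))
  expect_lt(mean(hp$Ca_ex), mean(ap$Ca_ex))
  expect_lt(mean(hp$pH), mean(ap$pH))

  ctrl <- hp[hp$position == "control", ]
  for (id in unique(ctrl$profile_id)) {
    p <- ctrl[ctrl$profile_id == id, ]
    expect_gte(p$soc[which.min(p$depth_top)], p$soc[which.max(p$depth_top)])
  }
})

test_that("integrated fill-minus-control SOC equals the configured burial bump", {
  cfg <- world_config(soc_noise_sd = 0, geochem_noise_sd = 0)
  site <- generate_sites(cfg, seed = 1)[8, ]
  f_fill <- terrasoc:::profile_soc_fun(site$ai, "fill", cfg$depth_max)
  f_ctrl <- terrasoc:::profile_soc_fun(site$ai, "control", cfg$depth_max)
  got <- oracle_quad(function(z) f_fill(z) - f_ctrl(z), 0, cfg$depth_max)
  soc0 <- 0.8 + 1.6 * site$ai
  bump <- 0.6 * soc0 * 12 * sqrt(2 * pi) *
    (pnorm(cfg$depth_max, 50, 12) - pnorm(0, 50, 12))
  expect_equal(got, bump, tolerance = 1e-6)

  # generated horizon SOC equals the layer means of the continuous profile
  prof <- generate_profiles(site, cfg, seed = 9)
  fill <- prof[prof$profile_id == sprintf("%s_fill_1", site$site_id), ]
  lm_soc <- vapply(seq_len(nrow(fill)), function(i)
    oracle_quad(f_fill, fill$depth_top[i], fill$depth_bottom[i]) /
      (fill$depth_bottom[i] - fill$depth_top[i]), numeric(1))
  expect_equal(fill$soc, lm_soc, tolerance = 1e-6)
})

test_that("gridded estimates honor the identity-bias and conservation contracts", {
  td <- data.frame(site_id = c("A", "B", "C"), true_delta = c(10, 40, 70))
  g <- generate_gridded_estimates(td, list(alpha = 0, beta = 1, sigma = 0),
                                  n_pixels = 4, pixel_sd = 0, seed = 1)
  expect_equal(g$sites$gridded_mean, td$true_delta, tolerance = 1e-12)
  expect_equal(g$sites$field_truth, td$true_delta, tolerance = 1e-12)
  expect_equal(g$sites$gridded_se, rep(0, 3))

  sums <- aggregate(stock ~ site_id + schema, data = g$layers, sum)
  ref <- unique(g$layers[, c("site_id", "schema", "profile_stock")])
  m <- merge(sums, ref)
  expect_equal(m$stock, m$profile_stock, tolerance = 1e-9)
})

test_that("regressing field on gridded recovers the generative bias triplet", {
  cfg <- world_config(n_sites = 1000,
                      delta_soc_model = list(intercept = -32, slope = 60,
                                             site_sd = 12))
  s <- generate_sites(cfg, seed = 21)
  g <- generate_gridded_estimates(s, list(alpha = 5, beta = 0.8, sigma = 10),
                                  n_pixels = 2, pixel_sd = 0, seed = 22)
  fit <- summary(lm(g$sites$field_truth ~ g$sites$gridded_mean))
  expect_lt(abs(fit$coefficients[1, 1] - 5), 3 * fit$coefficients[1, 2])
  expect_lt(abs(fit$coefficients[2, 1] - 0.8), 3 * fit$coefficients[2, 2])
  n <- cfg$n_sites
  se_sigma <- 10 / sqrt(2 * (n - 2))       # asymptotic SE of sigma-hat
  expect_lt(abs(fit$sigma - 10), 3 * se_sigma)
})

test_that("synthetic spectra reproduce their analytic construction", {
  z <- generate_spectrum(c(aliph_1 = 0, aliph_2 = 0, acid = 0, arom = 0),
                         baseline = c(0, 0, 0))
  expect_true(all(z$value == 1))           # reflectance 1 <=> absorbance 0

  one <- generate_spectrum(c(acid = 0.4), baseline = c(0, 0, 0))
  expect_equal(max(log10(1 / one$value)), 0.4, tolerance = 1e-3)

  amps <- c(arom = 0.3, acid = 0.5)
  ctr <- c(arom = 1525, acid = 1650)
  wid <- c(arom = 12, acid = 30)
  sp <- generate_spectrum(amps, ctr, wid, baseline = c(0.01, 2e-6, 0))
  A <- log10(1 / sp$value)
  for (b in names(amps)) {
    i <- which.min(abs(sp$wavenumber - ctr[[b]]))
    x <- sp$wavenumber[i]
    analytic <- 0.01 + 2e-6 * (x - 500) +
      sum(amps * exp(-(x - ctr)^2 / (2 * wid^2)))
    expect_equal(A[i], analytic, tolerance = 1e-9)
  }
  expect_error(generate_spectrum(c(acid = 0.2), wavenumbers = c(1, 1, 2)),
               "strictly increasing")
})

test_that("phenology truth integrals match quadrature and the configured terracing effect", {
  ph <- generate_phenology(season = c(100, 300), amplitude = 0,
                           base = 0.2, noise_sd = 0)
  expect_equal(ph$truth$tpp_control, 0.2 * 201, tolerance = 1e-12)
  expect_equal(tpp_integral(ph$control, c(100, 300)), 0.2 * 201,
               tolerance = 1e-12)

  ph2 <- generate_phenology(terrace_scale = 1.31)
  expect_equal(ph2$truth$delta_tpp, 31, tolerance = 1e-12)
  expect_equal(100 * (ph2$truth$tpp_terraced / ph2$truth$tpp_control - 1),
               31, tolerance = 1e-9)

  hump <- function(d) 0.05 + 0.6 * exp(-(d - 200)^2 / (2 * 45^2))
  # stored analytic integral vs dense quadrature of the daily-step sum's
  # continuous counterpart
  q <- oracle_quad(hump, 99.5, 300.5)
  expect_equal(ph2$truth$tpp_control, q, tolerance = 0.01 * q)
  # and the daily rectangle sum is within 1% of the analytic value
  expect_equal(tpp_integral(generate_phenology(noise_sd = 0)$control,
                            c(100, 300)),
               ph2$truth$tpp_control, tolerance = 0.01 * ph2$truth$tpp_control)
})

test_that("synthesis records drive every inclusion criterion", {
  clean <- generate_synthesis_records(100, seed = 4)
  f <- filter_synthesis(clean)
  expect_equal(nrow(f$included), 100)
  expect_equal(nrow(f$excluded), 0)

  one <- clean
  one$terrace_age[17] <- 0.5
  f1 <- filter_synthesis(one)
  expect_equal(f1$excluded$study_id, clean$study_id[17])
  expect_equal(f1$excluded$reason, "terrace age < 1 yr")

  # expected pass count under configured exclusion probabilities
  p <- c(missing_control = 0.1, young = 0.1, paddy = 0.1,
         fluvial_gravel = 0.05, desert = 0.05)
  rec <- generate_synthesis_records(2000, seed = 8, prob = p)
  keep_p <- prod(1 - p)
  got <- nrow(filter_synthesis(rec)$included)
  expect_lt(abs(got - 2000 * keep_p), 3 * sqrt(2000 * keep_p * (1 - keep_p)))
})

test_that("the full world is byte-identical under a fixed seed", {
  cfg <- world_config(n_sites = 5, n_profiles_per_position = 1,
                      n_imputed = 2)
  expect_identical(generate_world(cfg, seed = 42),
                   generate_world(cfg, seed = 42))
})
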