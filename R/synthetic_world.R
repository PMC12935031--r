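#' Configuration for a synthetic terracing study
#'
#' Bundles every parameter of the synthetic world: the aridity gradient, the
#' aridity -> expected-\eqn{\Delta}SOC model, the field-vs-gridded bias
#' structure, profile geometry and noise levels. Defaults emulate a
#' European-scale terrace survey: 14 sites spanning aridity index (AI,
#' MAP/PET) 0.32–2.17, strongly positive SOC responses in humid climates and
#' responses straddling zero in arid climates, and five sites whose
#' non-terraced controls are only available from gridded soil products.
#'
#' @param n_sites number of sites along the aridity gradient (>= 3).
#' @param ai_range numeric length-2, AI interval; must lie within
#'   \[0.2, Inf) — extremely arid climates carry no agricultural terraces and
#'   are rejected.
#' @param delta_soc_model list with `intercept`, `slope` (percent
#'   \eqn{\Delta}SOC per unit AI) and `site_sd` (between-site SD, percent).
#' @param bias list with `alpha` (intercept, percent), `beta` (slope) and
#'   `sigma` (residual SD, percent) linking field to gridded
#'   \eqn{\Delta}SOC: field = alpha + beta * gridded + N(0, sigma).
#' @param n_profiles_per_position profiles excavated per geomorphic position
#'   (cut / fill / control) per site.
#' @param depth_max profile depth, cm; `layer_thickness` must divide it.
#' @param layer_thickness sampling-interval thickness, cm.
#' @param n_pixels gridded pixels sampled per site (SE = pixel SD / sqrt(n)).
#' @param pixel_sd between-pixel SD of gridded \eqn{\Delta}SOC, percent.
#' @param field_se standard error of field-measured site \eqn{\Delta}SOC,
#'   percent.
#' @param n_imputed number of sites lacking field controls (imputed from the
#'   gridded product), spread evenly across the gradient.
#' @param soc_noise_sd lognormal sdlog of multiplicative SOC noise per
#'   horizon (0 = noise-free).
#' @param geochem_noise_sd lognormal sdlog of multiplicative noise on
#'   geochemical covariates.
#' @param spatial_corr within-site correlation of profile-level noise
#'   (default 0, i.e. independence between profiles).
#' @param bd_measured_frac fraction of profiles carrying measured bulk
#'   density (the rest rely on the pedotransfer function).
#' @param seed default seed used by [generate_world()].
#' @return object of class `world_config` (a validated list).
#' @seealso [generate_world()], [read_world_config()]
#' @export
world_config <- function(n_sites = 14,
                         ai_range = c(0.32, 2.17),
                         delta_soc_model = list(intercept = -43.5, slope = 75,
                                                site_sd = 12),
                         bias = list(alpha = 5, beta = 0.8, sigma = 10),
                         n_profiles_per_position = 3,
                         depth_max = 100,
                         layer_thickness = 10,
                         n_pixels = 10,
                         pixel_sd = 15,
                         field_se = 8,
                         n_imputed = 5,
                         soc_noise_sd = 0.15,
                         geochem_noise_sd = 0.25,
                         spatial_corr = 0,
                         bd_measured_frac = 0.4,
                         seed = 1L) {
  cfg <- list(n_sites = n_sites, ai_range = ai_range,
              delta_soc_model = delta_soc_model, bias = bias,
              n_profiles_per_position = n_profiles_per_position,
              depth_max = depth_max, layer_thickness = layer_thickness,
              n_pixels = n_pixels, pixel_sd = pixel_sd, field_se = field_se,
              n_imputed = n_imputed, soc_noise_sd = soc_noise_sd,
              geochem_noise_sd = geochem_noise_sd,
              spatial_corr = spatial_corr,
              bd_measured_frac = bd_measured_frac, seed = seed)
  validate_world_config(cfg)
  class(cfg) <- "world_config"
  cfg
}

validate_world_config <- function(cfg) {
  stopifnot_msg(cfg$n_sites >= 3, "n_sites must be >= 3")
  stopifnot_msg(length(cfg$ai_range) == 2 && all(is.finite(cfg$ai_range)) &&
                  cfg$ai_range[1] < cfg$ai_range[2],
                "ai_range must be a finite increasing interval")
  stopifnot_msg(cfg$ai_range[1] >= 0.2,
                "ai_range below 0.2 rejected: extremely arid climates carry no agricultural terraces")
  sds <- c(cfg$delta_soc_model$site_sd, cfg$bias$sigma, cfg$pixel_sd,
           cfg$field_se, cfg$soc_noise_sd, cfg$geochem_noise_sd)
  stopifnot_msg(all(sds >= 0), "all SD parameters must be >= 0")
  stopifnot_msg(cfg$depth_max > 0, "depth_max must be positive")
  stopifnot_msg(cfg$depth_max %% cfg$layer_thickness == 0,
                "layer_thickness must divide depth_max")
  stopifnot_msg(cfg$n_pixels >= 2, "n_pixels must be >= 2")
  stopifnot_msg(cfg$n_imputed < cfg$n_sites, "n_imputed must leave measured sites")
  invisible(cfg)
}

#' Read a world configuration from YAML
#'
#' The YAML schema mirrors the arguments of [world_config()]; keys absent
#' from the file keep their defaults.
#'
#' @param path YAML file.
#' @return `world_config` object.
#' @export
read_world_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(world_config))
  bad <- setdiff(names(raw), known)
  stopifnot_msg(length(bad) == 0,
                paste("unknown config keys:", paste(bad, collapse = ", ")))
  do.call(world_config, raw)
}

#' Names of the 26 soil physicochemical covariates
#'
#' Organically complexed (`_p`), poorly crystalline (`_o`) and highly
#' crystalline (`_d`) Fe/Al/Mn oxide pools, the crystallinity ratio
#' `Fe_d_Fe_t`, exchangeable base cations and total reserve in bases,
#' pH, C:N ratio, SOC physical fractions, FTIR-derived chemistry ratios and
#' soil texture.
#'
#' @return character vector of length 26.
#' @export
geochem_vars <- function() {
  c("Fe_p", "Al_p", "Mn_p", "Fe_o", "Al_o", "Mn_o",
    "Fe_d", "Al_d", "Mn_d", "Fe_d_Fe_t",
    "K_ex", "Ca_ex", "Mg_ex", "Na_ex", "TRB", "pH", "CN",
    "cPOC", "micro_agg", "s_c",
    "arom_aliph", "arom_acid", "aliph_acid",
    "clay", "silt", "sand")
}

#' Generate sites along the aridity gradient
#'
#' AI values are evenly spaced across `ai_range` (guaranteeing the gradient
#' is spanned); MAP/PET/MAT follow deterministic gradients consistent with
#' AI = MAP/PET; the true site-level \eqn{\Delta}SOC is drawn from the
#' configured linear aridity model plus Gaussian between-site noise.
#'
#' @param config a [world_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return data.frame with one row per site: `site_id`, `ai`, `mat`, `map`,
#'   `pet`, `climate_bin` ("arid"/"humid"), `climate_zone`, `true_delta`.
#' @export
generate_sites <- function(config, seed = config$seed) {
  validate_world_config(config)
  n <- config$n_sites
  ai <- if (n == 1) mean(config$ai_range) else
    seq(config$ai_range[1], config$ai_range[2], length.out = n)
  map <- 350 + 600 * ai
  pet <- map / ai                       # ai == map/pet exactly
  mat <- 20 - 7 * ai
  m <- config$delta_soc_model
  draws <- local_seed(seed, {
    list(delta = m$intercept + m$slope * ai + rnorm(n, 0, m$site_sd),
         # site-level productivity gain from terracing, percent; rises with
         # moisture availability, ~31% at the gradient midpoint
         dtpp = 10 + 17 * ai + rnorm(n, 0, 4))
  })
  cls <- classify_climate(ai)
  data.frame(site_id = sprintf("S%02d", seq_len(n)), ai = ai, mat = mat,
             map = map, pet = pet, climate_bin = cls$binary,
             climate_zone = cls$zone, true_delta = draws$delta,
             delta_tpp = draws$dtpp,
             stringsAsFactors = FALSE)
}

# Continuous SOC depth profile (percent by mass) for one site and position.
# Controls decay exponentially from a climate-dependent surface value; cut
# positions carry a reduced (partially replaced) surface value; fill
# positions add a Gaussian buried-topsoil bump.
profile_soc_fun <- function(ai, position, depth_max,
                            zstar = 30, bump_depth = 0.5, bump_sd = 12) {
  soc0 <- 0.8 + 1.6 * ai
  repl <- min(1.1, 0.45 + 0.35 * ai)    # topsoil-C replacement in cuts
  bump_amp <- 0.6 * soc0
  bd_cm <- bump_depth * depth_max
  switch(position,
    control = function(z) soc0 * exp(-z / zstar),
    cut     = function(z) soc0 * repl * exp(-z / zstar),
    fill    = function(z) soc0 * exp(-z / zstar) +
                bump_amp * exp(-(z - bd_cm)^2 / (2 * bump_sd^2)),
    stop("unknown position: ", position))
}

# exact layer mean of the continuous SOC profile over [a, b]
layer_mean_soc <- function(f, a, b) {
  vapply(seq_along(a), function(i)
    stats::integrate(f, a[i], b[i], rel.tol = 1e-10)$value / (b[i] - a[i]),
    numeric(1))
}

#' Generate depth-explicit horizon samples for one site
#'
#' Horizon SOC is the exact layer mean of a continuous depth profile
#' (exponential decay; fill positions add a Gaussian buried-topsoil bump),
#' perturbed by mean-preserving multiplicative lognormal noise. The 26
#' geochemical covariates follow aridity-linked lognormal trends: reactive
#' oxide pools increase and pH falls toward humid climates, exchangeable
#' base cations and crystalline oxides increase toward arid climates. Soil
#' potential respiration (SPR) responds to a latent ligand-exchange axis in
#' humid climates and a latent cation-bridging axis in arid climates, which
#' is what the attribution stage is expected to recover.
#'
#' @param site one-row data.frame from [generate_sites()].
#' @param config a [world_config()].
#' @param seed integer seed.
#' @return data.frame of horizon samples (one row per depth slice).
#' @export
generate_profiles <- function(site, config, seed = config$seed) {
  validate_world_config(config)
  stopifnot_msg(nrow(site) == 1, "generate_profiles() takes a single site row")
  lt <- config$layer_thickness
  tops <- seq(0, config$depth_max - lt, by = lt)
  bots <- tops + lt
  mid <- (tops + bots) / 2
  ai <- site$ai
  sdl <- config$soc_noise_sd
  gsd <- config$geochem_noise_sd
  positions <- c("cut", "fill", "control")

  local_seed(seed, {
    out <- list()
    site_u <- rnorm(1)                      # site-level intercept for SPR
    for (pos in positions) {
      f <- profile_soc_fun(ai, pos, config$depth_max)
      soc_true <- layer_mean_soc(f, tops, bots)
      for (p in seq_len(config$n_profiles_per_position)) {
        prof_u <- sqrt(config$spatial_corr) * site_u +
          sqrt(1 - config$spatial_corr) * rnorm(1)
        soc <- soc_true *
          if (sdl > 0) rlnorm(length(tops), -sdl^2 / 2, sdl) else 1
        clay <- pmin(55, pmax(5, 20 + 4 * ai + rnorm(length(tops), 0, 2 * (gsd > 0))))
        silt <- pmin(70, pmax(10, 35 + rnorm(length(tops), 0, 2 * (gsd > 0))))
        sand <- 100 - clay - silt
        gravel <- pmax(0, runif(length(tops), 0, 6))

        # latent stabilization axes shared within a horizon
        u_lig <- rnorm(length(tops))
        u_cat <- rnorm(length(tops))
        ln <- function(b0, slope_ai, load = 0, u = 0)
          exp(b0 + slope_ai * ai + load * u +
                if (gsd > 0) rnorm(length(tops), -gsd^2 / 2, gsd) else 0)
        g <- data.frame(
          Fe_p = ln(0.2, 0.55, 0.3, u_lig), Al_p = ln(-0.2, 0.55, 0.3, u_lig),
          Mn_p = ln(-1.6, 0.55, 0.3, u_lig),
          Fe_o = ln(0.9, 0.5, 0.3, u_lig), Al_o = ln(0.4, 0.5, 0.3, u_lig),
          Mn_o = ln(-1.2, 0.5, 0.3, u_lig),
          Fe_d = ln(2.1, -0.3), Al_d = ln(1.4, -0.3), Mn_d = ln(-0.4, -0.3),
          Fe_d_Fe_t = pmin(0.95, ln(-1.1, -0.25)),
          K_ex = ln(-0.6, -0.5, 0.3, u_cat), Ca_ex = ln(1.8, -0.5, 0.3, u_cat),
          Mg_ex = ln(0.6, -0.5, 0.3, u_cat), Na_ex = ln(-1.4, -0.5, 0.3, u_cat),
          TRB = ln(3.1, -0.45, 0.3, u_cat),
          pH = pmin(9, pmax(3.8, 7.9 - 1.3 * ai +
                              rnorm(length(tops), 0, 0.2 * (gsd > 0)))),
          CN = ln(2.4, 0.12), cPOC = ln(2.9, 0.15),
          micro_agg = ln(3.2, 0.05), s_c = ln(3.6, -0.05),
          arom_aliph = ln(0.1, -0.15), arom_acid = ln(-0.4, -0.15),
          aliph_acid = ln(-0.5, 0.1))
        g$clay <- clay; g$silt <- silt; g$sand <- sand

        # SPR: humid variance carried by the ligand axis, arid by the cation
        # axis; declines with depth; floored at a small positive rate
        w_h <- stats::plogis(4 * (ai - 1))
        spr <- pmax(0.5,
          28 - 0.08 * mid + 3 * prof_u -
            8 * w_h * u_lig - 6 * (1 - w_h) * u_cat +
            rnorm(length(tops), 0, 2 * (gsd > 0)))
        posl <- (60 + 9 * mid) *
          if (gsd > 0) rlnorm(length(tops), -0.01, 0.15) else 1

        bd_true <- pmax(0.4, -0.1 * soc + 0.002 * clay + 0.001 * silt + 1.4 +
                          rnorm(length(tops), 0, 0.04 * (sdl > 0)))
        measured <- p <= ceiling(config$bd_measured_frac *
                                   config$n_profiles_per_position)
        df <- data.frame(site_id = site$site_id,
                         profile_id = sprintf("%s_%s_%d", site$site_id, pos, p),
                         position = pos, depth_top = tops, depth_bottom = bots,
                         soc = soc, gravel = gravel,
                         bd_measured = if (measured) bd_true else NA_real_,
                         spr = spr, posl = posl,
                         stringsAsFactors = FALSE)
        out[[length(out) + 1]] <- cbind(df, g)
      }
    }
    do.call(rbind, out)
  })
}

#' Generate gridded-product \eqn{\Delta}SOC estimates for sites
#'
#' Constructs gridded estimates so that the bias relation
#' `field = alpha + beta * gridded + N(0, sigma)` holds by construction
#' with the residual independent of the gridded value: the latent gridded
#' value is the inverse-bias image of the climate-model site mean, and the
#' residual draw is added to the site's true \eqn{\Delta}SOC (returned as
#' `field_truth`), so grid-vs-reality mismatch becomes one more site-level
#' noise component. `n_pixels` noisy pixels around the latent value give
#' the reported mean and SE. Layered control stock profiles
#' are emitted in both the 6-layer (0-5-15-30-60-100-200 cm) and 7-layer
#' (0-20-40-60-80-100-150-200 cm) depth schemas; layer stocks sum exactly to
#' the profile stock written alongside.
#'
#' @param true_deltas data.frame with `site_id` and `true_delta` (percent).
#' @param bias list `alpha`, `beta`, `sigma`.
#' @param n_pixels pixels per site (>= 2).
#' @param pixel_sd between-pixel SD, percent.
#' @param seed integer seed.
#' @param control_stock optional named vector of per-site control profile
#'   stocks (kg C m^-2); generated lognormally when omitted.
#' @return list with `sites` (site_id, gridded_mean, gridded_se,
#'   gridded_true, field_truth — the site's true \eqn{\Delta}SOC including
#'   the bias residual) and `layers` (site_id, schema, top, bottom, stock,
#'   profile_stock).
#' @export
generate_gridded_estimates <- function(true_deltas, bias, n_pixels = 10,
                                       pixel_sd = 15, seed = NULL,
                                       control_stock = NULL) {
  stopifnot_msg(bias$sigma >= 0, "bias sigma must be >= 0")
  stopifnot_msg(n_pixels >= 2, "n_pixels must be >= 2")
  stopifnot_msg(bias$beta != 0, "bias beta must be nonzero")
  n <- nrow(true_deltas)
  schemas <- list(soilgrids = c(0, 5, 15, 30, 60, 100, 200),
                  hwsd = c(0, 20, 40, 60, 80, 100, 150, 200))
  local_seed(seed, {
    eps <- rnorm(n, 0, bias$sigma)
    g_true <- (true_deltas$true_delta - bias$alpha) / bias$beta
    field_truth <- true_deltas$true_delta + eps  # = alpha + beta*g_true + eps
    gm <- numeric(n); gse <- numeric(n)
    for (i in seq_len(n)) {
      px <- g_true[i] + rnorm(n_pixels, 0, pixel_sd)
      gm[i] <- mean(px)
      gse[i] <- sd(px) / sqrt(n_pixels)
    }
    if (is.null(control_stock))
      control_stock <- setNames(rlnorm(n, log(10), 0.3), true_deltas$site_id)
    layers <- do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(names(schemas), function(sc) {
        br <- schemas[[sc]]
        w <- exp(-br[-length(br)] / 40) - exp(-br[-1] / 40)
        stock <- control_stock[[true_deltas$site_id[i]]] * w / sum(w)
        data.frame(site_id = true_deltas$site_id[i], schema = sc,
                   top = br[-length(br)], bottom = br[-1], stock = stock,
                   profile_stock = control_stock[[true_deltas$site_id[i]]],
                   stringsAsFactors = FALSE)
      }))
    }))
    list(sites = data.frame(site_id = true_deltas$site_id, gridded_mean = gm,
                            gridded_se = gse, gridded_true = g_true,
                            field_truth = field_truth,
                            stringsAsFactors = FALSE),
         layers = layers)
  })
}

#' FTIR band definitions
#'
#' Aliphatic C-H (two sub-bands), protonated carboxylic (COOH, "acid") and
#' aromatic C=C band windows used for semi-quantification, in cm^-1.
#'
#' @return data.frame with `band`, `lo`, `hi`.
#' @export
ftir_bands <- function() {
  data.frame(band = c("aliph_1", "aliph_2", "acid", "arom"),
             lo = c(2898, 2839, 1570, 1500),
             hi = c(2976, 2870, 1720, 1550),
             stringsAsFactors = FALSE)
}

#' Generate one synthetic FTIR spectrum with known band heights
#'
#' Builds an absorbance trace as Gaussian peaks centred inside each band on
#' a configurable polynomial baseline, adds optional Gaussian noise, and
#' emits the corresponding reflectance spectrum (`R = 10^-A`). The exact
#' peak amplitudes above baseline are stored as ground truth.
#'
#' @param amplitudes named numeric: peak amplitudes (absorbance units) for
#'   bands `aliph_1`, `aliph_2`, `acid`, `arom`; must be >= 0.
#' @param centers,widths named numeric; default to band mid-points and
#'   moderate widths.
#' @param baseline numeric length 3: absorbance baseline coefficients
#'   `b0 + b1*(wn-500) + b2*(wn-500)^2`.
#' @param noise_sd additive absorbance noise SD.
#' @param wavenumbers strictly increasing grid, cm^-1.
#' @param seed integer seed.
#' @return an `ftir_spectrum` (reflectance mode) with attribute `truth`.
#' @export
generate_spectrum <- function(amplitudes,
                              centers = NULL, widths = NULL,
                              baseline = c(0.02, 0, 0),
                              noise_sd = 0,
                              wavenumbers = seq(500, 4000, by = 4),
                              seed = NULL) {
  bands <- ftir_bands()
  stopifnot_msg(all(diff(wavenumbers) > 0),
                "wavenumber grid must be strictly increasing")
  stopifnot_msg(all(amplitudes >= 0), "amplitudes must be >= 0")
  if (is.null(centers))
    centers <- setNames((bands$lo + bands$hi) / 2, bands$band)
  if (is.null(widths))
    widths <- setNames(c(16, 8, 32, 12), bands$band)
  A <- baseline[1] + baseline[2] * (wavenumbers - 500) +
    baseline[3] * (wavenumbers - 500)^2
  for (b in names(amplitudes)) {
    A <- A + amplitudes[[b]] *
      exp(-(wavenumbers - centers[[b]])^2 / (2 * widths[[b]]^2))
  }
  if (noise_sd > 0) A <- A + local_seed(seed, rnorm(length(A), 0, noise_sd))
  A <- pmax(A, 0)                        # keep reflectance in (0, 1]
  sp <- new_spectrum(wavenumbers, 10^(-A), mode = "reflectance")
  attr(sp, "truth") <- data.frame(band = names(amplitudes),
                                  amplitude = unname(unlist(amplitudes)),
                                  center = unname(centers[names(amplitudes)]),
                                  width = unname(widths[names(amplitudes)]),
                                  stringsAsFactors = FALSE)
  sp
}

#' Generate a collection of random synthetic FTIR spectra
#'
#' Amplitudes, peak centres (inside each band), widths and gentle linear
#' baselines are drawn at random; per-spectrum ground-truth heights are
#' returned alongside.
#'
#' @param n number of spectra.
#' @param seed integer seed.
#' @param amp_range amplitude range (absorbance units).
#' @param noise_sd additive absorbance noise SD.
#' @return list with `spectra` (list of `ftir_spectrum`) and `truth`
#'   (data.frame: sample, band, amplitude).
#' @export
generate_spectra <- function(n, seed = NULL, amp_range = c(0.05, 0.5),
                             noise_sd = 0.002) {
  bands <- ftir_bands()
  width_rng <- list(aliph_1 = c(12, 18), aliph_2 = c(6, 10),
                    acid = c(24, 40), arom = c(9, 15))
  local_seed(seed, {
    spectra <- vector("list", n)
    truth <- list()
    for (i in seq_len(n)) {
      amps <- setNames(runif(4, amp_range[1], amp_range[2]), bands$band)
      ctr <- setNames(runif(4, bands$lo + 0.25 * (bands$hi - bands$lo),
                            bands$hi - 0.25 * (bands$hi - bands$lo)),
                      bands$band)
      wid <- setNames(vapply(bands$band,
                             function(b) runif(1, width_rng[[b]][1],
                                               width_rng[[b]][2]),
                             numeric(1)), bands$band)
      bl <- c(runif(1, 0.01, 0.05), runif(1, 0, 5e-6), 0)
      spectra[[i]] <- generate_spectrum(amps, ctr, wid, baseline = bl,
                                        noise_sd = noise_sd, seed = NULL)
      truth[[i]] <- data.frame(sample = i, band = bands$band,
                               amplitude = unname(amps),
                               stringsAsFactors = FALSE)
    }
    list(spectra = spectra, truth = do.call(rbind, truth))
  })
}

#' Generate paired daily plant-phenology series with known integrals
#'
#' The control series is a Gaussian seasonal hump over a small baseline; the
#' terraced series is the control curve scaled by `terrace_scale` (default
#' 1.31, i.e. a 31 percent productivity gain) before noise is added. The
#' analytic growing-season integrals of the noise-free curves are stored as
#' ground truth.
#'
#' @param season integer length 2, start/end day of year (start < end).
#' @param peak_day,amplitude,width,base parameters of the seasonal hump.
#' @param terrace_scale multiplicative productivity effect of terracing.
#' @param noise_sd additive daily noise SD.
#' @param seed integer seed.
#' @return list with `control` and `terraced` data.frames (`day`, `ppi`),
#'   `season`, and `truth` (analytic TPPs and the true percent
#'   \eqn{\Delta}TPP).
#' @export
generate_phenology <- function(season = c(100, 300), peak_day = 200,
                               amplitude = 0.6, width = 45, base = 0.05,
                               terrace_scale = 1.31, noise_sd = 0,
                               seed = NULL) {
  stopifnot_msg(season[1] < season[2] && season[1] >= 1 && season[2] <= 365,
                "season must satisfy 1 <= start < end <= 365")
  day <- 1:365
  curve <- base + amplitude * exp(-(day - peak_day)^2 / (2 * width^2))
  gauss_int <- function(s) {
    L <- season[2] - season[1] + 1
    s * (base * L + amplitude * width * sqrt(2 * pi) *
           (pnorm(season[2], peak_day, width) -
              pnorm(season[1] - 1, peak_day, width)))
  }
  truth <- list(tpp_control = gauss_int(1),
                tpp_terraced = gauss_int(terrace_scale),
                delta_tpp = 100 * (terrace_scale - 1))
  local_seed(seed, {
    noise <- function() if (noise_sd > 0) rnorm(365, 0, noise_sd) else 0
    list(control = data.frame(day = day, ppi = curve + noise()),
         terraced = data.frame(day = day, ppi = terrace_scale * curve + noise()),
         season = season, truth = truth)
  })
}

#' Generate synthetic literature-synthesis records
#'
#' Each record carries paired terraced/control SOC stocks, climate, soil
#' type, terrace age and the exclusion flags the synthesis filter screens
#' for (missing control, terrace age < 1 yr, paddy terrace, fluvial gravel
#' terrace, desert environment), raised with the configured probabilities.
#'
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @param prob named numeric of flag probabilities (`missing_control`,
#'   `young`, `paddy`, `fluvial_gravel`, `desert`).
#' @param delta_model aridity -> \eqn{\Delta}SOC model as in
#'   [world_config()] (with `record_sd` noise).
#' @return data.frame of `SynthesisRecord` rows.
#' @export
generate_synthesis_records <- function(n, seed = NULL,
                                       prob = c(missing_control = 0,
                                                young = 0, paddy = 0,
                                                fluvial_gravel = 0,
                                                desert = 0),
                                       delta_model = list(intercept = -43.5,
                                                          slope = 75,
                                                          record_sd = 25)) {
  stopifnot_msg(n >= 1, "n must be >= 1")
  soil_types <- c("Cambisol", "Luvisol", "Podzol", "Vertisol", "Umbrisol")
  local_seed(seed, {
    ai <- runif(n, 0.25, 2.5)
    map <- 350 + 600 * ai
    pet <- map / ai
    delta <- delta_model$intercept + delta_model$slope * ai +
      rnorm(n, 0, delta_model$record_sd)
    soc_control <- rlnorm(n, log(8), 0.4)
    soc_terraced <- soc_control * pmax(0.05, 1 + delta / 100)
    fl <- function(p) runif(n) < (if (is.na(p)) 0 else p)
    age <- rlnorm(n, log(40), 1)
    young <- fl(prob[["young"]])
    age[young] <- runif(sum(young), 0.05, 0.95)
    miss <- fl(prob[["missing_control"]])
    soc_control[miss] <- NA_real_
    data.frame(study_id = sprintf("REC%03d", seq_len(n)),
               soc_terraced = soc_terraced, soc_control = soc_control,
               mat = 20 - 7 * ai, map = map, pet = pet, ai = ai,
               soil_type = sample(soil_types, n, replace = TRUE),
               terrace_age = age,
               paddy = fl(prob[["paddy"]]),
               fluvial_gravel = fl(prob[["fluvial_gravel"]]),
               desert = fl(prob[["desert"]]),
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic terracing study
#'
#' Runs every generator under one seed: sites with true \eqn{\Delta}SOC,
#' depth-explicit horizons for cut/fill/control profiles, field-observed
#' site \eqn{\Delta}SOC for measured sites (the `n_imputed` sites spread
#' evenly across the gradient carry gridded estimates only), gridded
#' estimates with layered stock profiles, FTIR spectra, paired phenology
#' and a literature-synthesis table.
#'
#' @param config a [world_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return object of class `terra_world`: list with `config`, `sites`,
#'   `horizons`, `site_delta`, `gridded`, `spectra`, `phenology`,
#'   `synthesis`.
#' @export
generate_world <- function(config = world_config(), seed = config$seed) {
  validate_world_config(config)
  sites <- generate_sites(config, seed = child_seed(seed, 1))
  horizons <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
    generate_profiles(sites[i, ], config, seed = child_seed(seed, 100 + i))))
  gridded <- generate_gridded_estimates(sites, config$bias,
                                        n_pixels = config$n_pixels,
                                        pixel_sd = config$pixel_sd,
                                        seed = child_seed(seed, 2))
  # grid-vs-reality residual is part of each site's realized truth
  sites$true_delta <- gridded$sites$field_truth
  imputed_idx <- unique(round(seq(2, nrow(sites) - 1,
                                  length.out = config$n_imputed)))
  source <- ifelse(seq_len(nrow(sites)) %in% imputed_idx, "gridded", "field")
  obs <- local_seed(child_seed(seed, 3),
                    sites$true_delta + rnorm(nrow(sites), 0, config$field_se))
  site_delta <- data.frame(site_id = sites$site_id, ai = sites$ai,
                           source = source,
                           obs_mean = ifelse(source == "field", obs, NA_real_),
                           obs_se = ifelse(source == "field",
                                           config$field_se, NA_real_),
                           true_delta = sites$true_delta,
                           stringsAsFactors = FALSE)
  spectra <- generate_spectra(2 * nrow(sites), seed = child_seed(seed, 4))
  phen <- generate_phenology(seed = child_seed(seed, 5), noise_sd = 0.01)
  synthesis <- generate_synthesis_records(99, seed = child_seed(seed, 6),
                                          prob = c(missing_control = 0.05,
                                                   young = 0.05, paddy = 0.05,
                                                   fluvial_gravel = 0.03,
                                                   desert = 0.02))
  structure(list(config = config, sites = sites, horizons = horizons,
                 site_delta = site_delta, gridded = gridded,
                 spectra = spectra, phenology = phen, synthesis = synthesis),
            class = "terra_world")
}

#' Write a synthetic world to tidy CSV tables plus a truth sidecar
#'
#' Writes `sites.csv`, `horizons.csv`, `site_delta.csv`, `gridded.csv`,
#' `gridded_layers.csv`, `spectra.csv` (long), `phenology.csv`,
#' `synthesis.csv` and `truth.json`.
#'
#' @param world a `terra_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    write.csv(df, file.path(dir, f), row.names = FALSE)
    f
  }
  spec_long <- do.call(rbind, lapply(seq_along(world$spectra$spectra),
    function(i) {
      sp <- world$spectra$spectra[[i]]
      data.frame(sample = i, wavenumber = sp$wavenumber, value = sp$value,
                 stringsAsFactors = FALSE)
    }))
  phen <- rbind(cbind(world$phenology$control, series = "control"),
                cbind(world$phenology$terraced, series = "terraced"))
  files <- c(
    wr(world$sites, "sites.csv"),
    wr(world$horizons, "horizons.csv"),
    wr(world$site_delta, "site_delta.csv"),
    wr(world$gridded$sites, "gridded.csv"),
    wr(world$gridded$layers, "gridded_layers.csv"),
    wr(spec_long, "spectra.csv"),
    wr(phen, "phenology.csv"),
    wr(world$synthesis, "synthesis.csv"))
  truth <- list(true_delta = setNames(as.list(world$sites$true_delta),
                                      world$sites$site_id),
                bias = world$config$bias,
                delta_soc_model = world$config$delta_soc_model,
                spectra = world$spectra$truth,
                phenology = world$phenology$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(files, "truth.json"))
}
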