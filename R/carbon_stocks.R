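#' Fit a pedotransfer function for bulk density
#'
#' Ordinary least squares fit of `BD = a*SOC + b*clay + c*silt + d` on
#' calibration samples carrying measured bulk density, with SOC, clay and
#' silt in percent and BD in g cm^-3. Predictions from the resulting model
#' are clipped to the physically plausible range \[0.2, 2.2\] g cm^-3 to
#' guard against extrapolation; clipping events are counted.
#'
#' @param calibration data.frame with columns `bd_measured`, `soc`, `clay`,
#'   `silt`; rows with missing `bd_measured` are dropped.
#' @return object of class `pedotransfer`: coefficients `a`, `b`, `c`, `d`,
#'   fit `r2`, calibration count `n_cal`.
#' @examples
#' cal <- data.frame(soc = c(0.5, 1, 2, 4, 6), clay = c(10, 20, 30, 25, 15),
#'                   silt = c(30, 35, 40, 30, 35))
#' cal$bd_measured <- -0.1 * cal$soc + 0.002 * cal$clay + 0.001 * cal$silt + 1.4
#' fit_pedotransfer(cal)
#' @export
fit_pedotransfer <- function(calibration) {
  cal <- calibration[!is.na(calibration$bd_measured), , drop = FALSE]
  stopifnot_msg(nrow(cal) >= 4,
                "pedotransfer calibration needs >= 4 samples with measured BD")
  X <- cbind(soc = cal$soc, clay = cal$clay, silt = cal$silt)
  stopifnot_msg(qr(cbind(1, X))$rank == 4,
                "singular pedotransfer design (constant or collinear SOC/clay/silt)")
  fit <- lm(cal$bd_measured ~ X)
  cf <- coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(a = unname(cf["Xsoc"]), b = unname(cf["Xclay"]),
                 c = unname(cf["Xsilt"]), d = unname(cf["(Intercept)"]),
                 r2 = r2, n_cal = nrow(cal)),
            class = "pedotransfer")
}

#' @export
print.pedotransfer <- function(x, ...) {
  cat(sprintf("Pedotransfer BD model (n = %d, R2 = %.3f):\n", x$n_cal, x$r2))
  cat(sprintf("  BD = %.4f*SOC + %.4f*clay + %.4f*silt + %.4f  [g cm^-3]\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Predict bulk density from a pedotransfer model
#'
#' @param object a [fit_pedotransfer()] model.
#' @param newdata data.frame with `soc`, `clay`, `silt` (percent).
#' @param ... unused.
#' @return numeric vector of fine-earth bulk densities, g cm^-3, clipped to
#'   \[0.2, 2.2\]; the number of clipped values is attached as attribute
#'   `n_clipped` (with a warning when positive).
#' @export
predict.pedotransfer <- function(object, newdata, ...) {
  bd <- object$a * newdata$soc + object$b * newdata$clay +
    object$c * newdata$silt + object$d
  clipped <- bd < 0.2 | bd > 2.2
  if (any(clipped))
    warning(sum(clipped), " pedotransfer prediction(s) clipped to [0.2, 2.2] g cm^-3")
  out <- pmin(pmax(bd, 0.2), 2.2)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Fine-earth bulk density with gravel correction
#'
#' Returns `(total_mass - gravel_mass) / (total_volume - gravel_volume)`
#' when the gravel mass fraction exceeds 3 percent; below that threshold the
#' correction is skipped and the uncorrected `total_mass / total_volume` is
#' returned.
#'
#' @param total_mass,gravel_mass sample and gravel (> 2 mm) masses, g.
#' @param total_volume,gravel_volume corresponding volumes, cm^3.
#' @return bulk density of the fine-earth fraction, g cm^-3.
#' @examples
#' bulk_density_fine(600, 500)                 # 1.2
#' bulk_density_fine(600, 500, 60, 25)         # 540/475
#' @export
bulk_density_fine <- function(total_mass, total_volume,
                              gravel_mass = 0, gravel_volume = 0) {
  stopifnot_msg(all(total_mass > gravel_mass) && all(gravel_mass >= 0),
                "need total_mass > gravel_mass >= 0")
  stopifnot_msg(all(total_volume > gravel_volume) && all(gravel_volume >= 0),
                "degenerate sample: need total_volume > gravel_volume >= 0")
  frac <- gravel_mass / total_mass
  ifelse(frac > 0.03,
         (total_mass - gravel_mass) / (total_volume - gravel_volume),
         total_mass / total_volume)
}

#' SOC density of a horizon
#'
#' `soc_density = SOC/100 * BD_fine * 10`, in kg C m^-2 per cm of depth.
#' The factor 10 converts g C cm^-3 over a 1 m^2 x 1 cm slab (10^4 cm^3 =
#' 10^4 g / 10^3 g kg^-1) into kg C m^-2 cm^-1.
#'
#' @param soc_pct SOC content, percent by mass (>= 0).
#' @param bd_fine fine-earth bulk density, g cm^-3 (>= 0).
#' @return SOC density, kg C m^-2 cm^-1.
#' @examples
#' soc_density(2, 1.25)   # 0.25
#' @export
soc_density <- function(soc_pct, bd_fine) {
  stopifnot_msg(all(soc_pct >= 0) && all(bd_fine >= 0),
                "soc_pct and bd_fine must be >= 0")
  soc_pct / 100 * bd_fine * 10
}

#' Profile SOC stock from depth-explicit horizons
#'
#' Sums horizon SOC density times thickness over a contiguous,
#' non-overlapping profile. Measured bulk density is used where present;
#' otherwise the supplied pedotransfer model predicts it.
#'
#' @param horizons data.frame for one profile: `depth_top`, `depth_bottom`,
#'   `soc`, optionally `bd_measured`, `clay`, `silt`.
#' @param pedotransfer optional [fit_pedotransfer()] model; required when
#'   any horizon lacks measured BD.
#' @return list of class `profile_stock`: `stock` (kg C m^-2), `depth`
#'   (cm), `density` (per-horizon kg C m^-2 cm^-1), `thickness`.
#' @export
profile_stock <- function(horizons, pedotransfer = NULL) {
  h <- horizons[order(horizons$depth_top), , drop = FALSE]
  stopifnot_msg(all(h$depth_top < h$depth_bottom) && all(h$depth_top >= 0),
                "need 0 <= depth_top < depth_bottom for every horizon")
  if (nrow(h) > 1) {
    gaps <- abs(h$depth_top[-1] - h$depth_bottom[-nrow(h)]) > 1e-8
    if (any(gaps)) {
      bad <- which(gaps)[1]
      stop(sprintf(
        "profile geometry error: interval [%g, %g] is followed by [%g, %g] (gap or overlap)",
        h$depth_top[bad], h$depth_bottom[bad],
        h$depth_top[bad + 1], h$depth_bottom[bad + 1]), call. = FALSE)
    }
  }
  bd <- if ("bd_measured" %in% names(h)) h$bd_measured else
    rep(NA_real_, nrow(h))
  if (any(is.na(bd))) {
    stopifnot_msg(!is.null(pedotransfer),
                  "horizons lack measured BD and no pedotransfer model was given")
    bd[is.na(bd)] <- suppressWarnings(
      predict(pedotransfer, h[is.na(bd), , drop = FALSE]))
  }
  dens <- soc_density(h$soc, bd)
  thick <- h$depth_bottom - h$depth_top
  structure(list(stock = sum(dens * thick),
                 depth = max(h$depth_bottom) - min(h$depth_top),
                 density = dens, thickness = thick),
            class = "profile_stock")
}

#' Stocks and site-level \eqn{\Delta}SOC for a whole horizon table
#'
#' Convenience wrapper applying [profile_stock()] per profile (fitting one
#' pedotransfer model on all measured-BD horizons) and aggregating to
#' site-by-position means.
#'
#' @param horizons horizon table as produced by [generate_profiles()].
#' @return list with `profiles` (profile_id, site_id, position, depth,
#'   stock), `pedotransfer` model, and `site_delta` (site_id, position,
#'   delta vs the site's control mean).
#' @export
stock_table <- function(horizons) {
  pt <- fit_pedotransfer(horizons)
  ids <- unique(horizons$profile_id)
  profiles <- do.call(rbind, lapply(ids, function(id) {
    h <- horizons[horizons$profile_id == id, , drop = FALSE]
    ps <- profile_stock(h, pt)
    data.frame(profile_id = id, site_id = h$site_id[1],
               position = h$position[1], depth = ps$depth, stock = ps$stock,
               stringsAsFactors = FALSE)
  }))
  ctrl <- aggregate(stock ~ site_id,
                    data = profiles[profiles$position == "control", ], mean)
  names(ctrl)[2] <- "control_stock"
  trt <- aggregate(stock ~ site_id + position,
                   data = profiles[profiles$position != "control", ], mean)
  sd <- merge(trt, ctrl, by = "site_id")
  sd$delta <- relative_change(sd$stock, sd$control_stock)
  list(profiles = profiles, pedotransfer = pt,
       site_delta = sd[order(sd$site_id, sd$position), ])
}

#' Harmonize a layered gridded stock profile to a target depth
#'
#' Sums whole layers lying within `target_depth` and adds a
#' thickness-proportional fraction of the layer straddling the target depth
#' (uniform-density-within-layer assumption).
#'
#' @param layers data.frame with `top`, `bottom`, `stock` covering
#'   \[0, >= target_depth\] (6- or 7-layer gridded schema).
#' @param target_depth depth to harmonize to, cm.
#' @return total stock to `target_depth`, kg C m^-2.
#' @export
harmonize_gridded_profile <- function(layers, target_depth) {
  l <- layers[order(layers$top), , drop = FALSE]
  stopifnot_msg(target_depth > 0, "target_depth must be positive")
  stopifnot_msg(max(l$bottom) >= target_depth,
                sprintf("coverage error: layers end at %g cm, target %g cm",
                        max(l$bottom), target_depth))
  frac <- pmin(pmax((target_depth - l$top) / (l$bottom - l$top), 0), 1)
  sum(l$stock * frac)
}

#' Relative change of a treated quantity against its control
#'
#' `100 * (treated - control) / control`, the percent-change metric applied
#' identically to SOC stocks (\eqn{\Delta}SOC), total plant productivity
#' (\eqn{\Delta}TPP) and vegetation indices.
#'
#' @param treated,control numeric; `control` must be positive.
#' @return percent change.
#' @examples
#' relative_change(1.75, 1)   # 75
#' @export
relative_change <- function(treated, control) {
  stopifnot_msg(all(control > 0),
                "undefined baseline: control must be > 0")
  100 * (treated - control) / control
}
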