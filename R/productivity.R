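#' Vegetation indices from surface reflectance
#'
#' NDVI = (NIR - red)/(NIR + red); EVI with the canonical coefficients
#' G = 2.5, C1 = 6, C2 = 7.5, L = 1; SAVI with soil-adjustment L = 0.5.
#'
#' @param red,nir,blue surface reflectances in \[0, 1\] (blue only feeds
#'   EVI).
#' @param savi_l SAVI soil-adjustment factor (default 0.5; SAVI -> NDVI as
#'   L -> 0).
#' @return data.frame with `ndvi`, `evi`, `savi`; undefined NDVI
#'   (nir + red = 0) is `NA` with a warning.
#' @export
vegetation_indices <- function(red, nir, blue = NULL, savi_l = 0.5) {
  stopifnot_msg(all(c(red, nir, blue) >= 0 & c(red, nir, blue) <= 1),
                "reflectances must lie in [0, 1]")
  denom <- nir + red
  if (any(denom == 0)) warning("nir + red = 0: NDVI undefined, set to NA")
  ndvi <- ifelse(denom == 0, NA_real_, (nir - red) / denom)
  evi <- if (is.null(blue)) rep(NA_real_, length(red)) else
    2.5 * (nir - red) / (nir + 6 * red - 7.5 * blue + 1)
  savi <- (1 + savi_l) * (nir - red) / (nir + red + savi_l)
  data.frame(ndvi = ndvi, evi = evi, savi = savi)
}

#' Savitzky-Golay smoothing of a daily series
#'
#' Least-squares local polynomial smoothing (degree 3, window 7 by
#' default). Edges are handled by the one-sided least-squares polynomial
#' refits of the Savitzky-Golay projection matrix, not by padding, so
#' polynomials up to the configured degree are reproduced exactly
#' everywhere.
#'
#' @param x numeric series (length >= window).
#' @param degree polynomial degree (default 3).
#' @param window odd window size greater than `degree` (default 7).
#' @return smoothed series of the same length.
#' @export
smooth_series <- function(x, degree = 3, window = 7) {
  stopifnot_msg(window %% 2 == 1, "window must be odd")
  stopifnot_msg(window > degree, "window must exceed the polynomial degree")
  stopifnot_msg(length(x) >= window, "series shorter than the window")
  signal::sgolayfilt(x, p = degree, n = window)
}

#' Growing-season integral of a daily phenology series (TPP)
#'
#' Total plant productivity as the daily sum (rectangle rule at the daily
#' step) of the phenology index between the start and end of the growing
#' season, inclusive.
#'
#' @param series data.frame with `day` and `ppi`.
#' @param season integer length 2 (start, end day), inside the series span.
#' @return TPP (index-days).
#' @export
tpp_integral <- function(series, season) {
  stopifnot_msg(season[1] < season[2], "season start must precede its end")
  stopifnot_msg(season[1] >= min(series$day) && season[2] <= max(series$day),
                "season outside the series span")
  sum(series$ppi[series$day >= season[1] & series$day <= season[2]])
}

#' Filter literature-synthesis records by the inclusion criteria
#'
#' Applies, in order: (i) paired terraced and control SOC reported;
#' (ii) terrace age >= 1 year; (iii) not a permanently waterlogged paddy
#' terrace; (iv) not a fluvial-context gravel terrace; (v) not a desert
#' environment. The first failing criterion is logged per excluded record;
#' \eqn{\Delta}SOC ([relative_change()]) is computed for survivors.
#'
#' @param records data.frame as from [generate_synthesis_records()].
#' @return list: `included` (with `delta_soc`), `excluded` (with `reason`).
#' @export
filter_synthesis <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  fail <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  fail(is.na(records$soc_terraced) | is.na(records$soc_control),
       "missing paired SOC")
  fail(records$terrace_age < 1, "terrace age < 1 yr")
  fail(records$paddy, "paddy terrace")
  fail(records$fluvial_gravel, "fluvial gravel terrace")
  fail(records$desert, "desert environment")
  inc <- records[is.na(reason), , drop = FALSE]
  exc <- records[!is.na(reason), , drop = FALSE]
  exc$reason <- reason[!is.na(reason)]
  if (nrow(inc))
    inc$delta_soc <- relative_change(inc$soc_terraced, inc$soc_control)
  list(included = inc, excluded = exc)
}

#' Loess trend of \eqn{\Delta}SOC along the aridity gradient
#'
#' Locally weighted regression (tricube kernel, degree 1) of
#' \eqn{\Delta}SOC on AI with a pointwise 95 percent band from a residual
#' bootstrap (percentiles of refitted curves).
#'
#' @param delta_soc,ai numeric vectors (>= 10 points).
#' @param span loess span (default 0.75).
#' @param n_boot residual-bootstrap replicates.
#' @param grid_n evaluation grid size.
#' @param seed integer seed.
#' @return data.frame: `ai`, `fit`, `lo`, `hi`.
#' @export
loess_trend <- function(delta_soc, ai, span = 0.75, n_boot = 500,
                        grid_n = 80, seed = NULL) {
  stopifnot_msg(length(delta_soc) >= 10, "need >= 10 points")
  stopifnot_msg(span * length(ai) >= 4,
                "span too small for local linear fits")
  d <- data.frame(ai = ai, y = delta_soc)
  fit <- loess(y ~ ai, data = d, span = span, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  grid <- data.frame(ai = seq(min(ai), max(ai), length.out = grid_n))
  f0 <- predict(fit, grid)
  res <- resid(fit)
  boot <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      db <- data.frame(ai = d$ai, y = fitted(fit) + sample(res, replace = TRUE))
      fb <- loess(y ~ ai, data = db, span = span, degree = 1,
                  control = loess.control(surface = "direct"))
      predict(fb, grid)
    }, numeric(grid_n))
  })
  data.frame(ai = grid$ai, fit = f0,
             lo = apply(boot, 1, quantile, 0.025, na.rm = TRUE),
             hi = apply(boot, 1, quantile, 0.975, na.rm = TRUE))
}
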