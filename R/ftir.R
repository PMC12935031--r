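#' Construct an FTIR spectrum object
#'
#' @param wavenumber strictly increasing grid, cm^-1.
#' @param value reflectance (in (0, 1\]) or absorbance values.
#' @param mode "reflectance" or "absorbance".
#' @param mask logical vector marking points excluded from SOC analysis.
#' @return object of class `ftir_spectrum`.
#' @export
new_spectrum <- function(wavenumber, value,
                         mode = c("reflectance", "absorbance"),
                         mask = rep(FALSE, length(wavenumber))) {
  mode <- match.arg(mode)
  stopifnot_msg(length(wavenumber) == length(value),
                "wavenumber and value lengths differ")
  stopifnot_msg(all(diff(wavenumber) > 0),
                "wavenumber grid must be strictly increasing")
  structure(list(wavenumber = wavenumber, value = value, mode = mode,
                 mask = mask),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("FTIR spectrum (%s): %d points, %.0f-%.0f cm^-1, %d masked\n",
              x$mode, length(x$wavenumber), min(x$wavenumber),
              max(x$wavenumber), sum(x$mask)))
  invisible(x)
}

#' Convert a reflectance spectrum to absorbance
#'
#' `A = log10(1/R)`, the DRIFT-spectroscopy convention.
#'
#' @param spectrum an `ftir_spectrum` in reflectance mode with values in
#'   (0, 1\].
#' @return the spectrum in absorbance mode.
#' @export
to_absorbance <- function(spectrum) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  stopifnot_msg(spectrum$mode == "reflectance",
                "spectrum is not in reflectance mode")
  bad <- spectrum$value <= 0
  if (any(bad))
    stop("nonpositive reflectance at wavenumbers: ",
         paste(head(spectrum$wavenumber[bad], 5), collapse = ", "),
         if (sum(bad) > 5) " ..." else "", call. = FALSE)
  out <- spectrum
  out$value <- log10(1 / spectrum$value)
  out$mode <- "absorbance"
  out
}

# the three spectral regions dominated by mineral (Fe/Al oxyhydroxide and
# silicate) absorption, excluded from organic-matter analysis
mineral_regions <- function() {
  list(c(-Inf, 1200), c(1750, 2000), c(3000, Inf))
}

#' Mask mineral-dominated spectral regions
#'
#' Marks <1200 cm^-1, 1750-2000 cm^-1 and >3000 cm^-1 as excluded; masked
#' points are dropped from all downstream area and peak computations.
#' Idempotent.
#'
#' @param spectrum an `ftir_spectrum` in absorbance mode.
#' @return the spectrum with its mask set.
#' @export
mask_mineral_regions <- function(spectrum) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  stopifnot_msg(spectrum$mode == "absorbance",
                "mask is applied to absorbance spectra")
  wn <- spectrum$wavenumber
  m <- rep(FALSE, length(wn))
  for (r in mineral_regions()) m <- m | (wn > r[1] & wn < r[2])
  spectrum$mask <- m
  spectrum
}

#' Total integrated spectral area over unmasked absorbance
#'
#' Trapezoidal integral computed separately over each contiguous unmasked
#' segment.
#'
#' @param spectrum masked absorbance `ftir_spectrum`.
#' @return integrated area (absorbance x cm^-1).
#' @export
spectral_area <- function(spectrum) {
  stopifnot_msg(spectrum$mode == "absorbance", "need an absorbance spectrum")
  keep <- !spectrum$mask
  wn <- spectrum$wavenumber
  v <- spectrum$value
  segs <- split(which(keep), cumsum(!keep)[keep])
  sum(vapply(segs, function(idx) {
    if (length(idx) < 2) return(0)
    sum(diff(wn[idx]) * (v[idx][-1] + v[idx][-length(idx)]) / 2)
  }, numeric(1)))
}

# Savitzky-Golay smoothed second derivative (window 11, degree 3 defaults)
sg_second_derivative <- function(values, spacing, window = 11, degree = 3) {
  if (length(values) < window) return(rep(NA_real_, length(values)))
  signal::sgolayfilt(values, p = degree, n = window, m = 2) / spacing^2
}

# endpoint on one flank of a peak: nearest interior strict local minimum;
# on a flank that descends monotonically to the search edge, the flank
# minimum (the edge) serves as the endpoint; a flank with no descending
# minimum at all falls back to the maximum of the smoothed second
# derivative (the bend of a rising shoulder).
flank_endpoint <- function(v, d2, idx, peak_at_end) {
  n <- length(idx)
  if (n < 2) return(idx[1])
  x <- v[idx]
  interior <- which(diff(sign(diff(x))) > 0) + 1   # strict local minima
  if (peak_at_end) interior <- rev(interior)       # nearest to the peak first
  if (length(interior) > 0) return(idx[interior[1]])
  mono_min <- which.min(x)
  edge <- if (peak_at_end) 1 else n
  if (mono_min == edge) return(idx[edge])          # descending flank
  d2x <- d2[idx]
  if (all(is.na(d2x))) return(idx[edge])
  idx[which.max(d2x)]
}

#' Semi-quantify one FTIR absorption band
#'
#' Locates the band peak (maximum absorbance inside the band window),
#' determines flanking endpoints within the window extended by
#' `margin` cm^-1 — nearest strict local minimum per flank, the flank
#' minimum where the trace descends monotonically to the search edge, or
#' the maximum of the Savitzky-Golay-smoothed second derivative on a flank
#' without one — draws a linear baseline between the endpoint values and
#' takes the maximum baseline-corrected absorbance between the endpoints as
#' the peak height (floored at 0). The height is also normalized by the
#' total integrated unmasked spectral area.
#'
#' @param spectrum masked absorbance `ftir_spectrum`.
#' @param band band name from [ftir_bands()] or a list with `band`, `lo`,
#'   `hi` (cm^-1).
#' @param margin endpoint-search extension beyond the band window, cm^-1.
#' @param sg_window,sg_degree Savitzky-Golay parameters for the
#'   second-derivative fallback.
#' @return list of class `peak_band`: `band`, `window`, `peak_wn`,
#'   `endpoints`, `endpoint_method` (per flank), `height`, `height_norm`.
#' @export
quantify_peak <- function(spectrum, band, margin = 40,
                          sg_window = 11, sg_degree = 3) {
  stopifnot_msg(spectrum$mode == "absorbance", "need an absorbance spectrum")
  if (is.character(band)) {
    bd <- ftir_bands()
    stopifnot_msg(band %in% bd$band, paste("unknown band:", band))
    band <- as.list(bd[bd$band == band, ])
  }
  wn <- spectrum$wavenumber
  v <- spectrum$value
  win <- which(wn >= band$lo & wn <= band$hi & !spectrum$mask)
  stopifnot_msg(length(win) >= 5,
                "band window must contain >= 5 unmasked grid points")
  ext <- which(wn >= band$lo - margin & wn <= band$hi + margin &
                 !spectrum$mask)

  if (sd(v[win]) == 0) {
    warning("flat band window (zero variance): returning zero height")
    return(structure(list(band = band$band, window = c(band$lo, band$hi),
                          peak_wn = mean(c(band$lo, band$hi)),
                          endpoints = c(band$lo, band$hi),
                          endpoint_method = c("flat", "flat"),
                          height = 0, height_norm = 0),
                     class = "peak_band"))
  }

  peak <- win[which.max(v[win])]
  spacing <- median(diff(wn))
  # endpoints are hunted on the Savitzky-Golay-smoothed trace so that
  # noise wiggles do not masquerade as flank minima
  vs <- if (length(v) >= sg_window)
    signal::sgolayfilt(v, p = sg_degree, n = sg_window) else v
  d2 <- sg_second_derivative(v, spacing, sg_window, sg_degree)

  left_idx <- ext[ext <= peak]
  right_idx <- ext[ext >= peak]
  lp <- flank_endpoint(vs, d2, left_idx, peak_at_end = TRUE)
  rp <- flank_endpoint(vs, d2, right_idx, peak_at_end = FALSE)
  method_of <- function(idx_set, ep, peak_at_end) {
    x <- vs[idx_set]
    interior <- which(diff(sign(diff(x))) > 0) + 1
    if (length(interior) > 0 && ep %in% idx_set[interior]) "local_minimum"
    else if (ep == idx_set[if (peak_at_end) 1 else length(idx_set)])
      "local_minimum"
    else "second_derivative"
  }
  meth <- c(method_of(left_idx, lp, TRUE), method_of(right_idx, rp, FALSE))

  seg <- lp:rp
  base <- v[lp] + (v[rp] - v[lp]) * (wn[seg] - wn[lp]) / (wn[rp] - wn[lp])
  height <- max(0, max(v[seg] - base))
  area <- spectral_area(spectrum)
  structure(list(band = band$band, window = c(band$lo, band$hi),
                 peak_wn = wn[peak], endpoints = c(wn[lp], wn[rp]),
                 endpoint_method = meth, height = height,
                 height_norm = if (area > 0) height / area else NA_real_),
            class = "peak_band")
}

#' SOC chemistry ratios from band heights
#'
#' Aromatic/aliphatic, aromatic/acid and aliphatic/acid ratios of
#' area-normalized peak heights; the two aliphatic sub-bands are summed
#' into a single aliphatic height. Zero denominators propagate as `NA`
#' with an `undefined` flag.
#'
#' @param peaks list of `peak_band` objects covering bands `aliph_1`,
#'   `aliph_2`, `acid`, `arom` (as from [quantify_peaks()]).
#' @return list of class `chemistry_ratios`: `arom_aliph`, `arom_acid`,
#'   `aliph_acid`, `heights` (named normalized heights), `undefined`.
#' @export
chemistry_ratios <- function(peaks) {
  h <- setNames(vapply(peaks, function(p) p$height_norm, numeric(1)),
                vapply(peaks, function(p) p$band, character(1)))
  need <- c("aliph_1", "aliph_2", "acid", "arom")
  stopifnot_msg(all(need %in% names(h)),
                paste("missing band heights:",
                      paste(setdiff(need, names(h)), collapse = ", ")))
  aliph <- h[["aliph_1"]] + h[["aliph_2"]]
  rat <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  out <- list(arom_aliph = rat(h[["arom"]], aliph),
              arom_acid = rat(h[["arom"]], h[["acid"]]),
              aliph_acid = rat(aliph, h[["acid"]]),
              heights = c(h, aliph = unname(aliph)))
  out$undefined <- names(which(vapply(out[1:3], is.na, logical(1))))
  class(out) <- "chemistry_ratios"
  out
}

#' Quantify all four bands of one spectrum
#'
#' Convenience wrapper: reflectance -> absorbance -> mineral masking ->
#' per-band [quantify_peak()].
#'
#' @param spectrum an `ftir_spectrum` (either mode).
#' @param ... passed to [quantify_peak()].
#' @return named list of `peak_band` objects.
#' @export
quantify_peaks <- function(spectrum, ...) {
  if (spectrum$mode == "reflectance") spectrum <- to_absorbance(spectrum)
  spectrum <- mask_mineral_regions(spectrum)
  bands <- ftir_bands()$band
  setNames(lapply(bands, function(b) quantify_peak(spectrum, b, ...)), bands)
}

#' FTIR chemistry table for a spectrum collection
#'
#' @param spectra list of `ftir_spectrum` objects.
#' @param ... passed to [quantify_peak()].
#' @return data.frame: sample, per-band heights (raw and normalized) and
#'   the three chemistry ratios.
#' @export
chemistry_table <- function(spectra, ...) {
  do.call(rbind, lapply(seq_along(spectra), function(i) {
    pk <- quantify_peaks(spectra[[i]], ...)
    cr <- chemistry_ratios(pk)
    data.frame(sample = i,
               aliph_1 = pk$aliph_1$height, aliph_2 = pk$aliph_2$height,
               acid = pk$acid$height, arom = pk$arom$height,
               aliph_1_norm = pk$aliph_1$height_norm,
               aliph_2_norm = pk$aliph_2$height_norm,
               acid_norm = pk$acid$height_norm,
               arom_norm = pk$arom$height_norm,
               arom_aliph = cr$arom_aliph, arom_acid = cr$arom_acid,
               aliph_acid = cr$aliph_acid)
  }))
}
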