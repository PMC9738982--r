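#' Construct a single absorption or transmittance spectrum
#'
#' A `spectrum` holds one optical measurement of a cell suspension: a strictly
#' increasing wavelength grid (nm) with one value per grid point, either as
#' transmittance fraction (0--1, relative to a blank-medium reference cuvette)
#' or as absorption percentage, \eqn{Abs = 100(1 - T)}. Metadata carries the
#' species label, the reference (cell-counter) concentration in cells/mL, the
#' sampling time in hours, and free-text set/cuvette identifiers.
#'
#' @param wavelengths_nm numeric, strictly increasing wavelength grid in nm.
#' @param values numeric, same length as `wavelengths_nm`.
#' @param value_kind `"transmittance_fraction"` or `"absorption_percent"`.
#' @param species optional species label (free text).
#' @param counter_concentration optional reference concentration, cells/mL.
#' @param time_h optional sampling time, hours.
#' @param set_id,cuvette_id optional free-text identifiers (e.g. week label).
#' @param true_concentration optional ground-truth concentration (used by the
#'   synthetic generator; `NA` for measured spectra).
#' @param tolerance admissible undershoot below 0 (absorption percentage
#'   points, or the equivalent fraction for transmittance) before validation
#'   fails; default 1.0, to admit reference-subtracted noise near zero.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(wavelengths_nm, values,
                     value_kind = c("absorption_percent", "transmittance_fraction"),
                     species = NA_character_, counter_concentration = NA_real_,
                     time_h = NA_real_, set_id = NA_character_,
                     cuvette_id = NA_character_, true_concentration = NA_real_,
                     tolerance = 1.0) {
  value_kind <- match.arg(value_kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stopf("wavelengths (%d) and values (%d) differ in length",
          length(wavelengths_nm), length(values))
  if (length(wavelengths_nm) == 0) stopf("empty spectrum")
  if (any(diff(wavelengths_nm) <= 0))
    stopf("wavelengths must be strictly increasing (violation near index %d)",
          which(diff(wavelengths_nm) <= 0)[1])
  s <- structure(list(
    wavelengths_nm = wavelengths_nm,
    values = values,
    value_kind = value_kind,
    meta = list(species = as.character(species),
                counter_concentration = as.numeric(counter_concentration),
                time_h = as.numeric(time_h), set_id = as.character(set_id),
                cuvette_id = as.character(cuvette_id),
                true_concentration = as.numeric(true_concentration))
  ), class = "spectrum")
  validate_spectrum(s, tolerance = tolerance)
  s
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f nm, %s\n",
              length(x$values), min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$value_kind))
  m <- x$meta
  if (!is.na(m$species)) cat("  species:", m$species, "\n")
  if (!is.na(m$counter_concentration))
    cat(sprintf("  counter concentration: %.3g cells/mL\n", m$counter_concentration))
  if (!is.na(m$time_h)) cat(sprintf("  time: %g h\n", m$time_h))
  invisible(x)
}

validate_spectrum <- function(s, tolerance = 1.0) {
  v <- s$values
  if (s$value_kind == "transmittance_fraction") {
    lo <- -tolerance / 100; hi <- 1 + tolerance / 100
  } else {
    lo <- -tolerance; hi <- 100 + tolerance
  }
  if (any(!is.finite(v))) stopf("non-finite spectrum values")
  if (any(v < lo) || any(v > hi))
    stopf("values outside [%g, %g] for kind %s (range %g..%g)",
          lo, hi, s$value_kind, min(v), max(v))
  invisible(s)
}

#' Collect spectra into an ordered set
#'
#' @param spectra list of [spectrum()] objects.
#' @return object of class `spectrum_set` with a `common_grid` flag that is
#'   `TRUE` when all members share a bitwise-identical wavelength grid.
#' @export
spectrum_set <- function(spectra) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (!all(vapply(spectra, inherits, logical(1), "spectrum")))
    stopf("all elements must be spectrum objects")
  common <- length(spectra) <= 1 ||
    all(vapply(spectra[-1], function(s)
      identical(s$wavelengths_nm, spectra[[1]]$wavelengths_nm), logical(1)))
  structure(list(spectra = spectra, common_grid = common),
            class = "spectrum_set")
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra, common grid: %s\n",
              length(x$spectra), x$common_grid))
  invisible(x)
}

#' Extract counter concentrations from a spectrum set
#' @param set a `spectrum_set`.
#' @return numeric vector of counter concentrations (cells/mL), `NA` if absent.
#' @export
counter_concentrations <- function(set) {
  vapply(set$spectra, function(s) s$meta$counter_concentration, numeric(1))
}

#' Convert between transmittance fraction and absorption percent
#'
#' Uses the defining relation \eqn{Abs(\lambda) = 100\,(1 - T(\lambda))} and
#' its algebraic inverse; the conversion is involutive to machine precision.
#'
#' @param s a `spectrum`.
#' @param target target value kind.
#' @return converted `spectrum` with metadata and grid preserved.
#' @export
convert_value_kind <- function(s, target = c("absorption_percent",
                                             "transmittance_fraction")) {
  target <- match.arg(target)
  if (s$value_kind == target) {
    warnf("spectrum already of kind %s; returning unchanged", target)
    return(s)
  }
  out <- s
  out$value_kind <- target
  out$values <- if (target == "absorption_percent") 100 * (1 - s$values)
                else 1 - s$values / 100
  out
}

#' Restrict a spectrum to a wavelength window
#'
#' Default window 330--860 nm: outside this band the white-light source and
#' detector leave too little signal over background noise.
#'
#' @param s a `spectrum`.
#' @param lo_nm,hi_nm inclusive window bounds in nm.
#' @return windowed `spectrum`; metadata preserved.
#' @export
window_spectrum <- function(s, lo_nm = 330, hi_nm = 860) {
  if (lo_nm >= hi_nm) stopf("window lower bound must be below upper bound")
  keep <- s$wavelengths_nm >= lo_nm & s$wavelengths_nm <= hi_nm
  if (!any(keep)) stopf("window [%g, %g] nm contains no samples", lo_nm, hi_nm)
  out <- s
  out$wavelengths_nm <- s$wavelengths_nm[keep]
  out$values <- s$values[keep]
  out
}

#' Default deuterium-lamp artifact mask windows (nm)
#'
#' The hydrogen Balmer emission lines of a deuterium lamp leave narrow spikes
#' in reference-divided spectra; these default masks bracket H-beta (486 nm)
#' and H-alpha (656 nm).
#' @return list of `c(lo, hi)` windows in nm.
#' @export
default_artifact_masks <- function() list(c(484, 488), c(654, 658))

#' Remove narrow lamp-emission artifacts by interpolation
#'
#' Samples inside each mask window are replaced by linear interpolation
#' between the nearest unmasked neighbours; the grid is unchanged.
#'
#' @param s a `spectrum`.
#' @param mask_windows list of `c(lo, hi)` nm windows;
#'   default [default_artifact_masks()].
#' @return `spectrum` with masked samples interpolated.
#' @export
remove_lamp_artifacts <- function(s, mask_windows = default_artifact_masks()) {
  if (length(mask_windows) == 0) return(s)
  w <- s$wavelengths_nm
  masked <- rep(FALSE, length(w))
  for (mw in mask_windows) {
    if (length(mw) != 2 || mw[1] >= mw[2]) stopf("each mask must be c(lo, hi) with lo < hi")
    masked <- masked | (w >= mw[1] & w <= mw[2])
  }
  if (!any(masked)) return(s)
  if (masked[1] || masked[length(w)])
    stopf("mask covers a grid end; no anchor for interpolation")
  out <- s
  out$values[masked] <- stats::approx(w[!masked], s$values[!masked],
                                      xout = w[masked])$y
  out
}

#' Resample a spectrum set onto a common wavelength grid
#'
#' Linear interpolation onto the first spectrum's grid. Grids whose coverage
#' differs by more than `max_coverage_diff_nm` are rejected rather than
#' extrapolated.
#'
#' @param set a `spectrum_set`.
#' @param max_coverage_diff_nm maximum allowed difference in grid end points.
#' @return `spectrum_set` with `common_grid = TRUE`.
#' @export
resample_common_grid <- function(set, max_coverage_diff_nm = 1) {
  if (set$common_grid) return(set)
  ref <- set$spectra[[1]]$wavelengths_nm
  out <- lapply(set$spectra, function(s) {
    w <- s$wavelengths_nm
    if (abs(w[1] - ref[1]) > max_coverage_diff_nm ||
        abs(w[length(w)] - ref[length(ref)]) > max_coverage_diff_nm)
      stopf("grid coverage differs by more than %g nm; refusing to resample",
            max_coverage_diff_nm)
    # rule = 2: constant extrapolation over the <= max_coverage_diff_nm edges
    s$values <- stats::approx(w, s$values, xout = ref, rule = 2)$y
    s$wavelengths_nm <- ref
    s
  })
  spectrum_set(out)
}

#' Clip small negative absorption values to zero
#'
#' Reference-subtracted noise can dip a little below zero near transparent
#' wavelengths; values in `[-tolerance, 0)` are clipped to 0 and counted.
#'
#' @param s a `spectrum` in absorption percent.
#' @param tolerance maximum admissible undershoot (percentage points).
#' @return `spectrum` with attribute `n_clipped` giving the clipped count.
#' @export
clip_negative_absorption <- function(s, tolerance = 1.0) {
  if (s$value_kind != "absorption_percent")
    stopf("clip_negative_absorption expects absorption_percent")
  neg <- s$values < 0
  if (any(s$values < -tolerance))
    stopf("absorption below -%g; not attributable to noise", tolerance)
  s$values[neg] <- 0
  attr(s, "n_clipped") <- sum(neg)
  s
}

#' Quality-filter a spectrum set by free two-Gaussian fit
#'
#' A documented stand-in for visual spectrum triage: each spectrum is fitted
#' with `n_gauss` free Gaussians ([fit_free_gaussians()]) and kept when the
#' fit attains \eqn{R^2 \ge} `r2_threshold` and the values satisfy the
#' spectrum invariants (small negatives clipped, see
#' [clip_negative_absorption()]).
#'
#' @param set `spectrum_set` in absorption percent on a common windowed grid.
#' @param r2_threshold minimum fit R-squared; default 0.9.
#' @param n_gauss number of Gaussians in the probe fit.
#' @param tolerance negative-absorption tolerance (percentage points).
#' @return list with elements `kept` and `rejected` (both `spectrum_set`) and
#'   `reasons` (character, one entry per rejected spectrum).
#' @export
quality_filter <- function(set, r2_threshold = 0.9, n_gauss = 2,
                           tolerance = 1.0) {
  kept <- list(); rejected <- list(); reasons <- character(0)
  for (s in set$spectra) {
    bad <- NULL
    s2 <- tryCatch(clip_negative_absorption(s, tolerance = tolerance),
                   error = function(e) { bad <<- conditionMessage(e); s })
    if (is.null(bad) && any(s2$values > 100 + tolerance))
      bad <- "absorption above 100%"
    if (is.null(bad)) {
      r2 <- tryCatch(fit_free_gaussians(s2, n_gauss = n_gauss)$r2,
                     error = function(e) -Inf)
      if (!is.finite(r2) || r2 < r2_threshold)
        bad <- sprintf("free %d-Gaussian fit R2 = %.3f below threshold %.3f",
                       n_gauss, r2, r2_threshold)
    }
    if (is.null(bad)) kept[[length(kept) + 1]] <- s2
    else {
      rejected[[length(rejected) + 1]] <- s
      reasons <- c(reasons, bad)
    }
  }
  list(kept = spectrum_set(kept), rejected = spectrum_set(rejected),
       reasons = reasons)
}
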