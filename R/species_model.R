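#' Gaussian component with concentration-dependent coefficients
#'
#' @param amplitude,center,width [subfunction()] objects (a bare number is
#'   wrapped as a constant sub-function). Amplitude in absorption percent,
#'   center and width in nm.
#' @return object of class `gaussian_component`.
#' @export
gaussian_component <- function(amplitude, center, width) {
  wrap <- function(x) if (inherits(x, "subfunction")) x else subfunction("constant", x)
  structure(list(amplitude = wrap(amplitude), center = wrap(center),
                 width = wrap(width)), class = "gaussian_component")
}

#' Species spectral-shape model
#'
#' An ordered sum of Gaussian components describing how a species' absorption
#' spectrum (percent) evolves with cell concentration:
#' \deqn{Abs(\lambda, C) = \sum_i a_i(C)\,
#'   \exp\!\left(-\left(\frac{\lambda - b_i(C)}{c_i(C)}\right)^2\right)}
#' where each coefficient is a [subfunction()] of C. By convention component 1
#' is the concentration-sensitive Gaussian and component 2 a near-constant
#' baseline rising toward the near infrared.
#'
#' @param name species label.
#' @param components list of [gaussian_component()]s (default length 2).
#' @param concentration_range `c(C_min, C_max)` cells/mL over which the model
#'   was calibrated.
#' @param wavelength_window `c(lo, hi)` nm.
#' @param concentration_floor concentration below which the species is treated
#'   as absent (contributes 0\% in mixtures); relevant for log-linear models
#'   whose coefficients are meaningless as C tends to 0. Default 1e4.
#' @return object of class `species_model`.
#' @export
species_model <- function(name, components, concentration_range,
                          wavelength_window = c(330, 860),
                          concentration_floor = 1e4) {
  if (length(components) < 1) stopf("need at least one Gaussian component")
  if (!all(vapply(components, inherits, logical(1), "gaussian_component")))
    stopf("components must be gaussian_component objects")
  if (length(concentration_range) != 2 ||
      concentration_range[1] >= concentration_range[2])
    stopf("concentration_range must be c(C_min, C_max) with C_min < C_max")
  structure(list(name = name, components = components,
                 concentration_range = as.numeric(concentration_range),
                 wavelength_window = as.numeric(wavelength_window),
                 concentration_floor = concentration_floor),
            class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf("<species_model> %s: %d Gaussian component(s), %g-%g cells/mL, %g-%g nm\n",
              x$name, length(x$components), x$concentration_range[1],
              x$concentration_range[2], x$wavelength_window[1],
              x$wavelength_window[2]))
  for (i in seq_along(x$components)) {
    g <- x$components[[i]]
    cat(sprintf("  Gaussian %d: amplitude %s(%s), center %s(%s), width %s(%s)\n",
                i, g$amplitude$family, paste(format(g$amplitude$params, digits = 4), collapse = ","),
                g$center$family, paste(format(g$center$params, digits = 4), collapse = ","),
                g$width$family, paste(format(g$width$params, digits = 4), collapse = ",")))
  }
  invisible(x)
}

#' Evaluate a species model on a wavelength grid
#'
#' @param m a [species_model()].
#' @param lambda_nm wavelength grid (nm).
#' @param C a single concentration (cells/mL). Values outside the model's
#'   calibrated range trigger an extrapolation warning, not an error.
#' @param warn_extrapolation emit the warning? Default `TRUE`.
#' @return absorption percent series, one value per grid point (raw model
#'   value; no clamping).
#' @export
eval_species_model <- function(m, lambda_nm, C, warn_extrapolation = TRUE) {
  if (length(C) != 1) stopf("C must be a single concentration")
  if (warn_extrapolation &&
      (C < m$concentration_range[1] || C > m$concentration_range[2]))
    warnf("concentration %g outside calibrated range [%g, %g]; extrapolating",
          C, m$concentration_range[1], m$concentration_range[2])
  out <- numeric(length(lambda_nm))
  for (g in m$components) {
    a <- eval_subfunction(g$amplitude, C)
    if (a == 0) next  # vanished component (e.g. Beer-Lambert amplitude at C = 0)
    b <- eval_subfunction(g$center, C)
    cc <- eval_subfunction(g$width, C)
    if (cc <= 0) stopf("evaluated Gaussian width %g <= 0 at C = %g", cc, C)
    out <- out + a * exp(-((lambda_nm - b) / cc)^2)
  }
  out
}

#' Combine absorption spectra by the absorbance-additivity mixture law
#'
#' Optical densities of independent absorbers add, so transmittances
#' multiply. In percent-absorption terms the spectrum of a mixture of n
#' species is
#' \deqn{Abs_{mix} = 100\left(1 - \prod_i \left(1 - Abs_i/100\right)\right).}
#'
#' @param spectra list of absorption-percent series on one grid (values in
#'   `[0, 100]` within `tolerance`).
#' @param tolerance admitted overshoot outside `[0, 100]` before validation
#'   fails; offending values are clamped into range with a warning.
#' @return combined absorption percent series.
#' @export
mix_absorption_spectra <- function(spectra, tolerance = 0.5) {
  if (length(spectra) == 0) stopf("no spectra to mix")
  n <- length(spectra[[1]])
  t_prod <- rep(1, n)
  clamped <- 0L
  for (v in spectra) {
    if (length(v) != n) stopf("all spectra must share one grid")
    if (any(v < -tolerance) || any(v > 100 + tolerance))
      stopf("absorption values outside [%g, %g]", -tolerance, 100 + tolerance)
    out_of_range <- v < 0 | v > 100
    if (any(out_of_range)) {
      clamped <- clamped + sum(out_of_range)
      v <- pmin(pmax(v, 0), 100)
    }
    t_prod <- t_prod * (1 - v / 100)
  }
  if (clamped > 0)
    warnf("%d value(s) clamped into [0, 100] before mixing", clamped)
  100 * (1 - t_prod)
}

#' Multi-species mixture model
#'
#' @param species list of [species_model()]s sharing one wavelength window.
#' @return object of class `mixture_model`.
#' @export
mixture_model <- function(species) {
  if (length(species) < 1) stopf("need at least one species")
  if (!all(vapply(species, inherits, logical(1), "species_model")))
    stopf("species must be species_model objects")
  win <- species[[1]]$wavelength_window
  for (m in species[-1])
    if (!isTRUE(all.equal(m$wavelength_window, win)))
      stopf("all species must share one wavelength window")
  structure(list(species = species), class = "mixture_model")
}

#' Evaluate a mixture model
#'
#' Each species is evaluated with [eval_species_model()] (a species below its
#' concentration floor contributes 0\%), individual spectra are clamped to
#' `[0, 100]`, and combined with [mix_absorption_spectra()].
#'
#' @param mm a [mixture_model()].
#' @param lambda_nm wavelength grid (nm).
#' @param concentrations one concentration per species (cells/mL).
#' @param warn_extrapolation passed to [eval_species_model()].
#' @return absorption percent series in `[0, 100]`.
#' @export
eval_mixture_model <- function(mm, lambda_nm, concentrations,
                               warn_extrapolation = FALSE) {
  if (length(concentrations) != length(mm$species))
    stopf("%d concentrations supplied for %d species",
          length(concentrations), length(mm$species))
  specs <- lapply(seq_along(mm$species), function(i) {
    m <- mm$species[[i]]; C <- concentrations[i]
    if (C < m$concentration_floor) return(numeric(length(lambda_nm)))
    v <- eval_species_model(m, lambda_nm, C,
                            warn_extrapolation = warn_extrapolation)
    pmin(pmax(v, 0), 100)
  })
  mix_absorption_spectra(specs)
}

#' Concentration equivalent of an absorption change
#'
#' Converts an absorption offset at one wavelength into the concentration
#' change that would produce it: solves
#' \eqn{Abs(\lambda, C') = Abs(\lambda, C) + \Delta Abs} for \eqn{C'} by
#' bracketed root finding and returns \eqn{C' - C}. Used e.g. to express
#' cuvette-to-cuvette absorption variability in cells/mL.
#'
#' @param m a [species_model()].
#' @param lambda_nm single wavelength (nm).
#' @param C reference concentration (cells/mL), inside the model range.
#' @param delta_abs absorption offset (percentage points).
#' @param rel_tol relative tolerance of the root find.
#' @return concentration change in cells/mL (sign follows `delta_abs` for a
#'   monotone model).
#' @export
concentration_equivalent_of_absorption_change <- function(m, lambda_nm, C,
                                                          delta_abs,
                                                          rel_tol = 1e-6) {
  if (delta_abs == 0) return(0)
  target <- eval_species_model(m, lambda_nm, C, warn_extrapolation = FALSE) +
    delta_abs
  lo <- m$concentration_range[1] / 2
  hi <- m$concentration_range[2] * 2
  f <- function(x)
    eval_species_model(m, lambda_nm, x, warn_extrapolation = FALSE) - target
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi))
    stopf(paste0("no concentration in [%g, %g] attains absorption %.3f%% at ",
                 "%g nm (attainable range %.3f%%..%.3f%%)"),
          lo, hi, target, lambda_nm, min(flo, fhi) + target,
          max(flo, fhi) + target)
  root <- stats::uniroot(f, c(lo, hi), tol = rel_tol * C)$root
  root - C
}

#' Write a species model to JSON
#'
#' @param m a [species_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_model <- function(m, path) {
  obj <- list(name = m$name,
              wavelength_window = m$wavelength_window,
              concentration_range = m$concentration_range,
              concentration_floor = m$concentration_floor,
              components = lapply(m$components, function(g)
                list(amplitude = subfunction_to_list(g$amplitude),
                     center = subfunction_to_list(g$center),
                     width = subfunction_to_list(g$width))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a species model from JSON
#' @param path JSON file written by [write_species_model()].
#' @return a [species_model()].
#' @export
read_species_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  species_model(
    name = obj$name,
    components = lapply(obj$components, function(g)
      gaussian_component(subfunction_from_list(g$amplitude),
                         subfunction_from_list(g$center),
                         subfunction_from_list(g$width))),
    concentration_range = as.numeric(unlist(obj$concentration_range)),
    wavelength_window = as.numeric(unlist(obj$wavelength_window)),
    concentration_floor = obj$concentration_floor %||% 1e4)
}

#' Built-in calibrated model for CEM T-lymphoblast suspensions
#'
#' Published two-Gaussian shape-model parameters for CEM cells (component 1:
#' Beer-Lambert amplitude, constant center, power-law width; component 2:
#' constant baseline Gaussian), valid for 1e5-1e6 cells/mL over 330-860 nm.
#' @return a [species_model()].
#' @export
cem_reference_model <- function() {
  read_species_model(system.file("extdata", "cem_reference.json",
                                 package = "speccult", mustWork = TRUE))
}

#' Built-in calibrated model for Candida albicans suspensions
#'
#' Published two-Gaussian shape-model parameters for C. albicans yeast
#' (log-linear amplitudes and a log-linear center), valid for 0.5e6-4e6
#' cells/mL over 330-860 nm. At these parameters the first Gaussian's center
#' lies far below the window, so that component acts as a broad sloping
#' background rather than a visible peak; the parameters are used as
#' published.
#' @return a [species_model()].
#' @export
ca_reference_model <- function() {
  read_species_model(system.file("extdata", "ca_reference.json",
                                 package = "speccult", mustWork = TRUE))
}
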