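# Synthetic-spectra generator: emulates dilution-series calibration sets,
# single-cuvette growth series, and reconstructed two-species mixtures with
# the noise structure of the measurement chain (cuvette-to-cuvette optical
# variability, per-wavelength detector noise, and cell-counter sampling
# dispersion). Ground-truth concentrations are always carried alongside the
# noisy counter labels so recovery experiments have an oracle.

#' Noise configuration for the synthetic generator
#'
#' @param cuvette_sd relative standard deviation of the per-cuvette
#'   multiplicative amplitude factor. Default 0.0106, i.e. a 2.5\% full width
#'   at half maximum (FWHM = 2.355 sd) of the absorption spread across
#'   disposable cuvettes at 600 nm.
#' @param detector_sd per-wavelength additive noise, absorption percentage
#'   points. Default 0.2.
#' @param counter_cv relative dispersion of the reported counter
#'   concentration (sampling error of a 10 uL aliquot). Default 0.10.
#' @param seed integer seed; identical seed and config give bitwise-identical
#'   output. `NULL` uses the current RNG state.
#' @param scale_baseline should the cuvette factor also scale baseline
#'   (concentration-independent) components? Default `TRUE`: the cuvette sits
#'   in the optical path of every component.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(cuvette_sd = 0.0106, detector_sd = 0.2,
                         counter_cv = 0.10, seed = NULL,
                         scale_baseline = TRUE) {
  if (cuvette_sd < 0 || detector_sd < 0 || counter_cv < 0)
    stopf("noise standard deviations must be >= 0")
  structure(list(cuvette_sd = cuvette_sd, detector_sd = detector_sd,
                 counter_cv = counter_cv, seed = seed,
                 scale_baseline = scale_baseline), class = "noise_config")
}

#' Zero-noise configuration
#' @return `noise_config` with all noise terms 0.
#' @export
noise_free <- function() noise_config(0, 0, 0, seed = NULL)

build_grid <- function(grid) {
  if (length(grid) != 3 || grid[3] <= 0)
    stopf("grid must be c(lo, hi, step) with step > 0")
  seq(grid[1], grid[2], by = grid[3])
}

# Evaluate model components split into concentration-sensitive vs baseline
# (constant-coefficient) parts so the cuvette factor can scale them
# separately.
eval_split <- function(m, lambda, C) {
  sensitive <- numeric(length(lambda)); baseline <- numeric(length(lambda))
  for (g in m$components) {
    a <- eval_subfunction(g$amplitude, C)
    if (a == 0) next
    b <- eval_subfunction(g$center, C)
    cc <- eval_subfunction(g$width, C)
    if (cc <= 0) stopf("evaluated Gaussian width %g <= 0 at C = %g", cc, C)
    v <- a * exp(-((lambda - b) / cc)^2)
    is_baseline <- all(vapply(g[c("amplitude", "center", "width")],
                              function(f) f$family == "constant", logical(1)))
    if (is_baseline) baseline <- baseline + v else sensitive <- sensitive + v
  }
  list(sensitive = sensitive, baseline = baseline)
}

synth_one <- function(m, lambda, C_true, noise, cuvette_factor = NULL,
                      species = m$name, set_id = NA_character_,
                      cuvette_id = NA_character_, time_h = NA_real_) {
  g <- cuvette_factor %||%
    (1 + stats::rnorm(1, 0, noise$cuvette_sd))
  parts <- eval_split(m, lambda, C_true)
  v <- if (noise$scale_baseline) g * (parts$sensitive + parts$baseline)
       else g * parts$sensitive + parts$baseline
  v <- v + stats::rnorm(length(lambda), 0, noise$detector_sd)
  v <- pmin(pmax(v, 0), 100)
  counter <- C_true * (1 + stats::rnorm(1, 0, noise$counter_cv))
  spectrum(lambda, v, "absorption_percent", species = species,
           counter_concentration = counter, time_h = time_h,
           set_id = set_id, cuvette_id = cuvette_id,
           true_concentration = C_true)
}

#' Generate a synthetic calibration set
#'
#' One spectrum per concentration: the model spectrum is scaled by a
#' per-cuvette factor `g ~ Normal(1, cuvette_sd)`, perturbed by i.i.d.
#' per-wavelength detector noise, and clipped to `[0, 100]`. The reported
#' counter concentration is `true * (1 + Normal(0, counter_cv))`; the true
#' concentration is stored in `meta$true_concentration`.
#'
#' @param m a [species_model()].
#' @param concentrations true concentrations (cells/mL). Default: 8 values
#'   log-spaced over the model's calibrated range, emulating a weekly
#'   dilution series.
#' @param grid `c(lo, hi, step)` in nm.
#' @param noise a [noise_config()].
#' @param set_id set label stored in each spectrum's metadata.
#' @return a [spectrum_set()] on a common grid.
#' @export
generate_calibration_set <- function(m,
                                     concentrations = logspace(
                                       m$concentration_range[1],
                                       m$concentration_range[2], 8),
                                     grid = c(330, 860, 1),
                                     noise = noise_config(),
                                     set_id = NA_character_) {
  if (length(concentrations) == 0) stopf("empty concentration list")
  lambda <- build_grid(grid)
  with_seed(noise$seed, {
    spectrum_set(lapply(seq_along(concentrations), function(i)
      synth_one(m, lambda, concentrations[i], noise,
                set_id = set_id, cuvette_id = sprintf("cuv%02d", i))))
  })
}

#' Sampling times from a measurement schedule
#'
#' Builds the union of per-segment regular sampling times, including both
#' endpoints of every segment, with duplicates removed.
#'
#' @param segments list of `c(start_h, end_h, step_h)`.
#' @return sorted numeric vector of times (hours).
#' @export
sampling_times <- function(segments) {
  t <- unlist(lapply(segments, function(sg) {
    if (length(sg) != 3 || sg[3] <= 0 || sg[1] >= sg[2])
      stopf("each segment must be c(start, end, step) with start < end, step > 0")
    unique(c(seq(sg[1], sg[2], by = sg[3]), sg[2]))
  }))
  sort(unique(t))
}

#' Default 30-hour monitoring schedule
#'
#' Hourly sampling for the first 4 h, half-hourly from 4 to 11 h, and
#' two-hourly from 21 to 30 h (25 time points; no overnight samples).
#' @return numeric vector of times (hours).
#' @export
monitoring_schedule_30h <- function()
  sampling_times(list(c(0, 4, 1), c(4, 11, 0.5), c(21, 30, 2)))

#' Piecewise-exponential concentration trajectory
#'
#' @param t times (hours).
#' @param C0 initial concentration (cells/mL).
#' @param schedule data frame with columns `t_start`, `t_end`,
#'   `doubling_time` (hours); segments must be contiguous and non-overlapping
#'   starting at `t = 0`. Growth continues at the last segment's rate beyond
#'   its end.
#' @return concentrations at `t`.
#' @export
piecewise_growth <- function(t, C0, schedule) {
  schedule <- schedule[order(schedule$t_start), , drop = FALSE]
  if (any(schedule$doubling_time <= 0)) stopf("doubling times must be > 0")
  if (nrow(schedule) > 1 &&
      any(schedule$t_start[-1] < schedule$t_end[-nrow(schedule)] - 1e-9))
    stopf("overlapping growth segments")
  vapply(t, function(ti) {
    lc <- log(C0); t_cur <- 0
    for (r in seq_len(nrow(schedule))) {
      k <- log(2) / schedule$doubling_time[r]
      seg_end <- if (r == nrow(schedule)) Inf else schedule$t_end[r]
      dt <- min(ti, seg_end) - t_cur
      if (dt <= 0) break
      lc <- lc + k * dt
      t_cur <- t_cur + dt
      if (t_cur >= ti) break
    }
    exp(lc)
  }, numeric(1))
}

#' Generate a synthetic single-cuvette growth series
#'
#' The culture grows piecewise-exponentially and is measured in a single
#' cuvette, so the cuvette-to-cuvette factor is absent (forced to 1);
#' detector noise and the counter label noise still apply.
#'
#' @param m a [species_model()].
#' @param C0 initial concentration (cells/mL).
#' @param schedule growth segments, see [piecewise_growth()].
#' @param sample_times measurement times (hours), e.g.
#'   [monitoring_schedule_30h()].
#' @param grid `c(lo, hi, step)` nm.
#' @param noise a [noise_config()]; `cuvette_sd` is ignored (single cuvette).
#' @return a [spectrum_set()] with `time_h` and ground-truth concentrations
#'   in the metadata.
#' @export
generate_growth_series <- function(m, C0, schedule,
                                   sample_times = monitoring_schedule_30h(),
                                   grid = c(330, 860, 1),
                                   noise = noise_config()) {
  if (C0 <= 0) stopf("C0 must be positive")
  lambda <- build_grid(grid)
  conc <- piecewise_growth(sample_times, C0, schedule)
  with_seed(noise$seed, {
    spectrum_set(lapply(seq_along(sample_times), function(i)
      synth_one(m, lambda, conc[i], noise, cuvette_factor = 1,
                cuvette_id = "culture", time_h = sample_times[i])))
  })
}

#' Generate reconstructed mixture spectra over a concentration grid
#'
#' Mimics computational reconstruction of co-culture spectra: one noisy
#' spectrum per species per concentration (each with its own cuvette factor
#' and counter label), combined with [mix_absorption_spectra()]. The returned
#' truth/counter tables have one row per mixture and one column per species.
#'
#' @param models list of [species_model()]s.
#' @param concentration_grid matrix or data frame (mixtures x species) of
#'   true concentrations.
#' @param grid `c(lo, hi, step)` nm.
#' @param noise a [noise_config()].
#' @return list with `set` (a [spectrum_set()] of mixture spectra), `truth`
#'   and `counter` matrices.
#' @export
generate_mixture_set <- function(models, concentration_grid,
                                 grid = c(330, 860, 1),
                                 noise = noise_config()) {
  concentration_grid <- as.matrix(concentration_grid)
  if (ncol(concentration_grid) != length(models))
    stopf("concentration grid has %d columns for %d species",
          ncol(concentration_grid), length(models))
  lambda <- build_grid(grid)
  with_seed(noise$seed, {
    counter <- concentration_grid
    spectra <- vector("list", nrow(concentration_grid))
    for (r in seq_len(nrow(concentration_grid))) {
      parts <- lapply(seq_along(models), function(i) {
        C <- concentration_grid[r, i]
        if (C < models[[i]]$concentration_floor)
          return(list(values = numeric(length(lambda)), counter = C))
        sp <- synth_one(models[[i]], lambda, C, noise)
        list(values = sp$values, counter = sp$meta$counter_concentration)
      })
      counter[r, ] <- vapply(parts, `[[`, numeric(1), "counter")
      mixed <- mix_absorption_spectra(lapply(parts, `[[`, "values"))
      spectra[[r]] <- spectrum(lambda, mixed, "absorption_percent",
                               species = "mixture",
                               cuvette_id = sprintf("mix%04d", r))
    }
    colnames(counter) <- vapply(models, `[[`, character(1), "name")
    truth <- concentration_grid
    colnames(truth) <- colnames(counter)
    list(set = spectrum_set(spectra), truth = truth, counter = counter)
  })
}
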