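# Accuracy machinery: bias/dispersion descriptors of calculated vs counter
# concentrations, leave-sets-out cross-validation, exponential growth-curve
# fitting, and crosstalk mean-plane analysis for mixture inversion.

#' Bias of calculated vs counter concentrations
#'
#' Least-squares intercept of the line `Y = X + Bias` fitted to
#' (counter, calculated) pairs, which reduces to `mean(calc - counter)`.
#' Positive bias means the spectral model overestimates the counter.
#'
#' @param calc calculated concentrations (cells/mL).
#' @param counter reference (counter) concentrations, same length.
#' @return bias in cells/mL.
#' @export
compute_bias <- function(calc, counter) {
  if (length(calc) != length(counter))
    stopf("calc (%d) and counter (%d) differ in length", length(calc),
          length(counter))
  if (length(calc) < 1) stopf("empty input")
  mean(calc - counter)
}

#' Dispersion of calculated concentrations about the Y = X + Bias line
#'
#' A root-mean-square form of the standard deviation taken about the biased
#' identity line:
#' \deqn{disp = \sqrt{\frac{1}{n}\sum_i (C_i^{calc} - (C_i + Bias))^2}.}
#'
#' @inheritParams compute_bias
#' @param bias the bias; defaults to [compute_bias()] of the same data, in
#'   which case the dispersion is the RMS residual about the fitted line.
#' @return dispersion in cells/mL.
#' @export
compute_dispersion <- function(calc, counter, bias = compute_bias(calc, counter)) {
  if (length(calc) != length(counter))
    stopf("calc (%d) and counter (%d) differ in length", length(calc),
          length(counter))
  sqrt(mean((calc - (counter + bias))^2))
}

#' Accuracy report: bias, dispersion and percent-at-center
#'
#' @inheritParams compute_bias
#' @param center reference concentration used to express the dispersion as a
#'   percentage; conventionally the midpoint of the calibrated concentration
#'   range.
#' @return an `accuracy_report`: list with `bias`, `dispersion`, `n`, and
#'   `percent_at_center` (= 100 * dispersion / center).
#' @export
accuracy_report <- function(calc, counter, center) {
  b <- compute_bias(calc, counter)
  d <- compute_dispersion(calc, counter, b)
  structure(list(bias = b, dispersion = d, n = length(calc),
                 percent_at_center = 100 * d / center),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> bias %.4g, dispersion %.4g cells/mL (%.2f%% at center), n = %d\n",
              x$bias, x$dispersion, x$percent_at_center, x$n))
  invisible(x)
}

#' Leave-sets-out cross-validation of a spectral-shape model
#'
#' For every `k_model`-subset of the experimental sets (lexicographic order
#' by set index), the model template's parameters are refit on the union of
#' the model sets ([minimize_global_surface()]; the structure stays fixed),
#' every spectrum of the held-out sets is inverted
#' ([estimate_concentration()]), and bias/dispersion against the counter
#' concentrations are computed. A combination whose calibration fails is
#' flagged and skipped.
#'
#' @param sets list of `spectrum_set`s (one per experimental set), all on one
#'   grid and carrying counter concentrations.
#' @param k_model number of sets used for model building per combination.
#' @param template `species_model` providing structure and start parameters.
#' @param center concentration used for percent-at-center; default the
#'   midpoint of the template's concentration range.
#' @param reltol,max_evals calibration controls, see
#'   [minimize_global_surface()].
#' @param grid_points,rel_tol inversion controls, see
#'   [estimate_concentration()].
#' @return a `crossval_report`: list with `combinations` (per combination:
#'   `model_sets`, `test_sets`, `report`, `failed`), `average_bias`,
#'   `average_dispersion`, `average_percent_at_center`, and `n_combinations`.
#' @export
cross_validate <- function(sets, k_model, template, center = NULL,
                           reltol = 1e-9, max_evals = 1e4,
                           grid_points = 200, rel_tol = 1e-6) {
  n <- length(sets)
  if (n < k_model + 1)
    stopf("need at least k_model + 1 = %d sets, got %d", k_model + 1, n)
  if (is.null(center)) center <- mean(template$concentration_range)
  combos <- utils::combn(n, k_model)
  results <- vector("list", ncol(combos))
  for (j in seq_len(ncol(combos))) {
    model_ids <- combos[, j]
    test_ids <- setdiff(seq_len(n), model_ids)
    pooled <- spectrum_set(unlist(lapply(sets[model_ids], `[[`, "spectra"),
                                  recursive = FALSE))
    cal <- tryCatch(minimize_global_surface(pooled, template, reltol = reltol,
                                            max_evals = max_evals),
                    error = function(e) e)
    if (inherits(cal, "error")) {
      results[[j]] <- list(model_sets = model_ids, test_sets = test_ids,
                           report = NULL, failed = conditionMessage(cal))
      next
    }
    test_spectra <- unlist(lapply(sets[test_ids], `[[`, "spectra"),
                           recursive = FALSE)
    calc <- vapply(test_spectra, function(s)
      unname(estimate_concentration(s, cal$model, grid_points = grid_points,
                                    rel_tol = rel_tol)$concentration),
      numeric(1))
    counter <- vapply(test_spectra, function(s)
      s$meta$counter_concentration, numeric(1))
    results[[j]] <- list(model_sets = model_ids, test_sets = test_ids,
                         report = accuracy_report(calc, counter, center),
                         failed = NULL)
  }
  ok <- !vapply(results, function(x) is.null(x$report), logical(1))
  if (!any(ok)) stopf("calibration failed in every combination")
  biases <- vapply(results[ok], function(x) x$report$bias, numeric(1))
  disps <- vapply(results[ok], function(x) x$report$dispersion, numeric(1))
  structure(list(combinations = results,
                 average_bias = mean(biases),
                 average_dispersion = mean(disps),
                 average_percent_at_center = 100 * mean(disps) / center,
                 n_combinations = ncol(combos)),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %d combinations; average bias %.4g, average dispersion %.4g cells/mL (%.2f%% at center)\n",
              x$n_combinations, x$average_bias, x$average_dispersion,
              x$average_percent_at_center))
  invisible(x)
}

#' Fit an exponential growth curve and doubling time
#'
#' Fits \eqn{C(t) = C_0 e^{kt}} by linear regression of log concentration on
#' time over the points inside the window; the doubling time is
#' \eqn{\ln 2 / k} (non-finite, flagged, when `k <= 0`). The dispersion about
#' the fit is the RMS residual over the same window,
#' \deqn{disp_{\Delta t} = \sqrt{\frac{1}{n}\sum_i (C(t_i) - ExpFit(t_i))^2}.}
#'
#' @param times hours.
#' @param concentrations cells/mL, positive.
#' @param window `c(t_start, t_end)` hours; default the full span.
#' @return a `growth_fit`: list with `C0`, `rate` (per hour),
#'   `doubling_time_h`, `disp_vs_fit`, `window`, `n`, and `fitted`.
#' @export
fit_growth_curve <- function(times, concentrations, window = range(times)) {
  if (length(times) != length(concentrations))
    stopf("times and concentrations differ in length")
  if (any(concentrations <= 0)) stopf("concentrations must be positive")
  inside <- times >= window[1] & times <= window[2]
  if (sum(inside) < 3) stopf("need at least 3 points inside the window")
  t_w <- times[inside]; c_w <- concentrations[inside]
  fit <- stats::lm(log(c_w) ~ t_w)
  k <- unname(stats::coef(fit)[2]); C0 <- exp(unname(stats::coef(fit)[1]))
  fitted_c <- C0 * exp(k * t_w)
  structure(list(C0 = C0, rate = k,
                 doubling_time_h = if (k > 0) log(2) / k else NA_real_,
                 disp_vs_fit = sqrt(mean((c_w - fitted_c)^2)),
                 window = window, n = sum(inside),
                 fitted = fitted_c),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  td <- if (is.na(x$doubling_time_h)) "n/a (non-growing)"
        else sprintf("%.2f h", x$doubling_time_h)
  cat(sprintf("<growth_fit> C0 = %.4g cells/mL, rate %.4g /h, doubling time %s, dispersion %.4g cells/mL (window %g-%g h, n = %d)\n",
              x$C0, x$rate, td, x$disp_vs_fit, x$window[1], x$window[2], x$n))
  invisible(x)
}

#' Fit crosstalk mean planes to mixture-inversion results
#'
#' For each species s, ordinary least squares of the calculated concentration
#' on all true concentrations:
#' \deqn{\hat{P}_s(C_1, ..., C_n) = p_0 + p_1 C_1 + ... + p_n C_n.}
#' For a perfect deconvolution the own-species slope is 1 and all cross
#' slopes are 0; non-zero cross slopes quantify the leakage ("crosstalk") of
#' one species' concentration into another species' estimate.
#'
#' @param true_grid matrix (samples x species) of true concentrations.
#' @param calc matrix (samples x species) of calculated concentrations.
#' @return list of `crosstalk_plane` objects, one per species: `p0`
#'   (cells/mL), `slopes` (unitless, one per true-concentration axis),
#'   `residual_rms`.
#' @export
fit_crosstalk_planes <- function(true_grid, calc) {
  true_grid <- as.matrix(true_grid); calc <- as.matrix(calc)
  if (nrow(true_grid) != nrow(calc))
    stopf("true_grid and calc differ in sample count")
  if (nrow(true_grid) < ncol(true_grid) + 2)
    stopf("need at least %d non-collinear samples", ncol(true_grid) + 2)
  if (qr(cbind(1, true_grid))$rank < ncol(true_grid) + 1)
    stopf("rank-deficient design: true concentrations are collinear")
  lapply(seq_len(ncol(calc)), function(sp) {
    fit <- stats::lm.fit(cbind(1, true_grid), calc[, sp])
    co <- fit$coefficients
    structure(list(species = colnames(calc)[sp] %||% sp,
                   p0 = unname(co[1]), slopes = unname(co[-1]),
                   residual_rms = sqrt(mean(fit$residuals^2))),
              class = "crosstalk_plane")
  })
}

#' @export
print.crosstalk_plane <- function(x, ...) {
  cat(sprintf("<crosstalk_plane> %s: p0 = %.4g, slopes (%s), residual RMS %.4g\n",
              x$species, x$p0,
              paste(format(x$slopes, digits = 4), collapse = ", "),
              x$residual_rms))
  invisible(x)
}
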