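# Calibration of species spectral-shape models from dilution-series spectra:
#   1. free multi-Gaussian fits of each spectrum,
#   2. iterated constant-fixing to discover which Gaussian coefficients are
#      concentration-independent,
#   3. parametric sub-function fits for the remaining coefficients,
#   4. global surface minimization of the summed squared error over all
#      spectra and wavelengths, started from the step-3 parameters.

coef_names <- function(n_gauss)
  as.vector(t(outer(seq_len(n_gauss), c("a", "b", "c"),
                    function(i, l) paste0(l, i))))

gauss_sum <- function(lambda, par, n_gauss) {
  out <- numeric(length(lambda))
  for (i in seq_len(n_gauss)) {
    a <- par[[paste0("a", i)]]; b <- par[[paste0("b", i)]]
    cc <- par[[paste0("c", i)]]
    out <- out + a * exp(-((lambda - b) / cc)^2)
  }
  out
}

#' Fit free Gaussian functions to one spectrum
#'
#' Least-squares fit of \eqn{\sum_i a_i \exp(-((\lambda - b_i)/c_i)^2)} over
#' the unpinned coefficients, by Levenberg-Marquardt from a deterministic
#' initialization: Gaussian 1 starts at the absorption-weighted centroid of
#' the window with width span/4 and amplitude max(values); Gaussian 2 starts
#' at the upper window edge with width span/3 and amplitude 10\% of max
#' (further Gaussians, if requested, are spread evenly across the window).
#'
#' When no coefficient is pinned, the returned components are ordered by
#' ascending center; pinned coefficients anchor component identity, so no
#' reordering is applied then.
#'
#' @param s `spectrum` in absorption percent on a windowed grid.
#' @param n_gauss number of Gaussian components (>= 1).
#' @param fixed named list pinning coefficients, e.g. `list(b1 = 533.7)`.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param extra_starts optional list of named full coefficient vectors tried
#'   as additional (highest-priority) starting points, e.g. the solution of a
#'   neighbouring spectrum in a dilution series.
#' @return list with `coefficients` (named vector a1,b1,c1,...), `r2`,
#'   `fitted`, `converged`, and `degenerate` (per-component flag set when a
#'   width collapses below 1 nm or an amplitude is < 1e-3 of the largest).
#' @export
fit_free_gaussians <- function(s, n_gauss = 2, fixed = list(),
                               max_iter = 200, extra_starts = list()) {
  if (s$value_kind != "absorption_percent")
    stopf("fit_free_gaussians expects absorption_percent")
  if (n_gauss < 1) stopf("n_gauss must be >= 1")
  w <- s$wavelengths_nm; v <- s$values
  span <- diff(range(w))
  nm <- coef_names(n_gauss)
  bad_fixed <- setdiff(names(fixed), nm)
  if (length(bad_fixed))
    stopf("unknown fixed coefficient(s): %s", paste(bad_fixed, collapse = ", "))

  vmax <- max(v)
  weights <- pmax(v, 0)
  centroid <- if (sum(weights) > 0) sum(w * weights) / sum(weights) else mean(w)
  # Deterministic multi-start: overlapping broad Gaussians create local
  # optima with near-identical residuals, so a handful of width/placement
  # combinations are tried and the lowest-SSE fit is kept.
  base_init <- function(c1_frac, a2_frac, b1_off = 0, b2_off = 0) {
    init <- c(a1 = vmax, b1 = centroid + b1_off, c1 = span * c1_frac)
    if (n_gauss >= 2)
      init <- c(init, a2 = a2_frac * vmax, b2 = max(w) + b2_off,
                c2 = span / 3)
    if (n_gauss > 2) {
      extra <- seq(min(w), max(w), length.out = n_gauss - 1)[-1]
      for (i in 3:n_gauss)
        init <- c(init, stats::setNames(
          c(0.05 * vmax, extra[i - 2], span / 4),
          paste0(c("a", "b", "c"), i)))
    }
    init[nm]
  }
  init_list <- list(base_init(1/4, 0.1),
                    base_init(1/2, 0.1),
                    base_init(1, 0.2),
                    base_init(1/2, 0.3, b1_off = -span / 4, b2_off = span / 4),
                    base_init(1/3, 0.1, b1_off = w[which.max(v)] - centroid))
  if (n_gauss == 2) {
    # close-center pairs: two comparable Gaussians straddling the centroid
    straddle <- c(a1 = 0.6 * vmax, b1 = centroid - span / 6, c1 = span / 4,
                  a2 = 0.6 * vmax, b2 = centroid + span / 6, c2 = span / 4)
    shoulder <- c(a1 = 0.8 * vmax, b1 = centroid, c1 = span / 3,
                  a2 = 0.5 * vmax, b2 = centroid + span / 3, c2 = span / 3)
    init_list <- c(init_list, list(straddle[nm], shoulder[nm]))
  }
  extra_starts <- lapply(extra_starts, function(p) p[nm])
  init_list <- c(extra_starts, init_list)

  free_nm <- setdiff(nm, names(fixed))
  if (length(free_nm) == 0) {
    par <- unlist(fixed)[nm]
    fit_v <- gauss_sum(w, as.list(par), n_gauss)
    return(list(coefficients = par, r2 = r_squared(v, fit_v), fitted = fit_v,
                converged = TRUE, degenerate = rep(FALSE, n_gauss)))
  }
  resid_fn <- function(p) {
    full <- as.list(c(p, unlist(fixed)))
    gauss_sum(w, full, n_gauss) - v
  }
  lower <- rep(-Inf, length(free_nm))
  lower[grepl("^c", free_nm)] <- 1e-3  # widths strictly positive
  best <- NULL
  for (init in init_list) {
    res <- minpack.lm::nls.lm(par = init[free_nm], fn = resid_fn,
                              lower = lower,
                              control = minpack.lm::nls.lm.control(
                                maxiter = max_iter, ftol = 1e-14,
                                ptol = 1e-14))
    sse <- sum(res$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(res = res, sse = sse)
    if (sse <= 1e-16 * sum(v^2)) break  # exact basin found
  }
  res <- best$res
  par <- c(res$par, unlist(fixed))[nm]
  converged <- res$info %in% 1:4
  if (!converged && res$info == 9)
    warnf("Gaussian fit hit the iteration cap; returning best-so-far")

  if (length(fixed) == 0 && n_gauss > 1) {
    ord <- order(par[paste0("b", seq_len(n_gauss))])
    par <- stats::setNames(
      as.vector(vapply(ord, function(i)
        par[paste0(c("a", "b", "c"), i)], numeric(3))), nm)
  }
  amps <- abs(par[paste0("a", seq_len(n_gauss))])
  widths <- par[paste0("c", seq_len(n_gauss))]
  degen <- widths < 1 | (amps < 1e-3 * max(amps))
  fit_v <- gauss_sum(w, as.list(par), n_gauss)
  list(coefficients = par, r2 = r_squared(v, fit_v), fitted = fit_v,
       converged = converged, degenerate = unname(degen))
}

coef_spread <- function(values, name, window_span) {
  if (grepl("^b", name)) stats::sd(values) / window_span
  else {
    m <- mean(values)
    if (m == 0) if (stats::sd(values) == 0) 0 else Inf
    else stats::sd(values) / abs(m)
  }
}

#' Discover model structure by iterated constant-fixing
#'
#' Repeatedly fits every spectrum with free Gaussians ([fit_free_gaussians()]),
#' computes a spread statistic for each still-free coefficient across the
#' dilution series (coefficient of variation for amplitudes and widths;
#' standard deviation divided by the window span for centers, whose offset is
#' arbitrary), and fixes the least-spread coefficient at its across-spectra
#' mean whenever its spread falls below `cv_threshold` -- one coefficient per
#' iteration, until none qualifies or `max_iters` is reached. Exact spread
#' ties are resolved in coefficient order (a1, b1, c1, a2, ...).
#'
#' After the first (fully free) pass, components are relabelled so that the
#' component whose amplitude correlates most strongly with concentration
#' becomes Gaussian 1; the remaining near-constant component then acts as a
#' baseline.
#'
#' @param set `spectrum_set` in absorption percent on a common grid, with
#'   counter concentrations; at least 5 spectra spanning a factor >= 3 in
#'   concentration are recommended (a warning is issued otherwise).
#' @param n_gauss Gaussians per spectrum.
#' @param cv_threshold spread below which a coefficient is deemed constant.
#' @param max_iters maximum number of fixing iterations.
#' @param force_constant character vector of coefficient names to fix
#'   unconditionally after the first pass (reproducing a manual choice).
#' @return list with `structure` (named list: `list(constant = value)` or
#'   `"free"` per coefficient) and `tables` (one audit data frame per
#'   iteration: concentration, coefficients, R2, plus attributes
#'   `iteration_index` and `fixed_map`).
#' @export
iterate_constant_fixing <- function(set, n_gauss = 2, cv_threshold = 0.05,
                                    max_iters = 8,
                                    force_constant = character(0)) {
  conc <- counter_concentrations(set)
  if (any(is.na(conc))) stopf("all spectra need counter concentrations")
  n_spec <- length(set$spectra)
  nm <- coef_names(n_gauss)
  if (n_spec < 3 * n_gauss)
    stopf("fewer spectra (%d) than free coefficients (%d)", n_spec,
          3 * n_gauss)
  if (n_spec < 5 || max(conc) < 3 * min(conc))
    warnf("calibration set is small or spans < factor 3 in concentration; structure discovery may be unreliable")
  span <- diff(range(set$spectra[[1]]$wavelengths_nm))

  fixed <- list()
  tables <- list()
  swap_done <- FALSE
  prev_coefs <- NULL
  for (iter in seq_len(max_iters + 1)) {
    # warm-start chaining: each spectrum also tries its neighbour's solution
    # and its own previous-iteration solution, which keeps the per-spectrum
    # fits in one consistent basin along the dilution series
    fits <- vector("list", n_spec)
    for (i in seq_len(n_spec)) {
      es <- list()
      if (i > 1) es <- c(es, list(fits[[i - 1]]$coefficients))
      if (!is.null(prev_coefs)) es <- c(es, list(prev_coefs[i, ]))
      fits[[i]] <- fit_free_gaussians(set$spectra[[i]], n_gauss = n_gauss,
                                      fixed = fixed, extra_starts = es)
    }
    coefs <- t(vapply(fits, `[[`, numeric(length(nm)), "coefficients"))
    colnames(coefs) <- nm

    if (!swap_done && n_gauss > 1 && stats::sd(conc) > 0) {
      # relabel so the amplitude most correlated with concentration is a1
      cors <- vapply(seq_len(n_gauss), function(i) {
        a <- coefs[, paste0("a", i)]
        if (stats::sd(a) == 0) -Inf else abs(stats::cor(a, conc))
      }, numeric(1))
      lead <- which.max(cors)
      if (is.finite(cors[lead]) && lead != 1) {
        ord <- c(lead, setdiff(seq_len(n_gauss), lead))
        coefs <- coefs[, as.vector(vapply(ord, function(i)
          paste0(c("a", "b", "c"), i), character(3))), drop = FALSE]
        colnames(coefs) <- nm
      }
      swap_done <- TRUE
    }

    prev_coefs <- coefs
    tab <- data.frame(counter_concentration = conc, coefs,
                      r2 = vapply(fits, `[[`, numeric(1), "r2"))
    attr(tab, "iteration_index") <- iter
    attr(tab, "fixed_map") <- fixed
    tables[[iter]] <- tab

    free_nm <- setdiff(nm, names(fixed))
    forced <- intersect(force_constant, free_nm)
    if (length(forced)) {
      fixed[[forced[1]]] <- mean(coefs[, forced[1]])
      next
    }
    if (length(free_nm) == 0 || iter > max_iters) break
    spreads <- vapply(free_nm, function(cn)
      coef_spread(coefs[, cn], cn, span), numeric(1))
    if (min(spreads) < cv_threshold) {
      pick <- free_nm[which.min(spreads)]
      fixed[[pick]] <- mean(coefs[, pick])
    } else break
  }
  if (length(fixed) == length(nm))
    warnf("all %d coefficients constant: spectra do not vary with concentration", length(nm))
  structure_out <- stats::setNames(lapply(nm, function(cn)
    if (cn %in% names(fixed)) list(constant = fixed[[cn]]) else "free"), nm)
  list(structure = structure_out, tables = tables)
}

sse_of <- function(obs, fit) sum((obs - fit)^2)

fit_one_family <- function(family, C, y) {
  n <- length(y)
  switch(family,
    constant = list(sf = subfunction("constant", mean(y)),
                    sse = sse_of(y, mean(y)), k = 1),
    log_linear = {
      if (any(C <= 0)) return(NULL)
      co <- stats::coef(stats::lm(y ~ log10(C)))
      list(sf = subfunction("log_linear", unname(co)),
           sse = sse_of(y, co[1] + co[2] * log10(C)), k = 2)
    },
    power = {
      if (any(C <= 0) || any(y <= 0)) return(NULL)
      co <- stats::coef(stats::lm(log(y) ~ log(C)))
      start <- c(p1 = exp(unname(co[1])), p2 = unname(co[2]))
      res <- minpack.lm::nls.lm(par = start, fn = function(p)
        p[1] * C^p[2] - y, lower = c(1e-300, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      p <- res$par
      list(sf = subfunction("power", unname(p)),
           sse = sse_of(y, p[1] * C^p[2]), k = 2)
    },
    beer_lambert_amplitude = {
      if (any(C < 0) || any(y >= 100) || any(y < 0)) return(NULL)
      mC <- mean(C)
      frac <- min(max(mean(y) / 100, 1e-6), 1 - 1e-9)
      p0 <- -log10(1 - frac) / mC
      f <- function(lp) sse_of(y, 100 * (1 - 10^(-10^lp * C)))
      opt <- stats::optimize(f, interval = log10(p0) + c(-3, 3),
                             tol = .Machine$double.eps^0.5)
      p1 <- 10^opt$minimum
      list(sf = subfunction("beer_lambert_amplitude", p1),
           sse = sse_of(y, 100 * (1 - 10^(-p1 * C))), k = 1)
    })
}

#' Fit candidate sub-function families to a coefficient-vs-concentration trend
#'
#' Each candidate family is least-squares fitted to the
#' (concentration, coefficient) rows; candidates whose domain excludes the
#' data (e.g. log-linear with C <= 0, power with non-positive values) are
#' skipped with a note. The best family is selected by small-sample corrected
#' AIC computed from the residual sum of squares, so that an extra parameter
#' must earn its keep; exact ties go to the family with fewest parameters,
#' then to family order. Per-family R-squared (original scale) is reported
#' alongside.
#'
#' @param C concentrations (cells/mL), length >= 3.
#' @param values coefficient values, same length.
#' @param candidates families to try.
#' @return list with `best` ([subfunction()]), `table` (data frame of family,
#'   r2, aicc, n_params), and `notes` (skipped candidates).
#' @export
fit_subfunction_families <- function(C, values,
                                     candidates = c("constant",
                                                    "beer_lambert_amplitude",
                                                    "power", "log_linear")) {
  if (length(C) != length(values)) stopf("C and values differ in length")
  if (length(C) < 3) stopf("need at least 3 rows to fit sub-functions")
  n <- length(values)
  scale2 <- mean(values^2) + 1e-300
  rows <- list(); notes <- character(0)
  for (fam in candidates) {
    fit <- tryCatch(fit_one_family(fam, C, values), error = function(e) NULL)
    if (is.null(fit)) {
      notes <- c(notes, sprintf("%s skipped (domain or fit failure)", fam))
      next
    }
    sse <- max(fit$sse, n * scale2 * 1e-28)  # floor to keep log() finite
    k <- fit$k + 1  # + residual variance
    aicc <- n * log(sse / n) + 2 * k +
      if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
    rows[[fam]] <- list(sf = fit$sf, r2 = 1 - fit$sse / (sse_of(values, mean(values)) + 1e-300),
                        aicc = aicc, n_params = fit$k)
  }
  if (length(rows) == 0) stopf("no candidate family could be fitted")
  tab <- data.frame(family = names(rows),
                    r2 = vapply(rows, `[[`, numeric(1), "r2"),
                    aicc = vapply(rows, `[[`, numeric(1), "aicc"),
                    n_params = vapply(rows, `[[`, numeric(1), "n_params"),
                    row.names = NULL)
  ord <- order(tab$aicc, tab$n_params, match(tab$family, candidates))
  list(best = rows[[tab$family[ord[1]]]]$sf, table = tab, notes = notes)
}

# --- global surface minimization -------------------------------------------

pack_model_params <- function(m) {
  out <- numeric(0)
  for (i in seq_along(m$components)) {
    g <- m$components[[i]]
    for (role in c("amplitude", "center", "width")) {
      p <- g[[role]]$params
      names(p) <- sprintf("g%d.%s.p%d", i, role, seq_along(p))
      out <- c(out, p)
    }
  }
  out
}

unpack_model_params <- function(m, par) {
  k <- 0
  for (i in seq_along(m$components)) {
    for (role in c("amplitude", "center", "width")) {
      np <- length(m$components[[i]][[role]]$params)
      m$components[[i]][[role]]$params <- unname(par[k + seq_len(np)])
      k <- k + np
    }
  }
  m
}

# Fast raw evaluation used inside the objective; invalid parameter regions
# (non-positive widths, non-positive p1 for saturating/power laws) return NA.
eval_packed <- function(m, par, lambda, C) {
  k <- 0; out <- numeric(length(lambda))
  for (i in seq_along(m$components)) {
    coef <- numeric(3); j <- 1
    for (role in c("amplitude", "center", "width")) {
      f <- m$components[[i]][[role]]
      np <- length(f$params); p <- par[k + seq_len(np)]; k <- k + np
      coef[j] <- switch(f$family,
        constant = p[1],
        beer_lambert_amplitude = if (p[1] <= 0) return(NULL)
                                 else 100 * (1 - 10^(-p[1] * C)),
        power = if (p[1] <= 0) return(NULL) else p[1] * C^p[2],
        log_linear = if (C <= 0) return(NULL) else p[1] + p[2] * log10(C))
      j <- j + 1
    }
    if (coef[3] <= 0) return(NULL)
    out <- out + coef[1] * exp(-((lambda - coef[2]) / coef[3])^2)
  }
  out
}

#' Globally refine model parameters on a spectrum surface
#'
#' Minimizes the summed squared error between the model and every spectrum in
#' the set,
#' \deqn{error = \sum_{\lambda} \sum_{C} (Abs_{model}(\lambda, C) - Abs_{obs})^2,}
#' over all sub-function parameters jointly (uniform weighting over
#' wavelengths and spectra), by derivative-free Nelder-Mead simplex search
#' started from the template's parameters. Convergence: relative objective
#' change below `reltol` or `max_evals` function evaluations.
#'
#' @param set `spectrum_set` in absorption percent on a common grid with
#'   counter concentrations.
#' @param template `species_model` providing structure and start parameters.
#' @param start optional named start vector overriding the template's packed
#'   parameters (see `pack_model_params` layout `g<i>.<role>.p<j>`).
#' @param reltol relative convergence tolerance of the simplex.
#' @param max_evals function-evaluation cap.
#' @return a `calibration_result`: list with `model`, `start_params`,
#'   `final_params`, `start_error`, `final_error`, `per_spectrum_r2`,
#'   `converged`, `evals`, and `iteration_log` (`NULL` here; filled by
#'   [calibrate_species_model()]).
#' @export
minimize_global_surface <- function(set, template, start = NULL,
                                    reltol = 1e-9, max_evals = 1e4) {
  conc <- counter_concentrations(set)
  if (any(is.na(conc))) stopf("all spectra need counter concentrations")
  if (!set$common_grid) stopf("spectra must share a common grid; see resample_common_grid()")
  lambda <- set$spectra[[1]]$wavelengths_nm
  obs <- lapply(set$spectra, `[[`, "values")
  p0 <- pack_model_params(template)
  if (!is.null(start)) {
    if (length(start) != length(p0)) stopf("start vector has wrong length")
    p0[] <- start
  }
  obs_mat <- do.call(cbind, obs)
  n_lam <- length(lambda); n_c <- length(conc)
  # per-(component, role) family codes and packed-parameter offsets
  layout <- list(); k <- 0
  for (i in seq_along(template$components)) {
    for (role in c("amplitude", "center", "width")) {
      f <- template$components[[i]][[role]]
      layout[[length(layout) + 1]] <-
        list(comp = i, role = role, family = f$family,
             idx = k + seq_along(f$params))
      k <- k + length(f$params)
    }
  }
  eval_coef <- function(entry, par) {
    p <- par[entry$idx]
    switch(entry$family,
      constant = rep(p[1], n_c),
      beer_lambert_amplitude = if (p[1] <= 0) NULL
                               else 100 * (1 - 10^(-p[1] * conc)),
      power = if (p[1] <= 0) NULL else p[1] * conc^p[2],
      log_linear = if (any(conc <= 0)) NULL else p[1] + p[2] * log10(conc))
  }
  objective <- function(par) {
    fit <- matrix(0, n_lam, n_c)
    for (ci in seq_along(template$components)) {
      ent <- layout[(ci - 1) * 3 + (1:3)]
      a <- eval_coef(ent[[1]], par); b <- eval_coef(ent[[2]], par)
      cc <- eval_coef(ent[[3]], par)
      if (is.null(a) || is.null(b) || is.null(cc) || any(cc <= 0))
        return(1e300)  # invalid region penalty
      z <- (outer(lambda, b, "-")) / rep(cc, each = n_lam)
      fit <- fit + exp(-z * z) * rep(a, each = n_lam)
    }
    sum((fit - obs_mat)^2)
  }
  e0 <- objective(p0)
  if (!is.finite(e0) || e0 >= 1e300)
    stopf("objective non-finite at the starting parameters")
  res <- stats::optim(p0, objective, method = "Nelder-Mead",
                      control = list(maxit = max_evals, reltol = reltol,
                                     parscale = pmax(abs(p0), 1e-8)))
  model <- unpack_model_params(template, res$par)
  r2 <- vapply(seq_along(obs), function(i)
    r_squared(obs[[i]], eval_packed(template, res$par, lambda, conc[i])),
    numeric(1))
  structure(list(model = model,
                 start_params = p0,
                 final_params = stats::setNames(res$par, names(p0)),
                 start_error = e0, final_error = res$value,
                 per_spectrum_r2 = r2,
                 converged = res$convergence == 0,
                 evals = res$counts[["function"]],
                 iteration_log = NULL),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> error %.6g -> %.6g (%s, %d evals)\n",
              x$start_error, x$final_error,
              if (x$converged) "converged" else "not converged", x$evals))
  cat(sprintf("  per-spectrum R2: %.4f .. %.4f (n = %d)\n",
              min(x$per_spectrum_r2), max(x$per_spectrum_r2),
              length(x$per_spectrum_r2)))
  invisible(x)
}

#' Calibrate a species model from a dilution-series spectrum set
#'
#' Full pipeline: [iterate_constant_fixing()] discovers which Gaussian
#' coefficients are constant; [fit_subfunction_families()] selects and fits a
#' concentration law for each free coefficient; the assembled start model is
#' then refined with [minimize_global_surface()], fitting all parameters
#' jointly.
#'
#' @inheritParams iterate_constant_fixing
#' @param name species label for the resulting model.
#' @param candidates sub-function families offered for free coefficients.
#' @param concentration_range calibrated range; default the span of the
#'   counter concentrations.
#' @param reltol,max_evals passed to [minimize_global_surface()].
#' @return a `calibration_result` whose `iteration_log` holds the
#'   constant-fixing audit trail and `start_model` the pre-minimization model.
#' @export
calibrate_species_model <- function(set, name = "species", n_gauss = 2,
                                    cv_threshold = 0.05, max_iters = 8,
                                    force_constant = character(0),
                                    candidates = c("constant",
                                                   "beer_lambert_amplitude",
                                                   "power", "log_linear"),
                                    concentration_range = NULL,
                                    reltol = 1e-9, max_evals = 1e4) {
  conc <- counter_concentrations(set)
  disc <- iterate_constant_fixing(set, n_gauss = n_gauss,
                                  cv_threshold = cv_threshold,
                                  max_iters = max_iters,
                                  force_constant = force_constant)
  last_tab <- disc$tables[[length(disc$tables)]]
  components <- vector("list", n_gauss)
  for (i in seq_len(n_gauss)) {
    sfs <- list()
    for (role in c(amplitude = "a", center = "b", width = "c")) {
      cn <- paste0(role, i)
      st <- disc$structure[[cn]]
      role_name <- names(which(c(amplitude = "a", center = "b", width = "c") == role))
      sfs[[role_name]] <- if (is.list(st)) subfunction("constant", st$constant)
      else fit_subfunction_families(conc, last_tab[[cn]],
                                    candidates = candidates)$best
    }
    components[[i]] <- gaussian_component(sfs$amplitude, sfs$center, sfs$width)
  }
  if (is.null(concentration_range)) concentration_range <- range(conc)
  win <- range(set$spectra[[1]]$wavelengths_nm)
  start_model <- species_model(name, components, concentration_range,
                               wavelength_window = win)
  out <- minimize_global_surface(set, start_model, reltol = reltol,
                                 max_evals = max_evals)
  out$iteration_log <- disc$tables
  out$structure <- disc$structure
  out$start_model <- start_model
  out
}
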