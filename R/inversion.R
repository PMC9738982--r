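# Concentration inversion: recover species concentrations from a measured
# absorption spectrum by least-squares matching of the spectral shape model.

prepare_inversion_spectrum <- function(s, window) {
  if (s$value_kind != "absorption_percent")
    stopf("inversion expects an absorption_percent spectrum")
  w <- s$wavelengths_nm
  if (min(w) < window[1] || max(w) > window[2]) {
    if (all(w < window[1] | w > window[2]))
      stopf("spectrum grid [%g, %g] nm is disjoint from the model window [%g, %g] nm",
            min(w), max(w), window[1], window[2])
    s <- window_spectrum(s, window[1], window[2])
  }
  s
}

#' Estimate a single species concentration from a spectrum
#'
#' Minimizes \eqn{\sum_\lambda (Abs_{model}(\lambda, C) - Abs_{obs}(\lambda))^2}
#' over C by a log-spaced grid scan over `[C_min/2, 2 C_max]` followed by
#' golden-section refinement around the best grid point.
#'
#' @param s `spectrum` in absorption percent (auto-windowed to the model
#'   window when wider).
#' @param m a [species_model()].
#' @param grid_points number of log-spaced scan points.
#' @param rel_tol relative tolerance of the refinement.
#' @return a `concentration_estimate`: list with `concentration` (cells/mL),
#'   `fit_r2`, `residual_sse`, `status` (`converged` / `at_bound`), and
#'   `solver_evals`.
#' @export
estimate_concentration <- function(s, m, grid_points = 200, rel_tol = 1e-6) {
  s <- prepare_inversion_spectrum(s, m$wavelength_window)
  w <- s$wavelengths_nm; v <- s$values
  lo <- m$concentration_range[1] / 2
  hi <- m$concentration_range[2] * 2
  grid <- logspace(lo, hi, grid_points)
  sse <- function(C) sum((eval_species_model(m, w, C,
                                             warn_extrapolation = FALSE) - v)^2)
  scan <- vapply(grid, sse, numeric(1))
  best <- which.min(scan)
  evals <- grid_points
  if (best == 1 || best == grid_points) {
    C_hat <- grid[best]; sse_hat <- scan[best]; status <- "at_bound"
  } else {
    opt <- stats::optimize(sse, interval = c(grid[best - 1], grid[best + 1]),
                           tol = rel_tol * grid[best])
    C_hat <- opt$minimum; sse_hat <- opt$objective; status <- "converged"
    evals <- evals + ceiling(log(diff(c(grid[best - 1], grid[best + 1])) /
                                   (rel_tol * grid[best])) / log(1.618)) + 2
  }
  fit <- eval_species_model(m, w, C_hat, warn_extrapolation = FALSE)
  structure(list(concentration = stats::setNames(C_hat, m$name),
                 fit_r2 = r_squared(v, fit), residual_sse = sse_hat,
                 status = status, solver_evals = evals),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat("<concentration_estimate>\n")
  for (i in seq_along(x$concentration))
    cat(sprintf("  %s: %.4g cells/mL%s\n", names(x$concentration)[i],
                x$concentration[i],
                if (!is.null(x$species_status) &&
                    x$species_status[i] != "converged")
                  paste0(" [", x$species_status[i], "]") else ""))
  cat(sprintf("  R2 = %.4f, SSE = %.4g, status: %s\n", x$fit_r2,
              x$residual_sse, x$status))
  invisible(x)
}

#' Estimate several species concentrations from one mixture spectrum
#'
#' Least-squares deconvolution under the absorbance-additivity mixture law:
#' a coarse log-spaced grid over the product of species search ranges
#' (each axis augmented with an "absent" 0 point) locates candidate basins,
#' then Nelder-Mead simplex refinement in log10-concentration space is run
#' from the best `n_starts` distinct grid points (plus any user `starts`).
#' The lowest-SSE solution wins; near-ties (SSE difference below `tie_tol`)
#' go to the smallest total concentration. Species whose estimate falls below
#' the model's concentration floor are reported `below_floor` and pinned to
#' 0; estimates on a search bound are flagged `at_bound`.
#'
#' @param s `spectrum` in absorption percent.
#' @param mm a [mixture_model()].
#' @param starts optional list of concentration vectors used as extra
#'   refinement starts.
#' @param grid_points log-spaced grid points per species axis.
#' @param n_starts number of refinement starts taken from the grid.
#' @param rel_tol relative convergence tolerance of the refinement.
#' @param tie_tol absolute SSE difference treated as a tie.
#' @return a `concentration_estimate` with one named concentration per
#'   species, `species_status` per species, and an overall `status`
#'   (`not_converged` when the residual surface is flat over the grid).
#' @export
estimate_mixture_concentrations <- function(s, mm, starts = NULL,
                                            grid_points = 15, n_starts = 3,
                                            rel_tol = 1e-6, tie_tol = 1e-9) {
  win <- mm$species[[1]]$wavelength_window
  s <- prepare_inversion_spectrum(s, win)
  w <- s$wavelengths_nm; v <- s$values
  n_sp <- length(mm$species)
  axes <- lapply(mm$species, function(m)
    c(0, logspace(m$concentration_range[1] / 2, m$concentration_range[2] * 2,
                  grid_points)))
  # per-species transmittance rows at the axis concentrations
  t_rows <- lapply(seq_len(n_sp), function(i) {
    m <- mm$species[[i]]
    vapply(axes[[i]], function(C) {
      if (C < m$concentration_floor) return(rep(1, length(w)))
      a <- pmin(pmax(eval_species_model(m, w, C, warn_extrapolation = FALSE),
                     0), 100)
      1 - a / 100
    }, numeric(length(w)))
  })
  idx_grid <- as.matrix(expand.grid(lapply(axes, seq_along)))
  scan <- vapply(seq_len(nrow(idx_grid)), function(r) {
    tp <- rep(1, length(w))
    for (i in seq_len(n_sp)) tp <- tp * t_rows[[i]][, idx_grid[r, i]]
    sum((100 * (1 - tp) - v)^2)
  }, numeric(1))
  flat <- (max(scan) - min(scan)) <= 1e-6 * max(max(scan),
                                                .Machine$double.xmin)

  mix_sse <- function(C) {
    fit <- eval_mixture_model(mm, w, C, warn_extrapolation = FALSE)
    sum((fit - v)^2)
  }
  lo <- vapply(mm$species, function(m) m$concentration_range[1] / 2, numeric(1))
  hi <- vapply(mm$species, function(m) m$concentration_range[2] * 2, numeric(1))
  evals <- nrow(idx_grid)

  refine <- function(C0) {
    active <- C0 > 0
    if (!any(active)) return(list(C = C0, sse = mix_sse(C0), evals = 1))
    obj <- function(lg) {
      C <- C0; C[active] <- 10^lg
      pen <- sum(pmax(lg - log10(hi[active]), 0)^2 +
                 pmax(log10(lo[active]) - lg, 0)^2)
      mix_sse(C) + pen * 1e6
    }
    lg0 <- log10(pmin(pmax(C0[active], lo[active]), hi[active]))
    if (sum(active) == 1) {
      res <- stats::optimize(obj, interval = lg0 + c(-0.3, 0.3), tol = 1e-9)
      par <- res$minimum; evals <- 40L
    } else {
      res <- stats::optim(lg0, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = rel_tol^2))
      par <- res$par; evals <- res$counts[["function"]]
    }
    C <- C0; C[active] <- pmin(pmax(10^par, lo[active]), hi[active])
    list(C = C, sse = mix_sse(C), evals = evals)
  }

  ord <- order(scan)
  grid_conc <- function(r)
    vapply(seq_len(n_sp), function(i) axes[[i]][idx_grid[r, i]], numeric(1))
  start_list <- lapply(utils::head(ord, n_starts), grid_conc)
  # also refine from the best point of each species-absent hyperplane so a
  # mixture can degrade gracefully to fewer species
  for (j in seq_len(n_sp)) {
    absent <- which(idx_grid[, j] == 1L)
    start_list <- c(start_list, list(grid_conc(absent[which.min(scan[absent])])))
  }
  if (!is.null(starts)) start_list <- c(start_list, starts)
  start_list <- unique(start_list)
  cands <- lapply(start_list, refine)
  evals <- evals + sum(vapply(cands, `[[`, numeric(1), "evals"))
  sses <- vapply(cands, `[[`, numeric(1), "sse")
  best_sse <- min(sses)
  # SSE differences below the solvers' numerical resolution are ties; the
  # threshold scales with the spectrum energy so parsimony (smallest total
  # concentration) can act on indistinguishable fits
  tie_eps <- max(tie_tol, 1e-10 * sum(v^2))
  tied <- which(sses <= best_sse + tie_eps)
  totals <- vapply(cands[tied], function(x) sum(x$C), numeric(1))
  pick <- cands[[tied[which.min(totals)]]]

  C_hat <- pick$C
  floors <- vapply(mm$species, `[[`, numeric(1), "concentration_floor")
  species_status <- rep("converged", n_sp)
  below <- C_hat < floors
  species_status[below] <- "below_floor"
  C_hat[below] <- 0
  near <- function(x, y) abs(x - y) <= 1e-3 * y
  species_status[!below & (near(C_hat, lo) | near(C_hat, hi))] <- "at_bound"
  status <- if (flat) "not_converged"
            else if (any(species_status == "at_bound")) "at_bound"
            else "converged"
  fit <- eval_mixture_model(mm, w, C_hat, warn_extrapolation = FALSE)
  names(C_hat) <- vapply(mm$species, `[[`, character(1), "name")
  structure(list(concentration = C_hat,
                 fit_r2 = r_squared(v, fit),
                 residual_sse = pick$sse,
                 status = status, species_status = species_status,
                 solver_evals = evals),
            class = "concentration_estimate")
}
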