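test_that("free two-Gaussian fit recovers its own model class exactly", {
  lam <- lam_fine
  v <- 60 * exp(-((lam - 530) / 500)^2) + 12 * exp(-((lam - 930) / 180)^2)
  fit <- fit_free_gaussians(spectrum(lam, v))
  expect_equal(unname(fit$coefficients), c(60, 530, 500, 12, 930, 180),
               tolerance = 1e-3)
  expect_gt(fit$r2, 0.9999)
  expect_false(any(fit$degenerate))
})

test_that("noiseless model spectra fit with near-perfect R2", {
  for (C in c(2e5, 5.5e5, 9e5)) {
    fit <- fit_free_gaussians(model_spectrum(cem, C))
    expect_gt(fit$r2, 0.98)
  }
})

test_that("pinned coefficients are honoured and a surplus Gaussian degenerates", {
  lam <- lam_fine
  v <- 60 * exp(-((lam - 530) / 400)^2)
  fit1 <- fit_free_gaussians(spectrum(lam, v), n_gauss = 1)
  fit2 <- fit_free_gaussians(spectrum(lam, v), n_gauss = 2)
  amps <- abs(fit2$coefficients[c("a1", "a2")])
  expect_true(min(amps) < 1e-3 * max(amps) || any(fit2$degenerate))
  expect_lte(sum((fit2$fitted - v)^2), sum((fit1$fitted - v)^2) + 1e-8)

  pin <- fit_free_gaussians(model_spectrum(cem, 5.5e5), fixed = list(b1 = 533.7))
  expect_identical(unname(pin$coefficients["b1"]), 533.7)
  expect_error(fit_free_gaussians(model_spectrum(cem, 5.5e5),
                                  fixed = list(q9 = 1)), "unknown fixed")
})

test_that("iterated constant-fixing discovers the generating structure", {
  set0 <- generate_calibration_set(cem, grid = c(330, 860, 1),
                                   noise = noise_free())
  disc <- iterate_constant_fixing(set0)
  kind <- vapply(disc$structure, function(x)
    if (is.list(x)) "constant" else "free", character(1))
  expect_identical(kind[c("a1", "c1")], c(a1 = "free", c1 = "free"))
  expect_identical(kind[c("b1", "a2", "b2", "c2")],
                   c(b1 = "constant", a2 = "constant", b2 = "constant",
                     c2 = "constant"))
  # the first coefficient deemed constant is the Gaussian-1 center
  first_fixed <- names(attr(disc$tables[[2]], "fixed_map"))
  expect_identical(first_fixed, "b1")
  # fixed values match the generating model
  expect_equal(disc$structure$b1$constant, 533.7, tolerance = 1e-4)
  expect_equal(disc$structure$a2$constant, 12.21, tolerance = 1e-3)
  # audit trail: one table per iteration, one row per spectrum
  expect_true(all(vapply(disc$tables, nrow, integer(1)) == 8L))
})

test_that("a flat series (same spectrum repeated) fixes every coefficient", {
  s <- model_spectrum(cem, 5.5e5, lam_coarse)
  set_flat <- spectrum_set(rep(list(s), 8))
  disc <- suppressWarnings(iterate_constant_fixing(set_flat))
  kind <- vapply(disc$structure, function(x)
    if (is.list(x)) "constant" else "free", character(1))
  expect_true(all(kind == "constant"))
})

test_that("too few spectra for the free coefficients is an error", {
  set_small <- spectrum_set(lapply(c(2e5, 5e5, 8e5), model_spectrum,
                                   m = cem, lam = lam_coarse))
  expect_error(suppressWarnings(iterate_constant_fixing(set_small)),
               "fewer spectra")
})

test_that("sub-function family selection recovers generating families", {
  C <- 10^seq(5, 6, length.out = 8)
  # saturating Beer-Lambert amplitude data
  fit_bl <- fit_subfunction_families(C, 100 * (1 - 10^(-7.45e-7 * C)))
  expect_identical(fit_bl$best$family, "beer_lambert_amplitude")
  expect_equal(fit_bl$best$params, 7.45e-7, tolerance = 5e-3)
  # power-law width data
  fit_pw <- fit_subfunction_families(C, 2.14 * C^0.41)
  expect_identical(fit_pw$best$family, "power")
  expect_equal(fit_pw$best$params, c(2.14, 0.41), tolerance = 1e-6)
  # log-linear data
  fit_ll <- fit_subfunction_families(C, -218.6 + 41.1 * log10(C))
  expect_identical(fit_ll$best$family, "log_linear")
  expect_equal(fit_ll$best$params, c(-218.6, 41.1), tolerance = 1e-6)
})

test_that("parsimony: constant wins over 2-parameter families on noisy constant data", {
  set.seed(42)
  for (rep in 1:5) {
    C <- 10^seq(5, 6, length.out = 8)
    y <- 23 * (1 + rnorm(8, 0, 0.01))
    fit <- fit_subfunction_families(C, y)
    expect_identical(fit$best$family, "constant")
    # the richer families do reach higher raw R2; parsimony must do the work
    expect_true(all(c("power", "log_linear") %in% fit$table$family))
  }
})

test_that("non-positive concentrations exclude the log-linear candidate", {
  C <- c(0, 10^seq(5, 6, length.out = 7))
  fit <- fit_subfunction_families(C, rep(5, 8),
                                  candidates = c("constant", "log_linear"))
  expect_identical(fit$best$family, "constant")
  expect_match(paste(fit$notes, collapse = " "), "log_linear")
})

test_that("global surface minimization recovers perturbed parameters", {
  set0 <- generate_calibration_set(cem, grid = c(330, 860, 2),
                                   noise = noise_free())
  cal_true <- minimize_global_surface(set0, cem)
  # fixed point: starting at the generating parameters moves nothing
  expect_lte(cal_true$final_error, cal_true$start_error)
  expect_lt(max(abs(cal_true$final_params - cem_true_params) /
                  abs(cem_true_params)), 1e-6)
  # +-20% perturbed start recovers every parameter within 0.5%
  set.seed(5)
  pert <- cem_true_params * (1 + runif(7, -0.2, 0.2))
  cal <- minimize_global_surface(set0, cem, start = pert)
  expect_lt(max(abs(cal$final_params - cem_true_params) /
                  abs(cem_true_params)), 0.005)
  expect_lt(cal$final_error, 1e-6 * sum(vapply(set0$spectra, function(s)
    sum(s$values^2), numeric(1))))
  expect_lte(cal$final_error, cal$start_error)
})

test_that("minimization rejects a non-finite start and reports convergence", {
  set0 <- generate_calibration_set(cem, grid = c(330, 860, 5),
                                   noise = noise_free())
  bad <- cem_true_params; bad[1] <- -1  # invalid Beer-Lambert p1
  expect_error(minimize_global_surface(set0, cem, start = bad), "non-finite")
  capped <- minimize_global_surface(set0, cem,
                                    start = cem_true_params * 1.1,
                                    max_evals = 10)
  expect_false(capped$converged)
  expect_lte(capped$final_error, capped$start_error)
})

test_that("noisy surface fits recover the Beer-Lambert coefficient within 2%", {
  p1_hat <- vapply(0:19, function(seed) {
    set_n <- generate_calibration_set(
      cem, grid = c(330, 860, 5),
      noise = noise_config(cuvette_sd = 0, detector_sd = 0.2, counter_cv = 0,
                           seed = seed))
    minimize_global_surface(set_n, cem, reltol = 1e-8)$final_params[[1]]
  }, numeric(1))
  expect_true(all(abs(p1_hat - 7.67e-7) / 7.67e-7 < 0.02))
})

test_that("structure discovery is exact across random parameter draws", {
  set.seed(99)
  for (rep in 1:20) {
    f <- 1 + runif(7, -0.3, 0.3)
    m <- species_model("draw", list(
      gaussian_component(subfunction("beer_lambert_amplitude", 7.67e-7 * f[1]),
                         subfunction("constant", 533.7 * f[2]),
                         subfunction("power", c(6.32 * f[3], 0.34 * f[4]))),
      gaussian_component(12.21 * f[5], 936.1 * f[6], 177.2 * f[7])),
      concentration_range = c(1e5, 1e6))
    set_r <- generate_calibration_set(m, grid = c(330, 860, 4),
                                      noise = noise_free())
    disc <- iterate_constant_fixing(set_r)
    kind <- vapply(disc$structure, function(x)
      if (is.list(x)) "constant" else "free", character(1))
    expect_identical(unname(kind), c("free", "constant", "free", "constant",
                                     "constant", "constant"))
  }
})

test_that("end-to-end calibration then inversion closes on the ground truth", {
  set0 <- generate_calibration_set(cem, grid = c(330, 860, 2),
                                   noise = noise_free())
  cal <- calibrate_species_model(set0, name = "CEM")
  truths <- counter_concentrations(set0)
  calc <- vapply(set0$spectra, function(s)
    unname(estimate_concentration(s, cal$model)$concentration), numeric(1))
  center <- mean(cal$model$concentration_range)
  expect_lt(abs(compute_bias(calc, truths)) / center, 1e-3)
  expect_lt(compute_dispersion(calc, truths) / center, 1e-3)
  expect_length(cal$per_spectrum_r2, 8)
  expect_gt(length(cal$iteration_log), 1)
})
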