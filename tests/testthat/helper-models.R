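# Shared fixtures: reference models, small wavelength grids, and generators
# for model-derived test spectra. All randomized helpers take explicit seeds.

cem <- cem_reference_model()
ca <- ca_reference_model()

# coarse grids keep the fitting tests fast; the step is a problem-size choice,
# not part of the method
lam_coarse <- seq(330, 860, by = 2)
lam_fine <- seq(330, 860, by = 1)

model_spectrum <- function(m, C, lam = lam_fine, ...) {
  v <- eval_species_model(m, lam, C, warn_extrapolation = FALSE)
  spectrum(lam, pmin(pmax(v, 0), 100), "absorption_percent",
           species = m$name, counter_concentration = C,
           true_concentration = C, ...)
}

random_spectrum_set <- function(n = 3, n_points = 20, seed = 1) {
  set.seed(seed)
  w <- sort(runif(n_points, 300, 900))
  spectrum_set(lapply(seq_len(n), function(i)
    spectrum(w, runif(n_points, 0, 100), "absorption_percent",
             species = sample(c("CEM", "CA", NA), 1),
             counter_concentration = if (i %% 2) runif(1, 1e5, 1e6) else NA,
             time_h = if (i %% 3 == 0) runif(1, 0, 30) else NA,
             set_id = sprintf("W%d", i), cuvette_id = sprintf("c%d", i))))
}

expect_spectrum_equal <- function(a, b) {
  expect_equal(a$wavelengths_nm, b$wavelengths_nm)
  expect_equal(a$values, b$values)
  expect_identical(a$value_kind, b$value_kind)
  expect_equal(a$meta, b$meta)
}

cem_true_params <- c(7.67e-7, 533.7, 6.32, 0.34, 12.21, 936.1, 177.2)
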