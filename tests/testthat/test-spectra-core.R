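test_that("spectrum construction enforces grid and value invariants", {
  expect_error(spectrum(c(400, 399, 401), c(1, 2, 3)), "strictly increasing")
  expect_error(spectrum(c(400, 410), c(1, 2, 3)), "differ in length")
  expect_error(spectrum(c(400, 410), c(-5, 50)), "outside")
  expect_error(spectrum(c(400, 410), c(0.5, 1.2), "transmittance_fraction"),
               "outside")
  # small negatives admitted within tolerance
  s <- spectrum(c(400, 410), c(-0.5, 50))
  expect_equal(s$values[1], -0.5)
})

test_that("transmittance/absorption conversion matches the defining relation and round-trips", {
  s <- spectrum(1:3, c(1, 0.25, 0.378), "transmittance_fraction")
  a <- convert_value_kind(s, "absorption_percent")
  expect_equal(a$values, c(0, 75, 62.2))
  expect_equal(a$meta, s$meta)
  back <- convert_value_kind(a, "transmittance_fraction")
  expect_equal(back$values, s$values, tolerance = 1e-15)  # involutive
  expect_warning(convert_value_kind(a, "absorption_percent"), "already")
  # round trip to machine precision across the full value range
  t_vals <- seq(0, 1, length.out = 101)
  s2 <- spectrum(seq_along(t_vals), t_vals, "transmittance_fraction")
  expect_equal(
    convert_value_kind(convert_value_kind(s2, "absorption_percent"),
                       "transmittance_fraction")$values, t_vals,
    tolerance = 1e-14)
})

test_that("windowing keeps inclusive bounds, is idempotent, rejects empty windows", {
  w <- seq(177, 892, by = 0.22)
  s <- spectrum(w, rep(10, length(w)))
  win <- window_spectrum(s)
  expect_true(all(win$wavelengths_nm >= 330 & win$wavelengths_nm <= 860))
  expect_gte(min(win$wavelengths_nm), 330)
  expect_identical(window_spectrum(win), win)  # idempotent
  expect_error(window_spectrum(s, 400.001, 400.002), "no samples")
  expect_error(window_spectrum(s, 500, 400), "lower bound")
})

test_that("lamp-artifact removal interpolates spikes and handles masks independently", {
  lam <- seq(330, 860, by = 0.5)
  smooth <- 60 * exp(-((lam - 530) / 400)^2)
  spiked <- smooth + 30 * (abs(lam - 656) < 1.2)
  s <- spectrum(lam, pmin(spiked, 100))
  clean <- remove_lamp_artifacts(s, list(c(654, 658)))
  expect_lt(max(abs(clean$values - smooth)), 0.1)
  # empty mask list is the identity
  expect_identical(remove_lamp_artifacts(s, list()), s)
  # two disjoint masks == sequential application
  both <- remove_lamp_artifacts(s, list(c(484, 488), c(654, 658)))
  seq_app <- remove_lamp_artifacts(remove_lamp_artifacts(s, list(c(484, 488))),
                                   list(c(654, 658)))
  expect_equal(both$values, seq_app$values)
  # mask touching the grid end has no interpolation anchor
  expect_error(remove_lamp_artifacts(s, list(c(855, 865))), "grid end")
})

test_that("windowing commutes with artifact removal for interior masks", {
  lam <- seq(177, 892, by = 0.5)
  set.seed(7)
  s <- spectrum(lam, pmin(pmax(50 * exp(-((lam - 530) / 300)^2) +
                                 rnorm(length(lam), 0, 0.3), 0), 100))
  masks <- list(c(484, 488), c(654, 658))
  a <- remove_lamp_artifacts(window_spectrum(s), masks)
  b <- window_spectrum(remove_lamp_artifacts(s, masks))
  expect_equal(a$values, b$values)
})

test_that("quality filter keeps model-shaped spectra and rejects noise", {
  good <- model_spectrum(cem, 5e5, lam_coarse)
  set.seed(3)
  noise <- spectrum(lam_coarse, runif(length(lam_coarse), 0, 60))
  qf <- quality_filter(spectrum_set(list(good, noise)))
  expect_equal(length(qf$kept), 1L)
  expect_equal(length(qf$rejected), 1L)
  expect_match(qf$reasons, "R2")
  # vacuous threshold keeps everything that satisfies the invariants
  qf0 <- quality_filter(spectrum_set(list(good, noise)), r2_threshold = 0)
  expect_equal(length(qf0$kept), 2L)
})

test_that("negative-absorption clipping counts and bounds its corrections", {
  s <- spectrum(1:4, c(-0.4, 0, 5, -0.2))
  cl <- clip_negative_absorption(s)
  expect_equal(cl$values, c(0, 0, 5, 0))
  expect_equal(attr(cl, "n_clipped"), 2L)
  s2 <- spectrum(1:2, c(-0.9, 5))
  expect_error(clip_negative_absorption(s2, tolerance = 0.5), "noise")
})

test_that("resampling to a common grid interpolates and guards coverage", {
  s1 <- spectrum(seq(330, 860, 1), seq(330, 860, 1) / 20)
  s2 <- spectrum(seq(330.4, 860, 0.7), seq(330.4, 860, 0.7) / 20)
  rs <- resample_common_grid(spectrum_set(list(s1, s2)))
  expect_true(rs$common_grid)
  # linear data interpolates exactly away from the extrapolated edges
  inner <- 2:(length(s1$values) - 1)
  expect_equal(rs$spectra[[2]]$values[inner], s1$values[inner],
               tolerance = 1e-12)
  s3 <- spectrum(seq(400, 860, 1), rep(1, 461))
  expect_error(resample_common_grid(spectrum_set(list(s1, s3))), "coverage")
})

test_that("wide CSV and two-column text round-trip randomized sets exactly", {
  for (seed in 1:5) {
    set <- random_spectrum_set(n = 3, seed = seed)
    f <- tempfile(fileext = ".csv")
    write_spectra(set, f)
    back <- read_spectra(f)
    expect_equal(length(back), length(set))
    for (i in seq_along(set$spectra))
      expect_spectrum_equal(back$spectra[[i]], set$spectra[[i]])

    f2 <- vapply(seq_along(set$spectra), function(i) tempfile(), character(1))
    write_spectra(set, f2, format = "two_column_text")
    back2 <- read_spectra(f2, format = "two_column_text")
    for (i in seq_along(set$spectra))
      expect_spectrum_equal(back2$spectra[[i]], set$spectra[[i]])
    unlink(c(f, f2))
  }
})

test_that("readers reject malformed rows, non-monotone grids, unknown kinds", {
  f <- tempfile()
  writeLines(c("# value_kind: absorption_percent", "400 1", "399 2", "401 3"), f)
  expect_error(read_spectra(f, format = "two_column_text"), "strictly increasing")
  writeLines(c("# value_kind: absorption_percent", "400 1", "410 oops"), f)
  expect_error(read_spectra(f, format = "two_column_text"), "line 3")
  writeLines(c("# value_kind: astral_percent", "400 1"), f)
  expect_error(read_spectra(f, format = "two_column_text"), "unknown value_kind")
  writeLines(c("400 1", "410 2"), f)
  expect_error(read_spectra(f, format = "two_column_text"), "value_kind")
  unlink(f)
})

test_that("wide CSV reads a 3-column table as two spectra on a common grid", {
  f <- tempfile(fileext = ".csv")
  writeLines(c('"wavelength;value_kind=absorption_percent","a;species=CEM;concentration=2e5","b"',
               "400,1,2", "410,2,3", "420,3,4", "430,4,5", "440,5,6"), f)
  set <- read_spectra(f)
  expect_equal(length(set), 2L)
  expect_true(set$common_grid)
  expect_equal(set$spectra[[1]]$meta$counter_concentration, 2e5)
  expect_identical(set$spectra[[1]]$meta$species, "CEM")
  unlink(f)
})

test_that("sidecar JSON metadata overrides header metadata", {
  f <- tempfile(fileext = ".csv")
  writeLines(c('"wavelength","a"', "400,1", "410,2"), f)
  jsonlite::write_json(list(value_kind = "absorption_percent",
                            columns = list(a = list(species = "CA",
                                                    counter_concentration = 1e6))),
                       paste0(f, ".json"), auto_unbox = TRUE)
  set <- read_spectra(f)
  expect_identical(set$spectra[[1]]$meta$species, "CA")
  expect_equal(set$spectra[[1]]$meta$counter_concentration, 1e6)
  unlink(c(f, paste0(f, ".json")))
})
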