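test_that("bias and dispersion match hand-computed and brute-force values", {
  expect_equal(compute_bias(c(1e5, 2e5), c(1e5, 2e5)), 0)
  expect_equal(compute_bias(c(2e5, 3e5) + 1000, c(2e5, 3e5)), 1000)
  # worked 2-point example: residuals +-10 cancel, RMS about the line is 10
  expect_equal(compute_bias(c(110, 190), c(100, 200)), 0)
  expect_equal(compute_dispersion(c(110, 190), c(100, 200), bias = 0), 10)
  expect_equal(compute_dispersion(c(110, 190) * 2, c(100, 200) * 2), 20)
  # exact offset data has zero dispersion about its own bias
  expect_equal(compute_dispersion(c(1, 2, 3) + 7, c(1, 2, 3), bias = 7), 0)
  expect_error(compute_bias(1:3, 1:4), "length")

  brute_bias <- function(calc, counter) {
    s <- 0
    for (i in seq_along(calc)) s <- s + (calc[i] - counter[i])
    s / length(calc)
  }
  brute_disp <- function(calc, counter, bias) {
    s <- 0
    for (i in seq_along(calc)) s <- s + (calc[i] - (counter[i] + bias))^2
    sqrt(s / length(calc))
  }
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    counter <- runif(n, 1e5, 1e6)
    calc <- counter * runif(n, 0.8, 1.2)
    b <- compute_bias(calc, counter)
    expect_equal(b, brute_bias(calc, counter), tolerance = 1e-12)
    expect_equal(compute_dispersion(calc, counter, b),
                 brute_disp(calc, counter, b), tolerance = 1e-12)
  }
})

test_that("accuracy report scales dispersion by the center concentration", {
  rep_ <- accuracy_report(c(110, 190), c(100, 200), center = 100)
  expect_equal(rep_$percent_at_center, 10)
  expect_equal(rep_$n, 2L)
})

test_that("cross-validation enumerates all distinct set combinations", {
  sets <- lapply(1:8, function(i)
    generate_calibration_set(cem, concentrations = 10^seq(5, 6, length.out = 5),
                             grid = c(330, 860, 10), noise = noise_free()))
  cv <- cross_validate(sets, 5, cem, max_evals = 50, grid_points = 60)
  expect_equal(cv$n_combinations, choose(8, 5))
  keys <- vapply(cv$combinations, function(x)
    paste(x$model_sets, collapse = "-"), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (x in cv$combinations) {
    expect_length(intersect(x$model_sets, x$test_sets), 0)
    expect_setequal(c(x$model_sets, x$test_sets), 1:8)
  }
})

test_that("a constant concentration shift in the test sets appears as negative bias", {
  K <- 5e4
  model_sets <- lapply(1:3, function(i)
    generate_calibration_set(cem, concentrations = 10^seq(5, 6, length.out = 6),
                             grid = c(330, 860, 5), noise = noise_free()))
  # test set: spectra generated at C, labelled C + K
  shifted <- spectrum_set(lapply(10^seq(5.1, 5.9, length.out = 6), function(C) {
    s <- model_spectrum(cem, C, seq(330, 860, 5))
    s$meta$counter_concentration <- C + K
    s
  }))
  cv <- cross_validate(c(model_sets, list(shifted)), 3, cem)
  held_out <- Filter(function(x) identical(x$test_sets, 4L), cv$combinations)
  expect_length(held_out, 1)
  expect_equal(held_out[[1]]$report$bias, -K, tolerance = 0.02)
})

test_that("growth fitting recovers exact exponentials and flags degenerate series", {
  t <- seq(0, 30, 1.5)
  gf <- fit_growth_curve(t, 5e5 * 2^(t / 26))
  expect_equal(gf$doubling_time_h, 26, tolerance = 1e-10)
  expect_equal(gf$C0, 5e5, tolerance = 1e-8)
  expect_equal(gf$disp_vs_fit, 0, tolerance = 1e-6)
  flat <- fit_growth_curve(t, rep(4e5, length(t)))
  expect_true(is.na(flat$doubling_time_h))
  expect_error(fit_growth_curve(t, rep(-1, length(t))), "positive")
  expect_error(fit_growth_curve(t[1:2], c(1e5, 2e5)), "at least 3")
})

test_that("growth fit recovers any doubling time from noise-free data", {
  set.seed(13)
  for (rep in 1:25) {
    Td <- runif(1, 5, 100)
    C0 <- runif(1, 1e5, 1e6)
    t <- sort(runif(8, 0, 40))
    gf <- fit_growth_curve(t, C0 * 2^(t / Td))
    expect_equal(gf$doubling_time_h, Td, tolerance = 1e-8)
    expect_equal(gf$C0, C0, tolerance = 1e-6)
  }
})

test_that("windowed growth fits separate piecewise doubling times", {
  t <- monitoring_schedule_30h()
  sched <- data.frame(t_start = c(0, 11), t_end = c(11, 30),
                      doubling_time = c(20, 27.7))
  conc <- piecewise_growth(t, 5e5, sched)
  early <- fit_growth_curve(t, conc, window = c(0, 11))
  late <- fit_growth_curve(t, conc, window = c(21, 30))
  full <- fit_growth_curve(t, conc)
  expect_equal(early$doubling_time_h, 20, tolerance = 0.01)
  expect_equal(late$doubling_time_h, 27.7, tolerance = 0.01)
  expect_gt(full$doubling_time_h, 20)
  expect_lt(full$doubling_time_h, 27.7)
})

test_that("crosstalk planes recover identity and injected linear maps", {
  set.seed(17)
  true_grid <- cbind(CEM = runif(30, 1e5, 1e6), CA = runif(30, 5e5, 4e6))
  planes <- fit_crosstalk_planes(true_grid, true_grid)
  expect_equal(planes[[1]]$slopes, c(1, 0), tolerance = 1e-9)
  expect_equal(planes[[2]]$slopes, c(0, 1), tolerance = 1e-9)
  expect_equal(planes[[1]]$p0, 0, tolerance = 1e-6)

  calc <- cbind(CEM = true_grid[, 1] + 0.04 * true_grid[, 2],
                CA = true_grid[, 2])
  planes2 <- fit_crosstalk_planes(true_grid, calc)
  expect_equal(planes2[[1]]$slopes[2], 0.04, tolerance = 1e-6)
  # invariant to sample ordering
  perm <- sample(nrow(true_grid))
  planes3 <- fit_crosstalk_planes(true_grid[perm, ], calc[perm, ])
  expect_equal(planes3[[1]]$slopes, planes2[[1]]$slopes, tolerance = 1e-9)
  # degenerate designs are rejected
  collinear <- cbind(1:10, 2 * (1:10))
  expect_error(fit_crosstalk_planes(collinear, collinear), "collinear")
})
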