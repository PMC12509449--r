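test_that("default forcing grid has 23 non-integer-multiple components", {
  f <- fix_spec$frequencies
  expect_length(f, 23)
  expect_equal(min(f), 0.5)
  expect_equal(max(f), 20.75)
  for (i in seq_along(f)) {
    for (j in seq_along(f)) {
      if (i == j) next
      r <- max(f[i], f[j]) / min(f[i], f[j])
      expect_gt(abs(r - round(r)), 1e-9)
    }
  }
})

test_that("forcing signal concentrates all spectral mass in its 23 bins", {
  sig <- make_forcing_signal(fix_spec, seed = 11)
  n <- length(sig$pressure)
  spec_mag <- Mod(fft(sig$pressure))[1:(n / 2)]
  freqs_axis <- (seq_len(n / 2) - 1) * fix_spec$sample_rate / n
  in_band <- freqs_axis >= fix_spec$f_min - 1e-9 &
    freqs_axis <= fix_spec$f_max + 1e-9
  n_loud <- sum(spec_mag[in_band] > 0.01 * max(spec_mag))
  expect_equal(n_loud, 23)
  # leakage anywhere else below 1% of the peak
  comp_bins <- round(fix_spec$frequencies * n / fix_spec$sample_rate) + 1
  expect_lt(max(spec_mag[-comp_bins]), 0.01 * max(spec_mag))
})

test_that("forcing signal is seed-deterministic and respects duration", {
  a <- make_forcing_signal(fix_spec, seed = 5)
  b <- make_forcing_signal(fix_spec, seed = 5)
  c <- make_forcing_signal(fix_spec, seed = 6)
  expect_identical(a$pressure, b$pressure)
  expect_false(identical(a$pressure, c$pressure))
  expect_length(a$pressure, fix_spec$duration * fix_spec$sample_rate)
})

test_that("undersampled specs are rejected", {
  expect_error(forcing_spec(sample_rate = 100),
               class = "capnovent_input_error")
})

test_that("impedance of a pure resistor is flat and real", {
  sig <- make_forcing_signal(fix_spec, seed = 2)
  z <- estimate_impedance(sig$pressure, sig$pressure / 30, fix_spec)
  expect_true(all(abs(Re(z$values) - 30) < 0.1))
  expect_true(all(abs(Im(z$values)) < 0.1))
  expect_equal(z$ensemble_count, 1L)
})

test_that("impedance of an R-C compartment matches the closed form", {
  r <- 20; cap <- 0.005
  z_true <- r - 1i / (2 * pi * fix_spec$frequencies * cap)
  sig <- make_forcing_signal(fix_spec, seed = 3)
  flow <- capnovent:::forcing_wave(
    sig$time, fix_spec$frequencies,
    fix_spec$amplitudes / Mod(z_true), sig$phases - Arg(z_true))
  z_hat <- estimate_impedance(sig$pressure, flow, fix_spec)
  expect_lt(max(Mod(z_hat$values - z_true) / Mod(z_true)), 0.01)
})

test_that("zero flow raises a singular-frequency error", {
  sig <- make_forcing_signal(fix_spec, seed = 2)
  err <- expect_error(
    estimate_impedance(sig$pressure, numeric(length(sig$pressure)), fix_spec),
    class = "capnovent_numerical_error")
  expect_match(conditionMessage(err), "0.5 Hz")
})

test_that("tube subtraction is exact and validates grids", {
  z <- cpm_impedance(fix_truth, fix_spec$frequencies)
  zero <- impedance_spectrum(fix_spec$frequencies,
                             rep(0 + 0i, 23))
  expect_equal(subtract_tube_impedance(z, zero)$values, z$values)
  expect_true(all(subtract_tube_impedance(z, z)$values == 0))
  tube <- tube_impedance(fix_spec$frequencies, 2, 0.01)
  loaded <- impedance_spectrum(fix_spec$frequencies, z$values + tube$values)
  expect_lt(max(Mod(subtract_tube_impedance(loaded, tube)$values - z$values)),
            1e-9)
  short <- impedance_spectrum(fix_spec$frequencies[1:10], z$values[1:10])
  expect_error(subtract_tube_impedance(z, short),
               class = "capnovent_input_error")
})

test_that("ensemble averaging reduces noise like 1/sqrt(n)", {
  z0 <- cpm_impedance(fix_truth, fix_spec$frequencies)
  expect_equal(ensemble_average(list(z0))$values, z0$values)
  conj_pair <- ensemble_average(list(
    z0, impedance_spectrum(z0$frequencies, Conj(z0$values))))
  expect_true(all(abs(Im(conj_pair$values)) < 1e-12))
  expect_error(ensemble_average(list()), class = "capnovent_input_error")

  noisy <- function(k, m) {
    set.seed(1000 + k * 100 + m)
    impedance_spectrum(z0$frequencies,
                       z0$values + complex(real = rnorm(23), imaginary = rnorm(23)))
  }
  # mean absolute deviation of a 20-average vs single replicates, many trials
  dev1 <- mean(sapply(1:30, function(k) mean(Mod(noisy(k, 1)$values - z0$values))))
  dev20 <- mean(sapply(1:30, function(k) {
    avg <- ensemble_average(lapply(1:20, function(m) noisy(k, m)))
    mean(Mod(avg$values - z0$values))
  }))
  expect_equal(dev20 / dev1, 1 / sqrt(20), tolerance = 0.25)
  expect_equal(ensemble_average(lapply(1:20, function(m) noisy(1, m)))$ensemble_count,
               20L)
})

test_that("constant-phase model matches its defining formula", {
  # alpha limits
  expect_equal(mechanical_state(1, 0, 100, 100)$alpha, 0.5)
  expect_gt(mechanical_state(1, 0, 1e-6, 1e3)$alpha, 0.999)
  # hand-evaluated oracle at 5 Hz (Raw 25, Iaw 0.1, G 300, H 1500)
  z5 <- cpm_impedance(fix_truth, 5)$values
  expect_equal(Re(z5), 39.7269, tolerance = 1e-4)
  expect_equal(Im(z5), -70.4930, tolerance = 1e-4)
  # full-grid agreement with the independent evaluation
  z <- cpm_impedance(fix_truth, fix_spec$frequencies)
  expect_equal(z$values,
               oracle_cpm(25, 0.1, 300, 1500, fix_spec$frequencies),
               tolerance = 1e-12)
  expect_error(cpm_impedance(fix_truth, c(0, 5)),
               class = "capnovent_input_error")
})

test_that("noiseless fits recover the generating parameters", {
  z <- cpm_impedance(fix_truth, fix_spec$frequencies)
  fit <- fit_constant_phase(z)
  expect_true(fit$converged)
  for (p in c("raw", "iaw", "g", "h")) {
    expect_lt(abs(fit$mech[[p]] / fix_truth[[p]] - 1), 0.005)
  }
  # eta is derived, never independently fitted
  expect_identical(fit$mech$eta, fit$mech$g / fit$mech$h)
  expect_error(fit_constant_phase(
    impedance_spectrum(1:3, cpm_impedance(fix_truth, 1:3)$values)),
    class = "capnovent_input_error")
})

test_that("fitting is robust to proportional noise and weighting choice", {
  z0 <- cpm_impedance(fix_truth, fix_spec$frequencies)
  errs <- sapply(1:10, function(s) {
    set.seed(s)
    zn <- impedance_spectrum(
      z0$frequencies,
      z0$values + 0.05 * Mod(z0$values) *
        complex(real = rnorm(23), imaginary = rnorm(23)))
    fit <- fit_constant_phase(zn)
    c(abs(fit$mech$g / 300 - 1), abs(fit$mech$h / 1500 - 1))
  })
  expect_lt(median(errs), 0.05)
  fit_rel <- fit_constant_phase(z0, weights = "relative")
  expect_lt(abs(fit_rel$mech$h / 1500 - 1), 0.005)
})

test_that("any 12-frequency subset recovers near-identical parameters", {
  z <- cpm_impedance(fix_truth, fix_spec$frequencies)
  full <- fit_constant_phase(z)
  set.seed(42)
  for (k in 1:3) {
    idx <- sort(sample(23, 12))
    sub <- impedance_spectrum(z$frequencies[idx], z$values[idx])
    fit <- fit_constant_phase(sub)
    for (p in c("raw", "iaw", "g", "h")) {
      expect_lt(abs(fit$mech[[p]] / full$mech[[p]] - 1), 0.02)
    }
  }
})

test_that("optimizer cost beats the brute-force grid oracle", {
  z <- cpm_impedance(fix_truth, fix_spec$frequencies)
  fit <- fit_constant_phase(z)
  grid_best <- oracle_grid_cost(
    z$values, z$frequencies,
    list(raw = 25, iaw = 0.1, g = 300, h = 1500), n = 8)
  expect_lte(fit$cost, grid_best)
})

test_that("spectra round-trip through CSV", {
  dir <- withr::local_tempdir()
  z <- cpm_impedance(fix_truth, fix_spec$frequencies)
  path <- file.path(dir, "z.csv")
  write_spectrum(z, path)
  back <- read_spectrum(path)
  expect_equal(back$frequencies, z$frequencies)
  expect_equal(back$values, z$values, tolerance = 1e-12)
})
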