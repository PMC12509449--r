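# Forced-oscillation measurement chain: multifrequency forcing signal,
# input-impedance estimation, tube correction, and ensemble averaging.

#' Forcing-signal specification
#'
#' Defines the small-amplitude pseudorandom pressure signal used for
#' oscillometry during short apneic windows: a sum of sinusoids whose
#' frequencies are mutually non-integer multiples, so that harmonic
#' distortion from one component never contaminates another.
#'
#' The default grid is built from the first 23 primes doubled and placed on
#' the 0.125 Hz resolution of an 8-s window: `f_k = 2 p_k / duration` Hz,
#' giving exactly 23 components from 0.5 Hz (p = 2) to 20.75 Hz (p = 83).
#' Ratios of distinct components are ratios of distinct primes and hence
#' never integers, and every component sits exactly on an FFT bin of the
#' window, so spectral estimation is leakage-free.
#'
#' @param f_min Lowest component frequency (Hz). Default 0.5.
#' @param f_max Highest component frequency (Hz). Default 20.75.
#' @param n_components Number of sinusoidal components. Default 23.
#' @param duration Window length (s). Default 8.
#' @param sample_rate Sampling rate (Hz), must be >= 10 * `f_max`.
#' @param amplitudes Per-component amplitudes (cmH2O); default equal
#'   amplitudes scaled so the composite signal has RMS 1 cmH2O.
#' @param frequencies Optional explicit frequency vector overriding the
#'   prime-grid construction (still validated against the invariants).
#' @return An object of class `forcing_spec`.
#' @export
forcing_spec <- function(f_min = 0.5, f_max = 20.75, n_components = 23,
                         duration = 8, sample_rate = 256,
                         amplitudes = NULL, frequencies = NULL) {
  check_number(f_min, "f_min", lower = .Machine$double.xmin)
  check_number(f_max, "f_max", lower = f_min)
  n_components <- check_count(n_components, "n_components", min = 1)
  check_number(duration, "duration", lower = .Machine$double.xmin)
  check_number(sample_rate, "sample_rate", lower = .Machine$double.xmin)
  if (sample_rate < 10 * f_max) {
    abort_input(sprintf(
      "sample_rate (%g Hz) must be at least 10 * f_max (%g Hz) to avoid aliasing",
      sample_rate, 10 * f_max))
  }
  if (is.null(frequencies)) {
    df <- 1 / duration
    k_min <- round(f_min / df)
    if (abs(k_min * df - f_min) > 1e-9) {
      abort_config("f_min must sit on the frequency resolution 1/duration")
    }
    if (k_min %% 2 != 0) {
      abort_config("f_min * duration must be even for the prime-grid construction")
    }
    k <- (k_min / 2) * first_primes(n_components)
    frequencies <- k * df
    if (max(frequencies) > f_max + 1e-9) {
      abort_config(sprintf(
        "prime grid exceeds f_max: need f_max >= %g Hz for %d components",
        max(frequencies), n_components))
    }
  } else {
    check_number(frequencies, "frequencies", lower = f_min, upper = f_max)
    if (length(frequencies) != n_components) {
      abort_input("`frequencies` must have length `n_components`")
    }
  }
  if (is.unsorted(frequencies, strictly = TRUE)) {
    abort_input("component frequencies must be strictly ascending")
  }
  rat <- outer(frequencies, frequencies, "/")
  off <- abs(rat - round(rat)) < 1e-9 & round(rat) >= 2
  if (any(off)) {
    abort_config("component frequencies must be mutually non-integer multiples")
  }
  if (is.null(amplitudes)) {
    # equal amplitudes, composite RMS 1 cmH2O: RMS^2 = sum(a^2)/2
    amplitudes <- rep(sqrt(2 / n_components), n_components)
  }
  check_number(amplitudes, "amplitudes", lower = 0)
  if (length(amplitudes) == 1) amplitudes <- rep(amplitudes, n_components)
  if (length(amplitudes) != n_components) {
    abort_input("`amplitudes` must have length `n_components`")
  }
  structure(
    list(f_min = f_min, f_max = f_max, n_components = n_components,
         duration = duration, sample_rate = sample_rate,
         frequencies = frequencies, amplitudes = amplitudes),
    class = "forcing_spec"
  )
}

#' @export
print.forcing_spec <- function(x, ...) {
  cat(sprintf(
    "<forcing_spec> %d components, %.3g-%.3g Hz, %gs @ %g Hz\n",
    x$n_components, min(x$frequencies), max(x$frequencies),
    x$duration, x$sample_rate))
  invisible(x)
}

#' Generate the pseudorandom forcing pressure signal
#'
#' Sum of the spec's sinusoids with phases drawn uniformly on `[0, 2*pi)`
#' from `seed`. The same seed always yields the same signal.
#'
#' @param spec A [forcing_spec].
#' @param seed Integer seed for the component phases.
#' @return A list with `time` (s), `pressure` (cmH2O), `phases` (rad) and
#'   the `spec` used.
#' @export
make_forcing_signal <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "forcing_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  phases <- with_seed(seed, stats::runif(spec$n_components, 0, 2 * pi))
  p <- forcing_wave(t, spec$frequencies, spec$amplitudes, phases)
  list(time = t, pressure = p, phases = phases, spec = spec)
}

# Evaluate sum_k a_k sin(2 pi f_k t + phi_k) on a time grid.
forcing_wave <- function(t, frequencies, amplitudes, phases) {
  arg <- outer(t, 2 * pi * frequencies)
  drop(sin(sweep(arg, 2, phases, "+")) %*% amplitudes)
}

#' Estimate respiratory input impedance
#'
#' Computes `Zrs(f) = Sxy(f) / Sxx(f)` at each component frequency, where
#' `Sxy` is the cross-spectrum of airway-opening pressure with flow and
#' `Sxx` the flow auto-spectrum, over the full analysis window. When every
#' component sits on an FFT bin of the window (the default spec) the
#' estimate is leakage-free.
#'
#' @param pressure Airway-opening pressure samples (cmH2O).
#' @param flow Flow samples (L/s), same length and rate.
#' @param spec The [forcing_spec] describing the excitation.
#' @return An [impedance_spectrum] with `ensemble_count = 1`.
#' @export
estimate_impedance <- function(pressure, flow, spec) {
  stopifnot(inherits(spec, "forcing_spec"))
  if (!is.numeric(pressure) || !is.numeric(flow) ||
      length(pressure) != length(flow) || length(pressure) < 2) {
    abort_input("`pressure` and `flow` must be equal-length numeric series")
  }
  n <- length(pressure)
  fs <- spec$sample_rate
  if (n / fs < 1 / min(spec$frequencies) - 1e-9) {
    abort_input("series must cover at least one period of the lowest component")
  }
  bins <- spec$frequencies * n / fs
  aligned <- all(abs(bins - round(bins)) < 1e-9)
  if (aligned) {
    fp <- stats::fft(pressure)
    fv <- stats::fft(flow)
    idx <- round(bins) + 1L
    p_hat <- fp[idx]
    v_hat <- fv[idx]
  } else {
    t <- (seq_len(n) - 1) / fs
    basis <- exp(-2i * pi * outer(spec$frequencies, t))
    p_hat <- drop(basis %*% pressure)
    v_hat <- drop(basis %*% flow)
  }
  auto <- Re(v_hat * Conj(v_hat))
  floor_ <- 1e-15 * max(1, sum(flow^2)) * n
  bad <- which(auto <= floor_)
  if (length(bad) > 0) {
    abort_numerical(sprintf(
      "flow auto-spectrum is singular at %g Hz: no flow energy at that component",
      spec$frequencies[bad[1]]))
  }
  z <- p_hat * Conj(v_hat) / auto
  impedance_spectrum(spec$frequencies, z, ensemble_count = 1L)
}

#' Subtract the measured tube impedance
#'
#' Removes the impedance of the tracheal tube and connecting tubing from a
#' respiratory-system spectrum by element-wise complex subtraction.
#'
#' @param zrs Measured [impedance_spectrum] (tube + respiratory system).
#' @param ztube Tube [impedance_spectrum] on the identical frequency grid.
#' @return An [impedance_spectrum]; `ensemble_count` of `zrs` is preserved.
#' @export
subtract_tube_impedance <- function(zrs, ztube) {
  stopifnot(inherits(zrs, "impedance_spectrum"),
            inherits(ztube, "impedance_spectrum"))
  if (length(zrs$frequencies) != length(ztube$frequencies) ||
      any(abs(zrs$frequencies - ztube$frequencies) > 1e-9)) {
    abort_input("frequency grids of `zrs` and `ztube` must be identical")
  }
  impedance_spectrum(zrs$frequencies, zrs$values - ztube$values,
                     ensemble_count = zrs$ensemble_count)
}

#' Ensemble-average impedance spectra
#'
#' Complex mean per frequency across repeated recordings of the same
#' condition; the returned `ensemble_count` is the total number of
#' recordings represented.
#'
#' @param spectra Non-empty list of [impedance_spectrum] objects on one grid.
#' @return An [impedance_spectrum].
#' @export
ensemble_average <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0 ||
      !all(vapply(spectra, inherits, TRUE, "impedance_spectrum"))) {
    abort_input("`spectra` must be a non-empty list of impedance_spectrum")
  }
  f0 <- spectra[[1]]$frequencies
  for (s in spectra) {
    if (length(s$frequencies) != length(f0) ||
        any(abs(s$frequencies - f0) > 1e-9)) {
      abort_input("all spectra must share one frequency grid")
    }
  }
  mat <- matrix(vapply(spectra, function(s) s$values, complex(length(f0))),
                nrow = length(f0))
  vals <- rowMeans(mat)
  n_tot <- sum(vapply(spectra, function(s) s$ensemble_count, integer(1)))
  impedance_spectrum(f0, vals, ensemble_count = n_tot)
}
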