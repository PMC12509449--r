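# Respiratory mechanical state and the constant-phase impedance model.

#' Respiratory mechanical state
#'
#' Bundles the four free parameters of the constant-phase model of
#' respiratory input impedance: Newtonian airway resistance `raw`
#' (cmH2O.s/L), airway inertance `iaw` (cmH2O.s^2/L), tissue damping `g` and
#' tissue elastance `h` (both cmH2O/L at 1 rad/s). Two quantities are always
#' derived, never set: hysteresivity `eta = g/h`, the coupling of dissipative
#' to elastic tissue forces, and the constant-phase exponent
#' `alpha = (2/pi) * atan(h/g)`.
#'
#' @param raw Airway resistance, > 0 (cmH2O.s/L).
#' @param iaw Airway inertance, >= 0 (cmH2O.s^2/L).
#' @param g Tissue damping, > 0 (cmH2O/L).
#' @param h Tissue elastance, > 0 (cmH2O/L).
#' @return An object of class `mechanical_state`.
#' @examples
#' mechanical_state(raw = 20, iaw = 0.15, g = 40, h = 200)
#' @export
mechanical_state <- function(raw, iaw, g, h) {
  check_number(raw, "raw", lower = .Machine$double.xmin)
  check_number(iaw, "iaw", lower = 0)
  check_number(g, "g", lower = .Machine$double.xmin)
  check_number(h, "h", lower = .Machine$double.xmin)
  structure(
    list(raw = raw, iaw = iaw, g = g, h = h,
         eta = g / h, alpha = (2 / pi) * atan(h / g)),
    class = "mechanical_state"
  )
}

#' @export
print.mechanical_state <- function(x, ...) {
  cat("<mechanical_state>\n")
  cat(sprintf("  Raw = %.4g cmH2O.s/L   Iaw = %.4g cmH2O.s2/L\n", x$raw, x$iaw))
  cat(sprintf("  G   = %.4g cmH2O/L     H   = %.4g cmH2O/L\n", x$g, x$h))
  cat(sprintf("  eta = %.4g             alpha = %.4g\n", x$eta, x$alpha))
  invisible(x)
}

#' Baseline rabbit respiratory mechanics
#'
#' Default single-animal mechanics used when none are supplied: values
#' representative of a healthy, anaesthetized adult rabbit at
#' end-expiration, with the tracheal tube impedance already removed.
#'
#' @return A [mechanical_state].
#' @export
baseline_mechanics <- function() {
  mechanical_state(raw = 20, iaw = 0.15, g = 40, h = 200)
}

#' Impedance spectrum container
#'
#' Complex respiratory input impedance sampled at a set of oscillation
#' frequencies, together with the number of recordings averaged into it.
#'
#' @param frequencies Strictly ascending frequencies (Hz), all > 0.
#' @param values Complex impedance values (cmH2O.s/L), same length.
#' @param ensemble_count Number of recordings averaged (>= 1).
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequencies, values, ensemble_count = 1L) {
  check_number(frequencies, "frequencies", lower = .Machine$double.xmin)
  if (is.unsorted(frequencies, strictly = TRUE)) {
    abort_input("`frequencies` must be strictly ascending")
  }
  values <- as.complex(values)
  if (length(values) != length(frequencies) || anyNA(values) ||
      any(!is.finite(Re(values))) || any(!is.finite(Im(values)))) {
    abort_input("`values` must be finite complex values matching `frequencies`")
  }
  ensemble_count <- check_count(ensemble_count, "ensemble_count")
  structure(
    list(frequencies = frequencies, values = values,
         ensemble_count = ensemble_count),
    class = "impedance_spectrum"
  )
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf(
    "<impedance_spectrum> %d frequencies, %.3g-%.3g Hz, ensemble of %d\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$ensemble_count
  ))
  invisible(x)
}

#' Constant-phase model impedance
#'
#' Evaluates the constant-phase model of respiratory input impedance,
#' `Z(w) = Raw + i.w.Iaw + (G - i.H) / w^alpha` with `w = 2.pi.f` in rad/s
#' and `alpha = (2/pi) * atan(H/G)`. The rad/s convention inside `w^alpha`
#' means `G` and `H` carry units of cmH2O/L at 1 rad/s.
#'
#' @param mech A [mechanical_state].
#' @param frequencies Frequencies (Hz), all > 0.
#' @return An [impedance_spectrum] of the model on the given grid.
#' @examples
#' z <- cpm_impedance(mechanical_state(25, 0.1, 300, 1500), c(1, 5, 20))
#' @export
cpm_impedance <- function(mech, frequencies) {
  stopifnot(inherits(mech, "mechanical_state"))
  check_number(frequencies, "frequencies", lower = .Machine$double.xmin)
  w <- 2 * pi * frequencies
  z <- mech$raw + 1i * w * mech$iaw +
    (mech$g - 1i * mech$h) / w^mech$alpha
  impedance_spectrum(frequencies, z)
}

# Series tube impedance (resistance + inertance), used both to corrupt
# synthesized recordings and as the default correction spectrum.
#' Tracheal tube impedance model
#'
#' Series resistance plus inertance model for the tracheal tube and
#' connecting tubing, `Z_t(f) = R_t + i.2.pi.f.I_t`.
#'
#' @param frequencies Frequencies (Hz).
#' @param r_tube Tube resistance (cmH2O.s/L), default 2.
#' @param i_tube Tube inertance (cmH2O.s^2/L), default 0.01.
#' @return An [impedance_spectrum].
#' @export
tube_impedance <- function(frequencies, r_tube = 2, i_tube = 0.01) {
  check_number(r_tube, "r_tube", lower = 0)
  check_number(i_tube, "i_tube", lower = 0)
  impedance_spectrum(frequencies,
                     r_tube + 1i * 2 * pi * frequencies * i_tube)
}
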