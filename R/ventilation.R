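# Breath-plan generation (PCV and variable ventilation) and delivery of the
# plans on a linear single-compartment lung.

#' Ventilator settings
#'
#' Protocol-level ventilator configuration shared by both modes. Defaults
#' reproduce the study protocol: tidal volume target 7 mL/kg, respiratory
#' rate 22/min (protocol range 20-25/min), PEEP 5 cmH2O, FiO2 0.4 and an
#' inspiratory:expiratory ratio of 1:2. In variable ventilation (VV) the
#' per-breath peak inspiratory pressure and rate fluctuate with the given
#' coefficients of variation; in pressure-controlled ventilation (PCV) both
#' CVs are identically zero.
#'
#' @param mode `"PCV"` or `"VV"`.
#' @param target_vt_per_kg Tidal volume target per body mass (mL/kg).
#' @param body_mass Body mass (kg).
#' @param rr_target Respiratory rate (breaths/min); values outside the
#'   20-25/min protocol window are accepted with a warning.
#' @param peep Positive end-expiratory pressure (cmH2O).
#' @param ie_ratio Inspiratory:expiratory time ratio as a single number
#'   (1:2 is `0.5`).
#' @param fio2 Inspired oxygen fraction, in (0, 1].
#' @param vv_cv_pip Coefficient of variation of per-breath driving pressure
#'   (VV only; must be 0 for PCV). Must be < 0.5 so the +/-2 SD truncation
#'   can never drive PIP to or below PEEP.
#' @param vv_cv_rr Coefficient of variation of per-breath rate (VV only).
#' @param averaging_window Breath count over which VV means are constrained
#'   to match the PCV targets (default 30).
#' @return An object of class `ventilator_settings`.
#' @export
ventilator_settings <- function(mode = c("PCV", "VV"),
                                target_vt_per_kg = 7,
                                body_mass = 3.9,
                                rr_target = 22,
                                peep = 5,
                                ie_ratio = 0.5,
                                fio2 = 0.4,
                                vv_cv_pip = if (mode == "VV") 0.2 else 0,
                                vv_cv_rr = if (mode == "VV") 0.2 else 0,
                                averaging_window = 30L) {
  mode <- match.arg(mode)
  check_number(target_vt_per_kg, "target_vt_per_kg", lower = 0)
  check_number(body_mass, "body_mass", lower = .Machine$double.xmin)
  check_number(rr_target, "rr_target", lower = 1, upper = 120)
  if (rr_target < 20 || rr_target > 25) {
    warning("rr_target outside the 20-25/min protocol window", call. = FALSE)
  }
  check_number(peep, "peep", lower = 0)
  check_number(ie_ratio, "ie_ratio", lower = 1e-6)
  check_number(fio2, "fio2", lower = 1e-12, upper = 1)
  check_number(vv_cv_pip, "vv_cv_pip", lower = 0)
  check_number(vv_cv_rr, "vv_cv_rr", lower = 0)
  averaging_window <- check_count(averaging_window, "averaging_window")
  if (mode == "PCV" && (vv_cv_pip != 0 || vv_cv_rr != 0)) {
    abort_input("PCV requires vv_cv_pip = vv_cv_rr = 0")
  }
  if (max(vv_cv_pip, vv_cv_rr) >= 0.5) {
    abort_config(
      "coefficients of variation >= 0.5 would let the 2 SD truncation floor bind (PIP <= PEEP)")
  }
  structure(
    list(mode = mode, target_vt_per_kg = target_vt_per_kg,
         body_mass = body_mass, rr_target = rr_target, peep = peep,
         ie_ratio = ie_ratio, fio2 = fio2, vv_cv_pip = vv_cv_pip,
         vv_cv_rr = vv_cv_rr, averaging_window = averaging_window),
    class = "ventilator_settings"
  )
}

insp_fraction <- function(settings) {
  settings$ie_ratio / (1 + settings$ie_ratio)
}

new_breath_plan <- function(pip, duration, settings, seed, pip_pcv) {
  if (any(pip <= settings$peep)) {
    abort_config("all breath PIPs must exceed PEEP")
  }
  if (any(duration <= 0)) abort_input("all breath durations must be positive")
  structure(
    list(breaths = data.frame(pip = pip, duration = duration),
         settings = settings, seed = seed, pip_pcv = pip_pcv),
    class = "breath_plan"
  )
}

#' @export
print.breath_plan <- function(x, ...) {
  cat(sprintf(
    "<breath_plan> %s, %d breaths, PIP %.3g-%.3g cmH2O, duration %.3g-%.3g s\n",
    x$settings$mode, nrow(x$breaths), min(x$breaths$pip), max(x$breaths$pip),
    min(x$breaths$duration), max(x$breaths$duration)))
  invisible(x)
}

#' Pressure-controlled ventilation breath plan
#'
#' Constant-PIP, constant-rate plan. The PIP is calibrated with
#' [calibrate_pip_for_vt] so that delivery on `mech` through
#' [simulate_breaths] yields the settings' tidal volume target.
#'
#' @param settings A [ventilator_settings] (any mode; CVs are ignored).
#' @param n_breaths Number of breaths (>= 1).
#' @param mech Lung [mechanical_state] used for PIP calibration.
#' @param pip Optional explicit PIP (cmH2O) bypassing calibration.
#' @return A `breath_plan`.
#' @export
make_pcv_plan <- function(settings, n_breaths, mech = baseline_mechanics(),
                          pip = NULL) {
  stopifnot(inherits(settings, "ventilator_settings"))
  n_breaths <- check_count(n_breaths, "n_breaths")
  if (is.null(pip)) pip <- calibrate_pip_for_vt(mech, settings)
  check_number(pip, "pip", lower = settings$peep + 1e-12)
  new_breath_plan(rep(pip, n_breaths),
                  rep(60 / settings$rr_target, n_breaths),
                  settings, seed = NULL, pip_pcv = pip)
}

#' Variable ventilation breath plan
#'
#' Draws independent truncated-Gaussian multipliers (+/- 2 SD) for the
#' per-breath driving pressure (PIP - PEEP) and the per-breath rate, then
#' rescales each disjoint `averaging_window`-breath window so that the
#' window mean rate equals `rr_target` and the window mean driving pressure
#' equals the calibrated PCV driving pressure exactly. On the plan's linear
#' lung model the windowed mean tidal volume therefore matches the PCV
#' target exactly; zero CVs reduce the plan to [make_pcv_plan].
#'
#' @inheritParams make_pcv_plan
#' @param seed Integer seed; identical seeds give identical plans.
#' @return A `breath_plan`.
#' @export
make_vv_plan <- function(settings, n_breaths, seed,
                         mech = baseline_mechanics(), pip = NULL) {
  stopifnot(inherits(settings, "ventilator_settings"))
  n_breaths <- check_count(n_breaths, "n_breaths")
  if (is.null(pip)) pip <- calibrate_pip_for_vt(mech, settings)
  dp0 <- pip - settings$peep
  # The stated CV is the CV of the truncated multiplier distribution, so the
  # pre-truncation SD is inflated by the +/-2 SD truncation shrink factor.
  shrink <- sqrt(1 - 4 * stats::dnorm(2) / (2 * stats::pnorm(2) - 1))
  if (max(settings$vv_cv_pip, settings$vv_cv_rr) >= shrink / 2) {
    abort_config(sprintf(
      "CV >= %.3f makes the truncation floor (PIP <= PEEP or rate <= 0) bind",
      shrink / 2))
  }
  mult <- with_seed(seed, list(
    pip = rtnorm(n_breaths, 1, settings$vv_cv_pip / shrink, z = 2),
    rate = rtnorm(n_breaths, 1, settings$vv_cv_rr / shrink, z = 2)
  ))
  win <- rep(seq_len(ceiling(n_breaths / settings$averaging_window)),
             each = settings$averaging_window)[seq_len(n_breaths)]
  m_pip <- mult$pip / stats::ave(mult$pip, win)
  m_rate <- mult$rate / stats::ave(mult$rate, win)
  rate <- settings$rr_target * m_rate
  new_breath_plan(settings$peep + dp0 * m_pip, 60 / rate, settings,
                  seed = seed, pip_pcv = pip)
}

#' Model-predicted tidal volume of a breath plan
#'
#' Static linear-model prediction `VT_i = (PIP_i - PEEP) / E` with
#' `E = H`, in mL. This is the quantity whose windowed mean the VV plan
#' constrains, independent of delivery dynamics.
#'
#' @param plan A `breath_plan`.
#' @param mech Lung [mechanical_state]; `E = H`.
#' @return Numeric vector of per-breath volumes (mL).
#' @export
model_vt <- function(plan, mech = baseline_mechanics()) {
  stopifnot(inherits(plan, "breath_plan"))
  (plan$breaths$pip - plan$settings$peep) / mech$h * 1000
}

#' Calibrate PIP to deliver the tidal-volume target
#'
#' Monotone bisection on PIP such that a single steady-state breath,
#' simulated with [simulate_breaths] on the single-compartment reduction of
#' `mech` (resistance `Raw + G/w_b^alpha` at the breathing frequency,
#' elastance `H`), delivers the settings' tidal-volume target to 0.1%.
#'
#' @param mech Lung [mechanical_state].
#' @param settings A [ventilator_settings].
#' @param dt Simulator time step (s), default 0.5 ms.
#' @return Calibrated PIP (cmH2O).
#' @export
calibrate_pip_for_vt <- function(mech, settings, dt = 5e-4) {
  stopifnot(inherits(mech, "mechanical_state"),
            inherits(settings, "ventilator_settings"))
  vt_target <- settings$target_vt_per_kg * settings$body_mass / 1000 # L
  if (vt_target == 0) return(settings$peep)
  one_breath_vt <- function(pip) {
    plan <- new_breath_plan(pip, 60 / settings$rr_target, settings,
                            seed = NULL, pip_pcv = pip)
    sim <- simulate_breaths(plan, mech, peep = settings$peep,
                            ie_ratio = settings$ie_ratio, dt = dt)
    sim$vt_ml[1] / 1000
  }
  lo <- settings$peep
  hi <- settings$peep + 2 * mech$h * vt_target
  for (i in 1:30) {
    if (one_breath_vt(hi) >= vt_target) break
    hi <- settings$peep + 2 * (hi - settings$peep)
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    vt <- one_breath_vt(mid)
    if (abs(vt - vt_target) <= 1e-3 * vt_target) return(mid)
    if (vt < vt_target) lo <- mid else hi <- mid
  }
  abort_numerical(sprintf(
    "PIP calibration did not converge in 100 bisections (target %.4g L, last VT %.4g L, bracket [%.4g, %.4g] cmH2O)",
    vt_target, vt, lo, hi))
}

#' Deliver a breath plan on a single-compartment lung
#'
#' Integrates the first-order equation of motion
#' `Pao = R V' + E V + PEEP` driven by an ideal square pressure wave
#' between PEEP and the per-breath PIP with the settings' I:E split.
#' `E = H` and `R = Raw + G / w_b^alpha` evaluated at the plan's nominal
#' breathing frequency. Within each constant-drive segment the state is
#' advanced by the exact exponential update (no integrator-order error);
#' the recorded volume trace is the trapezoidal antiderivative of the
#' recorded flow trace, so flow and volume are exactly conservative under
#' trapezoidal integration.
#'
#' @param plan A `breath_plan`.
#' @param mech Lung [mechanical_state].
#' @param peep PEEP (cmH2O); defaults to the plan's settings.
#' @param ie_ratio Inspiratory:expiratory ratio; defaults to the plan's.
#' @param dt Time step (s), must be <= 1 ms and > 0.
#' @return A list of class `simulated_breathing`: `time` (s), `pao` (cmH2O),
#'   `flow` (L/s), `volume` (L above end-expiratory volume), `vt_ml`
#'   (per-breath delivered tidal volume, mL), `breath` (per-sample breath
#'   index), and `dt`.
#' @export
simulate_breaths <- function(plan, mech, peep = plan$settings$peep,
                             ie_ratio = plan$settings$ie_ratio, dt = 5e-4) {
  stopifnot(inherits(plan, "breath_plan"), inherits(mech, "mechanical_state"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    abort_input("`dt` must be a positive time step")
  }
  if (dt > 1e-3 + 1e-12) abort_input("`dt` must be <= 1 ms")
  nb <- nrow(plan$breaths)
  if (nb < 1) abort_input("plan must contain at least one breath")
  e_mod <- mech$h
  w_b <- 2 * pi * mean(60 / plan$breaths$duration) / 60
  r_mod <- mech$raw + mech$g / w_b^mech$alpha
  tau <- r_mod / e_mod
  fi <- ie_ratio / (1 + ie_ratio)

  # Samples sit at t = 0, dt, 2dt, ...; a sample at a drive transition takes
  # its value from the segment that ends there (left limit), so trapezoidal
  # integration of the recorded flow reproduces the recorded volume exactly
  # and the volume trace never undershoots zero at end-expiration.
  v0 <- 0
  degenerate <- tau < dt / 10 # effectively resistance-free lung
  seg_flow <- vector("list", 2 * nb)
  seg_pao <- vector("list", 2 * nb)
  seg_vol <- if (degenerate) vector("list", 2 * nb) else NULL
  breath_idx <- vector("list", 2 * nb)
  vt_ml <- numeric(nb)
  v_state <- numeric(2 * nb + 1) # exact state at segment boundaries
  v_state[1] <- v0
  seg <- 0L
  for (b in seq_len(nb)) {
    n_tot <- max(2L, round(plan$breaths$duration[b] / dt))
    n_in <- max(1L, min(n_tot - 1L, round(n_tot * fi)))
    dp <- c(plan$breaths$pip[b] - peep, 0)
    nsteps <- c(n_in, n_tot - n_in)
    for (ph in 1:2) {
      seg <- seg + 1L
      v_start <- v_state[seg]
      v_targ <- dp[ph] / e_mod
      k <- seq_len(nsteps[ph])
      if (degenerate) {
        v <- rep(v_targ, nsteps[ph])
        f <- c((v_targ - v_start) / dt, rep(0, nsteps[ph] - 1L))
        seg_vol[[seg]] <- v
        v_state[seg + 1L] <- v_targ
      } else {
        decay <- exp(-k * dt / tau)
        v <- v_targ + (v_start - v_targ) * decay
        f <- (v_targ - v) / tau
        v_state[seg + 1L] <- v[nsteps[ph]]
      }
      seg_flow[[seg]] <- f
      seg_pao[[seg]] <- rep(peep + dp[ph], nsteps[ph])
      breath_idx[[seg]] <- rep(b, nsteps[ph])
    }
  }
  # At each drive transition the flow is discontinuous; the boundary sample
  # records the mean of the left and right limits, which halves the
  # trapezoidal discretization bias of the volume trace at the jump.
  if (!degenerate) {
    for (s in seq_len(2 * nb - 1)) {
      nxt_targ <- if (s %% 2 == 1) 0 else
        (plan$breaths$pip[s / 2 + 1] - peep) / e_mod
      f_right <- (nxt_targ - v_state[s + 1L]) / tau
      ns <- length(seg_flow[[s]])
      seg_flow[[s]][ns] <- (seg_flow[[s]][ns] + f_right) / 2
    }
  }
  # A breath-boundary sample carries the incoming inspiration's flow share,
  # so it belongs to the next breath for tidal-volume bookkeeping.
  for (b in seq_len(nb - 1)) {
    s <- 2L * b
    breath_idx[[s]][length(breath_idx[[s]])] <- b + 1L
  }
  f_init <- if (degenerate) 0 else
    (plan$breaths$pip[1] - peep) / e_mod / tau # flow as inspiration opens
  flow <- c(f_init, unlist(seg_flow, use.names = FALSE))
  pao <- c(plan$breaths$pip[1], unlist(seg_pao, use.names = FALSE))
  breath <- c(1L, unlist(breath_idx, use.names = FALSE))
  n <- length(flow)
  time <- (seq_len(n) - 1) * dt
  volume <- if (degenerate) {
    c(v0, unlist(seg_vol, use.names = FALSE))
  } else {
    v0 + cumtrapz(flow, dt)
  }
  # Per-breath samples are contiguous; avoid scanning the full trace per breath.
  ends <- cumsum(tabulate(breath, nbins = nb))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (b in seq_len(nb)) {
    idx <- starts[b]:ends[b]
    vt_ml[b] <- (max(volume[idx]) - volume[ends[b]]) * 1000
  }
  structure(
    list(time = time, pao = pao, flow = flow, volume = volume,
         vt_ml = vt_ml, breath = breath, dt = dt),
    class = "simulated_breathing"
  )
}

#' @export
print.simulated_breathing <- function(x, ...) {
  cat(sprintf(
    "<simulated_breathing> %d breaths, %.3g s @ dt = %g s, mean VT %.3g mL\n",
    max(x$breath), max(x$time) + x$dt, x$dt, mean(x$vt_ml)))
  invisible(x)
}

#' Driving pressure
#'
#' The difference between peak inspiratory pressure and PEEP.
#'
#' @param pip Peak inspiratory pressure (cmH2O), >= `peep`.
#' @param peep Positive end-expiratory pressure (cmH2O).
#' @return `pip - peep` (cmH2O); vectorized.
#' @examples
#' driving_pressure(10.4, 5) # 5.4
#' @export
driving_pressure <- function(pip, peep) {
  check_number(pip, "pip")
  check_number(peep, "peep")
  if (any(pip < peep)) abort_input("`pip` must be >= `peep`")
  pip - peep
}
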