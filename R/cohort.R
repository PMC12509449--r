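# Synthetic crossover cohort generator: 2 ventilation modes x 3 protocol
# stages per subject, with subject random intercepts, stage-dependent cell
# means, and blood-gas panels from which the shunt fraction is derived
# through the gas-exchange equations (never drawn independently).

STAGES <- c("START", "CP", "post-CP")
MODES <- c("PCV", "VV")

COHORT_OUTCOMES <- c("pao2_fio2", "paco2", "qs_qt", "raw", "g", "h",
                     "map", "hr", "co", "pdriving", "vt", "rr")

# Default per-cell moments. Printed stage summaries give the oxygenation
# index and Paco2 at CP and post-CP, and all hemodynamic/ventilation cells;
# START gas-exchange cells are back-computed from the printed relative
# changes (CP vs START: Pao2/FiO2 -8% PCV / -13% VV, Paco2 +28% / +49%).
# Absolute mechanics and shunt levels appear only in figures, so their
# defaults are plausible rabbit values carrying the printed relative changes
# (shunt +32% PCV / +61% VV at CP) and are configurable assumptions.
default_cells <- function() {
  cell <- function(outcome, mode, means, sds) {
    data.frame(outcome = outcome, mode = mode, stage = STAGES,
               mean = means, sd = sds)
  }
  rbind(
    cell("pao2_fio2", "PCV", c(405.5 / 0.92, 405.5, 405.5 / 0.92 * 0.96),
         c(35, 34.1, 35)),
    cell("pao2_fio2", "VV", c(370.5 / 0.87, 370.5, 370.5 / 0.87 * 1.03),
         c(35, 44.9, 35)),
    cell("paco2", "PCV", c(48.4 / 1.28, 48.4, 44.6), c(3.5, 5.1, 4.3)),
    cell("paco2", "VV", c(52.8 / 1.49, 52.8, 41.0), c(3.5, 6.0, 2.3)),
    cell("qs_qt", "PCV", c(0.080, 0.080 * 1.32, 0.080 * 1.26),
         c(0.020, 0.028, 0.025)),
    cell("qs_qt", "VV", c(0.080, 0.080 * 1.61, 0.080 * 1.05),
         c(0.020, 0.034, 0.021)),
    cell("raw", "PCV", c(20, 26, 20), c(3, 4, 3)),
    cell("raw", "VV", c(20, 26, 20), c(3, 4, 3)),
    cell("g", "PCV", c(40, 66, 40), c(6, 10, 6)),
    cell("g", "VV", c(40, 66, 40), c(6, 10, 6)),
    cell("h", "PCV", c(200, 330, 200), c(25, 45, 25)),
    cell("h", "VV", c(200, 330, 200), c(25, 45, 25)),
    cell("map", "PCV", c(67, 76, 75), c(16, 14, 13)),
    cell("map", "VV", c(68, 78, 73), c(15, 14, 15)),
    cell("hr", "PCV", c(219, 215, 225), c(10, 20, 11)),
    cell("hr", "VV", c(219, 215, 225), c(21, 31, 20)),
    cell("co", "PCV", c(0.51, 0.59, 0.58), c(0.18, 0.18, 0.16)),
    cell("co", "VV", c(0.47, 0.54, 0.53), c(0.12, 0.14, 0.18)),
    cell("pdriving", "PCV", c(5.4, 8.9, 5.2), c(0.8, 1.1, 0.8)),
    cell("pdriving", "VV", c(5.7, 8.5, 5.3), c(0.7, 1.5, 0.8)),
    cell("vt", "PCV", c(24.2, 24.1, 23.8), c(1.7, 1.6, 1.7)),
    cell("vt", "VV", c(24.1, 24.1, 24.2), c(1.6, 1.5, 1.7)),
    cell("rr", "PCV", c(22.2, 22.4, 22.4), c(1.6, 1.4, 1.4)),
    cell("rr", "VV", c(22.2, 22.1, 22.2), c(1.6, 1.6, 1.6))
  )
}

#' Stage-effect configuration for the synthetic cohort
#'
#' Per-(mode, stage) cell means and SDs for every outcome, plus the
#' variance decomposition and coupling parameters of the generative model:
#' each outcome is `cell mean + subject intercept + residual`, with the
#' subject intercept SD a fixed fraction of the outcome's average cell SD
#' and the residual SD chosen so the marginal cell SD matches the
#' configured value. At the capnoperitoneum stage the standardized
#' residuals of tissue elastance and of the oxygenation index are drawn
#' with correlation `coupling`, reproducing the observed association
#' between mechanical deterioration and oxygenation loss.
#'
#' @param cells Data.frame with columns `outcome`, `mode`, `stage`, `mean`,
#'   `sd`; defaults to the printed stage summaries (see Details in the
#'   package vignette).
#' @param between_subject_frac Subject-intercept SD as a fraction of the
#'   outcome's mean cell SD (default 0.5).
#' @param coupling Correlation between tissue-elastance and oxygenation
#'   residuals at the CP stage (default -0.6; negative means subjects whose
#'   elastance rises most lose the most oxygenation).
#' @param trunc_z Symmetric truncation of all residual draws, in SD units
#'   (default 2.5).
#' @param constants Ambient constants: `fio2`, `peep`, `p_atmos`, `p_h2o`,
#'   `rq`.
#' @param panel Moments for auxiliary blood-panel variables: hemoglobin,
#'   arterial saturation, venous PO2, airway inertance, body mass.
#' @return An object of class `stage_effect_config`.
#' @export
stage_effect_config <- function(cells = default_cells(),
                                between_subject_frac = 0.5,
                                coupling = -0.6,
                                trunc_z = 2.5,
                                constants = list(fio2 = 0.4, peep = 5,
                                                 p_atmos = 760, p_h2o = 47,
                                                 rq = 0.8),
                                panel = list(hb_mean = 12, hb_sd = 1,
                                             sao2_mean = 0.98, sao2_sd = 0.005,
                                             pvo2_mean = 45, pvo2_sd = 5,
                                             iaw_mean = 0.15, iaw_sd = 0.03,
                                             mass_mean = 3.9, mass_sd = 0.2)) {
  need <- c("outcome", "mode", "stage", "mean", "sd")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    abort_config("`cells` must have columns outcome, mode, stage, mean, sd")
  }
  check_number(cells$mean, "cells$mean")
  check_number(cells$sd, "cells$sd", lower = 0)
  check_number(between_subject_frac, "between_subject_frac", lower = 0,
               upper = 1)
  check_number(coupling, "coupling", lower = -1, upper = 1)
  check_number(trunc_z, "trunc_z", lower = 0.5)
  structure(
    list(cells = cells, between_subject_frac = between_subject_frac,
         coupling = coupling, trunc_z = trunc_z, constants = constants,
         panel = panel),
    class = "stage_effect_config"
  )
}

#' @export
print.stage_effect_config <- function(x, ...) {
  cat(sprintf(
    "<stage_effect_config> %d outcome cells, between-subject frac %.2g, coupling %.2g\n",
    nrow(x$cells), x$between_subject_frac, x$coupling))
  invisible(x)
}

cell_lookup <- function(cells, outcome) {
  sub <- cells[cells$outcome == outcome, ]
  if (nrow(sub) != length(MODES) * length(STAGES)) {
    abort_config(sprintf("outcome '%s' must have one cell per (mode, stage)",
                         outcome))
  }
  sub
}

#' Generate a synthetic crossover cohort
#'
#' Draws `n_subjects` animals through the full 2-mode x 3-stage crossover.
#' Every outcome is cell mean + subject intercept + truncated-Gaussian
#' residual. Internal-consistency guarantees: the shunt fraction is
#' computed through [oxygen_contents] and [shunt_fraction] from the
#' generated blood-gas panel (the venous saturation is solved so the panel
#' realizes the drawn shunt target, then the recorded `qs_qt` is recomputed
#' from the panel); hysteresivity is `g/h` exactly; `pdriving` is
#' `pip - peep` exactly; `pao2` is `pao2_fio2 * fio2` exactly. Arms
#' (PCV-first / VV-first) are assigned by a seeded balanced permutation.
#'
#' @param config A [stage_effect_config].
#' @param n_subjects Number of subjects (>= 2), default 11.
#' @param seed Integer seed.
#' @return A data.frame of class `capno_cohort`, one row per
#'   subject-mode-stage record.
#' @export
generate_cohort <- function(config = stage_effect_config(),
                            n_subjects = 11, seed = 1L) {
  stopifnot(inherits(config, "stage_effect_config"))
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2)
  heavy <- config$cells$sd > config$cells$mean / 2
  if (any(heavy)) {
    warning(sprintf(
      "%d cell(s) have SD > mean/2; physiologic truncation may bias their moments",
      sum(heavy)), call. = FALSE)
  }
  with_seed(seed, generate_cohort_impl(config, n_subjects))
}

generate_cohort_impl <- function(config, n_subjects) {
  cst <- config$constants
  pn <- config$panel
  zt <- config$trunc_z
  n_cells <- length(MODES) * length(STAGES)

  grid <- expand.grid(stage = STAGES, mode = MODES,
                      subject = seq_len(n_subjects),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject", "mode", "stage")]
  nr <- nrow(grid)

  # Arms: balanced seeded permutation (6/5 split at n = 11).
  first_mode <- rep(MODES, length.out = n_subjects)[sample.int(n_subjects)]
  arm <- ifelse(first_mode == "PCV", "PCV-first", "VV-first")
  grid$arm <- arm[grid$subject]

  mass <- rtnorm(n_subjects, pn$mass_mean, pn$mass_sd, zt)
  grid$body_mass <- mass[grid$subject]

  # Per-outcome variance split: shared subject intercept + cell residual.
  draw_outcome <- function(outcome, resid_z = NULL) {
    cells <- cell_lookup(config$cells, outcome)
    sd_b <- min(config$between_subject_frac * mean(cells$sd),
                0.9 * min(cells$sd))
    b <- rtnorm(n_subjects, 0, sd_b, zt)
    key <- match(paste(grid$mode, grid$stage),
                 paste(cells$mode, cells$stage))
    sd_e <- sqrt(pmax(cells$sd[key]^2 - sd_b^2, 0))
    z <- if (is.null(resid_z)) rtnorm(nr, 0, 1, zt) else resid_z
    cells$mean[key] + b[grid$subject] + sd_e * z
  }

  # Correlated CP residuals: elastance up <-> oxygenation down.
  z_h <- rtnorm(nr, 0, 1, zt)
  z_ind <- rtnorm(nr, 0, 1, zt)
  rho <- config$coupling
  z_pf <- z_ind
  at_cp <- grid$stage == "CP"
  z_pf[at_cp] <- pmin(pmax(
    rho * z_h[at_cp] + sqrt(1 - rho^2) * z_ind[at_cp], -zt), zt)

  vals <- list()
  for (oc in COHORT_OUTCOMES) {
    vals[[oc]] <- switch(oc,
      h = draw_outcome("h", resid_z = z_h),
      pao2_fio2 = draw_outcome("pao2_fio2", resid_z = z_pf),
      draw_outcome(oc)
    )
  }
  # Positivity floors (physiologic truncation).
  for (oc in COHORT_OUTCOMES) vals[[oc]] <- pmax(vals[[oc]], 1e-6)

  out <- cbind(grid, as.data.frame(vals))

  # Derived quantities and the blood-gas panel.
  out$eta <- out$g / out$h
  out$alpha <- (2 / pi) * atan(out$h / out$g)
  out$iaw <- pmax(rtnorm(nr, pn$iaw_mean, pn$iaw_sd, zt), 1e-4)
  out$pip <- out$pdriving + cst$peep
  out$peep <- cst$peep
  out$pdriving <- out$pip - out$peep # re-derive: identity holds bit-exactly
  out$fio2 <- cst$fio2
  out$pao2 <- out$pao2_fio2 * cst$fio2
  out$hb_art <- rtnorm(nr, pn$hb_mean, pn$hb_sd, zt)
  out$hb_ven <- out$hb_art
  out$sao2 <- pmin(rtnorm(nr, pn$sao2_mean, pn$sao2_sd, zt), 1)
  out$pvo2 <- pmax(rtnorm(nr, pn$pvo2_mean, pn$pvo2_sd, zt), 10)
  out$p_atmos <- cst$p_atmos
  out$p_h2o <- cst$p_h2o
  out$rq <- cst$rq

  # Solve venous saturation so the panel realizes the drawn shunt target,
  # then recompute the recorded shunt from the panel (exact consistency).
  pao2_alv <- cst$fio2 * (cst$p_atmos - cst$p_h2o) - out$paco2 / cst$rq
  if (any(pao2_alv <= 0)) {
    abort_config("configured Paco2/FiO2 cells imply non-positive alveolar PO2")
  }
  cc <- HUFNER * out$hb_art + pao2_alv * O2_SOLUBILITY
  ca <- HUFNER * out$hb_art * out$sao2 + out$pao2 * O2_SOLUBILITY
  qs_target <- pmin(pmax(out$qs_qt, 0.01), 0.9)
  cv <- cc - (cc - ca) / qs_target
  svo2 <- (cv - out$pvo2 * O2_SOLUBILITY) / (HUFNER * out$hb_ven)
  out$svo2 <- pmin(pmax(svo2, 0.10), 0.98 * out$sao2)
  panel <- blood_gas_panel(
    pao2 = out$pao2, paco2 = out$paco2, sao2 = out$sao2,
    hb_art = out$hb_art, pvo2 = out$pvo2, svo2 = out$svo2,
    hb_ven = out$hb_ven, fio2 = out$fio2, p_atmos = out$p_atmos,
    p_h2o = out$p_h2o, rq = out$rq)
  out$qs_qt <- shunt_fraction(oxygen_contents(panel))

  out$stage <- factor(out$stage, levels = STAGES)
  out$mode <- factor(out$mode, levels = MODES)
  class(out) <- c("capno_cohort", "data.frame")
  out
}

#' Synthesize raw oscillometry recordings for one cohort record
#'
#' Produces `n_reps` pressure/flow pairs whose underlying truth is the
#' record's mechanical state seen through the tracheal tube: the forcing
#' pressure drives a flow computed component-by-component through the total
#' impedance `Z_cpm + Z_tube`, and independent Gaussian noise proportional
#' to each channel's RMS is added. Running the measurement chain
#' ([estimate_impedance], [subtract_tube_impedance], [ensemble_average],
#' [fit_constant_phase]) on the output recovers the record's mechanics.
#'
#' @param record One-row data.frame with columns `raw`, `iaw`, `g`, `h`
#'   (e.g. a row of a `capno_cohort`), or a [mechanical_state].
#' @param spec A [forcing_spec].
#' @param noise_sd Proportional noise SD (fraction of channel RMS), >= 0.
#' @param n_reps Number of recordings (>= 1).
#' @param seed Integer seed.
#' @param tube Tube [impedance_spectrum] on the spec grid; default
#'   [tube_impedance] with R = 2, I = 0.01.
#' @param phase_seed Seed for the forcing phases (kept separate from
#'   `seed` so the same excitation can be reused across records, as a
#'   single physical ventilator would).
#' @return List of `n_reps` lists with elements `pressure` and `flow`.
#' @export
generate_oscillometry_raw <- function(record, spec = forcing_spec(),
                                      noise_sd = 0.03, n_reps = 3,
                                      seed = 1L,
                                      tube = tube_impedance(spec$frequencies),
                                      phase_seed = 20210216L) {
  mech <- if (inherits(record, "mechanical_state")) record else {
    mechanical_state(record$raw[1], record$iaw[1], record$g[1], record$h[1])
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  n_reps <- check_count(n_reps, "n_reps", min = 1)
  sig <- make_forcing_signal(spec, seed = phase_seed)
  z_tot <- cpm_impedance(mech, spec$frequencies)$values + tube$values
  # flow component k: (a_k/|Z_k|) sin(2 pi f_k t + phi_k - arg Z_k)
  flow0 <- forcing_wave(sig$time, spec$frequencies,
                        spec$amplitudes / Mod(z_tot),
                        sig$phases - Arg(z_tot))
  p_rms <- sqrt(mean(sig$pressure^2))
  f_rms <- sqrt(mean(flow0^2))
  with_seed(seed, lapply(seq_len(n_reps), function(r) {
    list(
      pressure = sig$pressure +
        noise_sd * p_rms * stats::rnorm(length(sig$pressure)),
      flow = flow0 + noise_sd * f_rms * stats::rnorm(length(flow0))
    )
  }))
}

#' Fit respiratory mechanics from raw oscillometry recordings
#'
#' Convenience wrapper for the full measurement chain: estimate impedance
#' per recording, subtract the tube, ensemble-average, fit the
#' constant-phase model.
#'
#' @param recordings List of `list(pressure, flow)` pairs.
#' @param spec The [forcing_spec] used to record them.
#' @param tube Tube [impedance_spectrum] to subtract.
#' @param weights Passed to [fit_constant_phase].
#' @return A `cpm_fit`.
#' @export
fit_oscillometry <- function(recordings, spec = forcing_spec(),
                             tube = tube_impedance(spec$frequencies),
                             weights = NULL) {
  spectra <- lapply(recordings, function(rec) {
    subtract_tube_impedance(
      estimate_impedance(rec$pressure, rec$flow, spec), tube)
  })
  fit_constant_phase(ensemble_average(spectra), weights = weights)
}
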