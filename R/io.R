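# Plain-text serialization: CSV for tabular artifacts, JSON for configs.

#' Write / read a breath plan as CSV
#'
#' One row per breath (`pip`, `duration`), with a JSON sidecar
#' (`<path>.json`) holding the generating settings and seed.
#'
#' @param plan A `breath_plan`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_breath_plan <- function(plan, path) {
  stopifnot(inherits(plan, "breath_plan"))
  utils::write.csv(plan$breaths, path, row.names = FALSE)
  sidecar <- c(unclass(plan$settings),
               list(seed = plan$seed, pip_pcv = plan$pip_pcv))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_breath_plan
#' @export
read_breath_plan <- function(path) {
  breaths <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  settings <- ventilator_settings(
    mode = side$mode, target_vt_per_kg = side$target_vt_per_kg,
    body_mass = side$body_mass, rr_target = side$rr_target,
    peep = side$peep, ie_ratio = side$ie_ratio, fio2 = side$fio2,
    vv_cv_pip = side$vv_cv_pip, vv_cv_rr = side$vv_cv_rr,
    averaging_window = side$averaging_window)
  new_breath_plan(breaths$pip, breaths$duration, settings,
                  seed = side$seed, pip_pcv = side$pip_pcv)
}

#' Write / read an impedance spectrum as CSV
#'
#' Columns `frequency_hz`, `z_real`, `z_imag`, `ensemble_count`.
#'
#' @param spectrum An [impedance_spectrum].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  utils::write.csv(data.frame(
    frequency_hz = spectrum$frequencies,
    z_real = Re(spectrum$values),
    z_imag = Im(spectrum$values),
    ensemble_count = spectrum$ensemble_count
  ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frequency_hz", "z_real", "z_imag")
  if (!all(need %in% names(d))) {
    abort_input("spectrum CSV needs columns frequency_hz, z_real, z_imag")
  }
  impedance_spectrum(d$frequency_hz, complex(real = d$z_real,
                                             imaginary = d$z_imag),
                     ensemble_count = d$ensemble_count[1] %||% 1L)
}

#' Write / read a simulated breathing trace as CSV
#'
#' One row per sample: `time`, `pao`, `flow`, `volume`, `breath`.
#'
#' @param sim A `simulated_breathing`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_breathing <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_breathing"))
  utils::write.csv(data.frame(time = sim$time, pao = sim$pao,
                              flow = sim$flow, volume = sim$volume,
                              breath = sim$breath),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize a stage-effect configuration to / from JSON
#'
#' Lossless round trip: numbers are written at full precision.
#'
#' @param config A [stage_effect_config].
#' @param path JSON path.
#' @return `path` invisibly (write); a [stage_effect_config] (read).
#' @export
write_stage_config <- function(config, path) {
  stopifnot(inherits(config, "stage_effect_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns")
  invisible(path)
}

#' @rdname write_stage_config
#' @export
read_stage_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- as.data.frame(raw$cells)
  cells$mean <- as.numeric(cells$mean)
  cells$sd <- as.numeric(cells$sd)
  stage_effect_config(
    cells = cells,
    between_subject_frac = as.numeric(raw$between_subject_frac),
    coupling = as.numeric(raw$coupling),
    trunc_z = as.numeric(raw$trunc_z),
    constants = lapply(raw$constants, as.numeric),
    panel = lapply(raw$panel, as.numeric)
  )
}

#' Write a cohort as tidy CSV
#'
#' @param cohort A `capno_cohort`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("subject", "mode", "stage") %in% names(d))) {
    abort_input("cohort CSV needs subject, mode and stage columns")
  }
  d$stage <- factor(d$stage, levels = STAGES)
  d$mode <- factor(d$mode, levels = MODES)
  class(d) <- c("capno_cohort", "data.frame")
  d
}
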