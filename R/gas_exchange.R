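# Oxygen-content, alveolar-gas and shunt computations.
#
# Units: pressures in mmHg, hemoglobin in g/dL, oxygen contents in mL O2/dL
# blood, saturations as fractions. Coefficients: Hufner constant 1.34 mL/g,
# plasma O2 solubility 0.0031 mL.dL^-1.mmHg^-1, respiratory quotient 0.8.

HUFNER <- 1.34
O2_SOLUBILITY <- 0.0031

#' Blood-gas panel
#'
#' One (or a batch of) arterial/venous blood-gas measurement(s) together
#' with the ambient constants needed for the alveolar-gas and shunt
#' equations. All arguments are vectorized and recycled to a common length.
#'
#' @param pao2 Arterial O2 tension (mmHg).
#' @param paco2 Arterial CO2 tension (mmHg).
#' @param sao2 Arterial O2 saturation, fraction in `[0, 1]`.
#' @param hb_art Arterial hemoglobin (g/dL).
#' @param pvo2 Mixed-venous O2 tension (mmHg).
#' @param svo2 Mixed-venous O2 saturation, fraction in `[0, 1]`.
#' @param hb_ven Venous hemoglobin (g/dL), defaults to `hb_art`.
#' @param fio2 Inspired O2 fraction, in (0, 1].
#' @param p_atmos Barometric pressure (mmHg), default 760.
#' @param p_h2o Water-vapor pressure (mmHg), default 47; must be < `p_atmos`.
#' @param rq Respiratory quotient, default 0.8.
#' @return A data.frame of class `blood_gas_panel`.
#' @export
blood_gas_panel <- function(pao2, paco2, sao2, hb_art, pvo2, svo2,
                            hb_ven = hb_art, fio2 = 0.4, p_atmos = 760,
                            p_h2o = 47, rq = 0.8) {
  check_number(pao2, "pao2", lower = .Machine$double.xmin)
  check_number(paco2, "paco2", lower = .Machine$double.xmin)
  check_number(sao2, "sao2", lower = 0, upper = 1)
  check_number(hb_art, "hb_art", lower = .Machine$double.xmin)
  check_number(pvo2, "pvo2", lower = .Machine$double.xmin)
  check_number(svo2, "svo2", lower = 0, upper = 1)
  check_number(hb_ven, "hb_ven", lower = .Machine$double.xmin)
  check_number(fio2, "fio2", lower = 1e-12, upper = 1)
  check_number(p_atmos, "p_atmos", lower = .Machine$double.xmin)
  check_number(p_h2o, "p_h2o", lower = 0)
  check_number(rq, "rq", lower = .Machine$double.xmin)
  if (any(p_h2o >= p_atmos)) abort_input("`p_h2o` must be below `p_atmos`")
  out <- data.frame(pao2 = pao2, paco2 = paco2, sao2 = sao2,
                    hb_art = hb_art, pvo2 = pvo2, svo2 = svo2,
                    hb_ven = hb_ven, fio2 = fio2, p_atmos = p_atmos,
                    p_h2o = p_h2o, rq = rq)
  class(out) <- c("blood_gas_panel", "data.frame")
  out
}

#' Alveolar oxygen tension
#'
#' Alveolar gas equation `PAO2 = FiO2 (P_atmos - P_H2O) - Paco2 / RQ`.
#'
#' @param panel A [blood_gas_panel].
#' @return Alveolar PO2 (mmHg), vectorized over the panel's rows.
#' @examples
#' p <- blood_gas_panel(pao2 = 150, paco2 = 45, sao2 = 0.98, hb_art = 12,
#'                      pvo2 = 40, svo2 = 0.75)
#' alveolar_po2(p) # 228.95
#' @export
alveolar_po2 <- function(panel) {
  stopifnot(inherits(panel, "blood_gas_panel"))
  pao2_alv <- panel$fio2 * (panel$p_atmos - panel$p_h2o) -
    panel$paco2 / panel$rq
  if (any(pao2_alv <= 0)) {
    abort_domain("alveolar PO2 is non-positive: unphysiologic FiO2/Paco2 combination")
  }
  pao2_alv
}

#' Capillary, arterial and venous oxygen contents
#'
#' `CaO2 = 1.34 Hb_art SaO2 + PaO2 0.0031`,
#' `CvO2 = 1.34 Hb_ven SvO2 + PvO2 0.0031`, and the end-capillary content
#' `CcO2 = 1.34 Hb_art + PAO2 0.0031`, which assumes fully saturated
#' capillary blood equilibrated with alveolar gas.
#'
#' @param panel A [blood_gas_panel].
#' @return A data.frame of class `oxygen_contents` with columns `cc`, `ca`,
#'   `cv` (mL O2/dL) and `pao2_alv` (mmHg).
#' @export
oxygen_contents <- function(panel) {
  stopifnot(inherits(panel, "blood_gas_panel"))
  pao2_alv <- alveolar_po2(panel)
  out <- data.frame(
    cc = HUFNER * panel$hb_art + pao2_alv * O2_SOLUBILITY,
    ca = HUFNER * panel$hb_art * panel$sao2 + panel$pao2 * O2_SOLUBILITY,
    cv = HUFNER * panel$hb_ven * panel$svo2 + panel$pvo2 * O2_SOLUBILITY,
    pao2_alv = pao2_alv
  )
  class(out) <- c("oxygen_contents", "data.frame")
  out
}

#' Intrapulmonary shunt fraction (modified Berggren equation)
#'
#' `Qs/Qt = (CcO2 - CaO2) / (CcO2 - CvO2)`, the fraction of cardiac output
#' bypassing gas exchange.
#'
#' @param contents An [oxygen_contents] object (or data.frame with columns
#'   `cc`, `ca`, `cv`).
#' @return Shunt fraction, vectorized.
#' @export
shunt_fraction <- function(contents) {
  if (!all(c("cc", "ca", "cv") %in% names(contents))) {
    abort_input("`contents` must provide cc, ca and cv")
  }
  if (any(contents$cc <= contents$cv)) {
    abort_domain("degenerate denominator: capillary content must exceed venous content")
  }
  (contents$cc - contents$ca) / (contents$cc - contents$cv)
}

#' Oxygenation index
#'
#' The PaO2/FiO2 ratio.
#'
#' @param pao2 Arterial O2 tension (mmHg).
#' @param fio2 Inspired O2 fraction, > 0.
#' @return `pao2 / fio2` (mmHg), vectorized.
#' @export
oxygenation_index <- function(pao2, fio2) {
  check_number(pao2, "pao2")
  check_number(fio2, "fio2", lower = 1e-12)
  pao2 / fio2
}

#' Batch gas-exchange computation
#'
#' Appends `pao2_alv`, `cco2`, `cao2`, `cvo2`, `qs_qt` and `pao2_fio2`
#' columns to a data.frame of blood-gas panels (one panel per row, columns
#' as in [blood_gas_panel]).
#'
#' @param panels A [blood_gas_panel] or plain data.frame with its columns.
#' @return The input with computed columns appended.
#' @export
compute_gas_exchange <- function(panels) {
  need <- c("pao2", "paco2", "sao2", "hb_art", "pvo2", "svo2")
  if (!all(need %in% names(panels))) {
    abort_input(sprintf("panels must provide columns: %s",
                        paste(need, collapse = ", ")))
  }
  panel <- blood_gas_panel(
    pao2 = panels$pao2, paco2 = panels$paco2, sao2 = panels$sao2,
    hb_art = panels$hb_art, pvo2 = panels$pvo2, svo2 = panels$svo2,
    hb_ven = panels$hb_ven %||% panels$hb_art,
    fio2 = panels$fio2 %||% 0.4,
    p_atmos = panels$p_atmos %||% 760,
    p_h2o = panels$p_h2o %||% 47,
    rq = panels$rq %||% 0.8
  )
  cont <- oxygen_contents(panel)
  panels$pao2_alv <- cont$pao2_alv
  panels$cco2 <- cont$cc
  panels$cao2 <- cont$ca
  panels$cvo2 <- cont$cv
  panels$qs_qt <- shunt_fraction(cont)
  panels$pao2_fio2 <- oxygenation_index(panel$pao2, panel$fio2)
  panels
}
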