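# Shared fixtures, built in code at test time.

fix_spec <- forcing_spec()

fix_truth <- mechanical_state(raw = 25, iaw = 0.1, g = 300, h = 1500)

fix_settings_pcv <- ventilator_settings("PCV")
fix_settings_vv <- ventilator_settings("VV")

# A zero-variance configuration: every outcome equals its cell mean.
fix_config_sd0 <- function() {
  cells <- capnovent:::default_cells()
  cells$sd <- 0
  stage_effect_config(
    cells = cells,
    panel = list(hb_mean = 12, hb_sd = 0, sao2_mean = 0.98, sao2_sd = 0,
                 pvo2_mean = 45, pvo2_sd = 0, iaw_mean = 0.15, iaw_sd = 0,
                 mass_mean = 3.9, mass_sd = 0)
  )
}

# Null configuration for one outcome: all six cells share the START mean.
fix_config_null <- function(outcome = "paco2") {
  cells <- capnovent:::default_cells()
  sel <- cells$outcome == outcome
  start_mean <- cells$mean[sel & cells$stage == "START" & cells$mode == "PCV"]
  cells$mean[sel] <- start_mean
  cells$sd[sel] <- 4
  stage_effect_config(cells = cells)
}
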