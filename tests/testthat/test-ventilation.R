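test_that("PCV plans are constant and match the rate setting", {
  set20 <- ventilator_settings("PCV", rr_target = 20)
  plan <- make_pcv_plan(set20, 30, pip = 11)
  expect_equal(nrow(plan$breaths), 30)
  expect_equal(plan$breaths$duration, rep(3.0, 30))
  expect_equal(length(unique(plan$breaths$pip)), 1L)
  expect_error(make_pcv_plan(set20, 0), class = "capnovent_input_error")
})

test_that("zero-variability VV degenerates to PCV", {
  set_vv0 <- ventilator_settings("VV", vv_cv_pip = 0, vv_cv_rr = 0)
  pcv <- make_pcv_plan(fix_settings_pcv, 60, pip = 10.5)
  vv <- make_vv_plan(set_vv0, 60, seed = 7, pip = 10.5)
  expect_identical(pcv$breaths$pip, vv$breaths$pip)
  expect_identical(pcv$breaths$duration, vv$breaths$duration)
})

test_that("VV plans are reproducible and seed-sensitive", {
  p1 <- make_vv_plan(fix_settings_vv, 90, seed = 3, pip = 10.5)
  p2 <- make_vv_plan(fix_settings_vv, 90, seed = 3, pip = 10.5)
  p3 <- make_vv_plan(fix_settings_vv, 90, seed = 4, pip = 10.5)
  expect_identical(p1$breaths, p2$breaths)
  expect_false(identical(p1$breaths$pip, p3$breaths$pip))
})

test_that("every disjoint 30-breath VV window reproduces the PCV targets", {
  mech <- baseline_mechanics()
  plan <- make_vv_plan(fix_settings_vv, 300, seed = 1, mech = mech)
  pcv_vt <- (plan$pip_pcv - fix_settings_vv$peep) / mech$h * 1000
  win <- rep(1:10, each = 30)
  rate_means <- as.vector(tapply(60 / plan$breaths$duration, win, mean))
  expect_equal(rate_means, rep(fix_settings_vv$rr_target, 10),
               tolerance = 1e-12)
  vt_means <- as.vector(tapply(model_vt(plan, mech), win, mean))
  expect_equal(vt_means, rep(pcv_vt, 10), tolerance = 1e-12)
})

test_that("VV empirical CV honors the configured CV within 15%", {
  for (s in 1:3) {
    plan <- make_vv_plan(fix_settings_vv, 300, seed = s, pip = 10.5)
    dp <- plan$breaths$pip - fix_settings_vv$peep
    cv <- sd(dp) / mean(dp)
    expect_lt(abs(cv / fix_settings_vv$vv_cv_pip - 1), 0.15)
  }
})

test_that("excessive CV triggers the truncation-floor config error", {
  set_big <- ventilator_settings("VV", vv_cv_pip = 0.45, vv_cv_rr = 0.2)
  expect_error(make_vv_plan(set_big, 30, seed = 1, pip = 10.5),
               class = "capnovent_config_error")
})

test_that("PIP calibration hits the tidal-volume target and scales with E", {
  mech <- baseline_mechanics()
  pip <- calibrate_pip_for_vt(mech, fix_settings_pcv)
  plan <- make_pcv_plan(fix_settings_pcv, 2, pip = pip)
  sim <- simulate_breaths(plan, mech)
  target <- fix_settings_pcv$target_vt_per_kg * fix_settings_pcv$body_mass
  expect_lt(abs(sim$vt_ml[2] / target - 1), 0.005)

  mech2 <- mechanical_state(mech$raw, mech$iaw, mech$g, 2 * mech$h)
  pip2 <- calibrate_pip_for_vt(mech2, fix_settings_pcv)
  expect_equal((pip2 - 5) / (pip - 5), 2, tolerance = 0.05)

  set0 <- ventilator_settings("PCV", target_vt_per_kg = 0)
  expect_equal(calibrate_pip_for_vt(mech, set0), set0$peep)
})

test_that("with negligible resistance the driving pressure is VT * E", {
  # static limit: R -> 0 so the compartment equilibrates within any Ti
  mech <- mechanical_state(raw = 1e-8, iaw = 0, g = 1e-8, h = 150)
  pip <- calibrate_pip_for_vt(mech, fix_settings_pcv)
  vt_l <- 7 * fix_settings_pcv$body_mass / 1000
  expect_equal(pip - 5, vt_l * 150, tolerance = 1e-3)
  # and the delivered volume matches the closed form VT = dP / E
  plan <- make_pcv_plan(fix_settings_pcv, 1, pip = 10)
  sim <- simulate_breaths(plan, mech)
  expect_equal(sim$vt_ml[1], (10 - 5) / 150 * 1000, tolerance = 1e-6)
})

test_that("a calibrated plan on an E = 150 lung delivers 7 mL/kg within 2%", {
  mech <- mechanical_state(raw = 10, iaw = 0.1, g = 1e-6, h = 150)
  pip <- calibrate_pip_for_vt(mech, fix_settings_pcv)
  sim <- simulate_breaths(make_pcv_plan(fix_settings_pcv, 3, pip = pip), mech)
  expect_lt(abs(mean(sim$vt_ml) / (7 * fix_settings_pcv$body_mass) - 1), 0.02)
})

test_that("inspiration follows the first-order exponential response", {
  # g ~ 0 makes the effective resistance Raw alone: tau = Raw / H = 0.3 s;
  # with duration 2.7 s and I:E 1:2 the inspiratory time is exactly 3 tau.
  mech <- mechanical_state(raw = 30, iaw = 0, g = 1e-9, h = 100)
  set <- suppressWarnings(
    ventilator_settings("PCV", rr_target = 60 / 2.7))
  plan <- make_pcv_plan(set, 1, pip = 12)
  sim <- simulate_breaths(plan, mech)
  plateau <- (12 - 5) / 100
  expect_equal(max(sim$volume), plateau * (1 - exp(-3)), tolerance = 1e-3)
})

test_that("flow integrates to volume by trapezoid and volume stays >= 0", {
  mech <- baseline_mechanics()
  plan <- make_vv_plan(fix_settings_vv, 10, seed = 2, mech = mech)
  sim <- simulate_breaths(plan, mech)
  expect_gte(min(sim$volume), 0)
  for (b in c(1, 5, 10)) {
    idx <- which(sim$breath == b)
    tr <- oracle_trapz(sim$flow[idx[1]:idx[length(idx)]], sim$dt)
    dv <- sim$volume[idx[length(idx)]] - sim$volume[idx[1]]
    expect_lt(abs(tr - dv), 1e-6)
  }
  expect_true(all(sim$vt_ml > 0))
})

test_that("delivered VT is strictly monotone in PIP and converges in dt", {
  mech <- baseline_mechanics()
  vts <- vapply(c(8, 10, 12, 14), function(p) {
    simulate_breaths(make_pcv_plan(fix_settings_pcv, 1, pip = p), mech)$vt_ml
  }, numeric(1))
  expect_true(all(diff(vts) > 0))

  plan <- make_pcv_plan(fix_settings_pcv, 2, pip = 10.5)
  vt_a <- simulate_breaths(plan, mech, dt = 1e-3)$vt_ml[2]
  vt_b <- simulate_breaths(plan, mech, dt = 5e-4)$vt_ml[2]
  expect_lt(abs(vt_a / vt_b - 1), 1e-3)
})

test_that("simulator and settings validate their inputs", {
  plan <- make_pcv_plan(fix_settings_pcv, 1, pip = 10)
  expect_error(simulate_breaths(plan, baseline_mechanics(), dt = 0),
               class = "capnovent_input_error")
  expect_error(simulate_breaths(plan, baseline_mechanics(), dt = 2e-3),
               class = "capnovent_input_error")
  expect_error(ventilator_settings("PCV", vv_cv_pip = 0.1),
               class = "capnovent_input_error")
  expect_error(ventilator_settings("VV", fio2 = 0),
               class = "capnovent_input_error")
  expect_warning(ventilator_settings("PCV", rr_target = 30),
                 "protocol window")
})

test_that("driving pressure is PIP minus PEEP", {
  expect_equal(driving_pressure(10.4, 5), 5.4)
  expect_equal(driving_pressure(5, 5), 0)
  expect_equal(driving_pressure(13.9, 5), 8.9)
  expect_error(driving_pressure(4, 5), class = "capnovent_input_error")
})

test_that("breath plans round-trip through CSV with their sidecar", {
  dir <- withr::local_tempdir()
  plan <- make_vv_plan(fix_settings_vv, 30, seed = 9, pip = 10.5)
  path <- file.path(dir, "plan.csv")
  write_breath_plan(plan, path)
  back <- read_breath_plan(path)
  expect_equal(back$breaths$pip, plan$breaths$pip)
  expect_equal(back$breaths$duration, plan$breaths$duration)
  expect_equal(back$settings$mode, "VV")
  expect_equal(back$seed, 9)
})
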