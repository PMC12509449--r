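test_that("rm_anova F statistics match base-R aov on seeded cohorts", {
  for (s in 1:3) {
    co <- generate_cohort(n_subjects = 8, seed = 200 + s)
    for (oc in c("paco2", "h")) {
      res <- rm_anova(co, oc)
      ref <- oracle_aov_f(co, oc)
      expect_equal(res$table$F, unname(ref), tolerance = 1e-8)
    }
  }
})

test_that("sphericity statistics match the mlm reference implementation", {
  co <- generate_cohort(n_subjects = 11, seed = 77)
  res <- rm_anova(co, "paco2")
  y <- oracle_wide(co, "paco2")
  fit <- stats::lm(y ~ 1)
  idata <- expand.grid(stage = factor(1:3), mode = factor(1:2))[, 2:1]
  m_stage <- stats::mauchly.test(fit, idata = idata, X = ~mode,
                                 M = ~mode + stage)
  expect_equal(res$table$mauchly_w[2], unname(m_stage$statistic),
               tolerance = 1e-10)
  expect_equal(res$table$mauchly_p[2], m_stage$p.value, tolerance = 1e-10)
  gg_ref <- stats:::sphericity(stats::SSD(fit),
                               T = stats:::Thin.row(
                                 stats:::Proj(model.matrix(~mode + stage, idata)) -
                                 stats:::Proj(model.matrix(~mode, idata))))
  expect_equal(res$table$eps_gg[2], gg_ref$GG.eps, tolerance = 1e-10)
  expect_equal(res$table$eps_hf[2], min(1, gg_ref$HF.eps), tolerance = 1e-10)
  # interaction-term sphericity against the same reference
  int_ref <- stats:::sphericity(stats::SSD(fit),
                                T = stats:::Thin.row(
                                  stats:::Proj(model.matrix(~mode * stage, idata)) -
                                  stats:::Proj(model.matrix(~mode + stage, idata))))
  expect_equal(res$table$eps_gg[3], int_ref$GG.eps, tolerance = 1e-10)
})

test_that("two-level factors are exactly spherical", {
  co <- generate_cohort(n_subjects = 6, seed = 9)
  res <- rm_anova(co, "map")
  expect_identical(res$table$mauchly_w[1], 1)
  expect_identical(res$table$eps_gg[1], 1)
  expect_identical(res$table$eps_hf[1], 1)
})

test_that("a constant outcome yields all-zero F statistics", {
  co <- generate_cohort(n_subjects = 5, seed = 10)
  co$flat <- 7.5
  res <- rm_anova(co, "flat")
  expect_equal(res$table$F, c(0, 0, 0))
  expect_equal(res$table$p, c(1, 1, 1))
})

test_that("missing cells are an error, never imputed", {
  co <- generate_cohort(n_subjects = 5, seed = 11)
  expect_error(rm_anova(co[-1, ], "paco2"), class = "capnovent_input_error")
})

test_that("a pure stage effect is detected and no mode effect invented", {
  # direct small-array simulation: stage shifts means, mode does nothing
  hits_stage <- hits_mode <- logical(100)
  for (s in 1:100) {
    set.seed(3000 + s)
    n <- 11
    y <- expand.grid(subject = 1:n, mode = c("PCV", "VV"),
                     stage = c("START", "CP", "post-CP"),
                     stringsAsFactors = FALSE)
    stage_eff <- c(START = 0, CP = 3, `post-CP` = 1)
    b <- rnorm(n, 0, 1.5)
    y$paco2 <- 40 + stage_eff[y$stage] + b[y$subject] + rnorm(nrow(y), 0, 2)
    res <- rm_anova(y, "paco2")
    hits_stage[s] <- res$table$p[2] < 0.05
    hits_mode[s] <- res$table$p[1] > 0.05
  }
  expect_gte(mean(hits_stage), 0.95)
  expect_gte(mean(hits_mode), 0.9)
})

test_that("Holm-Sidak matches the hand-evaluated step-down formula", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(holm_sidak(0.2), 0.2)
  expect_equal(holm_sidak(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_sidak(c(0.5, 1.2)), class = "capnovent_input_error")
})

test_that("Holm-Sidak adjusted p-values are valid for random inputs", {
  set.seed(123)
  for (k in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("relative changes handle degenerate and erroneous cases", {
  co <- generate_cohort(fix_config_sd0(), n_subjects = 4, seed = 1)
  rel <- relative_changes(co, "vt")
  # zero variance: CI width collapses to zero
  expect_equal(rel$ci_hi - rel$ci_lo, rep(0, 4), tolerance = 1e-9)
  one <- generate_cohort(n_subjects = 2, seed = 1)
  expect_error(relative_changes(one[one$subject == 1, ], "paco2"),
               class = "capnovent_input_error")
  co2 <- generate_cohort(n_subjects = 4, seed = 2)
  co2$paco2[co2$stage == "START"][1] <- 0
  expect_error(relative_changes(co2, "paco2"),
               class = "capnovent_domain_error")
})

test_that("relative changes recover a configured stage effect", {
  # PCV Paco2 configured at +28% CP vs START; average across seeds
  means <- sapply(1:20, function(s) {
    co <- generate_cohort(n_subjects = 11, seed = 500 + s)
    rel <- relative_changes(co, "paco2")
    rel$mean_pct[rel$mode == "PCV" & rel$contrast == "CP vs START"]
  })
  expect_equal(mean(means), 28, tolerance = 0.1)
})

test_that("pearson_r matches its definition and cor.test", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, x)$p, 0)
  expect_equal(pearson_r(x, -2 * x + 3)$r, -1)
  set.seed(99)
  xx <- rnorm(40); yy <- 0.5 * xx + rnorm(40)
  res <- pearson_r(xx, yy)
  ref <- stats::cor.test(xx, yy)
  expect_equal(res$r, unname(ref$estimate))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "capnovent_input_error")
  expect_error(pearson_r(1:2, 1:2), class = "capnovent_input_error")
})

test_that("a seeded bivariate-normal sample recovers rho = 0.8", {
  set.seed(1234)
  n <- 500
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  expect_equal(pearson_r(x, y)$r, 0.8, tolerance = 0.05 / 0.8)
})

test_that("pairwise cell contrasts form one Holm-Sidak family", {
  co <- generate_cohort(n_subjects = 11, seed = 21)
  pw <- pairwise_cells(co, "paco2")
  expect_equal(nrow(pw), 15)
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-12))
  expect_equal(pw$p_adj, holm_sidak(pw$p_raw))
  # the configured CP effect under PCV is a large, detected contrast
  big <- pw[pw$contrast == "PCV:CP - PCV:START", ]
  expect_true(big$significant)
})
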