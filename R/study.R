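# Full in-silico crossover study: cohort generation, per-record
# oscillometry refitting, gas-exchange computation, and the statistical
# analysis, with deterministic per-stage seed streams.

ANALYSIS_OUTCOMES <- c("pao2_fio2", "paco2", "qs_qt", "raw", "g", "h",
                       "eta", "map", "hr", "co", "pdriving", "vt", "rr")

#' Study configuration
#'
#' Bundles everything a full in-silico study needs: ventilator settings for
#' both modes, the oscillometry forcing spec, the cohort stage-effect
#' configuration, cohort size, the master seed (from which each stochastic
#' stage derives its own independent stream with [derive_seed]), and the
#' oscillometry acquisition parameters.
#'
#' @param n_subjects Number of subjects, default 11.
#' @param seed Master seed.
#' @param settings_pcv,settings_vv [ventilator_settings] for the two modes.
#' @param forcing A [forcing_spec].
#' @param stage_config A [stage_effect_config].
#' @param osc_n_reps Oscillometry recordings per record (default 3).
#' @param osc_noise_sd Proportional noise SD on raw signals (default 0.03).
#' @param tube_r,tube_i Tube resistance / inertance used both to corrupt
#'   and to correct the synthetic recordings.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 11, seed = 1L,
                         settings_pcv = ventilator_settings("PCV"),
                         settings_vv = ventilator_settings("VV"),
                         forcing = forcing_spec(),
                         stage_config = stage_effect_config(),
                         osc_n_reps = 3, osc_noise_sd = 0.03,
                         tube_r = 2, tube_i = 0.01) {
  structure(
    list(n_subjects = check_count(n_subjects, "n_subjects", min = 2),
         seed = as.integer(check_number(seed, "seed")),
         settings_pcv = settings_pcv, settings_vv = settings_vv,
         forcing = forcing, stage_config = stage_config,
         osc_n_reps = check_count(osc_n_reps, "osc_n_reps"),
         osc_noise_sd = check_number(osc_noise_sd, "osc_noise_sd", lower = 0),
         tube_r = check_number(tube_r, "tube_r", lower = 0),
         tube_i = check_number(tube_i, "tube_i", lower = 0)),
    class = "study_config"
  )
}

#' Run the full in-silico crossover study
#'
#' Generates the cohort, refits each record's respiratory mechanics from
#' synthesized raw oscillometry (estimate, tube-subtract, ensemble-average,
#' constant-phase fit), recomputes gas exchange from the blood-gas panels,
#' and runs the statistical analysis (repeated-measures ANOVA, pairwise
#' Holm-Sidak contrasts, relative changes, and the elastance-oxygenation
#' correlation). Deterministic: identical configs give identical bundles.
#'
#' @param config A [study_config].
#' @param outdir Optional directory; when given, writes `cohort.csv`,
#'   `fits.json`, `results.json` and `report.md` via [write_study].
#' @return A list of class `capno_study` with elements `cohort`, `fits`,
#'   `anova`, `pairwise`, `relative`, `correlation`, `config`.
#' @export
run_study <- function(config = study_config(), outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (config$n_subjects < 3) {
    warning("n_subjects < 3: analysis is under-powered; interpret with care",
            call. = FALSE)
  }
  cohort <- generate_cohort(config$stage_config, config$n_subjects,
                            seed = derive_seed(config$seed, 1))
  tube <- tube_impedance(config$forcing$frequencies,
                         config$tube_r, config$tube_i)

  # Oscillometry refit per record; the analysis uses the fitted mechanics.
  fits <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- tryCatch({
      raws <- generate_oscillometry_raw(
        cohort[i, ], spec = config$forcing, noise_sd = config$osc_noise_sd,
        n_reps = config$osc_n_reps, seed = derive_seed(config$seed, 1000 + i),
        tube = tube, phase_seed = derive_seed(config$seed, 2))
      fit_oscillometry(raws, spec = config$forcing, tube = tube)
    }, error = function(e) {
      abort_numerical(sprintf(
        "oscillometry stage failed for record %d (subject %s, %s, %s): %s",
        i, cohort$subject[i], cohort$mode[i], cohort$stage[i],
        conditionMessage(e)))
    })
    fits[[i]] <- rec
  }
  cohort$raw_fit <- vapply(fits, function(f) f$mech$raw, numeric(1))
  cohort$iaw_fit <- vapply(fits, function(f) f$mech$iaw, numeric(1))
  cohort$g_fit <- vapply(fits, function(f) f$mech$g, numeric(1))
  cohort$h_fit <- vapply(fits, function(f) f$mech$h, numeric(1))
  cohort$eta_fit <- vapply(fits, function(f) f$mech$eta, numeric(1))
  cohort$fit_cost <- vapply(fits, function(f) f$cost, numeric(1))
  cohort$fit_converged <- vapply(fits, function(f) f$converged, logical(1))

  # Gas exchange recomputed from panels (consistency by construction).
  cohort <- compute_gas_exchange(cohort)

  ana <- cohort
  for (oc in c("raw", "g", "h", "eta")) {
    ana[[oc]] <- cohort[[paste0(oc, "_fit")]]
  }
  anova_res <- lapply(ANALYSIS_OUTCOMES, function(oc) {
    tryCatch(rm_anova(ana, oc), error = function(e) {
      abort_input(sprintf("ANOVA failed for outcome '%s': %s", oc,
                          conditionMessage(e)))
    })
  })
  names(anova_res) <- ANALYSIS_OUTCOMES
  pairwise <- do.call(rbind, lapply(ANALYSIS_OUTCOMES, function(oc) {
    pairwise_cells(ana, oc)
  }))
  relative <- do.call(rbind, lapply(ANALYSIS_OUTCOMES, function(oc) {
    relative_changes(ana, oc)
  }))

  # Association between CP-induced changes in elastance and oxygenation.
  correlation <- lapply(MODES, function(md) {
    sub <- ana[ana$mode == md, ]
    dh <- relative_change_vec(sub, "h")
    dp <- relative_change_vec(sub, "pao2_fio2")
    tryCatch(pearson_r(dh, dp),
             error = function(e) list(r = NA_real_, p = NA_real_,
                                      n = length(dh)))
  })
  names(correlation) <- MODES

  bundle <- structure(
    list(cohort = cohort, fits = fits, anova = anova_res,
         pairwise = pairwise, relative = relative,
         correlation = correlation, config = config),
    class = "capno_study"
  )
  if (!is.null(outdir)) write_study(bundle, outdir)
  bundle
}

# Per-subject CP-vs-START percent change for one mode's records.
relative_change_vec <- function(sub, outcome) {
  y <- tapply(sub[[outcome]], list(sub$subject, as.character(sub$stage)),
              mean)
  100 * (y[, "CP"] - y[, "START"]) / y[, "START"]
}

#' @export
print.capno_study <- function(x, ...) {
  cat(sprintf("<capno_study> %d subjects, seed %d\n",
              x$config$n_subjects, x$config$seed))
  cat("Stage-effect ANOVA p-values (uncorrected):\n")
  for (oc in names(x$anova)) {
    tb <- x$anova[[oc]]$table
    cat(sprintf("  %-10s mode p = %.3g, stage p = %.3g, interaction p = %.3g\n",
                oc, tb$p[1], tb$p[2], tb$p[3]))
  }
  invisible(x)
}

#' Write a study bundle to disk
#'
#' Emits plain-text artifacts only: `cohort.csv` (tidy, one record per
#' row), `fits.json` (per-record constant-phase fits), `results.json`
#' (ANOVA, pairwise, relative-change and correlation tables), and
#' `report.md` (human-readable summary). Output is byte-stable for a fixed
#' configuration.
#'
#' @param bundle A `capno_study`.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "capno_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(bundle$cohort),
                   file.path(outdir, "cohort.csv"), row.names = FALSE)
  fits <- lapply(bundle$fits, function(f) {
    list(raw = f$mech$raw, iaw = f$mech$iaw, g = f$mech$g, h = f$mech$h,
         eta = f$mech$eta, alpha = f$mech$alpha, cost = f$cost,
         se = as.list(f$se), converged = f$converged,
         iterations = f$iterations)
  })
  jsonlite::write_json(fits, file.path(outdir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results <- list(
    anova = lapply(bundle$anova, function(a) {
      list(table = a$table, diagnostics = a$diagnostics)
    }),
    pairwise = bundle$pairwise,
    relative = bundle$relative,
    correlation = bundle$correlation
  )
  jsonlite::write_json(results, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(render_report(bundle), file.path(outdir, "report.md"))
  invisible(outdir)
}

render_report <- function(bundle) {
  lines <- c(
    "# In-silico capnoperitoneum crossover study",
    "",
    sprintf("Subjects: %d; master seed: %d.", bundle$config$n_subjects,
            bundle$config$seed),
    "",
    "## Repeated-measures ANOVA",
    "",
    "| outcome | mode p | stage p | interaction p | stage GG p | stage eps(GG) |",
    "|---|---|---|---|---|---|"
  )
  for (oc in names(bundle$anova)) {
    tb <- bundle$anova[[oc]]$table
    lines <- c(lines, sprintf(
      "| %s | %.4g | %.4g | %.4g | %.4g | %.3g |",
      oc, tb$p[1], tb$p[2], tb$p[3], tb$p_gg[2], tb$eps_gg[2]))
  }
  lines <- c(lines, "", "## Relative changes from START (mean [95% CI], %)",
             "", "| outcome | mode | contrast | mean % | 95% CI |",
             "|---|---|---|---|---|")
  rel <- bundle$relative
  for (i in seq_len(nrow(rel))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %.1f | [%.1f, %.1f] |",
      rel$outcome[i], rel$mode[i], rel$contrast[i], rel$mean_pct[i],
      rel$ci_lo[i], rel$ci_hi[i]))
  }
  lines <- c(lines, "", "## Elastance-oxygenation correlation (CP vs START)",
             "")
  for (md in names(bundle$correlation)) {
    co <- bundle$correlation[[md]]
    lines <- c(lines, sprintf("- %s: r = %.3f, p = %.4g (n = %d)", md,
                              co$r, co$p, co$n))
  }
  lines
}
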