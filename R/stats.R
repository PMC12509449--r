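# Crossover statistics: two-way within-subject ANOVA with Mauchly's test
# and Greenhouse-Geisser / Huynh-Feldt corrections, Holm-Sidak step-down
# adjustment, per-subject relative changes with t-based intervals, and
# Pearson correlation. The ANOVA decomposition is computed from first
# principles (cell/marginal means), not delegated; base-R `aov` serves as
# the independent cross-check in the test suite.

cohort_wide <- function(cohort, outcome) {
  need <- c("subject", "mode", "stage", outcome)
  if (!all(need %in% names(cohort))) {
    abort_input(sprintf("cohort must have columns: %s",
                        paste(need, collapse = ", ")))
  }
  subj <- sort(unique(cohort$subject))
  cells <- expand.grid(stage = STAGES, mode = MODES,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  y <- array(NA_real_, c(length(subj), length(MODES), length(STAGES)),
             dimnames = list(subj, MODES, STAGES))
  mi <- match(as.character(cohort$mode), MODES)
  si <- match(as.character(cohort$stage), STAGES)
  ui <- match(cohort$subject, subj)
  if (anyNA(mi) || anyNA(si)) {
    abort_input("mode must be PCV/VV and stage START/CP/post-CP")
  }
  dup <- duplicated(cbind(ui, mi, si))
  if (any(dup)) abort_input("duplicated subject-mode-stage records")
  y[cbind(ui, mi, si)] <- cohort[[outcome]]
  if (anyNA(y)) {
    abort_input(sprintf(
      "incomplete design for '%s': every subject needs all 6 (mode, stage) cells",
      outcome))
  }
  y
}

# Mauchly's W, its chi-square p, and GG/HF epsilons for a set of
# within-subject scores (n x k matrix of orthonormal-contrast projections).
sphericity_stats <- function(scores) {
  n <- nrow(scores)
  k <- ncol(scores)
  if (k < 2) {
    return(list(w = 1, p = NA_real_, gg = 1, hf = 1))
  }
  S <- stats::cov(scores)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  gg <- sum(ev)^2 / (k * sum(ev^2))
  # Huynh-Feldt with n - 1 error degrees of freedom, capped at 1.
  hf <- (n * k * gg - 2) / (k * (n - 1 - k * gg))
  hf <- min(1, max(hf, gg))
  w <- if (any(ev <= 0)) 0 else prod(ev) / (mean(ev))^k
  d <- 1 - (2 * k^2 + k + 2) / (6 * k * (n - 1))
  chisq <- if (w > 0) -(n - 1) * d * log(w) else Inf
  p <- stats::pchisq(chisq, k * (k + 1) / 2 - 1, lower.tail = FALSE)
  list(w = w, p = p, gg = gg, hf = hf)
}

# Orthonormal contrast matrix (Helmert) for m levels: m x (m-1).
orth_contrasts <- function(m) {
  cm <- stats::contr.helmert(m)
  sweep(cm, 2, sqrt(colSums(cm^2)), "/")
}

#' Two-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition for the 2-mode x 3-stage
#' crossover: each factor and the interaction is tested against its own
#' subject-interaction error term. Mauchly's sphericity test and
#' Greenhouse-Geisser / Huynh-Feldt epsilons are computed for the stage
#' factor and the interaction (the 2-level mode factor is spherical by
#' construction, W = 1 and epsilon = 1). Shapiro-Wilk (on cell-centered
#' residuals) and Brown-Forsythe (across the six cells) are reported as
#' diagnostics only; they never alter the test.
#'
#' @param cohort A `capno_cohort` or data.frame with columns `subject`,
#'   `mode`, `stage` and the outcome. The design must be complete and
#'   balanced; missing cells are an error, never imputed.
#' @param outcome Name of the outcome column.
#' @return A list of class `capno_rm_anova`: `table` (one row per effect
#'   with F, df, uncorrected and GG/HF-corrected p, Mauchly W and p, GG and
#'   HF epsilon) and `diagnostics` (Shapiro-Wilk and Brown-Forsythe p).
#' @export
rm_anova <- function(cohort, outcome) {
  y <- cohort_wide(cohort, outcome)
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (n < 2) abort_input("need at least 2 subjects")
  gm <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a - gm, m_b - gm, "+") - gm)^2)
  ss_as <- b * sum((m_sa - outer(m_s - gm, m_a - gm, "+") - gm)^2)
  ss_bs <- a * sum((m_sb - outer(m_s - gm, m_b - gm, "+") - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_s <- a * b * sum((m_s - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  eff <- function(name, ss, df1, ss_err, df2, sph) {
    scale_tot <- max(ss_tot, .Machine$double.eps)
    f <- if (ss <= 1e-12 * scale_tot) 0 else (ss / df1) / (ss_err / df2)
    p <- if (f == 0) 1 else stats::pf(f, df1, df2, lower.tail = FALSE)
    p_gg <- if (f == 0) 1 else
      stats::pf(f, df1 * sph$gg, df2 * sph$gg, lower.tail = FALSE)
    p_hf <- if (f == 0) 1 else
      stats::pf(f, df1 * sph$hf, df2 * sph$hf, lower.tail = FALSE)
    data.frame(effect = name, F = f, df1 = df1, df2 = df2, p = p,
               p_gg = p_gg, p_hf = p_hf, mauchly_w = sph$w,
               mauchly_p = sph$p, eps_gg = sph$gg, eps_hf = sph$hf)
  }

  # Sphericity: stage scores from mode-averaged data; interaction scores
  # from the interaction contrasts of the 6 cells.
  cb <- orth_contrasts(b)
  stage_scores <- m_sb %*% cb
  ca <- orth_contrasts(a)
  y_flat <- matrix(aperm(y, c(1, 3, 2)), nrow = n) # columns: stage within mode
  c_int <- kronecker(ca, cb) # (a*b) x (a-1)(b-1), column order mode-major
  int_scores <- y_flat %*% c_int
  sph_mode <- list(w = 1, p = NA_real_, gg = 1, hf = 1)
  sph_stage <- sphericity_stats(stage_scores)
  sph_int <- sphericity_stats(int_scores)

  tab <- rbind(
    eff("mode", ss_a, a - 1, ss_as, (a - 1) * (n - 1), sph_mode),
    eff("stage", ss_b, b - 1, ss_bs, (b - 1) * (n - 1), sph_stage),
    eff("mode:stage", ss_ab, (a - 1) * (b - 1), ss_abs,
        (a - 1) * (b - 1) * (n - 1), sph_int)
  )

  resid_cell <- as.vector(sweep(y, c(2, 3), m_ab))
  shapiro_p <- tryCatch(
    stats::shapiro.test(resid_cell)$p.value, error = function(e) NA_real_)
  bf_p <- tryCatch(brown_forsythe(y), error = function(e) NA_real_)

  structure(
    list(table = tab, outcome = outcome, n_subjects = n,
         diagnostics = list(shapiro_p = shapiro_p, brown_forsythe_p = bf_p)),
    class = "capno_rm_anova"
  )
}

# Brown-Forsythe equal-variance test across the 6 (mode, stage) cells:
# one-way ANOVA on absolute deviations from cell medians.
brown_forsythe <- function(y) {
  n <- dim(y)[1]
  grp <- rep(seq_len(6), each = n)
  vals <- c(y[, 1, 1], y[, 1, 2], y[, 1, 3], y[, 2, 1], y[, 2, 2], y[, 2, 3])
  med <- stats::ave(vals, grp, FUN = stats::median)
  d <- abs(vals - med)
  fit <- stats::lm(d ~ factor(grp))
  # diagnostic only: degenerate fits (e.g. 2 subjects) may warn harmlessly
  suppressWarnings(stats::anova(fit)[["Pr(>F)"]][1])
}

#' @export
print.capno_rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> outcome '%s', %d subjects\n", x$outcome,
              x$n_subjects))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Holm-Sidak step-down adjustment
#'
#' Orders the p-values ascending, applies the Sidak correction with a
#' shrinking family at each step, `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`,
#' enforces monotonicity, and returns the adjusted values in input order.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_sidak(c(0.01, 0.04)) # 0.0199, 0.04
#' @export
holm_sidak <- function(pvalues) {
  check_number(pvalues, "pvalues", lower = 0, upper = 1)
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- 1 - (1 - pvalues[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Per-subject relative changes from baseline
#'
#' For each ventilation mode and each follow-up stage (CP, post-CP),
#' computes the per-subject percent change from START,
#' `100 (x_stage - x_START) / x_START`, and summarizes it as the mean with
#' a t-based 95% confidence interval across subjects.
#'
#' @param cohort Cohort data.frame (see [rm_anova]).
#' @param outcome Name of the outcome column.
#' @param conf_level Confidence level, default 0.95.
#' @return Data.frame with one row per (mode, contrast): `mean_pct`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
relative_changes <- function(cohort, outcome, conf_level = 0.95) {
  y <- cohort_wide(cohort, outcome)
  n <- dim(y)[1]
  if (n < 2) abort_input("confidence intervals require n >= 2 subjects")
  if (any(y[, , 1] == 0)) {
    abort_domain("relative change undefined: a START value is zero")
  }
  out <- list()
  for (mi in seq_along(MODES)) {
    for (si in 2:3) {
      pct <- 100 * (y[, mi, si] - y[, mi, 1]) / y[, mi, 1]
      mean_pct <- mean(pct)
      se <- stats::sd(pct) / sqrt(n)
      tcrit <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
      out[[length(out) + 1]] <- data.frame(
        outcome = outcome, mode = MODES[mi],
        contrast = paste(STAGES[si], "vs START"),
        mean_pct = mean_pct, ci_lo = mean_pct - tcrit * se,
        ci_hi = mean_pct + tcrit * se, n = n)
    }
  }
  do.call(rbind, out)
}

#' Pearson correlation with t-test p-value
#'
#' Sample Pearson correlation and the two-sided p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, non-constant.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort_input("`x` and `y` must be equal-length numeric vectors")
  }
  n <- length(x)
  if (n < 3) abort_input("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_input("`x` and `y` must have nonzero variance")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' All pairwise cell contrasts with Holm-Sidak adjustment
#'
#' Paired t-tests between every pair of the six (mode, stage) cells for one
#' outcome, treated as a single family and adjusted with [holm_sidak].
#'
#' @param cohort Cohort data.frame.
#' @param outcome Name of the outcome column.
#' @param alpha Significance level for the `significant` flag.
#' @return Data.frame, one row per contrast: `mean_diff`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
pairwise_cells <- function(cohort, outcome, alpha = 0.05) {
  y <- cohort_wide(cohort, outcome)
  n <- dim(y)[1]
  cells <- expand.grid(stage = STAGES, mode = MODES,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  label <- paste(cells$mode, cells$stage, sep = ":")
  # column order matches `label`: PCV START/CP/post-CP, VV START/CP/post-CP
  ymat <- cbind(y[, 1, 1], y[, 1, 2], y[, 1, 3],
                y[, 2, 1], y[, 2, 2], y[, 2, 3])
  pairs <- utils::combn(6, 2)
  res <- apply(pairs, 2, function(ij) {
    d <- ymat[, ij[2]] - ymat[, ij[1]]
    if (stats::sd(d) == 0) {
      p <- if (mean(d) == 0) 1 else 0
    } else {
      p <- stats::t.test(d)$p.value
    }
    c(mean_diff = mean(d), p_raw = p)
  })
  out <- data.frame(
    outcome = outcome,
    contrast = paste(label[pairs[2, ]], "-", label[pairs[1, ]]),
    mean_diff = res["mean_diff", ], p_raw = res["p_raw", ])
  out$p_adj <- holm_sidak(out$p_raw)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
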