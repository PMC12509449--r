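# Independent oracles. Everything here re-derives expected values from the
# underlying math without touching the package's implementation paths.

# Constant-phase impedance evaluated directly from the formula (independent
# of cpm_impedance).
oracle_cpm <- function(raw, iaw, g, h, f) {
  w <- 2 * pi * f
  alpha <- (2 / pi) * atan(h / g)
  raw + 1i * w * iaw + (g - 1i * h) / w^alpha
}

# Brute-force grid search for the constant-phase fit: best cost over an
# n^4 log-spaced grid spanning truth/span .. truth*span in each parameter.
oracle_grid_cost <- function(z_values, freqs, truth, n = 15, span = 10) {
  gr <- lapply(truth, function(t0) {
    exp(seq(log(t0 / span), log(t0 * span), length.out = n))
  })
  w <- 2 * pi * freqs
  best <- Inf
  # vectorize over (g, h) pairs for each (raw, iaw) pair
  gh <- expand.grid(g = gr$g, h = gr$h)
  alpha <- (2 / pi) * atan(gh$h / gh$g)
  # tissue term: matrix (nrow(gh) x nfreq)
  tis <- (gh$g - 1i * gh$h) / outer(alpha, w, function(a, ww) ww^a)
  for (raw in gr$raw) {
    for (iaw in gr$iaw) {
      newt <- matrix(raw + 1i * w * iaw, nrow(gh), length(w), byrow = TRUE)
      r <- sweep(newt + tis, 2, z_values)
      cost <- rowSums(Re(r)^2 + Im(r)^2)
      best <- min(best, min(cost))
    }
  }
  best
}

# Trapezoidal integral of a sampled series.
oracle_trapz <- function(y, dt) sum((y[-length(y)] + y[-1]) / 2 * dt)

# Reference two-way within-subject ANOVA F statistics via base aov().
oracle_aov_f <- function(cohort, outcome) {
  df <- data.frame(
    y = cohort[[outcome]],
    subj = factor(cohort$subject),
    mode = factor(cohort$mode, levels = c("PCV", "VV")),
    stage = factor(cohort$stage, levels = c("START", "CP", "post-CP"))
  )
  s <- summary(stats::aov(y ~ mode * stage + Error(subj / (mode * stage)),
                          data = df))
  c(mode = s[["Error: subj:mode"]][[1]]$`F value`[1],
    stage = s[["Error: subj:stage"]][[1]]$`F value`[1],
    interaction = s[["Error: subj:mode:stage"]][[1]]$`F value`[1])
}

# Subject x 6-cell wide matrix (PCV then VV, stages in protocol order),
# used to drive the mlm-based sphericity oracle.
oracle_wide <- function(cohort, outcome) {
  subj <- sort(unique(cohort$subject))
  y <- matrix(NA_real_, length(subj), 6)
  k <- 0
  for (md in c("PCV", "VV")) {
    for (sg in c("START", "CP", "post-CP")) {
      k <- k + 1
      sel <- cohort$mode == md & cohort$stage == sg
      y[, k] <- cohort[[outcome]][sel][order(cohort$subject[sel])]
    }
  }
  y
}
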