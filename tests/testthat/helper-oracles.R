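# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive, explicit computations (loops, normal
# equations, aov decompositions) so they share no code with the package's
# own paths.

# Brute-force two-way mean squares via explicit cell loops.
oracle_mean_squares <- function(M) {
  n <- nrow(M); k <- ncol(M)
  grand <- sum(M) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + (mean(M[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + (mean(M[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (M[i, j] - grand)^2
  ss_res <- ss_tot - k * ss_rows - n * ss_cols
  list(BMS = k * ss_rows / (n - 1),
       JMS = n * ss_cols / (k - 1),
       EMS = ss_res / ((n - 1) * (k - 1)))
}

# Consistency ICC, F test and CI evaluated directly through the F-quantile
# definitions.
oracle_icc <- function(M, measures = "single", alpha = 0.05) {
  ms <- oracle_mean_squares(M)
  n <- nrow(M); k <- ncol(M)
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  Fobs <- ms$BMS / ms$EMS
  icc <- if (measures == "single") {
    (ms$BMS - ms$EMS) / (ms$BMS + (k - 1) * ms$EMS)
  } else {
    (ms$BMS - ms$EMS) / ms$BMS
  }
  fl <- Fobs / qf(1 - alpha / 2, df1, df2)
  fu <- Fobs * qf(1 - alpha / 2, df2, df1)
  ci <- if (measures == "single") {
    c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    c(1 - 1 / fl, 1 - 1 / fu)
  }
  list(icc = icc, F = Fobs, df1 = df1, df2 = df2,
       p = pf(Fobs, df1, df2, lower.tail = FALSE), ci = ci)
}

# Full repeated-measures 2x2 decomposition through stats::aov error strata.
oracle_rm_anova <- function(M) {
  n <- nrow(M)
  long <- data.frame(
    y = c(M[, "d1r1"], M[, "d1r2"], M[, "d2r1"], M[, "d2r2"]),
    subj = factor(rep(seq_len(n), 4)),
    day = factor(rep(c(1, 1, 2, 2), each = n)),
    run = factor(rep(c(1, 2, 1, 2), each = n)))
  fit <- summary(aov(y ~ day * run + Error(subj / (day * run)), data = long))
  grab <- function(stratum, term) {
    tb <- fit[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tb)), fixed = TRUE)[1]
    tb[i, "F value"]
  }
  list(day = grab("Error: subj:day", "day"),
       run = grab("Error: subj:run", "run"),
       interaction = grab("Error: subj:day:run", "day:run"))
}

# OLS through explicit normal equations.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Small fully-crossed beta table built directly from a truth draw (latent
# betas, no GLM noise).
latent_beta_table <- function(vc, n_subjects, rng_seed,
                              task = "T1", seed_region = "S1") {
  bt <- sample_coupling_betas(vc, n_subjects, 2L, 2L, rng_seed = rng_seed)
  data.frame(subject = bt$subject, task = task, seed = seed_region,
             day = bt$day, run = bt$run, beta = bt$b,
             excluded = FALSE, reason = NA_character_)
}

seed_stream_test <- function(key) ppirel:::seed_stream(99L, key)

# Tiny study configuration used across tests (one blocked task, one seed).
tiny_config <- function(n_subjects = 4L, ...) {
  study_config(n_subjects = n_subjects, tasks = "FM", seed_regions = "amyg",
               mu = list(FM = list(amyg = 0.5)),
               accuracy = c(FM = 1), ...)
}
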