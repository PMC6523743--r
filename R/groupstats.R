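# Group-level statistics on the PPI beta table: overall effect tests,
# effect sizes, day x run ANOVA, accuracy correlations, sample size.

new_stat_result <- function(statistic, family, df, p, n, estimate = NULL,
                            note = NULL) {
  structure(list(statistic = statistic, family = family, df = df, p = p,
                 n = n, estimate = estimate, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("%s(%s) = %.4g, p = %.4g, n = %d\n", x$family, dfs,
              x$statistic, x$p, x$n))
  invisible(x)
}

#' One-sample t-test of PPI betas against zero
#'
#' `t = mean / (sd / sqrt(n))` with `df = n - 1` and a two-sided p-value.
#' A zero-variance sample with non-zero mean is degenerate: the t is
#' infinite and p is reported as 0 with a warning.
#'
#' @param values Numeric vector of per-subject betas (finite, `n >= 2`).
#' @return A `stat_result` (family `"t"`); `estimate` holds the mean.
#' @export
one_sample_t <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || !all(is.finite(values)))
    stop_config("need >= 2 finite values")
  n <- length(values)
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) {
    warning("zero variance: degenerate one-sample t")
    t <- if (m == 0) 0 else Inf * sign(m)
    p <- if (m == 0) 1 else 0
    return(new_stat_result(t, "t", n - 1L, p, n, estimate = m,
                           note = "degenerate"))
  }
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  new_stat_result(t, "t", n - 1L, p, n, estimate = m)
}

#' Cohen's d of PPI betas
#'
#' Standardised mean difference from zero. The ROI-mean variant is
#' `mean / sd` of subject-level ROI betas (runs averaged beforehand by the
#' caller); the voxelwise variant computes d per voxel across subjects and
#' averages over the ROI's voxels, matching an effect size "averaged
#' across all voxels" of the target region.
#'
#' @param values Numeric vector (ROI-mean variant) or subjects x voxels
#'   matrix (voxelwise variant).
#' @return List of class `effect_size`: `d`, `variant`, `n`.
#' @export
cohens_d <- function(values) {
  if (is.matrix(values)) {
    if (nrow(values) < 2L) stop_config("need >= 2 subjects")
    d_vox <- apply(values, 2, function(v) mean(v) / stats::sd(v))
    return(structure(list(d = mean(d_vox), variant = "voxelwise-averaged",
                          n = nrow(values)), class = "effect_size"))
  }
  values <- as.numeric(values)
  if (length(values) < 2L) stop_config("need >= 2 values")
  s <- stats::sd(values)
  if (s == 0) warning("zero variance: degenerate Cohen's d")
  structure(list(d = mean(values) / s, variant = "roi-mean",
                 n = length(values)), class = "effect_size")
}

# Wide 2x2 cell matrix (d1r1, d1r2, d2r1, d2r2) for one task/seed;
# subjects with any missing/excluded cell are dropped listwise.
beta_cells_2x2 <- function(bt, task, seed) {
  sub <- bt[bt$task == task & bt$seed == seed, , drop = FALSE]
  sub$beta[sub$excluded] <- NA_real_
  cells <- c("d1r1", "d1r2", "d2r1", "d2r2")
  subs <- sort(unique(sub$subject))
  M <- matrix(NA_real_, length(subs), 4,
              dimnames = list(subs, cells))
  for (r in seq_len(nrow(sub))) {
    i <- match(sub$subject[r], subs)
    j <- match(paste0("d", sub$day[r], "r", sub$run[r]), cells)
    M[i, j] <- sub$beta[r]
  }
  complete <- stats::complete.cases(M)
  list(M = M[complete, , drop = FALSE], n_dropped = sum(!complete))
}

#' 2 x 2 day-by-run repeated-measures ANOVA
#'
#' Tests the main effects of day and run and their interaction on the PPI
#' beta for one task/seed, from the complete 2-day x 2-run cell matrix.
#' With a single two-level within-subject factor each effect reduces to a
#' paired contrast: the per-subject contrast scores are
#' `day = mean(day 2) - mean(day 1)`, `run = mean(run 2) - mean(run 1)` and
#' `interaction = (d1r1 - d1r2) - (d2r1 - d2r2)`; each F equals the square
#' of the one-sample t of the contrast scores, with df (1, n - 1). Subjects
#' with any missing cell are dropped listwise and counted.
#'
#' @param bt A `beta_table`.
#' @param task,seed Task and seed-region labels selecting the cells.
#' @return List with `day`, `run`, `interaction` (each a `stat_result`
#'   with family `"F"` whose `estimate` is the mean contrast score), `n`,
#'   `n_dropped`.
#' @export
rm_anova_2x2 <- function(bt, task, seed) {
  cc <- beta_cells_2x2(bt, task, seed)
  M <- cc$M
  n <- nrow(M)
  if (n < 3L) stop_config("need >= 3 complete subjects")
  contrasts <- list(
    day = (M[, "d2r1"] + M[, "d2r2"]) / 2 - (M[, "d1r1"] + M[, "d1r2"]) / 2,
    run = (M[, "d1r2"] + M[, "d2r2"]) / 2 - (M[, "d1r1"] + M[, "d2r1"]) / 2,
    interaction = (M[, "d1r1"] - M[, "d1r2"]) - (M[, "d2r1"] - M[, "d2r2"]))
  out <- lapply(contrasts, function(cs) {
    s <- stats::sd(cs)
    if (s == 0) {
      return(new_stat_result(0, "F", c(1L, n - 1L), 1, n,
                             estimate = mean(cs),
                             note = if (mean(cs) != 0) "degenerate" else NULL))
    }
    t <- mean(cs) / (s / sqrt(n))
    f <- t^2
    p <- stats::pf(f, 1, n - 1, lower.tail = FALSE)
    new_stat_result(f, "F", c(1L, n - 1L), p, n, estimate = mean(cs))
  })
  c(out, list(n = n, n_dropped = cc$n_dropped))
}

#' Pearson correlation with p-value
#'
#' Two-sided p via `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return A `stat_result` (family `"r"`); `statistic` is r, `estimate`
#'   the t value.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_config("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_config("zero variance in x or y")
  r <- sum(scale(x) * scale(y)) / (n - 1)
  if (abs(r) >= 1) {
    p <- 0
    t <- Inf * sign(r)
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  new_stat_result(r, "r", n - 2L, p, n, estimate = t)
}

#' Sample size for detecting a correlation
#'
#' Fisher-z approximation:
#' `n = ((z[1 - alpha/tails] + z[power]) / atanh(r))^2`, optionally with
#' the `+ 3` small-sample correction, rounded to the nearest integer or
#' up. The default convention (no correction, nearest rounding) returns 26
#' for r = 0.5, alpha = 0.05 two-tailed, power 0.80.
#'
#' @param r Target correlation, 0 < r < 1.
#' @param alpha Type-I error rate.
#' @param power Target power.
#' @param tails 1 or 2.
#' @param correction `"none"` or `"plus3"`.
#' @param rounding `"nearest"` or `"ceil"`.
#' @return Integer sample size.
#' @export
sample_size_correlation <- function(r, alpha = 0.05, power = 0.80,
                                    tails = 2,
                                    correction = c("none", "plus3"),
                                    rounding = c("nearest", "ceil")) {
  correction <- match.arg(correction)
  rounding <- match.arg(rounding)
  if (!(r > 0 && r < 1)) stop_config("r must be in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop_config("alpha must be in (0, 1)")
  if (!(power > 0 && power < 1)) stop_config("power must be in (0, 1)")
  za <- stats::qnorm(1 - alpha / tails)
  zb <- stats::qnorm(power)
  n <- ((za + zb) / atanh(r))^2
  if (correction == "plus3") n <- n + 3
  as.integer(if (rounding == "nearest") round(n) else ceiling(n))
}

#' Per-subject run-averaged betas for one task/seed
#'
#' Averages each included subject's betas over all available runs (used by
#' the overall PPI effect test and the battery gate).
#'
#' @param bt A `beta_table`.
#' @param task,seed Selection labels.
#' @return Named numeric vector of subject means (subjects with no
#'   included cell are omitted).
#' @export
subject_mean_betas <- function(bt, task, seed) {
  sub <- bt[bt$task == task & bt$seed == seed & !bt$excluded &
              is.finite(bt$beta), , drop = FALSE]
  if (nrow(sub) == 0L) return(stats::setNames(numeric(0), character(0)))
  tapply(sub$beta, sub$subject, mean)
}

#' Group-level statistics for every task/seed in a beta table
#'
#' For each task x seed region: the one-sample t of the run-averaged PPI
#' effect, Cohen's d (ROI-mean variant), and the 2 x 2 day-by-run ANOVA.
#'
#' @param bt A `beta_table`.
#' @return Nested list keyed by task then seed region; each entry has
#'   `t_test`, `d`, `anova`, `n`.
#' @export
group_stats <- function(bt) {
  tasks <- unique(bt$task)
  out <- list()
  for (tk in tasks) {
    out[[tk]] <- list()
    for (sr in unique(bt$seed[bt$task == tk])) {
      means <- subject_mean_betas(bt, tk, sr)
      entry <- list(n = length(means))
      if (length(means) >= 2L) {
        entry$t_test <- one_sample_t(means)
        entry$d <- cohens_d(means)
      }
      entry$anova <- tryCatch(rm_anova_2x2(bt, tk, sr),
                              ppirel_config_error = function(e) NULL)
      out[[tk]][[sr]] <- entry
    }
  }
  out
}
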