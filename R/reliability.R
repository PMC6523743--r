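# Two-way mixed-effects consistency ICCs, F-based confidence intervals,
# interpretation bands, and the five-cell reliability battery.

#' Two-way mean squares of a subjects x sessions matrix
#'
#' Decomposes an `n x k` matrix of betas into between-subjects (BMS),
#' between-sessions (JMS) and residual (EMS) mean squares:
#' \preformatted{
#'   BMS = k * sum_i (rowmean_i - grand)^2 / (n - 1)
#'   JMS = n * sum_j (colmean_j - grand)^2 / (k - 1)
#'   EMS = residual SS / ((n - 1)(k - 1))
#' }
#' Rows containing missing values are dropped (count reported).
#'
#' @param M Numeric matrix, subjects in rows (`n >= 3` after dropping),
#'   sessions in columns (`k >= 2`).
#' @return Object of class `anova_decomp`: `BMS`, `JMS`, `EMS`, `n`, `k`,
#'   `df` (named: subjects, sessions, residual), `n_dropped`.
#' @export
twoway_mean_squares <- function(M) {
  M <- as.matrix(M)
  complete <- stats::complete.cases(M)
  n_dropped <- sum(!complete)
  M <- M[complete, , drop = FALSE]
  n <- nrow(M); k <- ncol(M)
  if (n < 3L) stop_config("need >= 3 complete subjects")
  if (k < 2L) stop_config("need >= 2 sessions")
  grand <- mean(M)
  rm_ <- rowMeans(M); cm <- colMeans(M)
  bms <- k * sum((rm_ - grand)^2) / (n - 1)
  jms <- n * sum((cm - grand)^2) / (k - 1)
  resid <- M - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  structure(list(BMS = bms, JMS = jms, EMS = ems, n = n, k = k,
                 df = c(subjects = n - 1L, sessions = k - 1L,
                        residual = (n - 1L) * (k - 1L)),
                 n_dropped = n_dropped),
            class = "anova_decomp")
}

#' Two-way mixed-effects consistency ICC with F-test and 95% CI
#'
#' Single-measures `ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS)` or
#' average-measures `ICC(3,k) = (BMS - EMS) / BMS`. The session (scanner)
#' effect is fixed, the subject effect random, and systematic session
#' offsets are ignored ("consistency" rather than "absolute" agreement).
#' The F statistic is `BMS / EMS` on `(n - 1, (n - 1)(k - 1))` df with a
#' one-tailed p (testing ICC > 0); the confidence interval comes from
#' `F_L = F / qf(1 - alpha/2, df1, df2)` and
#' `F_U = F * qf(1 - alpha/2, df2, df1)`, mapped through
#' `(F - 1) / (F + k - 1)` (single) or `1 - 1/F` (average). The lower bound
#' can be negative. When `EMS = 0` (perfect consistency) the ICC is exactly
#' 1 with a degenerate CI.
#'
#' @param d An `anova_decomp` from [twoway_mean_squares()], or a matrix
#'   (decomposed first).
#' @param measures `"single"` or `"average"`.
#' @param alpha CI error rate (default 0.05, i.e. 95% CI, alpha/2 per
#'   tail).
#' @return Object of class `icc_result`: `icc`, `measures`,
#'   `agreement = "consistency"`, `F`, `df1`, `df2`, `p` (one-tailed),
#'   `ci` (length 2), `band` (see [classify_icc()]), `n`, `k`,
#'   `degenerate`.
#' @export
icc_consistency <- function(d, measures = c("single", "average"),
                            alpha = 0.05) {
  measures <- match.arg(measures)
  if (is.matrix(d) || is.data.frame(d)) d <- twoway_mean_squares(d)
  stopifnot(inherits(d, "anova_decomp"))
  n <- d$n; k <- d$k
  df1 <- n - 1L; df2 <- (n - 1L) * (k - 1L)
  if (d$BMS == 0 && d$EMS == 0)
    stop_config("constant matrix: ICC undefined")
  if (d$EMS == 0) {
    return(structure(list(icc = 1, measures = measures,
                          agreement = "consistency", F = Inf,
                          df1 = df1, df2 = df2, p = 0, ci = c(1, 1),
                          band = classify_icc(1), n = n, k = k,
                          degenerate = TRUE),
                     class = "icc_result"))
  }
  Fobs <- d$BMS / d$EMS
  icc <- if (measures == "single") {
    (d$BMS - d$EMS) / (d$BMS + (k - 1) * d$EMS)
  } else {
    (d$BMS - d$EMS) / d$BMS
  }
  p <- stats::pf(Fobs, df1, df2, lower.tail = FALSE)
  fl <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
  ci <- if (measures == "single") {
    c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    c(1 - 1 / fl, 1 - 1 / fu)
  }
  structure(list(icc = icc, measures = measures, agreement = "consistency",
                 F = Fobs, df1 = df1, df2 = df2, p = p, ci = ci,
                 band = classify_icc(icc), n = n, k = k,
                 degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s measures, consistency) = %.3f (95%% CI %.3f to %.3f), F(%d, %d) = %.3f, p = %.3g [%s]\n",
              x$measures, x$icc, x$ci[1], x$ci[2], x$df1, x$df2, x$F, x$p,
              x$band))
  invisible(x)
}

#' Conventional ICC interpretation bands
#'
#' `< 0.4` poor; `0.4` to `0.75` (inclusive) moderate-to-good; `> 0.75`
#' excellent.
#'
#' @param value ICC value (`<= 1`).
#' @return One of `"poor"`, `"moderate-to-good"`, `"excellent"`.
#' @export
classify_icc <- function(value) {
  stopifnot(value <= 1 + 1e-12)
  if (value < 0.4) "poor"
  else if (value <= 0.75) "moderate-to-good"
  else "excellent"
}

# The five battery cells as n x 2 matrices from a beta table.
battery_matrices <- function(bt, task, seed) {
  cc <- beta_cells_2x2_keepna(bt, task, seed)
  M <- cc
  list(
    between_day_both_runs = cbind(day1 = (M[, "d1r1"] + M[, "d1r2"]) / 2,
                                  day2 = (M[, "d2r1"] + M[, "d2r2"]) / 2),
    between_day_run1 = cbind(day1 = M[, "d1r1"], day2 = M[, "d2r1"]),
    between_day_run2 = cbind(day1 = M[, "d1r2"], day2 = M[, "d2r2"]),
    within_day_day1 = cbind(run1 = M[, "d1r1"], run2 = M[, "d1r2"]),
    within_day_day2 = cbind(run1 = M[, "d2r1"], run2 = M[, "d2r2"]))
}

# 2x2 cell matrix retaining NA rows (each battery cell drops rows
# independently, so e.g. a missing day-2 run does not discard within-day-1).
beta_cells_2x2_keepna <- function(bt, task, seed) {
  sub <- bt[bt$task == task & bt$seed == seed, , drop = FALSE]
  sub$beta[sub$excluded] <- NA_real_
  cells <- c("d1r1", "d1r2", "d2r1", "d2r2")
  subs <- sort(unique(sub$subject))
  M <- matrix(NA_real_, length(subs), 4, dimnames = list(subs, cells))
  for (r in seq_len(nrow(sub))) {
    i <- match(sub$subject[r], subs)
    j <- match(paste0("d", sub$day[r], "r", sub$run[r]), cells)
    M[i, j] <- sub$beta[r]
  }
  M
}

#' The five-cell reliability battery
#'
#' For each task x seed region in the beta table, computes five consistency
#' ICCs: three between-day (per-day run averages; run 1 only; run 2 only)
#' and two within-day (run 1 vs run 2, per day). By default a seed/task
#' whose overall group PPI effect (one-sample t on the 4-run subject
#' averages) is not significant is gated out and marked "not analysed".
#' Both single- and average-measures ICCs are computed; `measures` selects
#' which one populates the headline columns (CI, p, band).
#'
#' @param bt A `beta_table`.
#' @param measures `"average"` (default, the battery's reporting choice)
#'   or `"single"`.
#' @param gate Gate cells on a significant group PPI effect (default
#'   `TRUE`).
#' @param gate_alpha Significance level of the gate (default 0.05).
#' @param alpha CI error rate.
#' @return A `reliability_table` data frame: `task`, `seed`, `cell`, `n`,
#'   `icc`, `icc_single`, `icc_average`, `F`, `df1`, `df2`, `p`, `ci_low`,
#'   `ci_high`, `band`, `analysed`, `note`.
#' @export
reliability_battery <- function(bt, measures = c("average", "single"),
                                gate = TRUE, gate_alpha = 0.05,
                                alpha = 0.05) {
  measures <- match.arg(measures)
  cells <- c("between_day_both_runs", "between_day_run1",
             "between_day_run2", "within_day_day1", "within_day_day2")
  rows <- list()
  for (tk in unique(bt$task)) {
    for (sr in unique(bt$seed[bt$task == tk])) {
      analysed <- TRUE; note <- NA_character_
      if (gate) {
        means <- subject_mean_betas(bt, tk, sr)
        if (length(means) < 2L) {
          analysed <- FALSE; note <- "no data"
        } else {
          tt <- one_sample_t(means)
          if (tt$p >= gate_alpha) {
            analysed <- FALSE
            note <- sprintf("not analysed: group PPI effect p = %.3f >= %.2f",
                            tt$p, gate_alpha)
          }
        }
      }
      mats <- battery_matrices(bt, tk, sr)
      for (cl in cells) {
        row <- data.frame(task = tk, seed = sr, cell = cl, n = NA_integer_,
                          icc = NA_real_, icc_single = NA_real_,
                          icc_average = NA_real_, F = NA_real_,
                          df1 = NA_integer_, df2 = NA_integer_,
                          p = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, band = NA_character_,
                          analysed = analysed, note = note,
                          stringsAsFactors = FALSE)
        if (analysed) {
          res <- tryCatch({
            d <- twoway_mean_squares(mats[[cl]])
            sel <- icc_consistency(d, measures = measures, alpha = alpha)
            oth <- icc_consistency(
              d, measures = if (measures == "average") "single" else "average",
              alpha = alpha)
            list(sel = sel, oth = oth)
          }, ppirel_config_error = function(e) e)
          if (inherits(res, "error")) {
            row$analysed <- FALSE
            row$note <- paste0("not computable: ", conditionMessage(res))
          } else {
            sel <- res$sel
            row$n <- sel$n
            row$icc <- sel$icc
            row$icc_single <-
              if (measures == "single") sel$icc else res$oth$icc
            row$icc_average <-
              if (measures == "average") sel$icc else res$oth$icc
            row$F <- sel$F; row$df1 <- sel$df1; row$df2 <- sel$df2
            row$p <- sel$p; row$ci_low <- sel$ci[1]; row$ci_high <- sel$ci[2]
            row$band <- sel$band
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_table", "data.frame")
  out
}
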