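# Per-run PPI estimation: seed extraction, design construction, OLS fit.

#' Extract a representative seed time course
#'
#' In time-series mode (the recording stores a single seed course) the
#' stored course is returned. In voxel mode (`recording$seed` is a scans x
#' voxels matrix) the representative course is either the voxel mean or the
#' first eigenvariate (first principal-component score series, sign-aligned
#' to correlate positively with the voxel mean and scaled to unit
#' variance). With `activation` enabled, the voxel set is first restricted
#' to voxels whose task-activation GLM t statistic exceeds the threshold; a
#' subject whose seed retains no suprathreshold voxel raises a
#' `ppirel_seed_empty` condition, mirroring the exclusion of such subjects
#' from that seed's analyses.
#'
#' @param recording A `recording` (see [simulate_run()] /
#'   [as_voxel_recording()]).
#' @param method `"mean"` or `"eigenvariate"` (voxel mode only).
#' @param activation `NULL` (off) or a list with `p` (one-sided uncorrected
#'   p threshold on the activation t, default 0.05).
#' @return Numeric seed time course of length scans.
#' @export
extract_seed <- function(recording, method = c("mean", "eigenvariate"),
                         activation = NULL) {
  method <- match.arg(method)
  s <- recording$seed
  if (!is.matrix(s)) return(as.numeric(s))
  if (ncol(s) == 0L) stop_seed_empty("seed mask is empty")
  if (!is.null(activation)) {
    p_thr <- activation$p %||% 0.05
    ctx <- task_context(recording$events, recording$spec, recording$acq)
    X <- cbind(task = ctx$x_scans, recording$motion, intercept = 1)
    keep <- vapply(seq_len(ncol(s)), function(j) {
      f <- fit_ols(X, s[, j])
      p_one <- stats::pt(f$t[1], df = f$df, lower.tail = FALSE)
      is.finite(p_one) && p_one < p_thr
    }, logical(1))
    if (!any(keep))
      stop_seed_empty("no suprathreshold voxel in the seed mask at p < ",
                      p_thr)
    s <- s[, keep, drop = FALSE]
  }
  if (method == "mean" || ncol(s) == 1L) return(rowMeans(s))
  sc <- scale(s, center = TRUE, scale = FALSE)
  sv <- svd(sc, nu = 1, nv = 0)
  eig <- sv$u[, 1] * sv$d[1]
  vm <- rowMeans(s)
  if (stats::cor(eig, vm) < 0) eig <- -eig
  eig / stats::sd(eig)
}

#' Build the PPI design matrix
#'
#' Columns, in order: the interaction regressor
#' `(seed - mean(seed)) * psy_c`, the physiological covariate (seed), the
#' psychological covariate (HRF-convolved task regressor), six motion
#' regressors of no interest, an optional error regressor, optional drift
#' columns, and an intercept. Columns carry role tags.
#'
#' @param seed_tc Seed time course (length scans).
#' @param psy_c Centered psychological contrast code at scan resolution.
#' @param x_task HRF-convolved task regressor at scan resolution.
#' @param motion Scans x 6 motion matrix.
#' @param error_regressor Optional convolved error-trial regressor.
#' @param drift Optional drift basis (matrix from [dct_highpass()]).
#' @param interaction Optional replacement interaction column (used by the
#'   neural/deconvolution mode).
#' @return Object of class `ppi_design`: list with `X` (matrix) and `roles`
#'   (character vector).
#' @export
build_ppi_design <- function(seed_tc, psy_c, x_task, motion,
                             error_regressor = NULL, drift = NULL,
                             interaction = NULL) {
  n <- length(seed_tc)
  stopifnot(length(psy_c) == n, length(x_task) == n,
            is.matrix(motion), nrow(motion) == n, ncol(motion) == 6L)
  if (stats::sd(psy_c) == 0)
    stop_config("psychological code is constant: no task contrast")
  inter <- interaction %||% ((seed_tc - mean(seed_tc)) * psy_c)
  X <- cbind(ppi = inter, seed = seed_tc, task = x_task, motion)
  roles <- c("interaction", "physiological", "psychological",
             rep("motion", 6L))
  if (!is.null(error_regressor)) {
    stopifnot(length(error_regressor) == n)
    X <- cbind(X, error = error_regressor)
    roles <- c(roles, "error")
  }
  if (!is.null(drift) && ncol(drift) > 0L) {
    X <- cbind(X, drift)
    roles <- c(roles, rep("drift", ncol(drift)))
  }
  X <- cbind(X, intercept = 1)
  roles <- c(roles, "intercept")
  structure(list(X = X, roles = roles), class = "ppi_design")
}

#' Ordinary least-squares fit
#'
#' Fits `y` on the design by QR decomposition. Standard errors come from
#' the residual variance and the diagonal of the inverse Gram matrix;
#' `t = coefficient / SE`. A rank-deficient design is fit by the
#' minimum-norm (pseudo-inverse) solution with a warning; coefficients
#' whose columns lie in a collinear set still carry the pseudo-inverse
#' value but their standard errors are reported as `NA`.
#'
#' @param design A `ppi_design` or plain numeric matrix.
#' @param y Response time course.
#' @return Object of class `glm_fit`: `coef`, `se`, `t`, `df`, `sigma2`,
#'   `rank`, `fitted`, `residuals`.
#' @export
fit_ols <- function(design, y) {
  X <- if (inherits(design, "ppi_design")) design$X else design
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_config("non-finite values in design or response")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop_config("need more scans than regressors")
  qr_x <- qr(X)
  full_rank <- qr_x$rank == p
  if (full_rank) {
    coef <- qr.coef(qr_x, y)
    fitted <- drop(X %*% coef)
    res <- y - fitted
    df <- n - p
    sigma2 <- sum(res^2) / df
    xtx_inv <- chol2inv(qr.R(qr_x))
    se <- sqrt(sigma2 * diag(xtx_inv))
  } else {
    warning("rank-deficient design (rank ", qr_x$rank, " < ", p,
            "); using pseudo-inverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- drop(sv$v[, pos, drop = FALSE] %*%
                   ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
    names(coef) <- colnames(X)
    fitted <- drop(X %*% coef)
    res <- y - fitted
    df <- n - qr_x$rank
    sigma2 <- sum(res^2) / df
    # SEs only for columns not involved in a collinearity
    se <- rep(NA_real_, p)
    names(se) <- colnames(X)
  }
  tval <- coef / se
  structure(list(coef = coef, se = se, t = tval, df = df, sigma2 = sigma2,
                 rank = qr_x$rank, fitted = fitted, residuals = res),
            class = "glm_fit")
}

#' Deconvolve a seed time course to a neural-level series
#'
#' Estimates a microtime "neural" series whose convolution with the
#' double-gamma kernel reproduces the observed scan-resolution seed course,
#' by ridge-regularised least squares on the neural coefficients. A
#' positive penalty is required (the scan-to-microtime system is
#' underdetermined); as the penalty shrinks the reconvolved estimate
#' approaches the observed course, and as it grows the estimate shrinks to
#' zero.
#'
#' @param seed_tc Seed time course (length scans).
#' @param acq An [acq_spec()].
#' @param ridge_penalty Non-negative ridge penalty (default 0.01).
#' @return Numeric microtime neural series (length `scans * nbin`).
#' @export
deconvolve_seed <- function(seed_tc, acq, ridge_penalty = 0.01) {
  if (ridge_penalty < 0) stop_config("penalty must be >= 0")
  if (ridge_penalty == 0)
    stop_config("the deconvolution system is singular at penalty 0; ",
                "use a positive ridge penalty")
  n_micro <- micro_grid_length(acq)
  if (all(seed_tc == 0)) return(numeric(n_micro))
  kernel <- hrf_kernel(acq$dt)
  idx <- scan_onset_index(acq)
  # Convolution matrix restricted to scan-onset rows: C[s, j] = h[idx_s - j]
  C <- matrix(0, length(idx), n_micro)
  for (s in seq_along(idx)) {
    j <- seq_len(idx[s])
    lag <- idx[s] - j + 1L
    keep <- lag <= length(kernel)
    C[s, j[keep]] <- kernel[lag[keep]] * acq$dt
  }
  # baseline handled by a jointly fitted, unpenalised intercept (a neural
  # series cannot generate the signal's DC level at early scans)
  A <- cbind(C, 1)
  G <- crossprod(A)
  diag(G)[seq_len(n_micro)] <- diag(G)[seq_len(n_micro)] + ridge_penalty
  diag(G)[n_micro + 1L] <- diag(G)[n_micro + 1L] + 1e-12
  z <- drop(solve(G, crossprod(A, seed_tc)))
  z[seq_len(n_micro)]
}

convolved_error_regressor <- function(events, acq, kernel = NULL) {
  errs <- events[!events$correct, , drop = FALSE]
  if (nrow(errs) == 0L) return(NULL)
  attr(errs, "run_length") <- attr(events, "run_length")
  attr(errs, "conditions") <- attr(events, "conditions")
  class(errs) <- class(events)
  w <- stats::setNames(rep(1, length(unique(errs$condition))),
                       unique(errs$condition))
  convolve_to_scans(errs, w, acq, kernel = kernel)
}

#' Fit the PPI model to one run
#'
#' Composes seed extraction, (optionally) deconvolution, design
#' construction and the OLS fit, returning the interaction coefficient as
#' the PPI beta. In `bold` mode the interaction is
#' `(seed - mean(seed)) * psy_c` at scan resolution; in `neural` mode the
#' seed is deconvolved to the microtime grid, multiplied by the microtime
#' psychological code, reconvolved and sampled at scans. An error regressor
#' (convolved incorrect-trial events) is included for the gender
#' classification task when the subject made at least one error.
#'
#' @param recording A `recording`.
#' @param events Event table (defaults to the one stored in the recording).
#' @param mode `"bold"` (default) or `"neural"`.
#' @param seed_method,activation Passed to [extract_seed()].
#' @param drift Optional drift basis.
#' @param ridge_penalty Deconvolution penalty (`neural` mode).
#' @param ctx Optional pre-computed [task_context()].
#' @return Object of class `ppi_betas`: list with `beta` (interaction
#'   coefficient), `coef`, `se`, `t`, `df`, `mode`, `seed_method`, `meta`.
#' @export
fit_ppi_run <- function(recording, events = NULL, mode = c("bold", "neural"),
                        seed_method = "mean", activation = NULL,
                        drift = NULL, ridge_penalty = 0.01, ctx = NULL) {
  mode <- match.arg(mode)
  events <- events %||% recording$events
  acq <- recording$acq
  if (is.null(ctx)) ctx <- task_context(events, recording$spec, acq)
  seed_tc <- extract_seed(recording, method = seed_method,
                          activation = activation)
  interaction <- NULL
  if (mode == "neural") {
    neu <- deconvolve_seed(seed_tc, acq, ridge_penalty)
    interaction <- convolve_micro(neu * ctx$psy_micro, ctx$kernel,
                                  acq$dt)[scan_onset_index(acq)]
  }
  err_reg <- if ((recording$spec$name %||% "") == "GC")
    convolved_error_regressor(events, acq, kernel = ctx$kernel) else NULL
  des <- build_ppi_design(seed_tc, ctx$psy_scans, ctx$x_scans,
                          recording$motion, error_regressor = err_reg,
                          drift = drift, interaction = interaction)
  fit <- fit_target(des, recording)
  structure(c(fit, list(mode = mode, seed_method = seed_method,
                        meta = recording$meta)),
            class = "ppi_betas")
}

# Fit the design to the recording's target; voxel mode fits each target
# voxel and reports the ROI-mean beta alongside per-voxel betas.
fit_target <- function(des, recording) {
  tg <- recording$target
  if (is.matrix(tg)) {
    fits <- lapply(seq_len(ncol(tg)), function(j) fit_ols(des, tg[, j]))
    betas <- vapply(fits, function(f) unname(f$coef[1]), numeric(1))
    f1 <- fits[[1]]
    list(beta = mean(betas), voxel_betas = betas,
         coef = NULL, se = NULL, t = NULL, df = f1$df)
  } else {
    f <- fit_ols(des, tg)
    list(beta = unname(f$coef[1]), voxel_betas = NULL, coef = f$coef,
         se = f$se, t = f$t, df = f$df)
  }
}

#' Fit the PPI model across a whole study
#'
#' One row per (subject, task, seed region, day, run). Cells flagged
#' excluded in the study's truth table are carried through with their flag;
#' a `ppirel_seed_empty` condition raised during seed extraction marks the
#' affected rows excluded (reason `"seed_empty"`) rather than dropping
#' them.
#'
#' @param study A `ppi_study` from [simulate_study()] or [read_study()].
#' @param mode,seed_method,activation,drift,ridge_penalty Passed to
#'   [fit_ppi_run()].
#' @return A `beta_table` data frame with columns `subject`, `task`,
#'   `seed`, `day`, `run`, `beta`, `excluded`, `reason`.
#' @export
run_study_ppi <- function(study, mode = "bold", seed_method = "mean",
                          activation = NULL, drift = NULL,
                          ridge_penalty = 0.01) {
  tr <- study$truth
  out <- tr[, c("subject", "task", "seed", "day", "run")]
  out$beta <- NA_real_
  out$excluded <- tr$excluded
  out$reason <- tr$reason
  # regressor context depends only on (events, spec, acq); cache on the
  # exact event table so identical runs share one set of convolutions
  ctx_cache <- new.env(parent = emptyenv())
  get_ctx <- function(rec) {
    ck <- paste(rec$spec$name,
                paste(rec$events$onset, collapse = ","),
                paste(as.integer(rec$events$correct), collapse = ""),
                sep = "|")
    if (is.null(ctx_cache[[ck]]))
      ctx_cache[[ck]] <- task_context(rec$events, rec$spec, rec$acq)
    ctx_cache[[ck]]
  }
  for (r in seq_len(nrow(out))) {
    if (out$excluded[r]) next
    key <- study_cell_key(out$subject[r], out$day[r], out$run[r],
                          out$task[r], out$seed[r])
    rec <- study$recordings[[key]]
    if (is.null(rec)) {
      out$excluded[r] <- TRUE
      out$reason[r] <- "missing recording"
      next
    }
    res <- tryCatch(
      fit_ppi_run(rec, mode = mode, seed_method = seed_method,
                  activation = activation, drift = drift,
                  ridge_penalty = ridge_penalty, ctx = get_ctx(rec)),
      ppirel_seed_empty = function(e) e)
    if (inherits(res, "ppirel_seed_empty")) {
      out$excluded[r] <- TRUE
      out$reason[r] <- "seed_empty"
    } else {
      out$beta[r] <- res$beta
    }
  }
  class(out) <- c("beta_table", "data.frame")
  out
}

#' Expand a time-series recording to a small voxel block
#'
#' Replicates the seed and target region signals across the voxels of
#' small masks on a toy grid and adds independent white voxel noise;
#' useful for exercising the voxel-mode seed extraction and ROI-mean
#' estimation paths. With zero voxel noise the ROI-mean beta equals the
#' time-series-mode beta.
#'
#' @param recording A time-series `recording`.
#' @param n_seed_voxels,n_target_voxels Mask sizes.
#' @param voxel_noise_sd SD of the added white voxel noise.
#' @param grid 3-D grid dimensions (default `c(8, 8, 8)`).
#' @param rng_seed Integer seed for the voxel noise and mask placement.
#' @return A voxel-mode `recording`: `seed`/`target` are scans x voxels
#'   matrices; `seed_mask`/`target_mask` are 0/1 arrays on `grid` with
#'   voxel index maps.
#' @export
as_voxel_recording <- function(recording, n_seed_voxels = 10L,
                               n_target_voxels = 15L, voxel_noise_sd = 0,
                               grid = c(8L, 8L, 8L), rng_seed = NULL) {
  stopifnot(!is.matrix(recording$seed))
  n <- length(recording$seed)
  with_seed(rng_seed, {
    total <- prod(grid)
    vox <- sample.int(total, n_seed_voxels + n_target_voxels)
    seed_vox <- sort(vox[seq_len(n_seed_voxels)])
    targ_vox <- sort(vox[-seq_len(n_seed_voxels)])
    mk_mask <- function(ix) {
      m <- array(0L, dim = grid)
      m[ix] <- 1L
      m
    }
    expand <- function(x, k) {
      matrix(x, n, k) + if (voxel_noise_sd > 0)
        matrix(stats::rnorm(n * k, 0, voxel_noise_sd), n, k)
      else 0
    }
    rec <- recording
    rec$seed <- expand(recording$seed, n_seed_voxels)
    rec$target <- expand(recording$target, n_target_voxels)
    rec$seed_mask <- mk_mask(seed_vox)
    rec$target_mask <- mk_mask(targ_vox)
    rec$grid <- grid
    rec
  })
}
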