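# Seed extraction, PPI design, OLS, deconvolution, study-level fitting.

make_rec <- function(b = 0.5, sub = subject_params(), task = "FM",
                     rng_seed = 1) {
  sp <- task_spec(task)
  acq <- acq_for_task(sp)
  ev <- make_task_events(sp, rng_seed = if (sp$design == "event-related")
    rng_seed else NULL)
  simulate_run(sub, b, events = ev, acq = acq, spec = sp,
               rng_seed = rng_seed)
}

test_that("seed extraction reduces voxel blocks to representative courses", {
  rec <- make_rec()
  vox <- as_voxel_recording(rec, n_seed_voxels = 8, voxel_noise_sd = 0,
                            rng_seed = 2)
  expect_equal(extract_seed(vox, method = "mean"), rec$seed)
  # eigenvariate of a rank-1 block correlates perfectly with the source
  eig <- extract_seed(vox, method = "eigenvariate")
  expect_equal(abs(cor(eig, rec$seed)), 1, tolerance = 1e-10)
  expect_equal(sd(eig), 1, tolerance = 1e-10)
  expect_gt(cor(eig, rowMeans(vox$seed)), 0) # sign-aligned

  # time-series mode returns the stored course
  expect_equal(extract_seed(rec), rec$seed)
})

test_that("a non-responding seed under activation thresholding is excluded", {
  nullsub <- subject_params(a = 0)
  rec <- make_rec(sub = nullsub, rng_seed = 3)
  vox <- as_voxel_recording(rec, voxel_noise_sd = 0.1, rng_seed = 4)
  # strict threshold: a flat (a = 0) seed has no suprathreshold voxel
  expect_error(extract_seed(vox, activation = list(p = 1e-5)),
               class = "ppirel_seed_empty")
  # a responsive seed passes the same threshold
  rec2 <- make_rec(sub = subject_params(a = 2), rng_seed = 5)
  vox2 <- as_voxel_recording(rec2, voxel_noise_sd = 0.1, rng_seed = 6)
  expect_silent(extract_seed(vox2, activation = list(p = 0.05)))
})

test_that("PPI design has the documented composition and role tags", {
  rec <- make_rec()
  ctx <- task_context(rec$events, rec$spec, rec$acq)
  des <- build_ppi_design(rec$seed, ctx$psy_scans, ctx$x_scans, rec$motion)
  expect_equal(ncol(des$X), 10) # interaction + seed + task + 6 motion + 1
  expect_equal(des$roles[1], "interaction")
  expect_equal(sum(des$roles == "motion"), 6)
  expect_equal(sum(des$roles == "intercept"), 1)
  expect_true(all(is.finite(des$X)))
  expect_error(build_ppi_design(rec$seed, rep(0, length(rec$seed)),
                                ctx$x_scans, rec$motion),
               class = "ppirel_config_error")
})

test_that("OLS matches the normal-equations oracle", {
  set.seed(10)
  X <- cbind(matrix(rnorm(40 * 4), 40, 4), 1)
  beta <- c(2, -1, 0.5, 0, 3)
  y <- drop(X %*% beta) + rnorm(40, 0, 0.3)
  f <- fit_ols(X, y)
  expect_equal(unname(f$coef), unname(oracle_ols(X, y)), tolerance = 1e-8)
  # y equal to one column -> that coefficient 1, zero residuals
  f2 <- fit_ols(X, X[, 2])
  expect_equal(unname(f2$coef), c(0, 1, 0, 0, 0), tolerance = 1e-10)
  expect_equal(sum(f2$residuals^2), 0, tolerance = 1e-18)
  # y orthogonal to all columns -> all coefficients 0
  Q <- qr.Q(qr(X))
  yo <- rnorm(40)
  yo <- yo - Q %*% crossprod(Q, yo)
  f3 <- fit_ols(X, drop(yo))
  expect_equal(max(abs(f3$coef)), 0, tolerance = 1e-10)
  expect_error(fit_ols(X, c(rep(NA, 40))), class = "ppirel_config_error")
})

test_that("deconvolution inverts the forward convolution", {
  acq <- acq_spec(tr = 2, scans = 80, dt = 0.25)
  n_micro <- ppirel:::micro_grid_length(acq)
  neural <- numeric(n_micro)
  neural[100:180] <- 1
  neural[300:360] <- 1
  kernel <- hrf_kernel(acq$dt)
  bold <- ppirel:::convolve_micro(neural, kernel,
                                  acq$dt)[ppirel:::scan_onset_index(acq)]
  est <- deconvolve_seed(bold, acq, ridge_penalty = 1e-4)
  rebold <- ppirel:::convolve_micro(est, kernel,
                                    acq$dt)[ppirel:::scan_onset_index(acq)]
  rel_err <- sqrt(sum((rebold - bold)^2) / sum(bold^2))
  expect_lt(rel_err, 0.01)
  # ridge shrinkage limit
  big <- deconvolve_seed(bold, acq, ridge_penalty = 1e8)
  expect_lt(max(abs(big)), 1e-3)
  expect_equal(deconvolve_seed(rep(0, 80), acq), rep(0, n_micro))
  expect_error(deconvolve_seed(bold, acq, ridge_penalty = 0),
               class = "ppirel_config_error")
})

test_that("noise-free PPI fits recover the injected coefficient", {
  sub <- subject_params(sigma_target = 0)
  rec <- make_rec(b = 0.8, sub = sub, rng_seed = 7)
  expect_equal(fit_ppi_run(rec)$beta, 0.8, tolerance = 1e-6)
  # full noise-off: design is rank-deficient (seed proportional to task),
  # the pseudo-inverse fit still pins the interaction coefficient
  sub0 <- subject_params(sigma_seed = 0, sigma_target = 0)
  rec0 <- make_rec(b = 0.8, sub = sub0, rng_seed = 8)
  expect_warning(f0 <- fit_ppi_run(rec0), "rank-deficient")
  expect_equal(f0$beta, 0.8, tolerance = 1e-6)
})

test_that("PPI beta is invariant to nuisance reparameterisations", {
  rec <- make_rec(b = 0.6, rng_seed = 9)
  b0 <- fit_ppi_run(rec)$beta
  # shuffle motion columns
  rec2 <- rec
  rec2$motion <- rec$motion[, c(4, 1, 6, 2, 5, 3)]
  expect_equal(fit_ppi_run(rec2)$beta, b0, tolerance = 1e-10)
  # rescale motion regressors
  rec3 <- rec
  rec3$motion <- rec$motion * 100
  expect_equal(fit_ppi_run(rec3)$beta, b0, tolerance = 1e-8)
  # constants added to seed and target are absorbed by demeaning/intercept
  rec4 <- rec
  rec4$seed <- rec$seed + 50
  rec4$target <- rec$target + 200
  expect_equal(fit_ppi_run(rec4)$beta, b0, tolerance = 1e-8)
})

test_that("voxel-mode ROI-mean beta equals the time-series beta", {
  rec <- make_rec(b = 0.4, rng_seed = 11)
  vox <- as_voxel_recording(rec, voxel_noise_sd = 0, rng_seed = 12)
  f_ts <- fit_ppi_run(rec)
  f_vox <- fit_ppi_run(vox)
  expect_equal(f_vox$beta, f_ts$beta, tolerance = 1e-10)
  expect_equal(length(f_vox$voxel_betas), 15)
})

test_that("neural-mode fitting recovers neural-level interactions", {
  sp <- task_spec("FM")
  acq <- acq_for_task(sp)
  ev <- make_task_events(sp)
  sub <- subject_params(a = 1, sigma_seed = 0.05, sigma_target = 0.05)
  rec <- simulate_run(sub, 0.7, events = ev, acq = acq, spec = sp,
                      rng_seed = 13, neural = TRUE)
  fn <- fit_ppi_run(rec, mode = "neural", ridge_penalty = 1e-3)$beta
  expect_equal(fn, 0.7, tolerance = 0.1)
})

test_that("study-level fitting preserves layout, flags, and determinism", {
  cfg <- tiny_config(n_subjects = 29L)
  st <- simulate_study(cfg, rng_seed = 21)
  bt <- run_study_ppi(st)
  expect_equal(nrow(bt), 29 * 4)
  expect_identical(bt, run_study_ppi(st))
  expect_true(all(is.finite(bt$beta[!bt$excluded])))

  # a seed-empty subject is flagged for that seed region only
  cfg2 <- study_config(n_subjects = 4, tasks = "FM",
                       seed_regions = c("lamyg", "ramyg"),
                       mu = list(FM = list(lamyg = 0.5, ramyg = 0.5)),
                       accuracy = c(FM = 1), non_responder = 1L)
  st2 <- simulate_study(cfg2, rng_seed = 22)
  for (key in names(st2$recordings)) {
    if (grepl("seed-lamyg", key)) {
      st2$recordings[[key]] <- as_voxel_recording(
        st2$recordings[[key]], voxel_noise_sd = 0.1,
        rng_seed = seed_stream_test(key))
    }
  }
  bt2 <- run_study_ppi(st2, activation = list(p = 1e-5))
  lam1 <- bt2[bt2$seed == "lamyg" & bt2$subject == 1, ]
  expect_true(all(lam1$excluded))
  expect_true(all(lam1$reason == "seed_empty"))
  ram1 <- bt2[bt2$seed == "ramyg" & bt2$subject == 1, ]
  expect_false(any(ram1$excluded))
})
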