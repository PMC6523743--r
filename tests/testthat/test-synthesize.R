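# Synthetic study generator: coupling draws, analytic ICC, BOLD runs.

test_that("coupling draws respect the declared variance structure", {
  vc <- variance_components(mu = 0.4, sigma_subject2 = 0.5,
                            sigma_day2 = 0, sigma_run2 = 0)
  bt <- sample_coupling_betas(vc, 10, rng_seed = 1)
  # no day/run variance -> all four cells of each subject identical
  spread <- tapply(bt$b, bt$subject, function(x) diff(range(x)))
  expect_true(all(spread == 0))

  expect_identical(sample_coupling_betas(vc, 10, rng_seed = 2),
                   sample_coupling_betas(vc, 10, rng_seed = 2))
  expect_error(variance_components(sigma_subject2 = -1),
               class = "ppirel_config_error")
})

test_that("variance of subject means follows the law of total variance", {
  # with no between-subject component, Var(subject mean) =
  # sigma_day2 / n_days + sigma_run2 / (n_days * n_runs)
  vc <- variance_components(mu = 0, sigma_subject2 = 0, sigma_day2 = 0.6,
                            sigma_run2 = 0.8)
  bt <- sample_coupling_betas(vc, 10000, rng_seed = 3)
  v <- var(tapply(bt$b, bt$subject, mean))
  expect_equal(v, 0.6 / 2 + 0.8 / 4, tolerance = 0.05)
})

test_that("empirical variance decomposition matches the components", {
  vc <- variance_components(mu = 0.2, sigma_subject2 = 0.5,
                            sigma_day2 = 0.3, sigma_run2 = 0.4)
  bt <- sample_coupling_betas(vc, 10000, rng_seed = 4)
  sub_means <- tapply(bt$b, bt$subject, mean)
  day_means <- tapply(bt$b, interaction(bt$subject, bt$day), mean)
  # Var(cell) = s2s + s2d + s2r; Var(day mean) = s2s + s2d + s2r/2;
  # Var(subject mean) = s2s + s2d/2 + s2r/4
  expect_equal(var(bt$b), 1.2, tolerance = 0.05)
  expect_equal(var(day_means), 0.5 + 0.3 + 0.2, tolerance = 0.05)
  expect_equal(var(sub_means), 0.5 + 0.15 + 0.1, tolerance = 0.05)
  expect_equal(mean(bt$b), 0.2, tolerance = 0.05)
})

test_that("true_icc evaluates the stated formulas and orderings", {
  vc0 <- variance_components(mu = 0, sigma_subject2 = 2, sigma_day2 = 0,
                             sigma_run2 = 0)
  expect_equal(true_icc(vc0, "between_day_avg"), 1)
  vc <- variance_components(mu = 0, sigma_subject2 = 1, sigma_day2 = 0.5,
                            sigma_run2 = 1)
  expect_equal(true_icc(vc, "between_day_avg", n_runs_averaged = 2), 0.5)
  expect_equal(true_icc(vc, "between_day_single"), 1 / 2.5)
  expect_equal(true_icc(vc, "within_day"), 1.5 / 2.5)
  # Spearman-Brown step-up for average measures
  expect_equal(true_icc(vc, "between_day_avg", measures = "average"),
               2 * 0.5 / 1.5)
  # within-day >= between-day for any components
  set.seed(5)
  for (i in 1:20) {
    v <- variance_components(mu = 0, sigma_subject2 = runif(1),
                             sigma_day2 = runif(1), sigma_run2 = runif(1))
    expect_gte(true_icc(v, "within_day"), true_icc(v, "between_day_single"))
  }
  expect_error(true_icc(variance_components(0, 0, 0, 0), "within_day"),
               class = "ppirel_config_error")
})

test_that("noise-free runs reduce to the deterministic generative mean", {
  sp <- task_spec("FM")
  acq <- acq_for_task(sp)
  ev <- make_task_events(sp)
  sub <- subject_params(a = 1, lambda = 0, gamma = 0, beta0 = 7,
                       sigma_seed = 0, sigma_target = 0,
                       theta = rep(0, 6))
  rec <- simulate_run(sub, b = 0, events = ev, acq = acq, spec = sp,
                      rng_seed = 1)
  expect_equal(rec$target, rep(7, acq$scans))
  # with b = 1 and target noise off, OLS on the exact design recovers 1
  sub2 <- subject_params(sigma_target = 0)
  rec2 <- simulate_run(sub2, b = 1, events = ev, acq = acq, spec = sp,
                       rng_seed = 2)
  expect_equal(fit_ppi_run(rec2)$beta, 1, tolerance = 1e-8)
})

test_that("seed noise is AR(1) with the requested autocorrelation", {
  x <- ppirel:::ar1_noise(2e5, phi = 0.4, sigma = 1)
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, 0.4, tolerance = 0.02)
  expect_equal(sd(x), 1, tolerance = 0.02)
})

test_that("study layout is complete, reproducible, and honours exclusions", {
  cfg <- study_config(n_subjects = 29, tasks = "GC", seed_regions = "ramyg",
                      mu = list(GC = list(ramyg = -0.25)))
  st <- simulate_study(cfg, rng_seed = 9)
  expect_equal(nrow(st$truth), 29 * 2 * 2)
  expect_equal(length(st$recordings), 29 * 2 * 2)
  st2 <- simulate_study(cfg, rng_seed = 9)
  expect_identical(st$truth, st2$truth)
  k <- names(st$recordings)[5]
  expect_identical(st$recordings[[k]]$target, st2$recordings[[k]]$target)

  excl <- data.frame(subject = c(2, 5), task = "GC")
  st3 <- simulate_study(study_config(n_subjects = 6, tasks = "GC",
                                     seed_regions = "ramyg",
                                     exclusions = excl), rng_seed = 1)
  flagged <- st3$truth[st3$truth$excluded, ]
  expect_setequal(unique(flagged$subject), c(2, 5))
  expect_equal(nrow(flagged), 2 * 4) # cells kept, only marked
})

test_that("sample ICC on latent truth converges to the analytic value", {
  vc <- variance_components(mu = 0, sigma_subject2 = 1, sigma_day2 = 0.25,
                            sigma_run2 = 0.5)
  bt <- sample_coupling_betas(vc, 2000, rng_seed = 12)
  wide <- matrix(NA_real_, 2000, 4)
  idx <- cbind(bt$subject, (bt$day - 1) * 2 + bt$run)
  wide[idx] <- bt$b
  day_means <- cbind((wide[, 1] + wide[, 2]) / 2, (wide[, 3] + wide[, 4]) / 2)
  icc_hat <- icc_consistency(day_means, measures = "single")$icc
  expect_lt(abs(icc_hat - true_icc(vc, "between_day_avg")), 0.02)
  within1 <- icc_consistency(wide[, 1:2], measures = "single")$icc
  expect_lt(abs(within1 - true_icc(vc, "within_day")), 0.03)
})
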