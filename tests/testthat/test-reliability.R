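# Two-way mean squares, consistency ICCs, CIs, bands, battery.

test_that("two-way mean squares match the brute-force decomposition", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    M <- matrix(rnorm(n * k), n, k)
    d <- twoway_mean_squares(M)
    ref <- oracle_mean_squares(M)
    expect_equal(d$BMS, ref$BMS, tolerance = 1e-10)
    expect_equal(d$JMS, ref$JMS, tolerance = 1e-10)
    expect_equal(d$EMS, ref$EMS, tolerance = 1e-10)
    # SS identity
    ss <- (n - 1) * d$BMS + (k - 1) * d$JMS +
      (n - 1) * (k - 1) * d$EMS
    expect_equal(ss, sum((M - mean(M))^2), tolerance = 1e-8)
  }
})

test_that("column shifts are absorbed by the session effect", {
  set.seed(42)
  M <- matrix(rnorm(12), 6, 2)
  d0 <- twoway_mean_squares(M)
  M2 <- M
  M2[, 2] <- M2[, 2] + 3.7
  d1 <- twoway_mean_squares(M2)
  expect_equal(d1$BMS, d0$BMS, tolerance = 1e-10)
  expect_equal(d1$EMS, d0$EMS, tolerance = 1e-10)
  expect_gt(d1$JMS, d0$JMS)
})

test_that("additive-shift structure gives EMS 0 and ICC exactly 1", {
  M <- cbind(1:4, 2:5)
  d <- twoway_mean_squares(M)
  expect_equal(d$EMS, 0, tolerance = 1e-14)
  for (meas in c("single", "average")) {
    res <- icc_consistency(d, measures = meas)
    expect_equal(res$icc, 1)
    expect_equal(res$ci, c(1, 1))
    expect_equal(res$p, 0)
    expect_true(res$degenerate)
  }
  expect_error(icc_consistency(matrix(5, 4, 2)),
               class = "ppirel_config_error")
})

test_that("ICC, F, p and CI match the quantile-based oracle", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(5:29, 1); k <- sample(2:3, 1)
    M <- matrix(rnorm(n * k, sd = runif(1, 0.5, 2)), n, k) +
      rnorm(n) # subject effect
    for (meas in c("single", "average")) {
      res <- icc_consistency(M, measures = meas)
      ref <- oracle_icc(M, measures = meas)
      expect_equal(res$icc, ref$icc, tolerance = 1e-10)
      expect_equal(res$F, ref$F, tolerance = 1e-10)
      expect_equal(res$p, ref$p, tolerance = 1e-10)
      expect_equal(res$ci, ref$ci, tolerance = 1e-10)
    }
  }
})

test_that("weak-reliability instances yield negative CI lower bounds", {
  set.seed(44)
  M <- matrix(rnorm(18 * 2), 18, 2) # no subject effect: ICC near 0
  res <- icc_consistency(M, measures = "single")
  expect_lt(res$ci[1], 0)
  expect_lte(res$icc, 1)
  expect_true(res$ci[1] <= res$icc && res$icc <= res$ci[2])
})

test_that("ICC is invariant under column shifts and global affine scaling", {
  set.seed(45)
  M <- matrix(rnorm(20 * 2), 20, 2) + rnorm(20)
  base <- icc_consistency(M, measures = "single")$icc
  shifted <- M
  shifted[, 1] <- shifted[, 1] + 2.2
  shifted[, 2] <- shifted[, 2] - 0.7
  expect_equal(icc_consistency(shifted, measures = "single")$icc, base,
               tolerance = 1e-10)
  expect_equal(icc_consistency(5 * M + 11, measures = "single")$icc, base,
               tolerance = 1e-10)
})

test_that("single measures never exceed average measures when positive", {
  set.seed(46)
  for (rep in 1:25) {
    M <- matrix(rnorm(10 * 2), 10, 2) + rnorm(10, sd = runif(1, 0, 2))
    s <- icc_consistency(M, measures = "single")$icc
    a <- icc_consistency(M, measures = "average")$icc
    if (s >= 0 && a >= 0) expect_lte(s, a + 1e-12)
  }
})

test_that("interpretation bands follow the conventional cut points", {
  expect_equal(classify_icc(0.39), "poor")
  expect_equal(classify_icc(0.4), "moderate-to-good")
  expect_equal(classify_icc(0.75), "moderate-to-good")
  expect_equal(classify_icc(0.76), "excellent")
  expect_equal(classify_icc(0.832), "excellent")
  expect_equal(classify_icc(-0.3), "poor")
})

test_that("the battery yields five cells with the expected structure", {
  vc <- variance_components(mu = 0.5, sigma_subject2 = 0.09,
                            sigma_day2 = 0.01, sigma_run2 = 0)
  bt <- latent_beta_table(vc, n_subjects = 200, rng_seed = 47)
  rel <- reliability_battery(bt)
  expect_equal(nrow(rel), 5)
  expect_setequal(rel$cell,
                  c("between_day_both_runs", "between_day_run1",
                    "between_day_run2", "within_day_day1",
                    "within_day_day2"))
  expect_true(all(rel$analysed))
  # sigma_run2 = 0: within-day ICCs are exactly 1 (runs identical)
  within <- rel[grepl("within", rel$cell), ]
  expect_equal(within$icc, c(1, 1))
  # between-day single-measures ICCs near the analytic truth
  bd <- rel[rel$cell == "between_day_run1", ]
  expect_lt(abs(bd$icc_single - true_icc(vc, "between_day_single")), 0.1)
})

test_that("gating marks null seeds not analysed; tiny cells not computable", {
  vc_null <- variance_components(mu = 0, sigma_subject2 = 0.09,
                                 sigma_day2 = 0.03, sigma_run2 = 0.04)
  bt <- latent_beta_table(vc_null, n_subjects = 29, rng_seed = 48)
  rel <- reliability_battery(bt, gate = TRUE)
  expect_true(all(!rel$analysed))
  expect_true(all(grepl("not analysed", rel$note)))
  # gate off: computed anyway
  rel2 <- reliability_battery(bt, gate = FALSE)
  expect_true(all(rel2$analysed))

  bt_small <- latent_beta_table(variance_components(mu = 1, 0.1, 0, 0),
                                n_subjects = 2, rng_seed = 49)
  rel3 <- reliability_battery(bt_small, gate = FALSE)
  expect_true(all(!rel3$analysed))
  expect_true(all(grepl("not computable", rel3$note)))
})

test_that("battery cells drop incomplete subjects independently", {
  vc <- variance_components(mu = 0.5, 0.09, 0.03, 0.04)
  bt <- latent_beta_table(vc, n_subjects = 20, rng_seed = 50)
  # remove subject 1's day-2 cells: between-day cells lose one subject,
  # within-day-1 keeps all 20
  bt <- bt[!(bt$subject == 1 & bt$day == 2), ]
  rel <- reliability_battery(bt, gate = FALSE)
  expect_equal(rel$n[rel$cell == "between_day_both_runs"], 19)
  expect_equal(rel$n[rel$cell == "within_day_day1"], 20)
})
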