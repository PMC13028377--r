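# Agreement battery: bias/LOA, RMSE, ICC(3,1), CMD, bands, heatmap.

test_that("bias, random error and LOA follow the Bland-Altman construction", {
  s0 <- paired_sample(c(1, 2, 3), c(1, 2, 3))
  r0 <- bias_loa(s0)
  expect_equal(r0$bias, 0)
  expect_equal(r0$random_error, 0)
  expect_equal(c(r0$loa_low, r0$loa_high), c(0, 0))

  # hand-checked: differences {0.1, -0.1, 0.3, -0.3}, n-1 SD
  s <- paired_sample(c(0.1, -0.1, 0.3, -0.3), c(0, 0, 0, 0))
  r <- bias_loa(s, round_dp = NULL)
  expect_equal(r$bias, 0)
  expect_equal(r$random_error, 1.96 * sqrt(0.2 / 3), tolerance = 1e-12)
  expect_equal(r$random_error, 0.5061, tolerance = 1e-4)
  expect_equal(rmse_paired(s), sqrt(0.05), tolerance = 1e-12)

  # pure-bias case: RMSE equals the bias
  sb <- paired_sample(c(1.2, 2.2, 3.2), c(1, 2, 3))
  expect_equal(rmse_paired(sb), 0.2, tolerance = 1e-12)

  expect_error(paired_sample(1, 1))
})

test_that("RMSE and LOA identities hold on arbitrary samples", {
  set.seed(77)
  for (k in 1:20) {
    n <- sample(3:30, 1)
    s <- paired_sample(rnorm(n, 5), rnorm(n, 5), "toy")
    row <- bias_loa(s, round_dp = NULL)
    d <- s$ref - s$alt
    # rmse^2 = bias^2 + population variance of d
    expect_equal(rmse_paired(s)^2,
                 row$bias^2 + ((n - 1) / n) * (row$random_error / 1.96)^2,
                 tolerance = 1e-12)
    expect_equal(row$loa_high - row$loa_low, 2 * row$random_error,
                 tolerance = 1e-12)
    expect_gte(rmse_paired(s), abs(mean(d)) - 1e-12)
  }
})

test_that("LOA inputs are rounded to 3 decimals by convention", {
  s <- paired_sample(c(1.0004, 2.0004), c(1.0001, 2.0001))
  expect_equal(bias_loa(s, round_dp = 3)$bias, 0)          # rounds away
  expect_equal(bias_loa(s, round_dp = NULL)$bias, 3e-4, tolerance = 1e-12)
})

test_that("ICC(3,1) is exact on its invariances and matches the ANOVA oracle", {
  ref <- c(10, 12, 14, 16, 11)
  expect_equal(icc_3_1(paired_sample(ref, ref)), 1)
  expect_equal(icc_3_1(paired_sample(ref, ref + 3)), 1)    # fixed shift ignored

  set.seed(123)
  for (k in 1:200) {
    n <- sample(3:12, 1)
    r <- rnorm(n, 10, sample(c(0.5, 2), 1))
    a <- r + rnorm(n, sd = 0.5) + rnorm(1)
    s <- paired_sample(r, a)
    expect_equal(icc_3_1(s), icc_oracle_aov(r, a), tolerance = 1e-12)
  }

  expect_warning(out <- icc_3_1(paired_sample(c(1, 1, 1), c(1, 1, 1))),
                 "zero between-trial")
  expect_true(is.na(out))
  expect_error(icc_3_1(paired_sample(c(1, 2), c(1, 2))), "at least 3")
})

test_that("CMD measures shape and ignores amplitude", {
  x <- sin(seq(0, 4 * pi, length.out = 200))
  expect_equal(cmd(x, x), 1, tolerance = 1e-12)
  expect_equal(cmd(x, 2 * x + 3), 1, tolerance = 1e-12)
  expect_equal(cmd(x, -0.5 * x + 1), 1, tolerance = 1e-12)

  # matches the regression R-squared oracle
  set.seed(9)
  y <- x + rnorm(200, sd = 0.3)
  expect_equal(cmd(x, y), summary(lm(y ~ x))$r.squared, tolerance = 1e-12)

  # independent white noise: near zero
  set.seed(10)
  expect_lt(cmd(rnorm(1000), rnorm(1000)), 0.01)

  expect_warning(out <- cmd(rep(1, 10), rnorm(10)), "zero-variance")
  expect_true(is.na(out))
})

test_that("interpretation bands use the published cut-points, upper-inclusive", {
  expect_equal(interpret_agreement(0.898), "good")
  expect_equal(interpret_agreement(0.90), "excellent")
  expect_equal(interpret_agreement(-0.1), "poor")
  expect_equal(interpret_agreement(c(0.2, 0.5, 0.749, 0.75, 1)),
               c("poor", "moderate", "moderate", "good", "excellent"))
})

test_that("heatmap values are the negated bias, per the ML-minus-REF convention", {
  ref <- data.frame(trial_id = c("a", "b", "c"), variable = "v", units = "m",
                    value = c(1, 2, 3))
  alt <- data.frame(trial_id = c("a", "b", "c"), variable = "v", units = "m",
                    value = c(1.5, 2.5, 3.5))
  hm <- heatmap_values(ref, alt)
  expect_equal(hm$mean_difference, 0.5)
  row <- bias_loa(paired_sample(ref$value, alt$value))
  expect_equal(hm$mean_difference, -row$bias)
  expect_equal(heatmap_values(ref, ref)$mean_difference, 0)

  alt_bad <- alt; alt_bad$variable <- "other"
  expect_error(heatmap_values(ref, alt_bad), "unmatched")
})

test_that("waveform agreement aggregates per-trial CMD and enforces windows", {
  gt <- default_truth("male")
  ev <- detect_events(gt$trial, pole_plant = gt$events$pole_plant)
  mk <- function(trial) {
    extract_waveforms(whole_body_cm(trial, segmental_table("male")),
                      joint_angles(trial), ev)
  }
  wr <- list(mk(gt$trial), mk(gt$trial))
  wa <- list(mk(degrade_as_method(gt, noise_sd = 0.001, seed = 1)),
             mk(degrade_as_method(gt, noise_sd = 0.001, seed = 2)))
  res <- waveform_agreement(wr, wa, "cm_z")
  expect_length(res$cmd_per_trial, 2)
  expect_gt(res$cmd_mean, 0.99)
  expect_equal(res$band, "excellent")
})
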