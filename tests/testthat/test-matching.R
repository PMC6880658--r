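labeled_confounded <- function(n = 776, seed = 1) {
  sp <- split_by_anxiety(preset_cohort(n, "confounded_anxiety", seed = seed))
  rbind(sp$low, sp$high)
}

test_that("the null propensity model returns the group prevalence", {
  co <- preset_cohort(300, seed = 2)
  co$group <- rep(c("low_anxiety", "high_anxiety"), length.out = 300)
  # same covariate distributions in both groups up to noise: fitted values
  # must hover at the prevalence
  ps <- fit_propensity(co)
  expect_equal(unname(mean(ps)), 0.5, tolerance = 1e-6)
  expect_lt(sd(ps), 0.1)
})

test_that("logistic coefficients match a brute-force likelihood oracle", {
  set.seed(44)
  x <- round(rnorm(20), 2)
  y <- rbinom(20, 1, plogis(0.5 + 0.8 * x))
  df <- tiny_cohort_df()[rep(1, 20), ]
  df$subject_id <- sprintf("s%02d", 1:20)
  df$age <- 70 + x  # single informative covariate
  df$group <- ifelse(y == 1, "high_anxiety", "low_anxiety")
  co <- as_cohort_table(df)
  ps <- fit_propensity(co, match_config(covariates = "age"))
  nll <- function(b) -sum(y * log(plogis(b[1] + b[2] * x)) +
                            (1 - y) * log(1 - plogis(b[1] + b[2] * x)))
  oracle <- stats::optim(c(0, 0), nll, method = "BFGS")$par
  expect_equal(unname(qlogis(ps)), oracle[1] + oracle[2] * (70 + x - 70),
               tolerance = 1e-3)
})

test_that("a strongly shifted covariate separates the groups", {
  set.seed(46)
  df <- tiny_cohort_df()[rep(1, 400), ]
  df$subject_id <- sprintf("s%03d", 1:400)
  grp <- rep(c(0, 1), each = 200)
  df$age <- 74 + 2 * grp + rnorm(400)  # 2-SD shift
  df$group <- ifelse(grp == 1, "high_anxiety", "low_anxiety")
  co <- as_cohort_table(df)
  ps <- fit_propensity(co, match_config(covariates = "age"))
  # AUC by rank statistic
  r <- rank(ps)
  auc <- (sum(r[grp == 1]) - 200 * 201 / 2) / (200 * 200)
  expect_gt(auc, 0.9)
})

test_that("greedy matching follows the hand-enumerated order and caliper", {
  df <- tiny_cohort_df()[rep(1, 5), ]
  df$subject_id <- c("t1", "t2", "c1", "c2", "c3")
  df$group <- c("high_anxiety", "high_anxiety", rep("low_anxiety", 3))
  co <- as_cohort_table(df)
  ps <- setNames(c(0.8, 0.6, 0.79, 0.61, 0.2), df$subject_id)
  cfg <- match_config(caliper = 10, caliper_scale = "raw")
  res <- match_cohort(co, ps, cfg)
  expect_equal(res$n_matched, 2)
  expect_equal(res$pairs$treated_id, c("t1", "t2"))
  expect_equal(res$pairs$control_id, c("c1", "c2"))

  # a treated unit beyond the caliper from every control is discarded
  ps2 <- setNames(c(0.99, 0.6, 0.55, 0.61, 0.2), df$subject_id)
  cfg2 <- match_config(caliper = 0.5, caliper_scale = "raw")
  res2 <- match_cohort(co, ps2, cfg2)
  expect_equal(res2$n_matched, 1)
  expect_equal(res2$pairs$treated_id, "t2")
  expect_true(all(res2$pairs$distance <= res2$caliper_used))
})

test_that("matching balances the confounded preset and respects its invariants", {
  lab <- labeled_confounded(seed = 51)
  res <- match_cohort(lab)
  n_low <- sum(lab$group == "low_anxiety")
  n_high <- sum(lab$group == "high_anxiety")
  expect_lte(res$n_matched, min(n_low, n_high))
  expect_false(any(duplicated(c(res$pairs$treated_id, res$pairs$control_id))))
  lp <- qlogis(res$propensity)
  d <- abs(lp[res$pairs$treated_id] - lp[res$pairs$control_id])
  expect_true(all(d <= res$caliper_used + 1e-12))
  bal <- res$balance
  expect_lt(mean(abs(bal$smd_after)), mean(abs(bal$smd_before)))
  smd_m <- bal[bal$covariate == "madrs_sum", ]
  expect_lt(abs(smd_m$smd_after), abs(smd_m$smd_before) / 2)
})
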