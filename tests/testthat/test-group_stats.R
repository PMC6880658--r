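test_that("summary-based Welch equals the raw-data Welch test exactly", {
  set.seed(61)
  x <- rnorm(40, 1, 2)
  y <- rnorm(55, 0.4, 1.5)
  gc <- ttest_from_summary(mean(x), sd(x), length(x),
                           mean(y), sd(y), length(y))
  ht <- t.test(x, y)  # Welch by default
  expect_equal(gc$statistic, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(gc$df, unname(ht$parameter), tolerance = 1e-12)
  expect_equal(gc$p_value, ht$p.value, tolerance = 1e-12)

  same <- ttest_from_summary(1.2, 0.5, 30, 1.2, 0.5, 30)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("the Welch p-value matches a quadrature oracle on the t density", {
  gc <- ttest_from_summary(0, 1, 1000, 0.1, 1, 1000)
  oracle <- 2 * stats::integrate(function(u) stats::dt(u, gc$df),
                                 abs(gc$statistic), Inf)$value
  expect_equal(gc$p_value, oracle, tolerance = 1e-3)
})

test_that("two-proportion tests are symmetric and handle degenerate margins", {
  a <- two_proportion_test(30, 100, 45, 120)
  b <- two_proportion_test(45, 120, 30, 100)
  expect_equal(a$p_value, b$p_value)
  # swapping success/failure labels
  c_ <- two_proportion_test(70, 100, 75, 120)
  expect_equal(a$p_value, c_$p_value)

  eq <- two_proportion_test(25, 80, 25, 80)
  expect_equal(eq$p_value, 1)
  deg <- two_proportion_test(0, 50, 0, 60)
  expect_equal(deg$p_value, 1)
  expect_false(is.na(deg$flag))
})

test_that("paired t matches hand arithmetic and has the expected power", {
  x <- c(4, 6, 5, 7)
  y <- c(3, 6, 4, 5)
  gc <- paired_ttest(x, y)
  d <- x - y  # 1, 0, 1, 2
  t_hand <- mean(d) / (sd(d) / 2)
  expect_equal(gc$statistic, t_hand)
  expect_equal(gc$df, 3)
  expect_equal(gc$p_value, 2 * pt(-abs(t_hand), 3))
  expect_equal(gc$p_value, t.test(x, y, paired = TRUE)$p.value,
               tolerance = 1e-12)

  ident <- paired_ttest(x, x)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  set.seed(63)
  rejections <- sum(replicate(200, {
    d <- rnorm(199, 0.5, 1)
    paired_ttest(d, rep(0, 199))$p_value < 0.05
  }))
  expect_gte(rejections, 198)
})

test_that("the demographic report covers both phases with sensible tests", {
  sp <- split_by_anxiety(preset_cohort(776, "confounded_anxiety", seed = 71))
  tab <- table2_report(sp$low, sp$high)
  expect_true(all(tab$phase == "before"))
  expect_lt(tab$p_value[tab$variable == "madrs_sum"], 0.05)
  expect_lt(tab$p_value[tab$variable == "bai_sum"], 0.05)
  expect_equal(tab$test[tab$variable == "sex_female"], "two_proportion_cc")

  lab <- rbind(sp$low, sp$high)
  res <- match_cohort(lab)
  tab2 <- table2_report(sp$low, sp$high, matched = res, cohort = lab)
  after <- tab2[tab2$phase == "after", ]
  expect_equal(unique(after$test[after$variable == "madrs_sum"]), "paired_t")
  # matching shrinks the severity gap
  gap_before <- with(tab[tab$variable == "madrs_sum", ],
                     mean_high - mean_low)
  gap_after <- with(after[after$variable == "madrs_sum", ],
                    mean_high - mean_low)
  expect_lt(abs(gap_after), abs(gap_before) / 2)

  ident <- table2_report(sp$low, sp$low)
  expect_true(all(ident$p_value == 1))
})
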