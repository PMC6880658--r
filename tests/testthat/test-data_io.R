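test_that("cohort round-trips through CSV field-for-field", {
  co <- as_cohort_table(tiny_cohort_df())
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co))

  co2 <- preset_cohort(50, seed = 7)  # includes b1..b21 items
  write_cohort(co2, path)
  expect_equal(as.data.frame(read_cohort(path)), as.data.frame(co2))
})

test_that("validation rejects out-of-range, inconsistent and malformed tables", {
  df <- tiny_cohort_df()
  df$m3[2] <- 7L
  expect_error(as_cohort_table(df), "0\\.\\.6")

  df <- tiny_cohort_df()
  df$bai_sum[1] <- 70L
  expect_error(as_cohort_table(df), "0\\.\\.63")

  # BAI items must sum to bai_sum
  df <- as.data.frame(preset_cohort(20, seed = 3))
  df$b1[5] <- df$b1[5] + 1L
  expect_error(as_cohort_table(df), "does not equal the sum")

  df <- tiny_cohort_df()
  df$subject_id[2] <- "a"
  expect_error(as_cohort_table(df), "duplicate")

  df <- tiny_cohort_df()
  df$m5[1] <- NA
  expect_error(as_cohort_table(df), "complete-case")

  expect_error(as_cohort_table(tiny_cohort_df()[, -3]), "missing required")
})

test_that("eligibility keeps MADRS >= cutoff inclusively and drops flagged subjects", {
  df <- tiny_cohort_df()
  df[paste0("m", 1:10)] <- 1L  # sum = 10, exactly at the cutoff
  df$flags <- ""
  co <- as_cohort_table(df)
  kept <- suppressMessages(apply_eligibility(co))
  expect_equal(nrow(kept), 3)

  df[paste0("m", 1:9)] <- 1L
  df$m10 <- 0L  # sum = 9, just below
  co <- as_cohort_table(df)
  expect_warning(suppressMessages(kept <- apply_eligibility(co)),
                 "every subject")
  expect_equal(nrow(kept), 0)
})

test_that("the printed participant flow is reproduced from a flagged pool", {
  pool <- generate_eligible_pool(848, seed = 11)
  kept <- suppressMessages(apply_eligibility(pool))
  expect_equal(nrow(kept), 776)
  removed <- attr(kept, "removed")
  expect_equal(unname(removed[["bipolar"]]), 5)
  expect_equal(unname(removed[["schizophrenia"]]), 8)
  expect_equal(unname(removed[["other_mental_disorder"]]), 59)
  # idempotence
  kept2 <- suppressMessages(apply_eligibility(kept))
  expect_equal(as.data.frame(kept2), as.data.frame(kept),
               ignore_attr = TRUE)
  expect_equal(sum(attr(kept2, "removed")), 0)
})

test_that("anxiety split partitions at BAI >= 16 inclusively", {
  df <- tiny_cohort_df()
  df$bai_sum <- c(15L, 16L, 17L)
  co <- as_cohort_table(df)
  sp <- split_by_anxiety(co)
  expect_equal(sp$low$subject_id, "a")
  expect_setequal(sp$high$subject_id, c("b", "c"))
  expect_equal(nrow(sp$low) + nrow(sp$high), nrow(co))
  expect_length(intersect(sp$low$subject_id, sp$high$subject_id), 0)
  expect_true(all(sp$high$group == "high_anxiety"))
})

test_that("preset BAI split reproduces the study's group-size proportions", {
  # calibrated P(BAI >= 16) = 314/776; binomial 99.9% band at n = 776
  co <- preset_cohort(776, seed = 5)
  sp <- split_by_anxiety(co)
  n_high <- nrow(sp$high)
  expect_equal(n_high + nrow(sp$low), 776)
  band <- 314 + c(-1, 1) * 3.29 * sqrt(776 * (314 / 776) * (462 / 776))
  expect_gt(n_high, band[1])
  expect_lt(n_high, band[2])
})
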