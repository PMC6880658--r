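test_that("generation is bit-reproducible given the spec", {
  spec <- preset_lld("baseline_lld", n_subjects = 200, seed = 9)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_identical(as.data.frame(g1$cohort), as.data.frame(g2$cohort))
  expect_identical(g1$gold$true_anxiety_values, g2$gold$true_anxiety_values)
})

test_that("gold truth matches the precision matrix and the seeded pattern", {
  spec <- preset_lld("baseline_lld")
  gold <- generate_cohort(spec)$gold
  K <- spec$precision_matrix
  P <- gold$true_partial_correlations
  expect_equal(diag(P), rep(0, 10), ignore_attr = TRUE)
  expect_equal(P[1, 2], -K[1, 2] / sqrt(K[1, 1] * K[2, 2]))
  # vegetative nodes (reduced_sleep, reduced_appetite) touch the rest of the
  # network only through the seeded sleep-pessimism edge
  veg <- c(4, 5)
  cross <- P[veg, -veg]
  expect_equal(sum(cross != 0), 1)
  expect_lt(P[4, 9], 0)
})

test_that("a non-positive-definite precision matrix is rejected before sampling", {
  K <- diag(10)
  K[1, 2] <- K[2, 1] <- 1.2
  expect_error(custom_spec(K), "positive definite")
  expect_error(preset_lld("no_such_preset"), "baseline_lld")
})

test_that("independent latent symptoms yield near-zero polychoric estimates", {
  co <- generate_cohort(custom_spec(diag(10), n = 10000, seed = 21))$cohort
  S <- association_matrix(co)$values
  expect_lt(max(abs(S[upper.tri(S)])), 0.05)
})

test_that("a single seeded partial correlation is recovered through the ordinal layer", {
  # nodes 1-2 carry pcor 0.4 and are independent of the rest; the implied
  # latent correlation of the pair is exactly 0.4 (2x2 block inverse)
  K <- diag(10)
  K[1, 2] <- K[2, 1] <- -0.4
  co <- generate_cohort(custom_spec(K, n = 5000, seed = 13))$cohort
  items <- item_matrix(co)
  expect_equal(polychoric(items[, 1], items[, 2]), 0.4, tolerance = 0.05)
})

test_that("item margins follow the threshold-implied multinomial", {
  spec <- preset_lld("baseline_lld", n_subjects = 20000, seed = 31)
  co <- generate_cohort(spec)$cohort
  expected <- diff(c(0, pnorm(spec$item_thresholds[[1]]), 1))
  for (j in c(1, 6)) {
    obs <- tabulate(co[[paste0("m", j)]] + 1L, nbins = 7)
    pval <- suppressWarnings(stats::chisq.test(obs, p = expected)$p.value)
    expect_gt(pval, 0.001)
  }
})

test_that("severity confounding shifts MADRS with anxiety and is monotone in the shift", {
  co_conf <- preset_cohort(776, "confounded_anxiety", seed = 17)
  sp <- split_by_anxiety(co_conf)
  gap <- mean(madrs_sum(sp$high)) - mean(madrs_sum(sp$low))
  expect_gt(gap, 2.5)
  expect_lt(ttest_welch(madrs_sum(sp$low), madrs_sum(sp$high))$p_value, 0.05)

  cor_at_shift <- function(s) {
    spec <- preset_lld("baseline_lld", n_subjects = 3000, seed = 23)
    spec$severity_shift <- s
    co <- generate_cohort(spec)$cohort
    cor(madrs_sum(co), co$bai_sum)
  }
  cors <- vapply(c(0, 0.12, 0.3), cor_at_shift, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("null_two_group draws both arms from one generating process", {
  gr <- generate_null_groups(preset_lld("null_two_group"), 100, seed = 3)
  expect_equal(nrow(gr$a), 100)
  expect_equal(nrow(gr$b), 100)
  expect_length(intersect(gr$a$subject_id, gr$b$subject_id), 0)
})
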