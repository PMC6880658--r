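test_that("the bivariate normal CDF matches a high-precision quadrature oracle", {
  set.seed(5)
  for (i in 1:50) {
    h <- runif(1, -3, 3)
    k <- runif(1, -3, 3)
    r <- runif(1, -0.99, 0.99)
    oracle <- mvtnorm::pmvnorm(upper = c(h, k),
                               corr = matrix(c(1, r, r, 1), 2),
                               algorithm = mvtnorm::Miwa(steps = 2049))[1]
    expect_equal(lldnet:::.pbvnorm_cpp(h, k, r), oracle, tolerance = 1e-8)
  }
})

test_that("two-step ML agrees with the tetrachoric closed form on balanced tables", {
  # for symmetric 2x2 tables both margins put the threshold at 0 and the
  # closed form cos(pi / (1 + sqrt(ad/bc))) is exact
  for (tab in list(matrix(c(100, 50, 50, 100), 2),
                   matrix(c(200, 20, 20, 200), 2),
                   matrix(c(80, 80, 80, 80), 2))) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    closed <- cos(pi / (1 + sqrt(a * d / (b * c))))
    expect_equal(polychoric_table(tab), closed, tolerance = 0.01)
  }
})

test_that("polychoric is symmetric in its arguments", {
  set.seed(8)
  for (i in 1:5) {
    x <- sample(0:4, 400, replace = TRUE)
    y <- pmin(4, pmax(0, x + sample(-1:1, 400, replace = TRUE)))
    expect_equal(polychoric(x, y), polychoric(y, x), tolerance = 1e-5)
  }
})

test_that("polychoric hits the perfect-association and independence limits", {
  set.seed(12)
  z <- rnorm(2000)
  th <- qnorm(cumsum(rep(1 / 7, 6)))
  x <- findInterval(z, th)
  y_relab <- c(0, 0, 1, 2, 3, 3, 4)[x + 1]  # deterministic monotone relabeling
  expect_gte(polychoric(x, y_relab), 0.99)

  x_ind <- sample(0:6, 5000, replace = TRUE)
  y_ind <- sample(0:6, 5000, replace = TRUE)
  expect_lt(abs(polychoric(x_ind, y_ind)), 0.05)

  expect_error(polychoric(rep(1L, 100), sample(0:3, 100, replace = TRUE)),
               "single-category")
})

test_that("polyserial recovers latent correlations", {
  set.seed(19)
  th <- qnorm(cumsum(c(0.16, 0.19, 0.20, 0.17, 0.12, 0.09, 0.07))[1:6])
  z <- rnorm(5000)
  x <- findInterval(z, th)
  expect_gte(polyserial(x, z), 0.95)          # y IS the generating latent
  expect_lt(abs(polyserial(x, rnorm(5000))), 0.05)

  # dichotomous x cut at 0, latent correlation 0.5
  set.seed(20)
  n <- 10000
  u <- rnorm(n)
  y <- 0.5 * u + sqrt(1 - 0.25) * rnorm(n)
  x2 <- as.integer(u > 0)
  expect_equal(polyserial(x2, y), 0.5, tolerance = 0.05)

  expect_error(polyserial(x2, rep(1, n)), "constant")
})

test_that("association_matrix recovers the latent correlations of the generator", {
  g <- generate_cohort(preset_lld("baseline_lld", 2000, seed = 3))
  A <- association_matrix(g$cohort)
  latent <- cov2cor(solve(g$gold$spec$precision_matrix))
  expect_lt(max(abs(A$values - latent)), 0.07)
  expect_equal(diag(A$values), rep(1, 10), ignore_attr = TRUE)
  expect_equal(A$values, t(A$values))
  expect_false(A$psd_repaired)
  expect_true(all(A$method_per_pair[upper.tri(A$values)] == "polychoric"))
})

test_that("a decoupled anxiety node shows no association with the items", {
  co <- preset_cohort(5000, seed = 29)  # baseline preset: zero loadings
  A <- association_matrix(co, include_anxiety_node = TRUE)
  expect_equal(A$labels[11], "anxiety")
  expect_true(all(A$method_per_pair[11, -11] == "polyserial"))
  expect_lt(max(abs(A$values[11, 1:10])), 0.05)
})

test_that("indefinite matrices are repaired by eigenvalue clipping", {
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- 0.9
  S[1, 3] <- S[3, 1] <- 0.9
  S[2, 3] <- S[3, 2] <- -0.6  # indefinite triple
  expect_lt(min(eigen(S, symmetric = TRUE)$values), -1e-8)
  R <- nearest_psd(S)
  expect_gte(min(eigen(R, symmetric = TRUE)$values), -1e-8)
  expect_equal(diag(R), rep(1, 3))
  expect_lt(max(abs(R)), 1 + 1e-12)
})
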