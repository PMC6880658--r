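test_that("the penalty path boundaries behave: empty at lambda_max, dense at lambda_min", {
  A <- fake_assoc(diag(10), n = 500)
  path <- glasso_path(A)
  expect_true(all(path$n_edges == 0))  # independence in, no edges out

  S <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3)
  path3 <- glasso_path(fake_assoc(S, n = 500))
  expect_equal(path3$n_edges[1], 0)  # lambda_max kills every edge
})

test_that("a 3-node chain recovers its closed-form partial correlations", {
  # r13 = r12 * r23 means the 1-3 partial correlation is exactly zero; the
  # oracle for the others is the matrix inverse at vanishing penalty
  S <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3)
  cfg <- glasso_config(lambda_min_ratio = 0.001)
  net <- select_ebic(glasso_path(fake_assoc(S, n = 100000), config = cfg),
                     config = cfg)
  oracle <- lldnet:::precision_to_pcor(solve(S))
  expect_lt(abs(net$weights[1, 3]), 0.02)
  expect_equal(net$weights[1, 2], oracle[1, 2], tolerance = 0.02)
  expect_equal(net$weights[2, 3], oracle[2, 3], tolerance = 0.02)
  expect_equal(oracle[1, 2], 0.4472, tolerance = 1e-4)
})

test_that("two-node problems match the closed-form soft-threshold solution", {
  for (s in c(0.6, -0.45, 0.2)) {
    S <- matrix(c(1, s, s, 1), 2)
    path <- glasso_path(fake_assoc(S, n = 1000),
                        config = glasso_config(n_lambda = 20))
    for (l in seq_along(path$lambdas)) {
      lam <- path$lambdas[l]
      w12 <- sign(s) * max(abs(s) - lam, 0)  # glasso covariance off-diagonal
      Wcf <- matrix(c(1, w12, w12, 1), 2)
      K_oracle <- solve(Wcf)
      expect_equal(path$precision[, , l], K_oracle, tolerance = 1e-4,
                   ignore_attr = TRUE)
    }
  }
})

test_that("EBIC at gamma 0 is BIC and ties resolve toward sparsity", {
  A <- fake_assoc(matrix(c(1, .4, .4, 1), 2), n = 300)
  cfg <- glasso_config()
  path <- glasso_path(A, config = cfg)
  net <- select_ebic(path, config = cfg)
  bic <- -2 * path$loglik + path$n_edges * log(path$n)
  expect_equal(net$ebic, min(bic))
  expect_equal(net$lambda_selected,
               path$lambdas[which(bic <= min(bic) + 1e-9)[1]])
})

test_that("BIC removes the spurious edge of two independent variables", {
  set.seed(41)
  x <- sample(0:6, 1000, replace = TRUE)
  y <- sample(0:6, 1000, replace = TRUE)
  r <- polychoric(x, y)
  S <- matrix(c(1, r, r, 1), 2)
  cfg <- glasso_config()
  net <- select_ebic(glasso_path(fake_assoc(S, n = 1000), config = cfg),
                     config = cfg)
  expect_equal(net$weights[1, 2], 0)
})

test_that("selected networks are symmetric, zero-diagonal, sign-consistent and reproducible", {
  co <- preset_cohort(400, seed = 19)
  A <- association_matrix(co)
  cfg <- glasso_config()
  net <- select_ebic(glasso_path(A, config = cfg), config = cfg)
  W <- net$weights
  expect_equal(W, t(W), tolerance = 1e-8)
  expect_equal(diag(W), rep(0, 10), ignore_attr = TRUE)
  expect_true(all(abs(W) < 1))
  # same association in, bit-identical network out
  net2 <- select_ebic(glasso_path(A, config = cfg), config = cfg)
  expect_identical(net$weights, net2$weights)
  expect_identical(net$lambda_selected, net2$lambda_selected)
  # edge sign is the negated precision sign
  path <- glasso_path(A, config = cfg)
  best <- which(path$lambdas == net$lambda_selected)
  K <- path$precision[, , best]
  off <- upper.tri(K)
  expect_true(all(sign(W[off]) == -sign(K[off])))
  expect_equal(net$cluster_tags[4], "vegetative")
})

test_that("network files round-trip the weight matrix", {
  co <- preset_cohort(300, seed = 23)
  net <- estimate_network(co)
  stem <- withr::local_tempfile()
  write_network(net, stem)
  m <- read.csv(paste0(stem, "_matrix.csv"), check.names = FALSE)
  expect_equal(as.matrix(m[, -1]), net$weights, ignore_attr = TRUE)
  js <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(js$lambda_selected, net$lambda_selected)
  el <- read.csv(paste0(stem, "_edges.csv"))
  expect_equal(nrow(el), sum(net$weights[upper.tri(net$weights)] != 0))
})
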