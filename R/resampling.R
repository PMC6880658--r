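# Nonparametric bootstrap of edge weights and case-dropping stability of
# centrality, re-running the full polychoric + graphical lasso + EBIC chain
# per resample.

refit_network <- function(cohort, config, include_anxiety_node = FALSE) {
  estimate_network(cohort, config, include_anxiety_node)
}

#' Bootstrap confidence intervals for edge weights
#'
#' Resamples subjects with replacement, re-estimates the association matrix
#' and network per resample, and returns percentile 95% intervals for every
#' edge weight. Resamples whose estimation fails (e.g. a single-category item
#' after resampling) are skipped and counted; more than 5% failures is an
#' error.
#'
#' @param cohort A `cohort_table`.
#' @param config A [glasso_config()].
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; all resampling randomness flows from it.
#' @param include_anxiety_node Bootstrap the anxiety-augmented network?
#' @return An object of class `bootstrap_result`: list with `labels`,
#'   `point` (observed weights), `ci_low`, `ci_high` (matrices), `n_boot`,
#'   `n_failed`, `seed`.
#' @export
bootstrap_edges <- function(cohort, config = glasso_config(), n_boot = 1000L,
                            seed = 1L, include_anxiety_node = FALSE) {
  stopifnot(n_boot >= 100)
  net0 <- refit_network(cohort, config, include_anxiety_node)
  p <- length(net0$labels)
  ut <- upper.tri(net0$weights)
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, sum(ut))
  n <- nrow(cohort)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    net_b <- tryCatch(refit_network(cohort[idx, , drop = FALSE], config,
                                    include_anxiety_node),
                      error = function(e) NULL)
    if (is.null(net_b)) {
      failed <- failed + 1L
      next
    }
    draws[b, ] <- net_b$weights[ut]
  }
  if (failed > 0.05 * n_boot) {
    stop(sprintf("bootstrap estimation failed in %d of %d resamples", failed,
                 n_boot))
  }
  ok <- !is.na(draws[, 1])
  lo <- hi <- matrix(0, p, p, dimnames = dimnames(net0$weights))
  lo[ut] <- apply(draws[ok, , drop = FALSE], 2, quantile, probs = 0.025)
  hi[ut] <- apply(draws[ok, , drop = FALSE], 2, quantile, probs = 0.975)
  lo <- lo + t(lo)
  hi <- hi + t(hi)
  structure(
    list(labels = net0$labels, point = net0$weights, ci_low = lo,
         ci_high = hi, n_boot = as.integer(n_boot), n_failed = failed,
         seed = as.integer(seed)),
    class = "bootstrap_result"
  )
}

#' Case-dropping stability of node strength
#'
#' For each drop proportion, subsamples subjects without replacement,
#' re-estimates the network, and correlates (Spearman) the resampled node
#' strengths with the full-sample strengths. The correlation-stability (CS)
#' coefficient is the largest drop proportion whose 5th-percentile
#' correlation is still at least 0.7 (i.e. the correlation holds in >= 95% of
#' resamples); 0 if no proportion qualifies.
#'
#' @param cohort A `cohort_table`.
#' @param config A [glasso_config()].
#' @param drop_grid Increasing proportions in (0, 0.75].
#' @param n_boot Resamples per proportion.
#' @param seed Integer seed.
#' @return An object of class `stability_result`: list with `drop_grid`,
#'   `q05_correlation` (per proportion), `prop_above_07`, `cs_coefficient`,
#'   `n_boot`, `seed`.
#' @export
case_drop_stability <- function(cohort, config = glasso_config(),
                                drop_grid = seq(0.1, 0.75, by = 0.05),
                                n_boot = 100L, seed = 1L) {
  stopifnot(all(drop_grid > 0), all(drop_grid <= 0.75),
            !is.unsorted(drop_grid))
  s0 <- node_strength(refit_network(cohort, config))
  n <- nrow(cohort)
  set.seed(seed)
  q05 <- prop07 <- numeric(length(drop_grid))
  for (g in seq_along(drop_grid)) {
    keep_n <- max(length(s0) + 1L, round((1 - drop_grid[g]) * n))
    cors <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, keep_n)
      net_b <- tryCatch(refit_network(cohort[idx, , drop = FALSE], config),
                        error = function(e) NULL)
      if (is.null(net_b)) next
      sb <- node_strength(net_b)
      # an empty (or constant-strength) resampled network carries no rank
      # information: count it as zero stability, not as a failure
      cors[b] <- if (sd(sb) == 0 || sd(s0) == 0) 0
                 else cor(s0, sb, method = "spearman")
    }
    cors <- cors[!is.na(cors)]
    if (length(cors) < 0.95 * n_boot) {
      stop("case-drop estimation failed in more than 5% of resamples at drop ",
           drop_grid[g])
    }
    q05[g] <- quantile(cors, 0.05)
    prop07[g] <- mean(cors >= 0.7)
  }
  qualifies <- prop07 >= 0.95
  cs <- if (any(qualifies)) max(drop_grid[qualifies]) else 0
  structure(
    list(drop_grid = drop_grid, q05_correlation = q05,
         prop_above_07 = prop07, cs_coefficient = cs,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "stability_result"
  )
}
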