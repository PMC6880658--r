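# Permutation network comparison test (NCT). Observed statistics come from
# networks fit independently per group; the null distribution pools the
# subjects and randomly re-splits them at the original group sizes,
# re-running the full polychoric + graphical lasso + EBIC chain for both
# pseudo-groups at every permutation.

# Fast internal fit from a bare integer item matrix (the permutation loop's
# unit of work): polychoric matrix, PSD repair if needed, glasso path, EBIC.
fit_items <- function(items, config) {
  S <- .polychoric_matrix_cpp(items, 1e-6)
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) S <- unname(nearest_psd(S))
  n <- nrow(items)
  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max <= 0) lambda_max <- 1e-4
  lambdas <- exp(seq(log(lambda_max),
                     log(lambda_max * config$lambda_min_ratio),
                     length.out = config$n_lambda))
  fit <- .glasso_path_cpp(S, lambdas, config$penalize_diagonal, 1e-6, 1000L)
  p <- ncol(items)
  E <- fit$n_edges
  ebic <- -n * fit$loglik_term + E * log(n) + 4 * config$gamma * E * log(p)
  best <- which(ebic <= min(ebic) + 1e-9)[1]
  W <- precision_to_pcor(fit$precision[, , best])
  W[abs(W) < 1e-12] <- 0
  W
}

global_strength <- function(W) sum(abs(W[upper.tri(W)]))

#' Network comparison test
#'
#' Two-tailed permutation test comparing the networks of two independent
#' groups on three levels: global strength (difference in the sum of absolute
#' edge weights), global structure (maximum absolute edge difference), and
#' individual edges (per-edge differences with Holm correction). P-values use
#' the plus-one estimator `(1 + #{perm >= obs}) / (1 + n_perm)` and are never
#' exactly zero.
#'
#' @param group_a,group_b `cohort_table`s sharing the MADRS item set.
#' @param config A [glasso_config()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return An object of class `nct_result`: `s_observed`, `m_observed`,
#'   `edge_diffs` (matrix of observed `w_A - w_B`), `p_strength`,
#'   `p_structure`, `p_edges` (Holm-adjusted matrix), `p_edges_raw`,
#'   `n_perm`, `seed`, plus the two fitted weight matrices.
#' @export
nct <- function(group_a, group_b, config = glasso_config(), n_perm = 1000L,
                seed = 1L) {
  stopifnot(inherits(group_a, "cohort_table"), inherits(group_b, "cohort_table"),
            n_perm >= 100)
  items_a <- item_matrix(group_a)
  items_b <- item_matrix(group_b)
  na <- nrow(items_a)
  nb <- nrow(items_b)
  p <- ncol(items_a)
  if (min(na, nb) <= p) {
    stop("each group must have more subjects than nodes (>= ", p + 1,
         ") for network estimation")
  }
  wa <- tryCatch(fit_items(items_a, config),
                 error = function(e) stop("estimation failed for group A: ",
                                          conditionMessage(e)))
  wb <- tryCatch(fit_items(items_b, config),
                 error = function(e) stop("estimation failed for group B: ",
                                          conditionMessage(e)))
  ut <- upper.tri(wa)
  diffs <- wa - wb
  s_obs <- abs(global_strength(wa) - global_strength(wb))
  m_obs <- max(abs(diffs[ut]))

  # canonical pooled order + resampling the smaller group makes the null
  # distribution (and hence seed-matched p-values) invariant to group labels
  pooled <- rbind(items_a, items_b)
  pooled <- pooled[do.call(order, as.data.frame(pooled)), , drop = FALSE]
  ntot <- na + nb
  n_small <- min(na, nb)
  set.seed(seed)
  s_null <- m_null <- numeric(n_perm)
  edge_ge <- matrix(0, p, p)
  obs_abs <- abs(diffs)
  for (k in seq_len(n_perm)) {
    idx <- sample.int(ntot, n_small)
    wpa <- fit_items(pooled[idx, , drop = FALSE], config)
    wpb <- fit_items(pooled[-idx, , drop = FALSE], config)
    dperm <- wpa - wpb
    s_null[k] <- abs(global_strength(wpa) - global_strength(wpb))
    m_null[k] <- max(abs(dperm[ut]))
    edge_ge <- edge_ge + (abs(dperm) >= obs_abs - 1e-12)
  }
  p_strength <- (1 + sum(s_null >= s_obs - 1e-12)) / (1 + n_perm)
  p_structure <- (1 + sum(m_null >= m_obs - 1e-12)) / (1 + n_perm)
  p_raw <- (1 + edge_ge) / (1 + n_perm)
  diag(p_raw) <- NA
  padj <- matrix(NA_real_, p, p)
  padj[ut] <- stats::p.adjust(p_raw[ut], method = "holm")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  dimnames(diffs) <- dimnames(p_raw) <- dimnames(padj) <-
    list(colnames(items_a), colnames(items_a))
  structure(
    list(s_observed = s_obs, m_observed = m_obs, edge_diffs = diffs,
         p_strength = p_strength, p_structure = p_structure,
         p_edges = padj, p_edges_raw = p_raw,
         weights_a = wa, weights_b = wb,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "nct_result"
  )
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf(paste0("<nct_result> global strength diff = %.4f (p = %.4g), ",
                     "structure stat = %.4f (p = %.4g), %d permutations\n"),
              x$s_observed, x$p_strength, x$m_observed, x$p_structure,
              x$n_perm))
  invisible(x)
}

#' Significant edge differences
#'
#' Edges whose Holm-adjusted two-tailed permutation p-value falls below
#' `alpha`.
#'
#' @param result An `nct_result`.
#' @param alpha Significance level.
#' @return Data frame with columns `node_i`, `node_j`, `diff`, `p_adjusted`
#'   (possibly zero rows).
#' @export
edge_tests <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "nct_result"))
  ut <- which(upper.tri(result$p_edges), arr.ind = TRUE)
  keep <- !is.na(result$p_edges[ut]) & result$p_edges[ut] < alpha
  labs <- rownames(result$p_edges)
  data.frame(node_i = labs[ut[keep, 1]], node_j = labs[ut[keep, 2]],
             diff = result$edge_diffs[ut[keep, , drop = FALSE]],
             p_adjusted = result$p_edges[ut[keep, , drop = FALSE]],
             stringsAsFactors = FALSE)
}
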