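# Regularized Gaussian graphical model: graphical lasso over a log-spaced
# penalty path with EBIC model selection, edge weights reported as partial
# correlations.

#' Graphical lasso / EBIC configuration
#'
#' @param gamma EBIC hyperparameter (>= 0). At `gamma = 0` the criterion is
#'   ordinary BIC.
#' @param n_lambda Number of penalty values on the log-spaced path.
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest
#'   (the largest is the maximum absolute off-diagonal association, at which
#'   the model is empty).
#' @param penalize_diagonal Penalize the precision diagonal?
#' @return An object of class `glasso_config`.
#' @export
glasso_config <- function(gamma = 0, n_lambda = 100L, lambda_min_ratio = 0.01,
                          penalize_diagonal = FALSE) {
  stopifnot(gamma >= 0, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(
    list(gamma = gamma, n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio,
         penalize_diagonal = isTRUE(penalize_diagonal)),
    class = "glasso_config"
  )
}

#' Graphical lasso path
#'
#' Solves the L1-penalized Gaussian log-determinant problem by coordinate
#' descent at each penalty of a log-spaced grid running from
#' `lambda_max = max |off-diagonal association|` (empty model) down to
#' `lambda_max * lambda_min_ratio`, warm-starting along the path.
#'
#' @param assoc An `assoc_matrix` (PSD-repaired if needed).
#' @param n Sample size behind the association matrix (defaults to
#'   `assoc$n`); must exceed the number of nodes.
#' @param config A [glasso_config()].
#' @return An object of class `glasso_path`: list with `lambdas`,
#'   `precision` (array p x p x n_lambda), `loglik` (Gaussian log-likelihood
#'   up to constants, `(n/2)(log det K - tr(S K))`), `n_edges`, `labels`, `n`.
#' @export
glasso_path <- function(assoc, n = NULL, config = glasso_config()) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  if (is.null(n)) n <- assoc$n
  p <- length(assoc$labels)
  if (n <= p) stop("sample size must exceed the number of nodes")
  S <- assoc$values
  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max <= 0) lambda_max <- 1e-4
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * config$lambda_min_ratio),
                     length.out = config$n_lambda))
  fit <- .glasso_path_cpp(S, lambdas, config$penalize_diagonal, 1e-6, 1000L)
  if (any(!is.finite(fit$loglik_term))) {
    bad <- which(!is.finite(fit$loglik_term))[1]
    stop(sprintf("graphical lasso failed to produce a PD precision at lambda = %g",
                 lambdas[bad]))
  }
  structure(
    list(lambdas = lambdas,
         precision = fit$precision,
         loglik = (n / 2) * fit$loglik_term,
         n_edges = as.integer(fit$n_edges),
         labels = assoc$labels,
         n = n),
    class = "glasso_path"
  )
}

#' EBIC model selection on a graphical lasso path
#'
#' `EBIC = -2 loglik + E log(n) + 4 gamma E log(p)` with `E` the number of
#' edges (nonzero upper-triangle precision entries). The minimizing penalty
#' is selected; ties resolve toward the larger penalty (sparser model).
#' Weights of the selected model are standardized to partial correlations
#' `-K_ij / sqrt(K_ii K_jj)`.
#'
#' @param path A `glasso_path`.
#' @param n Sample size (defaults to the path's).
#' @param config A [glasso_config()] (supplies `gamma`).
#' @param cluster_tags Optional character vector of node cluster labels.
#' @return An object of class `symptom_network`: list with `labels`,
#'   `weights` (symmetric, zero diagonal partial correlations),
#'   `lambda_selected`, `ebic`, `n`, `cluster_tags`.
#' @export
select_ebic <- function(path, n = NULL, config = glasso_config(),
                        cluster_tags = NULL) {
  stopifnot(inherits(path, "glasso_path"))
  if (is.null(n)) n <- path$n
  p <- length(path$labels)
  E <- path$n_edges
  ebic <- -2 * path$loglik + E * log(n) + 4 * config$gamma * E * log(p)
  # ties toward the larger penalty: lambdas are decreasing, take first min
  best <- which(ebic <= min(ebic) + 1e-9)[1]
  K <- path$precision[, , best]
  W <- precision_to_pcor(K)
  W[abs(W) < 1e-12] <- 0
  dimnames(W) <- list(path$labels, path$labels)
  if (is.null(cluster_tags) && identical(path$labels[1:10], MADRS_LABELS)) {
    cluster_tags <- c(MADRS_CLUSTERS,
                      if (p == 11) "anxiety_node")
  }
  structure(
    list(labels = path$labels, weights = W,
         lambda_selected = path$lambdas[best],
         ebic = ebic[best], n = n,
         cluster_tags = cluster_tags),
    class = "symptom_network"
  )
}

#' Estimate a symptom network from a cohort
#'
#' Convenience chain: [association_matrix()] then [glasso_path()] then
#' [select_ebic()].
#'
#' @param cohort A `cohort_table`.
#' @param config A [glasso_config()].
#' @param include_anxiety_node Add the BAI-sum anxiety node?
#' @param anxiety_method Passed to [association_matrix()].
#' @return A `symptom_network`.
#' @export
estimate_network <- function(cohort, config = glasso_config(),
                             include_anxiety_node = FALSE,
                             anxiety_method = "polyserial") {
  assoc <- association_matrix(cohort, include_anxiety_node,
                              anxiety_method = anxiety_method)
  select_ebic(glasso_path(assoc, config = config), config = config)
}

#' @export
print.symptom_network <- function(x, ...) {
  E <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<symptom_network> %d nodes, %d edges, lambda = %.4g, EBIC = %.2f, n = %d\n",
              length(x$labels), E, x$lambda_selected, x$ebic, x$n))
  invisible(x)
}

network_edge_list <- function(net) {
  W <- net$weights
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  data.frame(node_i = net$labels[ut[, 1]], node_j = net$labels[ut[, 2]],
             weight = W[ut], stringsAsFactors = FALSE)
}

#' Write a symptom network to disk
#'
#' Emits a square-matrix CSV (`<stem>_matrix.csv`), an edge-list CSV
#' (`<stem>_edges.csv`, columns node_i, node_j, weight) and a JSON file
#' (`<stem>.json`) with labels, selected penalty, EBIC, sample size and
#' cluster tags.
#'
#' @param net A `symptom_network`.
#' @param stem Path stem without extension.
#' @return `stem`, invisibly.
#' @export
write_network <- function(net, stem) {
  write.csv(data.frame(label = net$labels, net$weights, check.names = FALSE),
            paste0(stem, "_matrix.csv"), row.names = FALSE)
  write.csv(network_edge_list(net), paste0(stem, "_edges.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(labels = net$labels, lambda_selected = net$lambda_selected,
         ebic = net$ebic, n = net$n, cluster_tags = net$cluster_tags,
         weights = net$weights),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(stem)
}
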