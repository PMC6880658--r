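# Ordinal association estimation: polychoric for item pairs, polyserial for
# the continuous BAI-sum anxiety node, with nearest-PSD repair of the
# assembled matrix.

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum likelihood: thresholds are fixed at the inverse standard
#' normal of the cumulative marginal proportions, then the latent correlation
#' maximizes the bivariate-normal cell likelihood of the contingency table
#' (Brent search on \[-0.999, 0.999\], tolerance `tol`). Empty cells carry no
#' likelihood contribution and need no adjustment; only a 2x2 table with a
#' zero cell (where the unrestricted MLE diverges to +/-1) receives a 0.5
#' continuity correction in every cell, and estimates are clipped at 0.999.
#'
#' @param x,y Integer-valued ordinal vectors of equal length (>= 10), each
#'   with at least two observed categories.
#' @param tol Optimizer tolerance.
#' @return The estimated latent correlation, in (-0.999, 0.999).
#' @export
polychoric <- function(x, y, tol = 1e-6) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  if (anyNA(x) || anyNA(y)) stop("polychoric does not accept missing values")
  .polychoric_vec_cpp(as.integer(x), as.integer(y), tol)
}

#' Polychoric correlation from a contingency table
#'
#' @param tab Matrix of cell counts (rows: categories of the first variable).
#' @param tol Optimizer tolerance.
#' @return The estimated latent correlation.
#' @export
polychoric_table <- function(tab, tol = 1e-6) {
  .polychoric_table_cpp(as.matrix(tab) * 1.0, tol)
}

#' Polyserial correlation of an ordinal and a continuous variable
#'
#' Two-step estimator: `y` is standardized, the thresholds of `x` come from
#' its marginal proportions, and the latent correlation maximizes the
#' conditional likelihood of the ordinal scores given `y`.
#'
#' @param x Integer-valued ordinal vector with >= 2 observed categories.
#' @param y Real-valued vector with positive variance.
#' @param tol Optimizer tolerance.
#' @return The estimated latent correlation.
#' @export
polyserial <- function(x, y, tol = 1e-6) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  if (anyNA(x) || anyNA(y)) stop("polyserial does not accept missing values")
  .polyserial_vec_cpp(as.integer(x), as.numeric(y), tol)
}

#' Nearest positive-semidefinite repair by eigenvalue clipping
#'
#' Clips negative eigenvalues to a small floor, reconstructs, and rescales to
#' unit diagonal. Used when a pairwise-assembled correlation matrix is
#' indefinite.
#'
#' @param mat Symmetric matrix with unit diagonal.
#' @param floor Eigenvalue floor.
#' @return The repaired correlation matrix.
#' @export
nearest_psd <- function(mat, floor = 1e-6) {
  e <- eigen(mat, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- stats::cov2cor(out)
  dimnames(out) <- dimnames(mat)
  (out + t(out)) / 2
}

#' Pairwise association matrix of a symptom cohort
#'
#' Assembles the 10x10 polychoric correlation matrix over the MADRS items,
#' optionally bordered by an 11th anxiety node computed from the BAI sum
#' score (polyserial against each item by default, Pearson on request). If
#' the pairwise matrix is indefinite it is repaired by eigenvalue clipping
#' and the repair is flagged.
#'
#' @param cohort A `cohort_table` with at least 30 subjects.
#' @param include_anxiety_node Add the BAI-sum anxiety node?
#' @param anxiety_method `"polyserial"` (default) or `"pearson"` for the
#'   anxiety-item associations.
#' @param tol Optimizer tolerance passed to the pairwise estimators.
#' @return An object of class `assoc_matrix`: list with `labels`, `values`
#'   (symmetric, unit diagonal), `method_per_pair` (character matrix),
#'   `psd_repaired` (logical) and `n`.
#' @export
association_matrix <- function(cohort, include_anxiety_node = FALSE,
                               anxiety_method = c("polyserial", "pearson"),
                               tol = 1e-6) {
  stopifnot(inherits(cohort, "cohort_table"))
  anxiety_method <- match.arg(anxiety_method)
  if (nrow(cohort) < 30) stop("association_matrix needs >= 30 subjects")
  items <- item_matrix(cohort)
  vals <- tryCatch(
    .polychoric_matrix_cpp(items, tol),
    error = function(e) stop("polychoric estimation failed: ", conditionMessage(e))
  )
  labels <- MADRS_LABELS
  methods <- matrix("polychoric", 10, 10)
  diag(methods) <- ""
  if (include_anxiety_node) {
    bai <- as.numeric(cohort$bai_sum)
    anx <- vapply(seq_len(10), function(j) {
      r <- tryCatch(
        if (anxiety_method == "polyserial") {
          polyserial(items[, j], bai, tol)
        } else {
          cor(items[, j], bai)
        },
        error = function(e) {
          stop("anxiety-node association failed for pair (",
               labels[j], ", anxiety): ", conditionMessage(e))
        }
      )
      r
    }, numeric(1))
    vals <- rbind(cbind(vals, anx), c(anx, 1))
    labels <- c(labels, "anxiety")
    methods <- rbind(cbind(methods, anxiety_method), c(rep(anxiety_method, 10), ""))
  }
  dimnames(vals) <- list(labels, labels)
  dimnames(methods) <- list(labels, labels)
  repaired <- FALSE
  ev_min <- min(eigen(vals, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    vals <- nearest_psd(vals)
    repaired <- TRUE
  }
  structure(
    list(labels = labels, values = vals, method_per_pair = methods,
         psd_repaired = repaired, n = nrow(cohort)),
    class = "assoc_matrix"
  )
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d nodes, n = %d, psd_repaired = %s\n",
              length(x$labels), x$n, x$psd_repaired))
  print(round(x$values, 3))
  invisible(x)
}

#' Write an association matrix to CSV with a JSON sidecar
#'
#' @param assoc An `assoc_matrix`.
#' @param path CSV path for the square matrix; `<path>.json` records labels,
#'   per-pair methods and the PSD-repair flag.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path) {
  write.csv(data.frame(label = assoc$labels, assoc$values,
                       check.names = FALSE),
            path, row.names = FALSE)
  jsonlite::write_json(
    list(labels = assoc$labels, psd_repaired = assoc$psd_repaired,
         n = assoc$n, method_per_pair = assoc$method_per_pair),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
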