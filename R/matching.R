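# Propensity-score matching: multivariable logistic propensity for
# high-anxiety membership, greedy 1:1 nearest-neighbour matching on the
# logit propensity within a caliper, unmatched subjects discarded.

#' Matching configuration
#'
#' @param covariates Covariate names entering the propensity model. `madrs_sum`
#'   and `sex` receive special handling (computed score sum; female
#'   indicator); all others must be numeric cohort columns.
#' @param caliper Caliper width. Under `caliper_scale = "sd_logit"` (the
#'   Rosenbaum-Rubin convention, default) the maximum pair distance is
#'   `caliper * SD(logit propensity)`; under `"raw"` it is an absolute
#'   distance on the logit scale.
#' @param caliper_scale `"sd_logit"` or `"raw"`.
#' @param ratio Controls per treated subject (fixed at 1).
#' @return An object of class `match_config`.
#' @export
match_config <- function(covariates = c("madrs_sum", "age", "sex",
                                        "education_years"),
                         caliper = 0.25,
                         caliper_scale = c("sd_logit", "raw"),
                         ratio = 1L) {
  stopifnot(caliper > 0, length(covariates) > 0, ratio == 1L)
  structure(
    list(covariates = covariates, caliper = caliper,
         caliper_scale = match.arg(caliper_scale), ratio = 1L),
    class = "match_config"
  )
}

covariate_frame <- function(cohort, covariates) {
  out <- lapply(covariates, function(v) {
    if (v == "madrs_sum") madrs_sum(cohort)
    else if (v == "sex") as.numeric(cohort$sex == "female")
    else if (v %in% names(cohort)) as.numeric(cohort[[v]])
    else stop("unknown matching covariate: ", v)
  })
  names(out) <- covariates
  as.data.frame(out)
}

#' Fit the propensity model
#'
#' Logistic regression (maximum likelihood via `glm`) of high-anxiety group
#' membership on the configured covariates.
#'
#' @param cohort A `cohort_table` whose `group` column labels every subject
#'   `low_anxiety` or `high_anxiety`.
#' @param config A [match_config()].
#' @return Named vector of fitted membership probabilities in (0, 1).
#' @export
fit_propensity <- function(cohort, config = match_config()) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (anyNA(cohort$group) || !all(cohort$group %in% c("low_anxiety",
                                                      "high_anxiety"))) {
    stop("every subject must be labeled low_anxiety or high_anxiety")
  }
  if (length(unique(cohort$group)) < 2) stop("both groups must be present")
  X <- covariate_frame(cohort, config$covariates)
  dat <- cbind(treated = as.numeric(cohort$group == "high_anxiety"), X)
  fit <- suppressWarnings(glm(treated ~ ., data = dat, family = binomial()))
  ps <- as.numeric(predict(fit, type = "response"))
  if (any(ps > 1 - 1e-10) || any(ps < 1e-10)) {
    stop("propensity model shows (near-)perfect separation; review covariates")
  }
  setNames(ps, cohort$subject_id)
}

smd <- function(x_t, x_c, sd_ref) {
  if (sd_ref <= 0) return(0)
  (mean(x_t) - mean(x_c)) / sd_ref
}

#' Greedy 1:1 nearest-neighbour matching with caliper
#'
#' Treated (high-anxiety) subjects are processed in decreasing propensity
#' order; each is paired with the nearest unused control on the logit
#' propensity scale, provided the distance is within the caliper (ties break
#' toward the lowest subject order). Unmatched subjects are discarded.
#' Standardized mean differences before and after matching (denominator: the
#' pre-matching pooled SD) are reported per covariate.
#'
#' @param cohort A labeled `cohort_table` (see [fit_propensity()]).
#' @param propensity Fitted probabilities, as returned by [fit_propensity()]
#'   (fitted from `cohort` if omitted).
#' @param config A [match_config()].
#' @return An object of class `match_result`: `pairs` (data frame of
#'   `treated_id`, `control_id`, `distance`), `propensity`, `caliper_used`
#'   (logit-scale width), `balance` (per-covariate SMD before/after),
#'   `n_matched`.
#' @export
match_cohort <- function(cohort, propensity = NULL, config = match_config()) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(propensity)) propensity <- fit_propensity(cohort, config)
  stopifnot(length(propensity) == nrow(cohort))
  lp <- qlogis(propensity)
  treated_idx <- which(cohort$group == "high_anxiety")
  control_idx <- which(cohort$group == "low_anxiety")
  if (length(treated_idx) == 0 || length(control_idx) == 0) {
    stop("both groups must be present")
  }
  cal <- if (config$caliper_scale == "sd_logit") {
    config$caliper * sd(lp)
  } else {
    config$caliper
  }
  ord <- treated_idx[order(lp[treated_idx], decreasing = TRUE)]
  available <- rep(TRUE, length(control_idx))
  pairs <- vector("list", length(ord))
  np <- 0L
  for (t in ord) {
    d <- abs(lp[control_idx] - lp[t])
    d[!available] <- Inf
    j <- which.min(d)  # ties break toward the lowest control order
    if (is.finite(d[j]) && d[j] <= cal) {
      np <- np + 1L
      pairs[[np]] <- data.frame(
        treated_id = cohort$subject_id[t],
        control_id = cohort$subject_id[control_idx[j]],
        distance = d[j], stringsAsFactors = FALSE)
      available[j] <- FALSE
    }
  }
  if (np == 0L) stop("no pairs satisfy the caliper; matching failed")
  pairs <- do.call(rbind, pairs[seq_len(np)])
  X <- covariate_frame(cohort, config$covariates)
  t_rows <- match(pairs$treated_id, cohort$subject_id)
  c_rows <- match(pairs$control_id, cohort$subject_id)
  balance <- do.call(rbind, lapply(config$covariates, function(v) {
    xt <- X[[v]][treated_idx]
    xc <- X[[v]][control_idx]
    sd_ref <- sqrt((var(xt) + var(xc)) / 2)
    data.frame(covariate = v,
               smd_before = smd(xt, xc, sd_ref),
               smd_after = smd(X[[v]][t_rows], X[[v]][c_rows], sd_ref),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(pairs = pairs, propensity = propensity, caliper_used = cal,
         balance = balance, n_matched = np),
    class = "match_result"
  )
}

#' Extract the matched cohorts
#'
#' @param cohort The labeled `cohort_table` that was matched.
#' @param result A `match_result`.
#' @return List of two `cohort_table`s (`low`, `high`) in pair order, so row
#'   `i` of one is matched to row `i` of the other.
#' @export
matched_groups <- function(cohort, result) {
  low <- cohort[match(result$pairs$control_id, cohort$subject_id), ,
                drop = FALSE]
  high <- cohort[match(result$pairs$treated_id, cohort$subject_id), ,
                 drop = FALSE]
  rownames(low) <- rownames(high) <- NULL
  list(low = low, high = high)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs, caliper (logit) = %.4f\n",
              x$n_matched, x$caliper_used))
  print(x$balance, row.names = FALSE)
  invisible(x)
}
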