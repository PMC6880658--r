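#' @useDynLib lldnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate binomial coef cor glm optimize pnorm pt
#'   qlogis plogis qnorm quantile rbinom rnorm runif sd setNames t.test
#'   prop.test var predict
#' @importFrom utils read.csv write.csv
NULL

# Canonical MADRS node labels, in instrument order (items 1..10).
MADRS_LABELS <- c(
  "apparent_sadness", "reported_sadness", "inner_tension", "reduced_sleep",
  "reduced_appetite", "concentration_difficulties", "lassitude",
  "inability_to_feel", "pessimistic_thought", "suicidal_thought"
)

# Symptom cluster tags (three-factor grouping used as node metadata).
MADRS_CLUSTERS <- c(
  "dysphoric_apathy_retardation", "dysphoric_apathy_retardation",
  "psychic_anxiety", "vegetative", "vegetative",
  "dysphoric_apathy_retardation", "dysphoric_apathy_retardation",
  "dysphoric_apathy_retardation", "psychic_anxiety", "psychic_anxiety"
)

KNOWN_FLAGS <- c("bipolar", "schizophrenia", "other_mental_disorder", "dementia")

madrs_cols <- function() paste0("m", 1:10)
bai_cols <- function() paste0("b", 1:21)

#' Cohort eligibility and grouping configuration
#'
#' Cutoffs and exclusion rules applied when selecting subjects and when
#' splitting a cohort into low- and high-anxiety groups. The defaults are the
#' conventional clinical thresholds: MADRS sum >= 10 marks non-remitted
#' depression, BAI sum >= 16 marks at least moderate anxiety.
#'
#' @param madrs_cutoff Minimum MADRS sum score (inclusive) for eligibility.
#' @param bai_cutoff Minimum BAI sum score (inclusive) for the high-anxiety
#'   group.
#' @param exclusion_set Character vector of diagnosis flags that disqualify a
#'   subject. Any of `"bipolar"`, `"schizophrenia"`,
#'   `"other_mental_disorder"`, `"dementia"`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(madrs_cutoff = 10L, bai_cutoff = 16L,
                          exclusion_set = KNOWN_FLAGS) {
  stopifnot(madrs_cutoff > 0, bai_cutoff > 0)
  bad <- setdiff(exclusion_set, KNOWN_FLAGS)
  if (length(bad) > 0) {
    stop("unknown exclusion flags: ", paste(bad, collapse = ", "))
  }
  structure(
    list(madrs_cutoff = as.integer(madrs_cutoff),
         bai_cutoff = as.integer(bai_cutoff),
         exclusion_set = exclusion_set),
    class = "cohort_config"
  )
}

#' MADRS sum score per subject
#'
#' @param cohort A `cohort_table`.
#' @return Integer vector of per-subject sums of the 10 MADRS items (0-60).
#' @export
madrs_sum <- function(cohort) {
  as.integer(rowSums(as.data.frame(cohort)[, madrs_cols()]))
}

has_bai_items <- function(cohort) all(bai_cols() %in% names(cohort))

#' Validate a cohort table
#'
#' Checks the score-range, sum-consistency and uniqueness invariants of a
#' cohort table and either returns the table (with class `cohort_table`) or
#' raises an error naming the offending rows/subjects.
#'
#' @param df A data frame with columns `subject_id`, `m1`..`m10`, `bai_sum`,
#'   `age`, `sex`, `education_years`, and optionally `b1`..`b21`, `flags`,
#'   `group`.
#' @return The validated table, classed as `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("subject_id", madrs_cols(), "bai_sum", "age", "sex",
                "education_years")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  if (!"group" %in% names(df)) df$group <- NA_character_
  df$group[!is.na(df$group) & df$group == ""] <- NA_character_
  df$subject_id <- as.character(df$subject_id)

  item_mat <- as.matrix(df[, madrs_cols()])
  if (anyNA(item_mat) || anyNA(df$bai_sum)) {
    bad <- which(rowSums(is.na(item_mat)) > 0 | is.na(df$bai_sum))
    stop("missing MADRS/BAI values (complete-case analysis only); rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  out_of_range <- which(rowSums(item_mat < 0 | item_mat > 6 |
                                  item_mat != round(item_mat)) > 0)
  if (length(out_of_range) > 0) {
    stop("MADRS items must be integers in 0..6; offending row(s): ",
         paste(utils::head(out_of_range, 10), collapse = ", "),
         " (subject ", df$subject_id[out_of_range[1]], ")")
  }
  bad_bai <- which(df$bai_sum < 0 | df$bai_sum > 63)
  if (length(bad_bai) > 0) {
    stop("bai_sum must lie in 0..63; offending row(s): ",
         paste(utils::head(bad_bai, 10), collapse = ", "))
  }
  if (has_bai_items(df)) {
    bmat <- as.matrix(df[, bai_cols()])
    if (anyNA(bmat)) {
      stop("missing BAI item values; complete-case analysis only")
    }
    if (any(bmat < 0 | bmat > 3 | bmat != round(bmat))) {
      stop("BAI items must be integers in 0..3")
    }
    mism <- which(rowSums(bmat) != df$bai_sum)
    if (length(mism) > 0) {
      stop("bai_sum does not equal the sum of b1..b21 for subject(s): ",
           paste(utils::head(df$subject_id[mism], 10), collapse = ", "))
    }
  }
  dup <- duplicated(df$subject_id)
  if (any(dup)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[dup]), collapse = ", "))
  }
  if (any(df$age <= 0)) stop("age must be positive")
  if (any(df$education_years < 0)) stop("education_years must be non-negative")
  unknown <- setdiff(unlist(strsplit(df$flags[df$flags != ""], ";")),
                     KNOWN_FLAGS)
  if (length(unknown) > 0) {
    stop("unknown exclusion flag(s): ", paste(unique(unknown), collapse = ", "))
  }
  for (m in madrs_cols()) df[[m]] <- as.integer(df[[m]])
  df$bai_sum <- as.integer(df$bai_sum)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header naming at least
#' `subject_id`, `m1`..`m10`, `bai_sum`, `age`, `sex`, `education_years`.
#' Optional columns: `b1`..`b21` (checked for consistency with `bai_sum`),
#' `flags` (semicolon-joined diagnosis flags) and `group`.
#'
#' @param path Path to the CSV file.
#' @return A validated `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_cohort_table(df)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: the written file round-trips field-for-field.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8", na = "")
  invisible(path)
}

subject_flags <- function(cohort) {
  strsplit(ifelse(cohort$flags == "", NA_character_, cohort$flags), ";")
}

#' Apply eligibility rules to a cohort
#'
#' Retains subjects whose MADRS sum is at or above the cutoff (inclusive) and
#' who carry none of the configured exclusion flags. Counts removed per reason
#' are attached as attribute `removed` and reported via message.
#'
#' @param cohort A `cohort_table`.
#' @param config A [cohort_config()].
#' @return The filtered `cohort_table`.
#' @export
apply_eligibility <- function(cohort, config = cohort_config()) {
  stopifnot(inherits(cohort, "cohort_table"))
  fl <- subject_flags(cohort)
  excluded_flag <- vapply(fl, function(f) {
    !all(is.na(f)) && any(f %in% config$exclusion_set)
  }, logical(1))
  below_cutoff <- madrs_sum(cohort) < config$madrs_cutoff
  removed <- c(
    below_madrs_cutoff = sum(below_cutoff & !excluded_flag),
    vapply(config$exclusion_set, function(flg) {
      sum(vapply(fl, function(f) !all(is.na(f)) && flg %in% f, logical(1)) &
            !below_cutoff)
    }, integer(1))
  )
  keep <- !below_cutoff & !excluded_flag
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  if (nrow(out) == 0) warning("eligibility filter removed every subject")
  message(sprintf("eligibility: retained %d of %d subjects (removed: %s)",
                  nrow(out), nrow(cohort),
                  paste(names(removed), removed, sep = "=", collapse = ", ")))
  out
}

#' Split a cohort into low- and high-anxiety groups
#'
#' High anxiety is BAI sum at or above the cutoff (inclusive); low anxiety is
#' the remainder. The two groups partition the input.
#'
#' @param cohort A `cohort_table` with `bai_sum` present for all subjects.
#' @param config A [cohort_config()].
#' @return A list with validated `cohort_table` elements `low` and `high`,
#'   each with its `group` column filled in.
#' @export
split_by_anxiety <- function(cohort, config = cohort_config()) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (anyNA(cohort$bai_sum)) {
    stop("bai_sum missing for subject(s): ",
         paste(cohort$subject_id[is.na(cohort$bai_sum)], collapse = ", "))
  }
  hi <- cohort$bai_sum >= config$bai_cutoff
  low <- cohort[!hi, , drop = FALSE]
  high <- cohort[hi, , drop = FALSE]
  low$group <- "low_anxiety"
  high$group <- "high_anxiety"
  rownames(low) <- NULL
  rownames(high) <- NULL
  list(low = low, high = high)
}

#' Extract the MADRS item score matrix
#'
#' @param cohort A `cohort_table`.
#' @return Integer matrix, one row per subject and one labeled column per
#'   MADRS item.
#' @export
item_matrix <- function(cohort) {
  m <- as.matrix(as.data.frame(cohort)[, madrs_cols()])
  storage.mode(m) <- "integer"
  colnames(m) <- MADRS_LABELS
  m
}
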