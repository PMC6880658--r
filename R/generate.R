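# Latent-Gaussian threshold simulator. Items arise by cutting a multivariate
# normal with a known sparse precision structure; an independent latent
# anxiety factor drives the BAI items and, via `severity_shift`, can shift
# every symptom's latent mean (severity confounding with the partial
# correlation structure left intact).

#' Generator specification for synthetic symptom cohorts
#'
#' Defines the latent-Gaussian threshold model behind [generate_cohort()]:
#' a 10-dimensional latent symptom vector with covariance equal to the
#' (correlation-standardized) inverse of `precision_matrix`, shifted by the
#' latent anxiety factor through `anxiety_loading` and `severity_shift`,
#' then cut at `item_thresholds` into 0-6 scores. BAI items load on the
#' anxiety factor with `bai_loading` plus unit noise and are cut at
#' `bai_thresholds` into 0-3 scores.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param precision_matrix Symmetric positive-definite 10x10 matrix over the
#'   latent symptom dimensions (unit diagonal scale).
#' @param item_thresholds List of 10 strictly increasing numeric vectors of
#'   length 6 (cut points for scores 0..6 on the unit-variance latent scale).
#' @param anxiety_loading Length-10 vector: effect of the latent anxiety
#'   factor on each symptom's latent value.
#' @param severity_shift Scalar mean shift of all latent symptoms per unit
#'   latent anxiety (the severity-confounding knob).
#' @param bai_loading Scalar loading of latent anxiety on each BAI item.
#' @param bai_thresholds Strictly increasing length-3 cut points for the BAI
#'   item scores 0..3.
#' @param covariate_model List with entries `age_mean`, `age_sd`,
#'   `age_anxiety_slope`, `education_mean`, `education_sd`,
#'   `education_anxiety_slope`, `p_female`, `sex_anxiety_slope` (logit scale).
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_subjects,
                           precision_matrix,
                           item_thresholds,
                           anxiety_loading = rep(0, 10),
                           severity_shift = 0,
                           bai_loading = 1.1,
                           bai_thresholds = c(0.26, 1.13, 2.00),
                           covariate_model = default_covariate_model(),
                           seed = 1L) {
  stopifnot(is.matrix(precision_matrix),
            nrow(precision_matrix) == 10, ncol(precision_matrix) == 10)
  if (max(abs(precision_matrix - t(precision_matrix))) > 1e-10) {
    stop("precision_matrix must be symmetric")
  }
  ev <- eigen(precision_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision_matrix must be positive definite")
  stopifnot(length(item_thresholds) == 10)
  for (th in item_thresholds) {
    stopifnot(length(th) == 6, all(diff(th) > 0))
  }
  stopifnot(length(anxiety_loading) == 10, length(severity_shift) == 1,
            length(bai_thresholds) == 3, all(diff(bai_thresholds) > 0))
  structure(
    list(n_subjects = as.integer(n_subjects),
         precision_matrix = precision_matrix,
         item_thresholds = item_thresholds,
         anxiety_loading = as.numeric(anxiety_loading),
         severity_shift = as.numeric(severity_shift),
         bai_loading = as.numeric(bai_loading),
         bai_thresholds = as.numeric(bai_thresholds),
         covariate_model = covariate_model,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' @rdname generator_spec
#' @export
default_covariate_model <- function() {
  list(age_mean = 74, age_sd = 7.8, age_anxiety_slope = 0,
       education_mean = 6.2, education_sd = 4.5, education_anxiety_slope = 0,
       p_female = 0.72, sex_anxiety_slope = 0)
}

# Partial correlations implied by a precision matrix: -K_ij / sqrt(K_ii K_jj),
# zero diagonal.
precision_to_pcor <- function(K) {
  d <- 1 / sqrt(diag(K))
  P <- -K * outer(d, d)
  diag(P) <- 0
  P
}

# The seeded sparse structure shared by the presets: three symptom clusters
# with strong within-cluster edges (reported-apparent sadness,
# concentration-lassitude, pessimism-suicidality at .35), moderate .2/.25
# within-cluster ties, one cross-cluster edge and one negative edge
# (reduced sleep - pessimistic thought).
lld_precision <- function() {
  P <- matrix(0, 10, 10)
  set_edge <- function(i, j, v) {
    P[i, j] <<- v
    P[j, i] <<- v
  }
  set_edge(1, 2, 0.35)   # apparent - reported sadness
  set_edge(1, 7, 0.20)   # apparent sadness - lassitude
  set_edge(2, 8, 0.20)   # reported sadness - inability to feel
  set_edge(2, 9, 0.20)   # reported sadness - pessimistic thought
  set_edge(6, 7, 0.35)   # concentration - lassitude
  set_edge(7, 8, 0.20)   # lassitude - inability to feel
  set_edge(3, 9, 0.20)   # inner tension - pessimistic thought
  set_edge(3, 10, 0.20)  # inner tension - suicidal thought
  set_edge(9, 10, 0.35)  # pessimistic - suicidal thought
  set_edge(4, 5, 0.25)   # reduced sleep - reduced appetite
  set_edge(4, 9, -0.18)  # reduced sleep - pessimistic thought (negative)
  K <- diag(10) - P
  dimnames(K) <- list(MADRS_LABELS, MADRS_LABELS)
  K
}

lld_item_thresholds <- function() {
  # marginal score probabilities give item means near 2.5 and a MADRS sum
  # mean near 24 (loosely in the range seen in moderate geriatric depression)
  p <- c(0.16, 0.19, 0.20, 0.17, 0.12, 0.09, 0.07)
  th <- qnorm(cumsum(p)[1:6])
  rep(list(th), 10)
}

#' Preset generator specifications
#'
#' Three frozen study designs:
#' \describe{
#'   \item{`baseline_lld`}{Three symptom clusters with the seeded sparse
#'     partial-correlation structure; anxiety decoupled from the symptom
#'     items (zero loadings, zero severity shift), so the BAI split is
#'     uninformative about the network.}
#'   \item{`confounded_anxiety`}{Same network structure, but latent anxiety
#'     shifts every symptom's latent mean (`severity_shift = 0.12`),
#'     inflating MADRS severity in the high-BAI group by about 3 sum points
#'     (a severity confound that is statistically unambiguous at n = 776)
#'     and mildly imbalancing age, education and sex - the confounding that
#'     propensity-score matching must remove. The partial-correlation
#'     structure itself is identical in both groups, so any post-matching
#'     network difference is sampling noise.}
#'   \item{`null_two_group`}{Alias of `baseline_lld`, used where two groups
#'     are drawn from one spec to study type-I error.}
#' }
#' The BAI thresholds and loading are calibrated so that about 40.5% of
#' subjects (the 314/776 split) fall at or above the BAI cutoff of 16.
#'
#' @param spec_name One of `"baseline_lld"`, `"confounded_anxiety"`,
#'   `"null_two_group"`.
#' @param n_subjects Cohort size (default 776).
#' @param seed Integer seed.
#' @return A [generator_spec()].
#' @export
preset_lld <- function(spec_name, n_subjects = 776L, seed = 1L) {
  presets <- c("baseline_lld", "confounded_anxiety", "null_two_group")
  if (!spec_name %in% presets) {
    stop("unknown preset '", spec_name, "'; available: ",
         paste(presets, collapse = ", "))
  }
  cov_model <- default_covariate_model()
  shift <- 0
  if (spec_name == "confounded_anxiety") {
    shift <- 0.12
    cov_model$age_anxiety_slope <- -1.85
    cov_model$education_anxiety_slope <- -0.40
    cov_model$sex_anxiety_slope <- 0.22
  }
  generator_spec(
    n_subjects = n_subjects,
    precision_matrix = lld_precision(),
    item_thresholds = lld_item_thresholds(),
    anxiety_loading = rep(0, 10),
    severity_shift = shift,
    seed = seed
  )
}

#' Generate a synthetic cohort with gold-standard truth
#'
#' Samples the latent-Gaussian threshold model of a [generator_spec()]:
#' per-subject latent symptom vectors are multivariate normal with covariance
#' equal to the correlation-standardized inverse precision, shifted by the
#' latent anxiety factor, and cut into ordinal scores. Generation is
#' bit-reproducible given the spec (including its seed).
#'
#' @param spec A [generator_spec()].
#' @return A list with elements `cohort` (a validated `cohort_table` with
#'   `b1..b21` BAI items) and `gold` (class `gold_standard`: the true partial
#'   correlation matrix, the per-subject latent anxiety values, and the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  Sigma <- stats::cov2cor(solve(spec$precision_matrix))
  L <- chol(Sigma)
  A <- rnorm(n)
  Z <- matrix(rnorm(n * 10), n, 10) %*% L
  lat <- Z + outer(A, spec$anxiety_loading + spec$severity_shift)
  items <- vapply(1:10, function(j) {
    findInterval(lat[, j], spec$item_thresholds[[j]])
  }, numeric(n))
  bai_lat <- spec$bai_loading * A + matrix(rnorm(n * 21), n, 21)
  bai_items <- matrix(findInterval(bai_lat, spec$bai_thresholds), n, 21)
  cm <- spec$covariate_model
  age <- pmax(60, round(cm$age_mean + cm$age_anxiety_slope * A +
                          cm$age_sd * rnorm(n), 1))
  education <- pmax(0, round(cm$education_mean +
                               cm$education_anxiety_slope * A +
                               cm$education_sd * rnorm(n), 1))
  p_fem <- plogis(qlogis(cm$p_female) + cm$sex_anxiety_slope * A)
  sex <- ifelse(runif(n) < p_fem, "female", "male")
  df <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (j in 1:10) df[[paste0("m", j)]] <- as.integer(items[, j])
  df$bai_sum <- as.integer(rowSums(bai_items))
  for (j in 1:21) df[[paste0("b", j)]] <- as.integer(bai_items[, j])
  df$age <- age
  df$sex <- sex
  df$education_years <- education
  df$flags <- ""
  df$group <- NA_character_
  gold <- structure(
    list(true_partial_correlations = precision_to_pcor(spec$precision_matrix),
         true_anxiety_values = A,
         spec = spec),
    class = "gold_standard"
  )
  list(cohort = as_cohort_table(df), gold = gold)
}

#' Generate two groups from one generating process
#'
#' Draws `2 * n_per_arm` subjects from a single spec and splits them by
#' position, so any network difference between the two returned tables is
#' sampling noise. Used to study the type-I error of the network comparison
#' test.
#'
#' @param spec A [generator_spec()] (its `n_subjects` is overridden).
#' @param n_per_arm Subjects per group.
#' @param seed Integer seed.
#' @return List of two `cohort_table`s, `a` and `b`.
#' @export
generate_null_groups <- function(spec, n_per_arm, seed = 1L) {
  spec$n_subjects <- as.integer(2 * n_per_arm)
  spec$seed <- as.integer(seed)
  cohort <- generate_cohort(spec)$cohort
  list(a = cohort[seq_len(n_per_arm), , drop = FALSE],
       b = cohort[n_per_arm + seq_len(n_per_arm), , drop = FALSE])
}

#' Generate a severity-eligible participant pool with exclusion flags
#'
#' Simulates a recruitment pool in which every subject already meets the
#' MADRS severity cutoff (rejection sampling on the baseline preset) and a
#' specified number of subjects carry each diagnosis exclusion flag, so the
#' eligibility filter removes exactly the flagged subjects.
#'
#' @param n_pool Pool size (default 848).
#' @param flag_counts Named integer vector of subjects per exclusion flag
#'   (default: 5 bipolar, 8 schizophrenia, 59 other mental disorder).
#' @param madrs_cutoff Severity floor every subject must meet.
#' @param seed Integer seed.
#' @return A validated `cohort_table` of `n_pool` subjects.
#' @export
generate_eligible_pool <- function(n_pool = 848L,
                                   flag_counts = c(bipolar = 5L,
                                                   schizophrenia = 8L,
                                                   other_mental_disorder = 59L),
                                   madrs_cutoff = 10L,
                                   seed = 1L) {
  stopifnot(sum(flag_counts) <= n_pool,
            all(names(flag_counts) %in% KNOWN_FLAGS))
  spec <- preset_lld("baseline_lld", n_subjects = n_pool, seed = seed)
  cohort <- generate_cohort(spec)$cohort
  # replace under-cutoff subjects by redrawing until the pool is eligible
  draw_seed <- seed
  repeat {
    low <- which(madrs_sum(cohort) < madrs_cutoff)
    if (length(low) == 0) break
    draw_seed <- draw_seed + 1000L
    spec2 <- preset_lld("baseline_lld", n_subjects = length(low),
                        seed = draw_seed)
    repl <- generate_cohort(spec2)$cohort
    for (cl in setdiff(names(cohort), "subject_id")) {
      cohort[[cl]][low] <- repl[[cl]]
    }
  }
  set.seed(seed + 777L)
  flagged <- sample(n_pool, sum(flag_counts))
  cohort$flags[flagged] <- rep(names(flag_counts), times = flag_counts)
  as_cohort_table(cohort)
}
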