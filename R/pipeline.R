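# Full study orchestration: eligibility -> baseline network (+ centrality,
# bootstrap) -> anxiety-augmented network -> BAI split -> pre-matching NCT
# and demographics -> propensity matching -> post-matching NCT and
# demographics. One master seed; stage seeds derive from it by a stable hash
# of the stage name.

#' Derive a stage seed from the master seed
#'
#' Stable string hash of the stage name folded into the master seed, kept in
#' the 32-bit signed range, so every stage is reproducible independently of
#' execution order.
#'
#' @param seed Master integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1048573
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' @param cohort_path Path to the input cohort CSV (or `NULL` when a
#'   `cohort_table` is passed to [run_study()] directly).
#' @param cohort A [cohort_config()].
#' @param glasso A [glasso_config()].
#' @param matching A [match_config()].
#' @param alpha Significance level for reporting.
#' @param n_boot Bootstrap resamples for edge CIs.
#' @param n_perm NCT permutations.
#' @param seed Master seed.
#' @param output_dir Directory for result files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL,
                            cohort = cohort_config(),
                            glasso = glasso_config(),
                            matching = match_config(),
                            alpha = 0.05,
                            n_boot = 1000L,
                            n_perm = 1000L,
                            seed = 1L,
                            output_dir = "lldnet-results") {
  stopifnot(alpha > 0, alpha < 1)
  structure(
    list(cohort_path = cohort_path, cohort = cohort, glasso = glasso,
         matching = matching, alpha = alpha, n_boot = as.integer(n_boot),
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full study pipeline
#'
#' Executes, in order: eligibility filter; baseline 10-node network with
#' centrality and bootstrap edge CIs; anxiety-augmented 11-node network; BAI
#' split; pre-matching NCT and demographic report; propensity matching;
#' post-matching NCT and demographic report. Result files (CSV/JSON) are
#' written under `config$output_dir` and a JSON manifest with stage counts
#' and artifact paths is returned (and written as `manifest.json`).
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional `cohort_table` (otherwise read from
#'   `config$cohort_path`).
#' @return The manifest, invisibly (list with stage counts, headline
#'   statistics and file paths).
#' @export
run_study <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$cohort_path)) stop("no cohort given")
    cohort <- read_cohort(config$cohort_path)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path_of <- function(x) file.path(config$output_dir, x)
  manifest <- list(seed = config$seed, n_input = nrow(cohort),
                   defaults = list(
                     madrs_cutoff = config$cohort$madrs_cutoff,
                     bai_cutoff = config$cohort$bai_cutoff,
                     gamma = config$glasso$gamma,
                     n_lambda = config$glasso$n_lambda,
                     lambda_min_ratio = config$glasso$lambda_min_ratio,
                     caliper = config$matching$caliper,
                     caliper_scale = config$matching$caliper_scale,
                     n_boot = config$n_boot, n_perm = config$n_perm),
                   stages = list(), files = list())
  finish <- function() {
    jsonlite::write_json(manifest, path_of("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      finish()  # abort, leaving the manifest of completed stages on disk
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  eligible <- run_stage("eligibility", function() {
    suppressMessages(apply_eligibility(cohort, config$cohort))
  })
  manifest$stages$eligibility <- list(
    n_eligible = nrow(eligible),
    removed = as.list(attr(eligible, "removed")))

  baseline <- run_stage("baseline_network", function() {
    estimate_network(eligible, config$glasso)
  })
  write_network(baseline, path_of("baseline_network"))
  cent <- centrality_table(baseline)
  write.csv(cent, path_of("baseline_centrality.csv"), row.names = FALSE)
  boot <- run_stage("bootstrap", function() {
    bootstrap_edges(eligible, config$glasso, n_boot = config$n_boot,
                    seed = stage_seed(config$seed, "bootstrap"))
  })
  jsonlite::write_json(
    list(n_boot = boot$n_boot, n_failed = boot$n_failed,
         labels = boot$labels, point = boot$point, ci_low = boot$ci_low,
         ci_high = boot$ci_high),
    path_of("baseline_bootstrap.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  manifest$stages$baseline_network <- list(
    n = baseline$n,
    n_edges = sum(baseline$weights[upper.tri(baseline$weights)] != 0),
    lambda = baseline$lambda_selected,
    top_strength = cent$node[order(-cent$strength)][1:3])

  anx_net <- run_stage("anxiety_network", function() {
    estimate_network(eligible, config$glasso, include_anxiety_node = TRUE)
  })
  write_network(anx_net, path_of("anxiety_network"))
  anx_edges <- anx_net$weights["anxiety", ]
  manifest$stages$anxiety_network <- list(
    n_anxiety_edges = sum(anx_edges != 0),
    strongest_anxiety_edge = names(which.max(abs(anx_edges[
      names(anx_edges) != "anxiety"])))
  )

  groups <- run_stage("split", function() {
    split_by_anxiety(eligible, config$cohort)
  })
  manifest$stages$split <- list(n_low = nrow(groups$low),
                                n_high = nrow(groups$high))

  nct_pre <- run_stage("nct_pre_matching", function() {
    nct(groups$low, groups$high, config$glasso, n_perm = config$n_perm,
        seed = stage_seed(config$seed, "nct_pre"))
  })
  manifest$stages$nct_pre_matching <- list(
    s_observed = nct_pre$s_observed, m_observed = nct_pre$m_observed,
    p_strength = nct_pre$p_strength, p_structure = nct_pre$p_structure)
  tab_pre <- table2_report(groups$low, groups$high)
  write.csv(tab_pre, path_of("demographics_before.csv"), row.names = FALSE)

  labeled <- rbind(groups$low, groups$high)
  mres <- run_stage("matching", function() {
    match_cohort(labeled, config = config$matching)
  })
  write.csv(mres$pairs, path_of("matched_pairs.csv"), row.names = FALSE)
  write.csv(mres$balance, path_of("matching_balance.csv"), row.names = FALSE)
  manifest$stages$matching <- list(
    n_matched = mres$n_matched, caliper_logit = mres$caliper_used,
    smd_madrs_before = mres$balance$smd_before[
      mres$balance$covariate == "madrs_sum"],
    smd_madrs_after = mres$balance$smd_after[
      mres$balance$covariate == "madrs_sum"])

  mg <- matched_groups(labeled, mres)
  nct_post <- run_stage("nct_post_matching", function() {
    nct(mg$low, mg$high, config$glasso, n_perm = config$n_perm,
        seed = stage_seed(config$seed, "nct_post"))
  })
  manifest$stages$nct_post_matching <- list(
    s_observed = nct_post$s_observed, m_observed = nct_post$m_observed,
    p_strength = nct_post$p_strength, p_structure = nct_post$p_structure)
  tab_post <- table2_report(mg$low, mg$high, matched = mres, cohort = labeled)
  write.csv(tab_post, path_of("demographics_after.csv"), row.names = FALSE)

  manifest$files <- list(
    manifest = path_of("manifest.json"),
    baseline_network = path_of("baseline_network.json"),
    baseline_centrality = path_of("baseline_centrality.csv"),
    baseline_bootstrap = path_of("baseline_bootstrap.json"),
    anxiety_network = path_of("anxiety_network.json"),
    demographics_before = path_of("demographics_before.csv"),
    matched_pairs = path_of("matched_pairs.csv"),
    matching_balance = path_of("matching_balance.csv"),
    demographics_after = path_of("demographics_after.csv"))
  finish()
}
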