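# Shared fixtures: tiny hand-built cohorts and independent oracles used
# across test files. Everything is generated in code; no data files.

# A minimal valid 3-subject cohort data frame (no BAI items).
tiny_cohort_df <- function() {
  df <- data.frame(subject_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  set.seed(42)
  for (j in 1:10) df[[paste0("m", j)]] <- sample(0:6, 3, replace = TRUE)
  df$bai_sum <- c(5L, 20L, 16L)
  df$age <- c(70, 75.5, 81)
  df$sex <- c("female", "male", "female")
  df$education_years <- c(6, 0, 12.5)
  df$flags <- c("", "bipolar", "")
  df$group <- NA_character_
  df
}

# Cohort with n subjects from a given preset (validated cohort_table).
preset_cohort <- function(n, preset = "baseline_lld", seed = 1) {
  generate_cohort(preset_lld(preset, n_subjects = n, seed = seed))$cohort
}

# Generator spec with an arbitrary 10x10 precision matrix; defaults to the
# identity (independent latent symptoms) and BAI decoupled from the items.
custom_spec <- function(K = diag(10), n = 1000, seed = 1) {
  dimnames(K) <- NULL
  generator_spec(n_subjects = n, precision_matrix = K,
                 item_thresholds = lldnet:::lld_item_thresholds(), seed = seed)
}

# Build an assoc_matrix object around a given correlation matrix, for driving
# the glasso path directly with known inputs.
fake_assoc <- function(S, n = 1000) {
  p <- nrow(S)
  labels <- paste0("v", seq_len(p))
  dimnames(S) <- list(labels, labels)
  structure(list(labels = labels, values = S,
                 method_per_pair = matrix("polychoric", p, p),
                 psd_repaired = FALSE, n = n),
            class = "assoc_matrix")
}

# Build a symptom_network object from a weight matrix.
fake_network <- function(W) {
  p <- nrow(W)
  labels <- if (is.null(rownames(W))) paste0("v", seq_len(p)) else rownames(W)
  dimnames(W) <- list(labels, labels)
  structure(list(labels = labels, weights = W, lambda_selected = NA_real_,
                 ebic = NA_real_, n = NA_integer_, cluster_tags = NULL),
            class = "symptom_network")
}

# Exhaustive-path centrality oracle for small networks (p <= 7): enumerates
# every simple path per node pair, finds the minimal total length (edge
# length 1/|w|), and credits betweenness fractionally over tied minimal
# paths. Independent of igraph.
oracle_centrality <- function(W, tol = 1e-9) {
  p <- nrow(W)
  len <- ifelse(W != 0, 1 / abs(W), Inf)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, total) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- list(path = path, length = total)
        return()
      }
      for (nxt in seq_len(p)) {
        if (nxt %in% path || !is.finite(len[last, nxt])) next
        walk(c(path, nxt), total + len[last, nxt])
      }
    }
    walk(s, 0)
    out
  }
  dmat <- matrix(Inf, p, p)
  diag(dmat) <- 0
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      lens <- vapply(ps, `[[`, numeric(1), "length")
      dmin <- min(lens)
      dmat[s, t] <- dmat[t, s] <- dmin
      minimal <- ps[lens <= dmin + tol]
      for (pp in minimal) {
        inner <- setdiff(pp$path, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(minimal)
      }
    }
  }
  closeness <- vapply(seq_len(p), function(i) {
    di <- dmat[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) 0 else 1 / sum(di)
  }, numeric(1))
  list(closeness = closeness, betweenness = btw)
}

# Random sparse signed weight matrix on p nodes.
random_weights <- function(p, seed) {
  set.seed(seed)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < 0.55) {
        W[i, j] <- W[j, i] <- runif(1, -0.9, 0.9) |>
          (\(x) if (abs(x) < 0.05) 0.1 else x)()
      }
    }
  }
  W
}
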