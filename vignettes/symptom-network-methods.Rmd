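---
title: "Methods: regularized symptom networks for late-life depression with comorbid anxiety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lldnet` implements the full analysis chain used in psychometric network
studies of geriatric depression rated with the MADRS (10 clinician-rated
items, each 0–6) in cohorts that are split into low- and high-anxiety groups
by the BAI sum score (21 items, 0–3 each; cutoff 16). This vignette explains
the statistical machinery, the choices the package makes where the
literature leaves room, and what the synthetic-data generator does and does
not emulate.

## The model

Symptoms are modeled as a Gaussian graphical model (GGM) on a latent
continuous scale. Each observed ordinal item is a thresholded version of a
latent standard-normal variable; the network of interest is the sparse
partial-correlation structure of those latent variables. Estimation has
three stages:

1. **Ordinal association.** Every item pair gets a polychoric correlation:
   thresholds are fixed at the inverse-normal of the cumulative marginal
   proportions, then the latent correlation maximizes the bivariate-normal
   likelihood of the observed contingency table (two-step maximum
   likelihood). When a continuous anxiety node is added, its associations
   with the items are polyserial by default (the BAI sum, with 64 possible
   values, is treated as continuous; Pearson is available via
   `anxiety_method = "pearson"`). Two-step rather than full-information ML
   is the convention of the ordinal-network toolchain and is an order of
   magnitude cheaper; the difference is negligible at the sample sizes
   involved.
2. **Sparse precision estimation.** The graphical lasso solves the
   L1-penalized Gaussian log-determinant problem by coordinate descent over
   a log-spaced path of 100 penalties, from `lambda_max` (the largest
   absolute off-diagonal association, at which the model is empty) down to
   `lambda_max / 100`. Warm starts carry solutions along the path.
3. **Model selection.** The extended BIC,
   `EBIC = -2 loglik + E log(n) + 4 γ E log(p)` with `E` the edge count,
   picks the penalty. The default `γ = 0` reduces EBIC to ordinary BIC —
   the hyperparameter used for the analyses this package reproduces. Ties
   resolve toward the larger penalty (sparser model), deterministically.
   Edge weights are reported as partial correlations
   `-K_ij / sqrt(K_ii K_jj)`.

## Numerical choices

* The bivariate normal CDF uses Genz's adaptive Gauss–Legendre quadrature
  (3/6/10 point rules by correlation magnitude, with the separate
  high-correlation expansion); absolute error is below 1e-10 across the
  usable range, which the test suite verifies against an independent
  quadrature oracle.
* The latent correlation is maximized by Brent search on
  [-0.999, 0.999] with tolerance 1e-6; estimates are clipped at ±0.999.
* Empty contingency cells contribute no likelihood term and need no
  adjustment. Only 2×2 tables with a zero cell — where the unrestricted MLE
  diverges to ±1 — receive a 0.5 continuity correction in every cell. A
  blanket 0.5-correction on larger tables was evaluated and rejected: 7×7
  symptom tables almost always contain empty corner cells, and the blanket
  correction biases strong associations visibly downward (a perfect
  monotone relabeling estimates near 0.96 instead of the clipped 0.999).
* A pairwise-assembled correlation matrix can be indefinite; it is repaired
  by clipping eigenvalues at 1e-6, reconstructing, and rescaling to unit
  diagonal. The repair is flagged in `psd_repaired`.
* Glasso convergence is declared when the mean absolute change of the
  working covariance falls below 1e-6 times the mean absolute off-diagonal
  input; precision entries are exactly zero where the lasso coefficients
  are zero (pattern symmetrized by OR).
* All estimation is deterministic: the same association matrix yields a
  bit-identical network.

## Centrality

Strength is the sum of absolute incident weights. Closeness and betweenness
follow the weighted-network convention: edge length `1/|w|`, shortest paths
by Dijkstra (delegated to igraph), closeness as the inverse summed distance
over *reachable* nodes (0 for isolated nodes), betweenness with fractional
credit over tied shortest paths. The test suite validates both against an
exhaustive simple-path enumeration oracle on networks of up to 6 nodes.

## Resampling

Edge-weight accuracy uses the nonparametric bootstrap: subjects are
resampled with replacement, the full polychoric + glasso + EBIC chain is
re-run, and percentile 2.5/97.5 intervals are reported (n_boot default
1000; percentile rather than BCa, matching the ecosystem default).
Centrality stability uses case dropping: at each drop proportion, subjects
are subsampled without replacement and the Spearman correlation between
resampled and full-sample strength is recorded; the CS coefficient is the
largest drop proportion whose correlation stays ≥ 0.7 in at least 95% of
resamples. A resampled network with no edges carries no rank information
and is scored as zero correlation rather than discarded. All randomness
flows from a single integer seed.

## The network comparison test

Two groups are compared on three levels: global strength (absolute
difference of summed absolute edge weights), global structure (maximum
absolute edge difference), and individual edges (Holm-corrected two-tailed
permutation p-values). The null distribution pools the subjects and
re-splits them at the original group sizes, refitting the entire
estimation chain for both pseudo-groups at each permutation — costlier than
re-inverting a fixed association matrix but faithful to how the observed
statistics are produced. P-values use the plus-one estimator
`(1 + #{perm ≥ obs}) / (1 + n_perm)` and can never be exactly zero. The
pooled rows are put in a canonical sort order and the permutation draws the
smaller group, which makes seed-matched results exactly invariant to group
labeling. Because EBIC selection zeroes most edges, permutation statistics
are heavily tied and the test runs somewhat conservative at small
permutation counts; the type-I error stays within the binomial band around
the nominal level in the acceptance suite.

## Propensity-score matching

To separate "anxiety makes depression more severe" from "anxiety changes
the symptom network", high-anxiety subjects are matched 1:1 to low-anxiety
subjects on a logistic propensity model (default covariates: MADRS sum,
age, sex, education years). Matching is greedy nearest-neighbour on the
logit propensity, processing treated subjects in decreasing propensity
order, with ties broken toward the lowest subject order, and a caliper of
0.25 — interpreted, per the Rosenbaum–Rubin convention, as 0.25 standard
deviations of the logit propensity (raw-scale calipers are available via
`caliper_scale = "raw"`). Unmatched subjects are discarded. Balance is
reported as standardized mean differences with the pre-matching pooled SD
as denominator. The phrase "scores summed per covariate" that sometimes
describes this procedure is read as a single multivariable logistic model,
which is what the standard matching software fits.

Greedy caliper matching has an information limit: when the pre-matching
separation is large, the within-caliper nearest control sits systematically
below the treated subject and a residual standardized difference of order
one tenth of the pooled SD survives. An optimal monotone pairing does no
better, so this is a property of 1:1 matching without replacement, not of
the greedy heuristic.

## The synthetic cohort generator

Because clinical symptom-level data of this kind are not publicly
deposited, the generator provides cohorts with known truth. Latent symptom
vectors are multivariate normal with covariance equal to the
correlation-standardized inverse of a specified precision matrix (unit
latent variances make the thresholds identifiable — the standard polychoric
convention); items arise by thresholding. A latent anxiety factor `A ~
N(0,1)` drives the 21 BAI items (loading 1.1, thresholds 0.26/1.13/2.00,
calibrated once so that the expected high-anxiety fraction equals the
314/776 split of the motivating cohort and the BAI sum averages ≈ 15) and,
in the confounded preset, shifts every symptom's latent mean by
`severity_shift × A`. A mean shift leaves the partial-correlation structure
identical in both anxiety groups, which encodes "comorbid anxiety worsens
severity without changing the psychopathological structure" as the
generating truth that the matching + comparison pipeline should recover.

The `baseline_lld` preset seeds three symptom clusters
(dysphoric apathy/retardation, psychic anxiety, vegetative) with strong
within-cluster edges (reported–apparent sadness, concentration–lassitude,
pessimism–suicidality at partial correlation 0.35, supporting edges at
0.18–0.25) and one negative cross edge (reduced sleep – pessimistic
thought). In this preset the anxiety factor is fully decoupled from the
items: a shared factor loading on several items would add a rank-one
common component and change the marginal item precision pattern, which
would invalidate the preset's gold edge pattern as a recovery target.
Anxiety–item coupling therefore lives exclusively in the severity shift of
`confounded_anxiety`.

`severity_shift = 0.12` was fixed by a one-time joint calibration: it is
the largest shift at which (a) the high–low MADRS gap (~3.3 points) is
detected by a Welch test in essentially every replicate, (b) greedy caliper
matching brings the post-matching MADRS standardized mean difference below
0.1 in ≥ 90% of replicates, and (c) the post-matching comparison test is
null in ≥ 80% of replicates. Larger shifts reproduce a larger printed
severity gap but run into the matching information limit described above.
Covariates are sampled to loosely resemble a community geriatric cohort
(age ≈ 74 ± 8, education ≈ 6 years, ~72% female), with mild
anxiety-linked imbalance in the confounded preset.

What the generator does **not** emulate: item-specific threshold profiles
(all items share one marginal distribution), missing data, informative
dropout, measurement error beyond the threshold model, medication effects,
or any non-Gaussian latent dependence. Passing tests therefore demonstrate
that the pipeline recovers truth *under the latent-Gaussian threshold
model*, not that real MADRS data satisfy that model.

## Problem sizes and defaults

The package defaults are `n_lambda = 100`, `lambda_min_ratio = 0.01`,
`γ = 0`, `n_boot = 1000`, `n_perm = 1000`, caliper 0.25 SD(logit). The test
suite exercises the Monte-Carlo properties at reduced but statistically
meaningful sizes chosen as the package's own validation design: type-I
error with 200 replicate comparisons of 150 subjects per arm at 200
permutations; edge recovery with 20 replicates at the motivating cohort
size n = 776; matching balance and post-matching null comparisons with 50
replicates at n = 776 and 200 permutations.

## Known limitations

* Complete-case only: rows with any missing MADRS/BAI value are rejected at
  validation (no imputation is attempted, and none is claimed for the
  motivating study).
* The polychoric matrix is assembled pairwise; PSD repair perturbs all
  entries slightly when triggered.
* The NCT assumes exchangeability under the null; severity differences
  between groups make the pre-matching test a joint test of structure and
  severity-driven effects.
* Greedy 1:1 caliper matching discards subjects and retains a small
  systematic severity residual when separation is large (see above);
  paired tests on tightly matched pairs are very powerful against that
  residual, so a non-significant post-matching severity test should not be
  over-interpreted as exact balance.
* BIC selection (`γ = 0`) is liberal: expect a few small spurious edges at
  n in the hundreds; raise `γ` for sparser networks.
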