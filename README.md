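# lldnet

Symptom-network analysis of late-life depression with comorbid anxiety.

Psychometric network studies treat psychiatric disorders not as a latent
disease emitting symptoms, but as a system of symptoms influencing one
another. For ordinal clinician ratings such as the MADRS (10 items, each
scored 0–6), the standard pipeline estimates a Gaussian graphical model on
the latent scale: polychoric correlations between item pairs, a graphical
lasso fit of the sparse precision matrix, and EBIC selection of the
penalty, reporting edges as partial correlations
`w_ij = -K_ij / sqrt(K_ii K_jj)`. A clinical question in geriatric
psychiatry motivates the surrounding machinery: does comorbid anxiety
(BAI ≥ 16) *restructure* the depression symptom network, or does it merely
*inflate severity*? Because anxious patients are also more severely
depressed, naive group comparisons confound the two; the package therefore
combines a permutation network comparison test (NCT) with 1:1
propensity-score matching on severity and demographics, so that the
comparison can be rerun between severity-matched groups.

`lldnet` is written for biostatisticians and psychiatric-epidemiology
researchers who need this chain as tested, reusable building blocks:

* `read_cohort()` / `apply_eligibility()` / `split_by_anxiety()` — cohort
  I/O, MADRS ≥ 10 eligibility, BAI ≥ 16 grouping.
* `polychoric()`, `polyserial()`, `association_matrix()` — two-step ML
  ordinal associations with PSD repair, optional continuous anxiety node.
* `glasso_path()`, `select_ebic()`, `estimate_network()` — coordinate
  -descent graphical lasso over a 100-point penalty path, EBIC (γ = 0 ⇒
  BIC) selection.
* `centrality_table()` — strength, closeness, betweenness (lengths 1/|w|).
* `bootstrap_edges()`, `case_drop_stability()` — edge CIs and the CS
  coefficient.
* `nct()`, `edge_tests()` — permutation test of global strength, global
  structure, and Holm-corrected individual edges.
* `fit_propensity()`, `match_cohort()` — logistic propensity, greedy 1:1
  nearest-neighbour matching with a 0.25 SD(logit) caliper.
* `ttest_from_summary()`, `two_proportion_test()`, `paired_ttest()`,
  `table2_report()` — the demographic comparison table.
* `preset_lld()` / `generate_cohort()` — a latent-Gaussian threshold
  simulator with known sparse partial-correlation truth, including a
  severity-confounded preset for validating the matching step.
* `run_study()` — the full pipeline with one master seed and a JSON
  manifest.

## Worked example

Simulate a severity-confounded cohort of 776 elderly subjects, estimate the
baseline network, match, and compare the matched groups:

```r
library(lldnet)

g      <- generate_cohort(preset_lld("confounded_anxiety", 776, seed = 42))
cohort <- g$cohort

net <- estimate_network(cohort)
net
#> <symptom_network> 10 nodes, 15 edges, lambda = 0.04759, EBIC = 7051.06, n = 776

head(centrality_table(net)[order(-centrality_table(net)$strength), 1:3], 3)
#>                  node                      cluster  strength
#> 9 pessimistic_thought              psychic_anxiety 0.8910473
#> 7           lassitude dysphoric_apathy_retardation 0.7080636
#> 2    reported_sadness dysphoric_apathy_retardation 0.6650884

sp  <- split_by_anxiety(cohort)          # 474 low / 302 high anxiety
lab <- rbind(sp$low, sp$high)
m   <- match_cohort(lab)
m
#> <match_result> 298 pairs, caliper (logit) = 0.0912
#>        covariate   smd_before    smd_after
#>        madrs_sum  0.352789906  0.019727049
#>              age -0.001354632 -0.005745723
#>              sex  0.051296879 -0.007614676
#>  education_years -0.005247705 -0.034802856

mg <- matched_groups(lab, m)
nct(mg$low, mg$high, n_perm = 500, seed = 7)
#> <nct_result> global strength diff = 0.0839 (p = 0.8423), structure stat = 0.1299 (p = 0.6567), 500 permutations
```

Reading the output: the estimated network keeps 15 of 45 possible edges;
pessimistic thought, lassitude and reported sadness carry the most
strength. Before matching, the high-anxiety group is visibly more severe
(MADRS standardized mean difference 0.35); matching reduces that to 0.02
across 298 pairs. The post-matching NCT finds no difference in global
strength (p = .84) or structure (p = .66) — as it should, since this
preset generates both groups from one partial-correlation structure and
confounds only the severity.

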