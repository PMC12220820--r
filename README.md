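# panpcd

Pan-programmed-cell-death (pan-PCD) analysis for injured tissue
transcriptomics: derive an injury-specific core cell-death gene panel from
bulk expression across injury models, score single cells for panel activity,
stratify them into high/low activity populations, quantify per-cell-type
injury sensitivity with score slopes, and screen perturbation-profile
libraries for compounds that reverse the panel signature.

Programmed cell death after tissue injury (e.g. spinal cord injury) is not
one pathway but a web of interacting modalities — apoptosis, necroptosis,
pyroptosis, ferroptosis, autophagy, lysosome-dependent death, and others.
`panpcd` treats them jointly: a curated multi-pathway gene catalog is
intersected with injury differential expression and replicated across injury
models to yield a compact core panel, and that panel becomes the measuring
instrument for per-cell cell-death programme activity.

## The statistics at the core

* **Moderated differential expression.** For gene *g* with pooled two-group
  variance *s²_g* on *d_g* degrees of freedom, variances are shrunk toward an
  empirical-Bayes prior, with posterior variance
  *s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)* and
  *t = logFC / (s̃_g √(1/n_A + 1/n_B))* on *d₀ + d_g* df. The prior
  *(d₀, s₀²)* is moment-matched on log *s²_g* (digamma/trigamma equations,
  Newton iteration); `prior_df = 0` recovers the ordinary pooled t-test
  exactly. DEGs are called at |log₂FC| > 1.5 and *P* < 0.05 (strict).
* **Recovery-curve AUC score.** Per cell, genes are ranked by expression
  (seeded random tie-breaks); with *R(j)* the number of panel genes at rank
  ≤ *j* and *k* = ⌈`top_fraction`·n⌉,
  *score = Σ_{j≤k} R(j) / Σ_{j≤k} min(j, m)* ∈ [0, 1]. Being rank-based, the
  score is invariant to any monotone per-cell transform of expression.
* **Automatic high/low threshold.** Gaussian-kernel density (Silverman
  bandwidth, 512-point grid); the threshold is the density valley between the
  two dominant modes, falling back to mean + 2·sd when the distribution is
  not credibly bimodal. Cells are `high` iff score > threshold (strict).
* **Score slope.** Per cell type, OLS of score on a 0/1 sham/injured
  indicator: the slope equals the difference of group means, with 95% CI and
  p from the t-distribution; ratios of slopes get percentile-bootstrap CIs
  over cell-level resampling.
* **Connectivity screening.** A query signature (up/down panel genes by
  logFC sign) is compared to each compound's ranked perturbation profile via
  the classic two-arm Kolmogorov–Smirnov tag statistic,
  *s = (ks(up) − ks(down))/2* when the arms disagree in sign and 0 otherwise;
  library scores are scaled to ±100, p-values come from random tag-set
  permutations, and a compound is a consensus reverser when its scaled score
  is negative with *P* < 0.05 in **every** dataset. A Spearman-correlation
  mode handles continuous signatures.

All simulators (`simulate_bulk_timecourse()`, `simulate_cell_population()`,
`simulate_perturbation_library()`, `simulate_score_shift()`) plant ground
truth — responder genes, per-cell activity labels, compound classes — so
every stage of the pipeline is testable end to end without external data.

## Worked example

```r
library(panpcd)

sim    <- simulate_cell_population(cell_sim_config(n_cells = 1000, seed = 1))
scores <- score_cells_auc(sim$counts, sim$panel, sim$cell_meta, seed = 1)
(thr   <- detect_threshold(scores))
#> <pcd_threshold> 0.0469 (method: bimodal_minimum, 2 candidate modes)

strat <- stratify_cells(scores, thr)
high_fraction(strat, group)
#> # A tibble: 2 x 5
#>   group   n_cells n_high n_low frac_high
#>   <chr>     <int>  <int> <int>     <dbl>
#> 1 injured    1000    586   414     0.586
#> 2 sham       1000    194   806     0.194

tidy(group_slope(strat, "sham", "injured"))
#> # A tibble: 1 x 5
#>   term      estimate conf.low conf.high  p.value
#>   <chr>        <dbl>    <dbl>     <dbl>    <dbl>
#> 1 microglia   0.0390   0.0348    0.0432 5.10e-68
```

The simulated injured arm carries 60% planted high-activity cells against
20% in sham; the detected valley threshold recovers fractions of 0.586 and
0.194, and the slope — the per-cell-type injury-sensitivity metric — is the
mean score rise from sham to injured with its confidence interval.

`run_benchmark(seed = 1)` chains every stage (bulk simulation → panel
derivation → cell scoring → threshold → stratification → slopes → signature
→ 3-dataset consensus screen) and reports recovery metrics against the
planted truth.

## Packaged fixtures

`inst/extdata/` ships a **synthetic** 13-pathway pan-PCD catalog
(963 unique genes; `pcd_catalog_fixture()`) and a **synthetic** 68-gene core
panel spanning 7 PCD types (`pcd_panel_fixture()`). They are constructed
stand-ins anchored on canonical cell-death genes and sized like published
curations; use them for examples and pipeline tests, not biological
inference.
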