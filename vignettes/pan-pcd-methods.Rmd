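---
title: "Methods: pan-PCD panel derivation, cell scoring, and signature-reversal screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-PCD panel derivation, cell scoring, and signature-reversal screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpcd)
```

# Scope and model

`panpcd` implements a pipeline for studying pan-programmed-cell-death
(pan-PCD) activity after tissue injury. Cell death after injury is executed
through several interlocking programmes — apoptosis, necroptosis, pyroptosis,
ferroptosis, autophagy, lysosome-dependent death, entotic death, and more —
whose cross-talk makes single-pathway analyses incomplete. The package's
working objects are: a *catalog* (gene → set of PCD-type memberships merged
from pathway collections), a *panel* (the compact injury-specific core gene
list distilled from the catalog), per-cell *score tables*, per-cell-type
*slope tables*, and per-compound *connectivity tables*.

The pipeline has four stages, each usable on its own:

1. **Catalog curation** — merge GMT pathway sets, normalize symbols, keep
   full multi-membership.
2. **Panel derivation** — call injury DEGs per acute time point with a
   moderated t-test, pool them across time points, intersect with the
   catalog, replicate across additional injury models with rank-sum tests,
   and intersect across models.
3. **Cell scoring** — rank-based recovery-curve AUC per cell, automatic
   bimodal thresholding, high/low stratification, and group-contrast slopes.
4. **Connectivity screening** — KS tag statistics of an up/down query
   signature against ranked perturbation profiles, ±100 scaling, permutation
   p-values, and an all-datasets consensus reversal rule.

# Differential expression and the variance prior

`moderated_t_test()` computes, for each gene, the pooled two-group variance
$s_g^2$ on $d_g = n_A + n_B - 2$ degrees of freedom and shrinks it toward a
prior: $\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, with
$t = \mathrm{logFC} / (\tilde{s}_g \sqrt{1/n_A + 1/n_B})$ referred to
$t_{d_0 + d_g}$. When `prior_df` is unset, $(d_0, s_0^2)$ is estimated by
moment matching on $\log s_g^2$: under the scaled-F model,
$E[\log s_g^2]$ and $\mathrm{Var}[\log s_g^2]$ are digamma/trigamma
expressions in $d_0$ and $d_g$, and the trigamma equation is inverted by
Newton iteration. Two boundary conventions matter:

* `prior_df = 0` reproduces the ordinary pooled two-sample t-test exactly
  (verified to 1e-10 against a textbook oracle in the test suite);
* when the moment estimate finds no excess dispersion the prior degrees of
  freedom are infinite and the common variance is the arithmetic mean of the
  gene variances, matching the reference empirical-Bayes implementation. In
  that branch we keep the contractual $d_0 + d_g$ (infinite) reference
  distribution; the reference implementation caps total df at the summed
  residual df, which perturbs p-values in the fourth decimal only.
* a gene with zero variance and zero logFC carries no evidence: $p = 1$.

DEG calls use strict thresholds $|\log_2 FC| > 1.5$ and $P < 0.05$; a gene
exactly at the fold-change boundary is excluded. These thresholds are the
conventional acute-injury settings and are exposed as arguments.

**Design choice (DEG pooling).** Per-time-point DEG sets from the acute
window (1/3/7 days post-injury) are *unioned* before intersecting with the
catalog: the panel should capture genes active at *any* acute phase, and the
union matches how a single injury-responsive DEG pool is contrasted with the
catalog in practice. `combine = "intersection"` is available for the
stricter reading.

**Design choice (rank-sum refinement).** Cross-model replication uses an
unadjusted two-sided Wilcoxon rank-sum test at $\alpha = 0.05$ per candidate
— this is a per-gene replication filter on a pre-selected list, not a
discovery scan, so family-wise correction would be miscalibrated. The exact
null is used when both groups have ≤ 10 tie-free samples; otherwise the
normal approximation with tie correction. Injured samples are pooled across
time points against sham by default (per-time-point testing is a config
choice on the caller's side). Candidates missing from a model's platform are
*dropped and reported*, never silently retained: an untestable gene cannot
claim replication.

# Cell scoring

## Recovery-curve AUC

Each cell's genes are ranked by expression, rank 1 highest. With $m$ panel
genes in the measured universe, $k = \lceil \text{top\_fraction} \cdot n
\rceil$, and $R(j)$ the count of panel genes at rank $\le j$, the score is

$$ \mathrm{AUC} = \frac{\sum_{j=1}^{k} R(j)}{\sum_{j=1}^{k} \min(j, m)} \in [0, 1]. $$

`top_fraction` defaults to 0.05 — the top 5% of the ranking, the documented
default of the reference rank-AUC tool — and is exposed because panels much
smaller than $k$ saturate slowly. Ties (dominated by the sparse-count zero
block) are broken by a *seeded random shuffle*: any deterministic tie order
(alphabetical, input order) would bias panel genes systematically, whereas a
seeded shuffle is unbiased and reproducible. A corollary, enforced by tests:
the score is invariant under any strictly monotone per-cell transform, so
raw counts, CPM, or log-normalized input give identical scores.

## Module score

The complementary mean-expression score subtracts, per cell, the mean of
control genes drawn (seeded, with replacement, `n_ctrl = 100` per panel
gene) from the same average-expression bin (`n_bins = 24` equal-frequency
bins) from the mean of panel genes. Expression-matched controls remove the
depth/abundance component: a null panel scores ≈ 0, and adding a per-cell
constant leaves scores unchanged (exactly, when the constant offsets apply
to whole cells, since bins depend only on gene averages).

## Threshold and strata

`detect_threshold()` fits a Gaussian KDE (Silverman bandwidth `nrd0`,
512-point grid). If at least two modes reach 5% of the peak density, the
threshold is the density minimum strictly between the two highest modes
(`bimodal_minimum`); otherwise mean + 2·sd, clipped to the observed range
(`mean_plus_2sd`). The applied method is always recorded — the two
heuristics answer different questions and downstream strata must be
auditable. This is our concretization of the reference tool's
multi-heuristic "automatic" threshold, not a claim of numeric equivalence to
it; on real cord-injury data that tool reported a threshold of 0.13, while
the synthetic study here detects its valley near 0.04–0.05 (the simulated
score distribution is sharper than real data). Stratification is strict:
`high` iff score > threshold, so a cell exactly at the threshold is `low`.
Requiring ≥ 50 cells guards the KDE; with fewer cells the valley position is
noise.

## Slopes and slope ratios

`group_slope()` regresses score on a 0/1 indicator per cell type: the OLS
slope *is* the difference of group means (identity asserted to 1e-12 in
tests); the regression framing supplies the CI and p. Pooling all
post-injury time points against sham is the default contrast. Zero-variance
inputs return slope 0 with $p = 1$; perfectly separated inputs (zero
residual variance, nonzero slope) return a degenerate CI at the point
estimate with $p = 0$ rather than tripping the regression machinery.

`slope_ratio()` compares two populations (e.g. adult vs neonatal microglia)
by the ratio of their slopes, with a percentile bootstrap over cells
resampled within each population × group stratum. A cell-level bootstrap is
used instead of the delta method because score distributions are bimodal
and truncated at [0, 1]. When the denominator's CI spans zero the ratio is
flagged unstable (and a zero denominator is an error).

# Enrichment and connectivity

`preranked_enrichment()` implements the weighted running-sum statistic:
genes sorted by statistic descending, hits advance by $|r|^w$ normalized
over hits, misses by $1/(n - m)$; the enrichment score is the signed maximum
deviation, in $[-1, 1]$. The null permutes gene labels; NES divides the
score by the mean magnitude of same-sign permutation scores, and the
p-value uses the add-one estimator $(1 + \#\{\text{same-sign } |es_\pi| \ge
|es|\})/(1 + \#\text{same-sign})$, which can never return 0 at finite
permutation counts.

`ks_connectivity()` uses the classic two-arm tag KS statistic: for a tag set
with ascending profile ranks $V_{(1..t)}$ among $n$ genes,
$a = \max_j [j/t - V_{(j)}/n]$, $b = \max_j [V_{(j)}/n - (j-1)/t]$,
$ks = a$ if $a > b$ else $-b$; the raw connectivity is
$s = (ks(\text{up}) - ks(\text{down}))/2$ when the arms disagree in sign and
0 otherwise. The division by 2 keeps $s \in [-1, 1]$; library-wide scaling
then maps the strongest mimic/reverser to ±100 per run, preserving signs and
zeros.

**A property worth knowing.** The same-sign → 0 convention puts a large
atom (≈ 46% under the null) at $s = 0$, hence at $p = 1$: KS-mode
permutation p-values are uniform in their lower range and conservative above
it. That is the correct behaviour of this statistic, not a defect — but it
means distribution-level uniformity checks belong to the continuous
correlation mode (`correlation_connectivity()`, Spearman over shared genes
with a shuffle null), whose p-values are verifiably Uniform(0,1) under the
null. The screening decision at $\alpha = 0.05$ uses only the calibrated
lower tail either way.

Both scoring modes feed `consensus_screen()`: a compound is retained when
its scaled score is negative and $P < \alpha$ in **every** dataset (missing
compounds cannot be retained), ranked by ascending mean scaled score. KS
mode is the default because the ±100 convention the field quotes is
KS-based; the dichotomized-vs-continuous query question is left to the user
since both modes are first-class.

# The synthetic study

The generators define the study conditions the tests and the acceptance
script run under; all are pure functions of their config (seed included).

* **Bulk time course** (`bulk_sim_config()`): log2 expression, baseline
  means Uniform(2, 10), Gaussian noise sd 0.2, additive injury effect 2.0
  (log2) on responder genes at 1/3/7 dpi, 4 replicates per arm across three
  injury models (crush, contusion, hemisection); 30 core responders shared
  by all models plus 10 model-specific responders each, inside a 200-gene
  catalog within 1000 genes. Age-dependent attenuation multiplies the effect
  by (1, 1, 1) in the adult-like arm and (1, 0.4, 0.1) in the neonatal-like
  arm — a persistent vs attenuating acute response. Four replicates per arm
  were chosen because a 3-vs-3 two-sided exact rank-sum test cannot reach
  $p < 0.05$ (its smallest attainable p is 0.1), so the cross-model
  replication filter needs at least 4-vs-4; four is also a realistic
  microarray group size.
* **Single cells** (`cell_sim_config()`): negative-binomial UMI counts
  (dispersion 0.5, i.e. size 2), library sizes LogNormal(log 5000, 0.3),
  2000 genes, 2000 cells per arm; panel-gene relative abundances multiplied
  by 3 in latent high-activity cells, whose prevalence is 0.2 in sham and
  0.6 in injured arms — mirroring the roughly 20% → 60% shift in
  high-scoring cells reported for injured cord. Panel genes are planted at
  mid-to-upper baseline abundance (0.55–0.90 abundance quantiles): PCD genes
  are moderately expressed in vivo, and a rank-based scorer cannot see
  elevation of genes whose counts stay at zero.
* **Score shifts** (`simulate_score_shift()`): Gaussian score tables with
  planted group shifts 0.16 (adult-like) and 0.02 (neonatal-like), sd 0.05,
  2000 cells per arm — an 8:1 slope contrast echoing the adult/neonatal
  sensitivity gap without claiming numeric reproduction of any dataset.
* **Perturbation libraries** (`library_sim_config()`): 5 reversers
  ($-\gamma \cdot$ signature + noise), 2 mimics ($+\gamma$), 43 inert
  (noise), $\gamma = 1$, noise sd 0.5, 1000 genes.

What the simulation does **not** emulate: batch effects, ambient RNA,
doublets, cell-type mixtures with shared markers, platform-specific
microarray noise, or dependence between compounds. Passing tests therefore
demonstrate that the algorithms recover what they are defined to recover
under clean planted signal — they do not certify performance on real data,
where the thresholds and score distributions will differ (see the threshold
note above).

# Numerical choices and degenerate inputs

* Gene symbols are matched case-insensitively and stored in mouse
  title-case (`Gsdmd`), since source collections mix human and mouse styles;
  panels are matched to measured universes case-insensitively, returning the
  universe's own spelling.
* Seeded randomness is confined: every stochastic routine takes a `seed`
  argument and restores the caller's RNG state (`withr`); pipeline stages
  derive independent child seeds from one master seed.
* Rank ties in profiles for connectivity use `ties.method = "first"` after
  the stated descending sort; tag permutation nulls sample ranks directly,
  which is exact for tie-free profiles and is shared across compounds of a
  library run (the null depends only on arm sizes and universe size).
* Degenerate paths are explicit rather than accidental: all-zero cells
  error with offending ids; empty panel–universe overlap errors; empty
  model intersections error with per-model sizes; single-compound libraries
  scale to ±100; identical scores stratify everything low.
* Benchmark problem sizes (1000–2000 genes, 2000 cells/arm, 50-compound
  libraries, 1000 permutations/bootstraps) are the package's default study
  scale: large enough for stable rank statistics and KDE thresholds, small
  enough that the full benchmark runs in well under a minute on one core.

# Known limitations

* The panel-derivation step assumes input expression is already normalized
  and log2-scale; no within-package normalization is attempted for bulk
  data (single-cell module scoring has `lognormalize_counts()`).
* The automatic threshold is a heuristic; on borderline bimodality the
  `mean_plus_2sd` fallback is conservative and should be inspected via
  `autoplot()` on the threshold object.
* KS-mode permutation p-values are conservative above their calibrated
  lower tail (the $s = 0$ atom); rank compounds by score, decide by the
  $\alpha$ tail.
* The scorers quantify *panel activity*, not cell death itself; a high
  score marks transcriptional engagement of death programmes, which only
  orthogonal measurements can confirm.
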