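---
title: "Consensus ligand-receptor scoring: models, parameters and design"
author: "CCCbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ligand-receptor scoring: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CCCbench)
```

# The inference problem

Cell-cell communication (CCC) analysis asks which ligand-receptor
interactions are likely active between pairs of cell populations in a
clustered single-cell RNA-seq dataset. A CCC *event* is modelled as a
transmitter (ligand-side) protein entity expressed by a *source* cluster
and a receiver (receptor-side) entity expressed by a *target* cluster.
Which transmitter binds which receiver comes from a prior-knowledge
resource; the expression data supply the evidence that a given cluster pair
uses a given interaction. Both autocrine (source = target) and paracrine
pairs are scored.

Entities may be heteromeric complexes (subunits joined by `"_"` in their
canonical, upper-cased, lexicographically sorted form). Throughout the
package a complex is represented in each cluster by its *minimally
expressed* subunit: every statistic of the entity is taken from the subunit
with the smallest cluster log-mean (the fraction of expressing cells is the
minimum across subunits). This is the conservative convention: a complex
can never appear more active than its weakest part.

# Cluster-level statistics

All scoring systems consume one `ClusterStats` object computed by
`summarizeClusters()` from the log-normalized layer
(`normalizeCounts()`: each cell scaled to 10,000 total counts, then
`ln(1 + x)`). Per gene `g` and cluster `c` it holds:

* `mean_log`: mean of the log-normalized values; `mean_lin`: mean of their
  de-logged values.
* `prop`: fraction of cells with non-zero expression.
* `log2fc`: one-vs-rest fold change
  `log2((mean_lin_in + 1) / (mean_lin_rest + 1))`. The pseudocount of 1
  bounds the statistic at zero expression; the de-logged scale makes fold
  changes interpretable as expression ratios.
* `zscore`: z-score of the gene's cluster log-means *across clusters*
  (0 when the cross-cluster standard deviation is 0). Scoring across
  cluster means rather than cells is what makes this a cluster-specificity
  measure.
* `de_p`: two-sided one-vs-rest Wilcoxon rank-sum p-value. The
  implementation is a vectorised rank-sum: exact (via the null rank-sum
  distribution) when a gene has no ties and both groups have fewer than 50
  cells, otherwise a normal approximation with tie and continuity
  corrections, matching `stats::wilcox.test`. Raw (not adjusted) p-values
  are used by the differential-expression filter.
* `mu`: the mean over all entries of the normalized matrix, the
  regularisation constant of the LRscore. The normalized layer is used for
  consistency with every other statistic (the originating method's wording
  does not pin down a layer); this is exposed should an alternative be
  needed.

# The six scoring systems

With `l = mean_log(ligand, source)`, `r = mean_log(receptor, target)`
(entity-level, min-subunit), all methods first require both entities to be
expressed in at least `prop_threshold` (default 0.10, boundary inclusive)
of their cluster's cells.

1. **CellPhoneDB-style** (`scoreCellPhoneDB`): magnitude `(l + r) / 2`;
   cluster labels are reshuffled globally `n_permutations` times (default
   1000) and the one-sided empirical p-value is the fraction of
   permutations whose magnitude reaches the observed value. Ties count
   toward the p-value and `0/N` is allowed (no `+1` smoothing): the p-value
   is an empirical null over exactly `N` draws. Specificity is `1 - p`.
2. **Connectome-style** (`scoreConnectome`): `weight_norm = l * r`;
   `weight_scale` is the mean of the two cross-cluster z-scores. Every
   subunit of both entities must pass the Wilcoxon filter
   (`de_p <= 0.05`, inclusive).
3. **NATMI-style** (`scoreNATMI`): magnitude `l * r`; specificity is the
   product of each entity's share of its summed cluster means,
   `(l / sum_c l_c) * (r / sum_c r_c)`. The denominators run over *all*
   clusters (they are global normalisers, not restricted to clusters
   passing the proportion filter); a zero denominator yields 0. Exclusive
   expression gives specificity 1; uniform expression over `C` clusters
   gives `1 / C^2`.
4. **SingleCellSignalR-style** (`scoreSCA`):
   `LRscore = sqrt(l r) / (mu + sqrt(l r))`, exactly 0.5 when
   `sqrt(l r) = mu`. Two optional filters mirror the originating method's
   usage: `|log2fc| >= 1.5` on both entities, and `LRscore >= 0.5`
   (both inclusive, both on by default). Magnitude-only.
5. **logFC mean** (`scoreLogFCMean`): the average of the ligand's and the
   receptor's one-vs-rest log2 fold changes; a single-score method.
6. **Crosstalk scores** (`scoreCrosstalk`): the product of min-max
   normalised PEM and NST components. `PEM_gc = max(0, log10(S_gc /
   E_gc))` where `S` sums normalized expression per gene and cluster and
   `E_gc` is its expectation from the margins; the pair PEM is the mean of
   the ligand's PEM in the source and the receptor's in the target, and any
   entity with PEM 0 forces the score to 0. NST penalises autocrine
   signalling via the mutual information (base 2) of ligand and receptor
   across the source cluster's cells after equal-frequency binning into
   `crosstalk_bins = 4` bins: paracrine pairs get `1 - minmax(MI)`,
   autocrine pairs the minmax-rescaled inverse `1 / (1 - minmax(MI) +
   eps)`. The published description of these scores is qualitative; the
   concrete binning, the pair-PEM mean and the autocrine inverse transform
   are this package's operationalisation, kept behind `methodConfig()` so
   alternates can be slotted in. Binning uses quantile boundaries with
   `findInterval`, so tied values share a bin and the result is invariant
   under cell permutation (at the price of unbalanced bins when zeros
   dominate). A min-max over constant values is defined as 0.5 everywhere
   (it only matters when the forced-zero rule already applies or a single
   combination exists).

# Consensus by robust rank aggregation

Each method is ranked by its recommended key (`rankInteractions()`):
ascending permutation p with magnitude breaking ties, or descending
specificity/magnitude as appropriate, with average ranks on ties. The rank
matrix (`buildRankMatrix()`) spans the *union universe* of interactions
surviving any method's filters; normalized ranks are divided by the
universe size and interactions a method filtered out are imputed at the
maximum rank 1. For sorted normalized ranks `r(1) <= ... <= r(K)` the rho
statistic is `min_k P(Beta(k, K - k + 1) <= r(k))` — the probability that
the k-th of K uniform order statistics falls at or below `r(k)` — and the
corrected score is the Bonferroni bound `min(rho K, 1)`, the standard form
of the published aggregation algorithm (exact rho null distributions are
deliberately out of scope). Consensus ranks ascend by corrected score.

Planted-interaction recovery is evaluated on this union-universe ranking:
the median planted interaction's normalized rank is compared with 0.05.
Measuring recovery within each method's post-filter survivor list would be
misleading for strongly filtering methods (after the `|log2fc| >= 1.5`
prefilter the survivors on synthetic data are almost exclusively planted
pairs), so the shared universe with max-rank imputation — the same
construction the consensus uses — is the reference frame.

# Evaluation components

**Top-k overlap.** `topRanked()` keeps the top `k` (default 1000) or top
fraction (ceiling) *including ties* at the boundary; `jaccardMatrix()`
compares runs and summarises each group (same method across resources, or
same resource across methods) by its median off-diagonal pairwise Jaccard
index. `relativeStrength()` min-max scales a method's scores and divides
each cluster's mean scaled score (as source and as target) by the overall
mean; constant scores scale to 0.5 with a warning.

**Cytokine activities.** `buildPseudobulk()` sums raw counts per cluster
(`log2(1 + sum)`), dropping per cluster the genes expressed in under 10%
of its cells or with a summed count not above 5 (the count bound is
strict, the proportion bound inclusive). `mlmActivities()` regresses one
profile jointly on all cytokine signature columns; the t-value of each
coefficient is the activity score, and a cytokine is called active in a
cluster when its score is positive and the Benjamini-Hochberg FDR is at or
below 0.05 (inclusive).

**Spatial colocalization.** Cluster proportion vectors across spots are
Pearson-correlated; the off-diagonal coefficients are z-scaled globally
(one pooled distribution, not per cluster) and a pair is colocalized at
`z >= 1.645` (inclusive), the upper 5% tail. Neighborhood-enrichment
z-score matrices are thresholded at the same value; calls are made over
unordered pairs using the larger of the two directed entries.

**Rank-interval odds ratios.** At each cutoff over a grid spanning
100-10,000 (`{100, 250, 500, 1000, 2500, 5000, 10000}` by default; only
the range ends are prescribed, the interior grid is this package's
choice), membership in the top of the ranking is cross-tabulated against
the binary modality call. The odds-ratio point estimate is the sample OR
with Haldane's `+0.5` on zero cells (flagged `capped`); the p-value is the
exact test on raw counts.

**Receptor specificity.** Protein abundance profiles are centred-log-ratio
transformed (`ln(x+1)` minus the profile mean), z-scored across clusters
per receptor, and thresholded at 1.645 to define the positive class.
AUROC uses the supplied prediction scores; AUPRC is averaged over 100
seeded draws with the negative class downsampled to the positive count,
binding the random expectation to 0.5. The average-precision estimator has
a small positive finite-sample bias (order `1/n_positives`), which is why
null-calibration checks use fixtures with on the order of a hundred
positives.

# Robustness analyses

Four seeded manipulations over fractions in [0, 0.40]: per-cluster cell
subsampling, shuffling a fraction of labels (a random subset's labels are
permuted among themselves, preserving cluster sizes; fixed points make the
realised mislabeled share smaller than nominal), and resource corruption
replacing a share of records with random ordered pairs of the 2000 most
variable genes — either uniformly or selectively sparing the records
underlying the baseline top set. The baseline is each method's top 250
(ties included) on unmodified inputs and the reported statistic is the
overlap fraction with the perturbed top 250, 5 repetitions per fraction.
In the packaged checks the shuffle-label sweep uses the grid
`{0, 0.2, 0.4}` with 5 repetitions and 100 permutations for the
permutation-based method; these are analysis-size choices (the overlap
statistic depends on ranks, which stabilise well below 1000 permutations).

# The synthetic scenario

`ccScenario()` fixes the study conditions: 2000 genes, 20 clusters of 100
cells, negative binomial counts (mean 0.5, dispersion 2) with log-normal
per-cell library factors (CV 0.3), 20 planted ligand-receptor pairs whose
ligand is raised 8-fold in its source cluster and receptor (all subunits)
in its target cluster, a quarter of planted receptors emitted as 2-subunit
complexes, and 180 decoy resource records among genes untouched by the
planting. These defaults are chosen to resemble a moderately sized,
moderately overdispersed droplet-based dataset in which planted signals are
strong but not degenerate; `generateModalities()` adds spot proportions
with shared latent factors for colocalized pairs, disjoint-support cytokine
signatures named after the planted ligands, and protein abundance elevated
5-fold for planted receptors.

What passing tests on this generator do **not** show: the generator has no
batch effects, doublets, ambient RNA, cluster imbalance or annotation
error, and its decoys are expression-uniform, so real-data performance —
where filters interact with technical structure — is not certified by
these checks. Two consequences of its construction are worth knowing.
First, recovery is near-ceiling by design (planted effects are 8-fold);
the checks are regression guards on the scoring semantics, not benchmarks.
Second, the z >= 1.645 ground-truth call for receptor abundance has a
~5-10% false-positive rate on noise-only decoy receptors (the z-score is
scale-invariant, so no noise level avoids this), which bounds the
attainable AUROC of any prediction against that truth well below 1; the
cleaner planted signals are the cytokine activities and colocalization
calls.

# Degenerate inputs and numerical conventions

* Cells with zero total counts are an error naming the cell; all-zero
  genes are carried through as zeros.
* A cluster with fewer than 3 cells warns but is summarised; a cluster
  smaller than the crosstalk bin count reduces the bin count with a
  warning.
* Entities with any subunit absent from the data are dropped from scoring.
* Zero cross-cluster standard deviation gives z-score 0; `mu <= 0` is a
  hard error for the LRscore.
* Permutation p-values compare with `>=` on magnitudes computed through
  the same code path as the observed value, so exact ties (e.g. constant
  data) give p = 1.
* The enrichment background is the union of all resources in the
  collection *including* the tested resource (a resource equal to the
  collection has odds ratio exactly 1); FDR correction spans all
  resource-by-category tests of one annotation database.
* OmniPath-style curation filtering is exposed as
  `filterByCuration(min_refs = 1)` — "at least one literature reference" —
  since the exact threshold is not pinned down by convention.

# Limitations

The package scores one-to-one transmitter-receiver interactions only:
probability models with downstream mediators, deconvolution, neighborhood
enrichment from coordinates, ortholog mapping and live resource retrieval
are out of scope (their outputs are consumed as inputs where relevant).
Ranks, not calibrated probabilities, are the comparable currency across
methods; the consensus corrected score is a Bonferroni-bounded order
statistic, not a p-value.
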