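# CCCbench

Consensus ligand-receptor scoring and evaluation of cell-cell
communication from clustered single-cell RNA-seq data.

Cell-cell communication (CCC) tools combine a prior-knowledge resource of
transmitter-receiver (ligand-receptor) interactions with a scoring method
that weighs each interaction by the expression of the transmitter in a
source cluster and the receiver in a target cluster. Published tools
differ in both ingredients and disagree substantially in their top
predictions, which makes a common interface — same input, same filters,
comparable ranks — the prerequisite for comparing, aggregating and
evaluating them. CCCbench is for computational biologists who want to run
several scoring systems on one dataset, build a consensus, and quantify
how much the predictions agree with each other, with auxiliary modalities,
and with themselves under noise.

## What it computes

**Six scoring systems under one interface** (all operating on cluster-level
statistics of the log-normalized expression, with heteromeric complexes
represented by their minimally expressed subunit, and both entities
required in ≥ 10% of their cluster's cells):

| method | magnitude | specificity |
|---|---|---|
| `cellphonedb` | (l + r)/2 | 1 − permutation p (1000 label reshuffles) |
| `connectome` | l · r | mean of cross-cluster z-scores |
| `natmi` | l · r | (l/Σ<sub>c</sub> l<sub>c</sub>) · (r/Σ<sub>c</sub> r<sub>c</sub>) |
| `sca` | √(l·r)/(μ + √(l·r)) | — |
| `logfc` | mean of one-vs-rest log2FC | same |
| `crosstalk` | minmax(PEM) · minmax(NST) | same |

with l, r the ligand/receptor cluster log-means and μ the dataset-wide
mean of the normalized matrix.

**Consensus** by robust rank aggregation: for each interaction's sorted
normalized ranks r(1) ≤ … ≤ r(K) across K methods (missing entries imputed
at the maximum rank 1),

ρ = min<sub>k</sub> P(Beta(k, K−k+1) ≤ r(k)),  corrected score = min(ρK, 1).

**Evaluation**: top-k overlap with ties (Jaccard matrices, cell-type
interaction frequencies, relative interaction strength); robustness of
each method's top-250 to cell subsampling, label shuffling and resource
corruption (0–40%, 5 repetitions); agreement with cytokine activities
(pseudobulk + multivariate linear model, rank-interval Fisher odds
ratios), spatial colocalization (proportion correlations or
neighborhood-enrichment z-scores at z ≥ 1.645) and receptor protein
abundance (AUROC / downsampled AUPRC). A resource toolkit covers complex
dissociation, unique/shared counts, pairwise similarity, Fisher category
enrichment with FDR tiers, and localisation/curation filtering. A seeded
synthetic-data generator plants ground-truth interactions, colocalized
cluster pairs, active cytokines and specific receptors.

## Worked example

```r
library(CCCbench)

sc  <- ccScenario(n_genes = 500, n_clusters = 6, cells_per_cluster = 50,
                  n_planted_pairs = 6, n_decoy_interactions = 40, seed = 42)
gen <- generateDataset(sc)           # SingleCellExperiment + ground truth
res <- generateResource(sc, gen$truth)
res
#> LRResource with 46 interactions from 1 resource
#>   complex-containing records: 2

scored <- scoreMethods(gen$dataset, res,
                       config = methodConfig(n_permutations = 500, seed = 42))
table(scored$method)
#> cellphonedb  connectome   crosstalk       logfc       natmi         sca
#>        1656          67        1656        1656        1656          21

cons <- consensusRank(scored)
head(attr(cons, "rra"), 6)
#>                    interaction          rho corrected_score
#> 1569       C05^C06^G0005^G0011 1.986086e-16    1.191651e-15
#> 923        C03^C04^G0003^G0009 7.576315e-16    4.545789e-15
#> 1246       C04^C05^G0004^G0010 7.576315e-16    4.545789e-15
#> 277  C01^C02^G0001^G0007_G0013 2.262276e-15    1.357365e-14
#> 600  C02^C03^G0002^G0008_G0014 5.523134e-13    3.313880e-12
#> 236        C06^C01^G0006^G0012 1.501777e-12    9.010663e-12
```

The six interactions with the smallest corrected scores are exactly the
six planted (source, target, ligand, receptor) tuples — note the two
heteromeric receptors (`G0007_G0013`, `G0008_G0014`) recovered through the
min-subunit rule. Each row of `scored` is one (source, target, ligand,
receptor, method) record with magnitude, specificity and, for the
permutation method, a p-value; `connectome` and `sca` return fewer rows
because their differential-expression filters remove non-specific
combinations. Downstream:

```r
rk  <- rankInteractions(cons, "consensus")
top <- topRanked(rk, k = 50)              # ties at the boundary included
celltypeFrequencies(top, "source")        # share of top edges per cluster
```

A thin command-line wrapper with subcommands
`simulate | score | consensus | overlap | robustness | agreement |
resource-stats` is installed at
`system.file("scripts", "ccc-cli.R", package = "CCCbench")`.

See `vignettes/ccc-consensus.Rmd` for the statistical details and design
rationale.

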