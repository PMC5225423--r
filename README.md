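# miRpanel

Circulating miRNAs are attractive minimally-invasive biomarkers for
diseases — such as chronic pancreatitis — whose late-stage diagnosis
comes too late to preserve organ function. A typical discovery study
profiles a few hundred miRNA probes in two groups of serum/plasma
samples (patients vs healthy controls), screens for differentially
expressed miRNAs (DEmiRs), asks which single miRNAs or correlated
miRNA pairs separate the groups as classifier features, and then asks
*why* pairs act together by testing whether their shared target genes
concentrate in common pathways. miRpanel packages that entire workflow
for R users — bioinformaticians and biostatisticians running two-group
miRNA microarray panels — as tested, composable functions.

## What it computes

1. **Differential screen.** Per-miRNA moderated t (limma
   empirical-Bayes) or Welch t on log2 intensities; Benjamini–Hochberg
   FDR; a miRNA is a DEmiR when `p < 0.05`, `|log2FC| ≥ 0.8` and
   `FDR < 0.05` (all thresholds configurable).
2. **Correlation strata.** Pearson CE for every unordered DEmiR pair
   over all samples; pairs binned by sign and |CE| (default edges
   0.6/0.7/0.8).
3. **Classifier evaluation.** RBF-kernel SVM under stratified 5-fold
   cross-validation; pooled out-of-fold decision scores scored by
   ROC/AUC, where AUC is the Mann–Whitney probability
   `P(score_case > score_control)` with half credit for ties.
4. **Synergy network.** For each candidate pair, the co-target set
   (intersection of target-gene sets) is tested for pathway
   over-representation with the upper hypergeometric tail
   `p = Σ_{x=k}^{min(n,M)} C(M,x) C(N−M,n−x) / C(N,n)`
   (`N` = target universe, `M` = pathway size, `n` = co-targets,
   `k` = overlap), BH-adjusted across pathways within the pair; pairs
   with ≥ 1 significant pathway become edges annotated with CE.
5. **Modules & topology.** Overlapping communities by the Clique
   Percolation Method (k-cliques sharing k−1 nodes percolate; default
   k = 3) and a five-statistic global topology summary (average
   shortest path, betweenness, closeness, clustering coefficient,
   degree).
6. **Synthetic studies.** A generator that plants DEmiRs, latent-factor
   correlation blocks (nominal CE = loading², default 0.95² ≈ 0.90),
   MCAR missing values and exact co-target synergy pairs — with ground
   truth — so the whole pipeline is testable offline.

I/O covers tab-separated expression matrices and label files, GEO
series-matrix parsing, per-database target tables with consensus
filtering (link kept when supported by ≥ 4 databases by default), GMT
pathway sets, and SIF/GraphML network export for Cytoscape.

## Worked example

```r
library(miRpanel)

# a synthetic 38 vs 38 study: 900 probes, 20 planted DEmiRs,
# two correlated miRNA families, 3 planted synergy pairs
sim   <- generate_expression(sim_config(seed = 1))
truth <- sim$truth$de$mirna_id
ann   <- generate_annotation(
  annotation_config(planted_synergy_pairs =
                      list(truth[1:2], truth[3:4], truth[5:6]),
                    seed = 1001),
  truth)

run <- run_discovery(sim$expr, ann$targets, ann$pathways,
                     run_config(seed = 1))
#> preprocess: kept 900/900 miRNAs after missing-value screening
#> differential: 20 DEmiRs (10 up, 10 down)
#> correlation: 190 pairs (90 positive, 100 negative)
#> classifier: evaluated 6 feature sets; best AUC 0.991
#> network: 6 miRNAs, 3 edges (0 positive, 3 negative)
#> modules: 0 CPM modules at k=3

run$auc_table[, c("set_name", "n_features", "auc")]
#>                   set_name n_features       auc
#> 1 stratum:positive_(0.8,1]          8 0.8677285
#> 2          single:mir-0725          1 0.8310249
#> 3          single:mir-0775          1 0.8268698
#> 4          single:mir-0037          1 0.7950139
#> 5          single:mir-0471          1 0.8199446
#> 6       panel:top_combined          4 0.9909972
```

Reading the output: the screen recovered exactly the 20 planted DEmiRs
(10 up, 10 down); the eight miRNAs of the two planted correlation
blocks form the CE > 0.8 stratum; each top single DEmiR classifies
decently (AUC ≈ 0.80–0.83) while the combined 4-miRNA panel reaches
AUC 0.99 — the panel-beats-singles behaviour the workflow is designed
to detect. The network recovered the three planted synergy pairs and
nothing else:

```r
run$network$edges[, c("mirna_a", "mirna_b", "ce", "best_pathway", "best_p_adj")]
#>    mirna_a  mirna_b         ce best_pathway   best_p_adj
#> 1 mir-0037 mir-0105 -0.3335260        pw001 6.627330e-22
#> 2 mir-0129 mir-0187 -0.2659671        pw002 4.374038e-20
#> 3 mir-0270 mir-0277 -0.3453140        pw003 4.374038e-20
```

Three disjoint edges contain no triangle, so CPM at k = 3 correctly
reports no module. `write_network(run$network, "net.sif", "sif")`
exports the graph for Cytoscape.

A thin command-line front end is included:

```sh
Rscript inst/cli/mirpanel.R simulate --out-dir sim --seed 1
Rscript inst/cli/mirpanel.R run-all --expr sim/expression.tsv \
    --labels sim/labels.tsv --targets sim/targets.tsv \
    --gmt sim/pathways.gmt --out-dir results
```

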