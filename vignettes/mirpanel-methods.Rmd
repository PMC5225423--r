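---
title: "miRpanel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRpanel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

miRpanel implements a complete discovery workflow for circulating miRNA
biomarker panels from two-group (case vs control) expression microarrays.
This vignette describes the statistical model behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design choices taken where several defensible
conventions exist.

## The analysis model

### Differential screening

Input intensities are assumed to be on the log2 scale, approximately
Gaussian per miRNA after preprocessing. Pre-processing consists of
missing-value screening — rows with more than `max_missing_frac`
(default 0.2) missing entries are removed — followed by row-median
imputation, so that the test stage sees a complete matrix.

The per-miRNA effect is the difference of group means on the log2 scale
(the log2 fold change). Two test statistics are available:

* `moderated_t` (default): limma's empirical-Bayes moderated t.
  Per-row sample variances are shrunk toward a pooled prior whose
  scale and degrees of freedom are estimated from all rows; this is the
  standard choice for microarrays because it stabilizes the variance
  estimate of each individual probe using the whole array.
* `welch_t`: the unequal-variance two-sample t statistic with
  Welch–Satterthwaite degrees of freedom. It makes no exchangeability
  assumption across rows and serves as a dependency-light reference.

We do not promise numerical identity with any particular version of
limma's prior-df estimate; the contract, enforced by tests, is the
direction of shrinkage (extreme variance ratios are pulled in) and
calibration under the null. Rows constant in both groups with equal
means are reported as `log2fc = 0`, `p = 1` by definition.

A miRNA is declared differential (a "DEmiR") when jointly
`p < 0.05`, `|log2FC| >= 0.8` and BH-adjusted `FDR < 0.05`. The
boundary conventions are strict `<` on the two probabilities and `>=`
on the fold change. All three thresholds are `run_config()` arguments.

### Correlation stratification

For every unordered pair of DEmiRs we compute the Pearson correlation
coefficient (CE) of the two expression vectors over **all** samples,
cases and controls pooled. Pooling is a deliberate choice: a pair whose
members co-vary across the whole cohort — including the shift between
groups — is exactly the kind of pair that is informative as a joint
classification feature. Per-group correlation can be obtained by
subsetting the `mirna_expr` object before calling `pairwise_ce()`.
Missing values are handled with pairwise-complete observations.

Pairs are split by sign (CE > 0 positive, CE < 0 negative; exactly 0
belongs to neither class) and binned by |CE| with default edges
0.6/0.7/0.8, yielding the strata (0.6, 0.7], (0.7, 0.8] and (0.8, 1]
per sign. The exact bin edges used in published figures of this kind
are rarely stated precisely, so they are a configuration knob.

### Classifier evaluation

Feature sets — single miRNAs, pairs, the miRNA union of a CE stratum,
or a combined panel — are scored with a radial-basis-function SVM under
stratified 5-fold cross-validation. Within each fold, features are
standardized using training-fold statistics only, and every sample is
scored exactly once by a model that never saw it. Decision scores are
pooled across folds into a single ROC curve (per-fold averaging is
available via `pool_folds = FALSE`); pooling matches the common
practice of publishing one curve per feature set.

AUC is computed by the Mann–Whitney identity: the probability that a
random case outscores a random control, with half credit for ties.
This makes the AUC invariant under strictly increasing transforms of
the scores and antisymmetric under label reversal, both of which are
enforced by tests.

SVM hyperparameters are deliberately plain — cost 1, RBF gamma
`1/(d * mean feature variance)` on the standardized training fold —
because the evaluation is comparative (which feature set separates the
groups better), not an attempt to squeeze out the best absolute
classifier. Both are recorded in the run manifest.

### Co-target synergy and the miRNA–miRNA network

Two miRNAs are functionally synergistic when the genes they co-target
(the intersection of their target sets) are over-represented in at
least one pathway. For a pair with `n` co-targets, a pathway with
`M` genes inside the target universe of size `N`, and overlap `k`,
the enrichment probability is the upper hypergeometric tail

$$p = \sum_{x=k}^{\min(n, M)} \frac{\binom{M}{x}\binom{N-M}{n-x}}{\binom{N}{n}},$$

including the observed overlap. The universe `N` is the union of all
genes in the consensus target map — not the whole genome — which keeps
`M <= N` well-defined and reflects that only predicted targets can ever
appear in a co-target set. P-values are BH-adjusted **across pathways
within each pair** (a global across-pairs adjustment is available), and
an edge is created when at least one adjusted p-value is below
`alpha = 0.05`. Candidate pairs default to all unordered DEmiR pairs;
no |CE| floor is applied to edges, matching the observation that
published synergy networks carry edges across the whole correlation
range. Consensus targets keep a (miRNA, gene) link supported by at
least `min_db = 4` prediction databases; whether "more than three"
means 3 or 4 is genuinely ambiguous in common usage, so the knob is
exposed and the stricter reading is the default.

### Modules and topology

Communities in the synergy network are detected with the Clique
Percolation Method: two k-cliques are adjacent when they share k−1
nodes, and modules are the node unions of the connected components of
this clique-adjacency relation. CPM is the natural choice here because
miRNA functional modules overlap (one miRNA can serve in two modules),
which partitional methods cannot express. The default k = 3 is the
smallest non-trivial clique size and the usual CPM default; module
counts for k in {3, 4, 5} can be compared by calling
`clique_percolation()` directly. Clique enumeration goes through
pivoting maximal-clique search with a configurable cap
(`max_maximal_cliques`) that errors rather than silently truncating on
pathological inputs.

The global topology summary reports five node-averaged statistics
(average shortest path, betweenness, closeness, clustering coefficient,
degree) with conventions pinned by brute-force oracle tests: distances
are unweighted; node pairs in different components are excluded;
betweenness is normalized by (n−1)(n−2)/2 within each component;
closeness is the reciprocal mean distance to reachable nodes; the
clustering coefficient is the per-node triangle density with 0 for
degree < 2. Published tables of this kind rarely state which tool (and
hence which normalization) produced them, so the conventions are
documented here and frozen by tests rather than matched to any one
program.

## The synthetic-data generator

`generate_expression()` emulates the two-group microarray structure the
analysis assumes:

* log2-Gaussian intensities with per-miRNA baselines uniform on
  [6, 12] and residual SD `noise_sd` (default 1, a typical
  between-replicate spread for log2 microarray data);
* planted DEmiRs whose group means differ by `effect_log2`
  (default 1.5), half up and half down;
* correlation blocks: rows in a block share a per-sample latent factor,
  `resid = loading * F + sqrt(1 - loading^2) * eps`, so the nominal
  pairwise CE is `loading^2` *independently of* `noise_sd`. With the
  default loading 0.95 a block plants CE ≈ 0.90, comfortably inside the
  top stratum. Blocks are carved from the planted differential rows
  first, with a shared effect direction, emulating co-regulated miRNA
  families that are jointly differential;
* completely-at-random missingness at rate `missing_frac`
  (default 0.02). Real microarray missingness is not random —
  low-intensity probes drop out preferentially — but no mechanism is
  documented for the screening step this emulates, so MCAR is the
  neutral choice.

The default design — 38 vs 38 samples, 900 probes, 20 planted DEmiRs,
two 4-member blocks — mirrors the two-group whole-blood cohort scale at
which this kind of screen is typically run; a 10 vs 9 configuration for
small pilot cohorts is a one-line change of `sim_config()`.

`generate_annotation()` plants functional synergy: each designated
miRNA pair shares exactly `co_target_overlap` target genes (default
10), all placed inside one designated pathway (default size 20, within
a universe of 5000 genes and 50 targets per miRNA), while all other
targets are drawn uniformly. Planted pairs must be node-disjoint: when
pairs share a miRNA it is impossible to guarantee every pairwise
overlap exactly, so the generator refuses rather than approximate.
With these defaults the planted enrichment is overwhelming
(p ≈ 1e-15 before adjustment) while random pairs share ~0.5 genes and
essentially never survive the within-pair BH correction — tests verify
both directions.

What passing on synthetic data does **not** show: robustness to
intensity-dependent (non-Gaussian, heteroscedastic) noise, probe-level
artifacts, batch effects, or annotation bias in real target-prediction
databases. The generator is a correctness harness for the statistical
machinery, not a simulator of array physics.

## Numerical choices

* The hypergeometric tail is evaluated through R's `phyper`
  (log-space internally); `p = 1` exactly at `k = 0`.
* BH adjustment is the standard step-up; tests verify it against a
  brute-force implementation of the definition.
* Correlations use pairwise-complete observations; zero-variance
  features are excluded from pairing with a warning rather than
  propagating NaN.
* TSV writers print doubles with 17 significant digits so write/read
  round-trips are bit-exact.
* Ties in classifier scores receive the 0.5-credit Mann–Whitney
  convention throughout.
* Seeds: every stochastic entry point (`sim_config`,
  `annotation_config`, `cv_config`) carries its own seed; identical
  configuration implies bit-identical output.

## Problem sizes in the shipped checks

The package's test-suite and the reproduction script run entirely on
synthetic data at the design scale: 38 vs 38 samples with 900 probes
for differential recovery (10 replicate studies), 20 replicates for
correlation-block recovery, 50 label permutations for the null AUC, 500
random vectors for the AUC oracle, every valid hypergeometric problem
with a universe up to 12 for the enumeration oracle, 50 random graphs
up to 12 nodes for the CPM oracle, and 40-node graphs for the topology
oracle. These sizes keep a full run in minutes on a laptop while
leaving the binomial error of the calibration checks well inside their
asserted bands.

## Known limitations

* Two-group designs only: no covariates, pairing, or multi-class
  support.
* The moderated test delegates to limma; exotic limma options (trend,
  robust) are not exposed.
* The synergy stage tests all candidate pairs exhaustively; for very
  large DEmiR sets (thousands) the quadratic pair count would need the
  optional sampling mode.
* GEO series-matrix parsing covers the standard single-table layout;
  multi-table or SOFT-format files are out of scope.
* Weighted or directed networks are not supported anywhere in the
  network stack.
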