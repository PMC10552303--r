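---
title: "Methods: metabolite-gene association screening in GF vs SPF fetal multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolite-gene association screening in GF vs SPF fetal multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the study design

Fetuses of germ-free (GF) mouse dams develop without exposure to maternal
microbial metabolites; fetuses of specific-pathogen-free (SPF) dams are
exposed through the placenta. Comparing the two conditions across fetal
tissues (intestine, brain, placenta) links microbially modulated
metabolites to fetal gene-expression programs. The design has an
important nesting: each dam contributes two fetuses per assay, and — the
organs being too small for both assays — gene expression and metabolite
profiling are performed on *different* fetuses of the same litter. All
metabolite-gene association analysis therefore operates on litter
(dam-level) means, justified by a twin-similarity QC test, and the
correlation analyses use only the SPF dams, so that associations reflect
dose-response within the exposed group rather than the gross GF/SPF
physiological difference.

`fetomics` implements this workflow end to end:

1. **Gene prefiltering** — keep genes with ≥ 5 reads in ≥ 12 fetuses
   (≥ 11 for brain, where one sample is excluded as an outlier in the
   motivating design).
2. **Median-of-ratios normalization** of counts (reference = per-gene
   geometric mean over samples with all-positive counts; size factor =
   per-sample median count/reference ratio).
3. **Differential expression** — an externally supplied DE table is used
   verbatim when given; otherwise a clearly flagged stand-in runs: per
   gene, ordinary least squares on log2(normalized + 1) with group and
   sex terms, a two-sided t-test on the group coefficient, and
   Benjamini-Hochberg (BH) adjustment. The stand-in is a screening
   device for synthetic data, not a negative-binomial DE model; every
   downstream report carries its `source` flag.
4. **Metabolite status** — per tissue, a feature is `gf_absent` when it
   has zero GF detections and detections in at least half of the SPF
   samples; otherwise `spf_higher` when a Welch test on
   log2(intensity + 1) gives BH p < 0.05 with the SPF mean higher;
   otherwise `unchanged`. Features qualifying in at least one tissue
   form the analysis set.
5. **Litter averaging and twin QC** — dam-level means; the QC statistic
   is mean(within-litter sample Spearman) − mean(between-litter), with a
   one-sided permutation p over reassignments of fetuses to dams
   (litter sizes preserved, add-one correction).
6. **Three association routes on SPF dam means** — (a) the direct
   screen: all metabolite × gene Spearman correlations, retaining
   |rho| > 0.9; (b) complete-linkage hierarchical clustering on
   1 − Spearman for genes and metabolites separately, linking cluster
   pairs whose member-wise mean rho exceeds 0.7 (0.6 for brain); (c)
   plaid-model biclustering of the |rho| matrix.
7. **ORA and scoring** — for each analysis-set metabolite, the three
   route gene sets are tested for over-representation against a GMT
   collection (exact upper-tail hypergeometric p, BH across the
   collection's terms, minimum overlap 2); metabolites are ranked within
   each route by the number of significant terms (average ranks on
   ties) and the combined score is the sum of the three route ranks,
   final ranking ascending.
8. **Dependency labels** — analysis-set metabolites are lowest in GF, so
   linear extrapolation of the within-SPF correlation predicts the GF
   expression shift; pairs whose observed GF shift contradicts it (for
   example a negatively correlated gene that is nonetheless
   downregulated in GF, the pattern seen for carnitine-shuttle genes
   against aryl sulfates) are labeled `nonlinear_discordant`.

# Key parameters

All thresholds live in `pipeline_config()`:

| parameter | default | meaning |
|---|---|---|
| `rho_pair` | 0.9 | direct-screen Spearman threshold on SPF dam means |
| `use_absolute_rho` | TRUE | screen on the magnitude; the sign is kept on every pair |
| `rho_cluster`, `rho_cluster_brain` | 0.7 / 0.6 | cluster-link mean-rho thresholds |
| `alpha` | 0.05 | BH significance level throughout |
| `prefilter_min_reads`, `prefilter_min_samples` | 5 / 12 (brain 11) | gene prefilter |
| `target_cluster_genes`, `target_cluster_features` | 16–43 / 7–15 | calibrated mean cluster sizes for the tree cut |
| `max_layers`, `row_release`, `col_release`, `n_shuffles` | 10 / 0.7 / 0.7 / 3 | plaid budget, release thresholds and permutation copies |
| `n_perm` | 1000 | twin-similarity permutations |

Brain tissue automatically receives the laxer cluster threshold and the
reduced prefilter quorum through the `brain_tissues` override map.

# Numerical and design choices

**Absolute vs signed screening.** The screen threshold is printed as a
positive number, yet strong negative associations are biologically real
(translation-related genes correlate mostly negatively with these
metabolites). The default screens on |rho| and records the signed value;
`use_absolute_rho = FALSE` restores a strictly positive screen. Cluster
linking is signed by default (`signed_cluster_link`).

**Tree cut.** Only the resulting mean cluster sizes are calibrated
(16–43 genes, 7–15 features per cluster); the cut rule picks, among all
cuts whose mean size lands in the target range, the finest one (largest
number of clusters), which resolves natural fine structure while
matching the calibration. If no cut lands in the range the closest mean
size is used and a warning logged. Constant profiles have undefined rank
correlations; such items become singleton clusters and are excluded from
the direct screen with a log entry.

**Plaid biclustering.** The model is a background mean plus constant-mean
layers (no row/column effects). Each layer is grown from a seed row
holding one of the largest-magnitude residual cells: initial columns are
those where the seed row reaches three quarters of its extreme value,
and membership updates then alternate under the release-tightened
residual-reduction bound (a row/column is a member iff its mean residual
exceeds |mu|(1+release)/2), with a final pruning pass iterated to a
fixpoint. A layer is accepted only if its importance (members × mu²)
exceeds the best importance obtained on `n_shuffles` copies of the
residual whose entries are permuted within rows and then within columns
— a null that destroys row-column association while preserving the
value distribution. Fitting stops at the first rejection or at
`max_layers`. Accepted layers are ranked by mean internal |rho| and the
top half (minimum one) is kept for the bicluster route; ties break by
area, then lexicographic row id.

**ORA.** The universe is the tissue's prefiltered genes — the measured
universe, not the genome — and the BH family is all terms of the
collection tested for one gene list. Terms overlapping the query by
fewer than `ora_min_overlap = 2` genes are never called significant,
which suppresses singleton-driven hits.

**Scoring.** The combined score is the rank sum across routes
(scale-free across routes with very different hit-count magnitudes); a
sum-of-counts alternative is available (`score_method = "hit_sum"`).
Final ties break by total hits, then feature id, making the ranking
deterministic and order-invariant.

**Determinism.** Every stochastic step (twin permutations, plaid
shuffles, the generator) flows from explicit integer seeds; identical
inputs, configuration and seed reproduce outputs byte-identically.

# The synthetic twin-litter generator

`generate_synthetic_study()` emulates the study conditions: 6 GF + 6 SPF
dams, two fetuses per dam per assay with alternating sexes (a switch
reproduces the two-male metabolome exception), three tissues, 2000 genes
and 500 molecular features.

* **Counts** are negative binomial with gene baselines drawn
  log-normal(log 200, 1.5) — so prefiltering drops a nontrivial minority
  of genes — times a per-gene per-dam litter effect (SD 0.3 on the log
  scale), a sex effect on 50 genes, a planted GF/SPF effect on 200
  genes (|log2 FC| 1–2.5), and a per-sample library-size factor.
* **Intensities** are log-normal with per-feature per-dam litter
  effects, fetus-level noise, a 1000-count detection floor (non-detects
  are zero-filled, as in common LC-MS tables), whole families of
  features planted as GF-absent (zero in every GF sample) or
  SPF-elevated (4-fold).
* **Drivers.** Five driver metabolites carry a dam-level exposure
  modeled as an evenly spaced dose gradient across the SPF dams
  (randomly assigned to dams per driver), with GF dams pinned well below
  the gradient. Each driver drives 30 genes (80% positively, 20%
  negatively) through that exposure. The latent coupling noise is
  derived by inverting the classical Pearson-to-Spearman moment
  relation, so `coupling_strength = 0.95` is genuinely the target
  dam-level Spearman magnitude at n = 6 dams. Twenty discordant pairs
  couple negatively within SPF and additionally suppress the gene in GF
  by 2.5 log2 units, reproducing the observed
  "negative SPF correlation yet lower GF expression" pattern.
* **Gene sets.** For every driver the emitted GMT collection contains a
  specificity ladder of eight enriched sets (cores covering 10% to 90%
  of the linked genes, plus filler), emulating the redundancy and
  granularity of real ontologies, in which a transcriptional program
  lights up several related terms and only near-complete gene recovery
  reaches the most specific ones. Background sets fill the collection to
  100 terms.
* **Truth.** All planted structure (drivers, statuses, linked and
  discordant pairs, enriched set ids, DE and sex genes, the dam-level
  exposures, family labels) is returned as a `synthetic_truth` object
  for recovery tests, and `write_study()` emits the standard pipeline
  input files.

`generate_null_study()` keeps the generative model but zeroes all group
effects, drivers and couplings, with empty truth lists. The calibration
analyses (type-I error of the metabolite test; uniformity of the
twin-similarity permutation p) additionally set `litter_sd = 0` and
`sex_effect_genes = 0`, because both tests assume exchangeable fetuses
under the null; they run on a single tissue with a reduced genome since
neither quantity involves the gene dimension. Problem sizes used by the
packaged benchmarks: 10 replicate studies for driver recovery and
discordant labeling, 50 null replicates for the metabolite test, 100 for
twin-p uniformity, and 10 seeds of a 100 × 100 planted-block problem for
plaid recovery.

Two optional covariance layers are off by default: `family_sd` gives
compound families (12 features each) a shared dam-level latent, the way
chemically related compounds (aryl sulfates, trimethylated compounds)
co-vary in real LC-MS data, and `gene_module_sd` does the same for
co-regulated DE-gene modules. They are available because real data have
this structure, and they are off by default because the default
conditions model features and genes as independent apart from the
planted structure.

# What passing tests do and do not show

The generator's data are much cleaner than real LC-MS and 3'-RNA-seq
output: no batch effects, no retention-time drift or co-eluting feature
redundancy, no heteroskedastic intensity floors beyond a hard detection
limit, no shared-baseline compositional artifacts, and tissues differ
only by independent draws, not biology. Recovery results on synthetic
data are therefore upper bounds on real-data behavior.

Two limitations deserve emphasis. First, with six SPF dams a Spearman
screen at |rho| > 0.9 is close to demanding a perfect rank match, and a
metabolite with no gene coupling still aligns with a given exposure
gradient by chance with probability about 1.7%; across hundreds of
analysis-set features several such look-alikes arise in every run and
are genuinely indistinguishable from drivers at the dam level. Count-based
ORA scoring saturates for them just as for true drivers, so the planted
drivers concentrate at the top of the ranking but their exact positions
vary from seed to seed, and the top of the list should always be read as
a candidate set, not a verdict. Second, enabling the optional family and
module covariance makes whole blocks of features and genes correlate
through single 6-point latent draws; spurious block-level correlations
then pass the cluster-link and bicluster thresholds at an appreciable
rate, degrading driver recovery — with so few dams the method has no way
to distinguish a real dose-response block from a lucky latent
alignment. This mirrors the caution required with the real study design
and is the main reason the prioritization is a screen to be followed by
targeted validation.
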