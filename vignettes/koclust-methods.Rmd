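---
title: "Methods: functional clustering of KO abundance profiles"
author: "koclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional clustering of KO abundance profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koclust)
```

# The problem

A shotgun metagenome, assembled and annotated, can be summarised as a vector
of KEGG-ortholog (KO) abundances: for each KO, the read-coverage-weighted sum
of the estimated copies of every gene carrying that annotation. Across a
compendium of environmental metagenomes these profiles form a sample-by-KO
count matrix that is *compositional* — each sample's counts are constrained
by its sequencing and assembly depth, so only relative information is
meaningful. koclust implements an analysis chain for such compendia: quality
filtering, compositional normalization, unsupervised clustering with
data-driven model selection, discovery of the orthologs that define each
cluster, and covariate analyses linking clusters to community GC content and
contig-level taxonomy.

# Preprocessing

**Sample QC** (`applySampleQC`). A sample is retained only if it has no data
use restriction, more than 100,000 assembled genes, more than 30% of genes
carrying a KO annotation, estimated gene-copy data available, and is not a
combined assembly of multiple read libraries. Both numeric thresholds are
strict inequalities, read literally from the selection rule they encode; a
sample whose metadata is missing for a criterion fails that criterion. The
returned report records every per-criterion verdict.

**Ecosystem labels** (`assignEcosystemLabels`). A sample is labelled by its
`ecosystem_type` metadata field when strictly more than 100 samples in the
table share that type; otherwise the broader `ecosystem` field is used, and
`"Unclassified"` when both are missing. This collapses long-tail categories
without discarding samples.

**Rare-KO filter** (`filterRareKOs`). KOs present (count > 0) in less than
10% of samples are removed; exactly 10% is kept. Prevalence is a fraction of
samples with a strictly positive count. The filter runs *before*
normalization, so the CLR geometric mean is taken over the retained KOs.

**CLR normalization** (`clrNormalize`). Per sample $i$ and KO $j$,

$$\mathrm{clr}_{ij} = \log_2(x_{ij} + c) - \frac{1}{p}\sum_k \log_2(x_{ik} + c),$$

so zero marks a KO at the sample's geometric-mean abundance, and differences
of CLR values are log2 fold-changes. We use the deterministic point-estimate
CLR with a pseudocount prior $c$ (default 0.5, the uniform prior familiar
from the ALDEx2 family of tools) rather than Monte-Carlo sampling of
Dirichlet instances: every downstream statistic consumes a single normalized
value per KO per sample, and the point estimate keeps the pipeline
deterministic. The prior is configurable; $c = 0$ is allowed when no zeros
remain. Two contracts are tested: each sample's CLR values average to zero
within $10^{-9}$, and with $c = 0$ the transform is invariant to per-sample
rescaling (compositional invariance).

# Clustering and model selection

All clustering operates on Euclidean distance in the full CLR space; a
configurable alternative is to cluster PCA scores (`pcaProject`), but the
full space is the default since k-means and Ward are both variance-based and
the CLR matrix is dense.

**k-means** (`kmeansFit`) is Lloyd's algorithm with k-means++ initialization,
keeping the best of `nInit = 10` restarts by within-cluster sum of squares
(WCSS); the WCSS trace is recorded and is non-increasing by construction. An
emptied cluster is re-seeded at the point farthest from its assigned
centroid. Fits are deterministic given a seed. **Ward** (`wardFit`) is the
Lance–Williams minimum-variance recurrence on squared Euclidean distances;
merge heights equal twice the WCSS increase of each merge and are monotone.
Partitions are read off by cutting the dendrogram.

**Model selection** (`bootstrapSelect`) draws `B = 100` subsamples of 80% of
the samples without replacement and, for every method and candidate $k$,
scores each replicate by (i) its mean silhouette width on the subsample and
(ii) the adjusted Rand index (ARI) against a reference model fitted once on
the full data, restricted to the subsample. The reference-based ARI was a
design choice the selection rule leaves open: comparing each replicate with a
full-data consensus is simple, reproducible, and measures stability of the
partition rather than agreement between random replicate pairs. Subsamples
are shared across methods and $k$ (a paired design that removes subsample
noise from comparisons). The chosen model maximizes mean silhouette, with
ties broken by higher mean ARI and then smaller $k$ — favouring parsimony.
The subsample fraction (0.8) and without-replacement sampling are defaults
exposed in the interface.

**Final fit** (`fitFinal`). To limit overfitting, the final k-means model is
trained on a seeded random half of the samples and every sample — trained on
or held out — is assigned to its nearest centroid, the natural k-means
prediction rule. `trainFraction = 1` reduces exactly to a full-data fit.
**Sub-clustering** (`subcluster`) refits k-means with `kSub = 2` inside each
parent cluster.

**Scores.** The mean silhouette uses the standard cohesion/separation width
with singletons scored 0; the ARI is the chance-corrected pair-counting
index, defined as 1 for identical degenerate partitions. Both are
implemented in-package and verified against brute-force oracles and the
independent implementations in `cluster` and `mclust`.

# Marker-KO discovery

For each KO, abundance differences across clusters are tested with the
Kruskal-Wallis H test (mid-ranks, tie-corrected, chi-square p-value) followed
by Dunn's post-hoc z tests on the joint ranking, with tie-corrected variance.
A KO is a **marker** of cluster $c$ iff

* every Dunn comparison involving $c$ has Bonferroni-corrected $p < 0.001$
  (the multiplier is the $g(g-1)/2$ cluster pairs of that KO), and
* its median log2 fold-change over *every* other cluster exceeds 2.

On CLR data the fold-change is computed as the difference of cluster medians
(CLR is already log2, so differences are log2 fold-changes). The alternative
reading — the median of all pairwise sample differences — is available as
`lfcMethod = "median_of_differences"`; difference-of-medians is the default
as the convention in marker-gene practice. The fold-change requirement makes
marker assignments mutually exclusive, and the Kruskal-Wallis results are
reported but deliberately do not enter the rule.

Because the Bonferroni correction is per KO (not across the thousands of
KOs), KO-level multiplicity is controlled empirically: `permutationFDR`
shuffles the cluster labels (preserving cluster sizes) 100 times, re-runs
the complete criterion, and estimates
$\mathrm{FDR} = \overline{\mathrm{FP}} / \max(\text{observed}, 1)$. Ranks and
tie corrections are label-free and computed once across permutations. With
no observed markers the estimate is reported as 0 with an explicit flag.

Markers are rolled up to KEGG pathways and categories (`mapMarkersToPathways`;
a KO in several pathways counts once per pathway and once per distinct
category, unmapped markers are tallied) and ranked per cluster by the
minimum fold-change over other clusters (`topMarkers`, default top 15, ties
broken by H then KO id).

# Covariate analyses

**GC content.** Differences in assembled-metagenome GC fraction across
clusters use the same Kruskal-Wallis/Dunn machinery
(`compareAcrossClusters`). Per-KO association is a simple linear regression
of CLR abundance on the GC fraction (`gcKORegression`): OLS slope and
intercept, Pearson $r$ as goodness of fit, and a Wald test of the slope via
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom — algebraically the
same test `linregress`-style implementations report. GC is used as the
fraction in [0, 1] (slopes scale accordingly if percentages are preferred)
and is taken from sample metadata, not recomputed from sequence. Regression
runs on all QC-passing samples regardless of cluster; per-cluster
stratification is available by subsetting. Bonferroni-adjusted p-values
across KOs are reported alongside raw ones.

**Taxonomy.** Contig counts per domain (bacteria, archaea, eukaryota,
viruses, unassigned) are converted to per-sample fractions
(`taxonomyProportions`; zero-contig samples dropped with a warning) and
compared across clusters per domain.

# The synthetic-data generator

`simulateKOProfiles` emulates the statistical structure the pipeline assumes,
with every planted effect recorded as ground truth:

* per-KO baseline log2 abundances $\mu_j \sim N(6, 2^2)$ — a long-tailed
  abundance distribution typical of functional profiles;
* $k$ latent clusters; markers of cluster $c$ get $\mu_j + \delta$ (default
  $\delta = 4$) in their own cluster's samples;
* a per-sample GC fraction with cluster-dependent means (defaults
  0.62/0.45/0.45, sd 0.03 — one high-GC cluster against two lower ones) and
  a designated KO set whose log2 abundance follows GC with slope
  `gcBeta = 8`;
* per-sample depth $2^{N(21, 0.5^2)}$ (totals around $2\times10^6$ estimated
  gene copies); the expected composition is closed to the depth and counts
  are Poisson draws around it;
* a taxonomy table with one archaea-enriched cluster (15% vs 1% archaeal
  contigs), and metadata that passes QC by construction.

The reference validation scenario is 3 clusters × 60 samples and 2000 KOs
with 10 markers per cluster. Because marker effects are planted on the log2
scale *before* closure and markers are a small fraction of total abundance,
the realized CLR-scale shift approximately equals $\delta$; this is verified
(bias below 0.2 at $n = 60$, $\delta = 4$). Poisson noise was chosen over
negative binomial deliberately: every downstream statistic is rank- or
CLR-based, so the simpler noise model suffices and keeps planted CLR effect
sizes interpretable.

What the generator does *not* emulate: phylogenetic correlation between KOs,
assembly and annotation artefacts, overdispersion beyond Poisson, shared
pathway structure between markers and background, or realistic ecosystem
label noise. Passing tests therefore demonstrate that the statistical
machinery recovers known structure under its stated assumptions — not that
real compendia satisfy those assumptions.

# Numerical and design choices

* **Boundary semantics**: QC thresholds strict; prevalence threshold
  inclusive; both read literally from the selection rules they implement.
* **Ties**: mid-ranks everywhere; tie-corrected KW and Dunn variances; an
  all-tied KO yields $H = 0$, $p = 1$ (not an error).
* **Degenerate inputs**: a single cluster is an error for silhouette;
  identical degenerate partitions have ARI 1; constant GC is an error while
  a constant KO regresses to $r = 0$, $p = 1$; `prior = 0` CLR requires
  strictly positive counts.
* **Tie-breaks**: model selection by silhouette, then ARI, then smaller k;
  marker ranking by fold-change, then H, then KO id; k-means restarts by
  WCSS with the first-best kept.
* **Determinism**: every stochastic routine takes a seed; the pipeline
  driver derives stage seeds from a master seed by a stable string hash, so
  toggling one stage cannot change another's draws. Pipeline stage values
  are always reloaded from the stage's own output files, making resumed runs
  byte-identical to fresh ones.
* **Problem sizes in the shipped checks**: the validation suite exercises
  the reference scenario at full size for single-run properties, and scales
  repetition counts to what a desk-class machine handles comfortably —
  bootstrap scans use k = 2..5 with B = 12 replicates and 2 k-means++
  restarts per fit (the planted separation leaves selection variance tiny),
  100 independent scenario regenerations for cluster-number recovery, 20
  paired replicates for the recall-vs-effect-size curve, 50 null datasets
  for regression calibration and 40 null seeds for the no-marker check. The
  committed example fixture is a miniature (36 samples × 150 KOs, seed
  recorded) regenerable byte-identically in code.

# Limitations

The pipeline assigns every sample to exactly one cluster; soft or
hierarchical memberships beyond one sub-clustering level are out of scope,
as are UMAP/t-SNE embeddings, consensus clustering, BRITE hierarchy
traversal beyond flat pathway/category roll-ups, rarefaction and alternative
normalizations, and any causal interpretation of the GC associations. The
marker criterion tests each KO marginally: co-varying KO blocks are not
modelled. Live retrieval from annotation databases is intentionally not
implemented; all inputs are delimited text.
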