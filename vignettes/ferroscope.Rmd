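---
title: "Scoring ferroptosis activity, virtual regulator knockout and survival stratification"
author: "ferroscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring ferroptosis activity, virtual regulator knockout and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroscope)
library(SummarizedExperiment)
```

# Overview

`ferroscope` implements a connected set of procedures for studying
ferroptosis regulation in transcriptomics: gene-set scoring of five
ferroptosis sub-pathway axes, single-sample GSEA for transcription-factor
regulon activity, an in-silico regulator knockout built on masked
correlation weights, risk-score survival stratification, and spatial spot
scoring with graph clustering. This vignette is the package's account of
the underlying models, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator emulates, and the
numerical conventions the implementation commits to.

# Gene sets and the detected-gene filter

Gene sets are typed (`GeneSet`, `GeneSetCollection`) with ordered-set
semantics: iteration order is first-appearance order, so every downstream
table is stable across runs. Symbols are compared case-sensitively after
whitespace trimming; alias resolution is deliberately out of scope because
it is irreproducible without pinning an annotation source — users map
identifiers before import.

The bundled five-axis collection (overall ferroptosis, iron metabolism,
lipid peroxidation, antioxidant defense, GPX4 axis; 80 genes in the union)
is a **synthetic reconstruction** assembled from genes commonly attributed
to each axis in the ferroptosis literature. It ships as an editable GMT
file rather than hard-coded lists so an exact database export (e.g. a
FerrDb curation) can be substituted without touching code. The same holds
for the 23 bundled TF regulons and the 19 immune signatures.

Signature scoring is only meaningful when enough of a set is detected. The
filter keeps a set when its intersection with the detected-gene universe
has at least `min_overlap = 5` members, the conventional reliability floor
for single-sample enrichment of small sets; the bound is inclusive at 5 and
every rejection is reported with its overlap count rather than silently
dropped.

# Module scores

The per-observation module score of a set $S$ is the binned-control
statistic standard in single-cell analysis: all genes are ranked by mean
expression across observations and cut into `n_bins = 25` equal-size bins;
each set gene draws up to `n_ctrl = 50` control genes from its own bin
(excluding set members; if a bin pool is no larger than `n_ctrl` the whole
pool is used, and an empty pool falls back to the nearest bin with a
warning); the score is

$$\mathrm{score}(c) = \frac{1}{|S|}\sum_{g \in S} x_{gc}
 \;-\; \frac{1}{|C|}\sum_{g \in C} x_{gc}$$

on log-normalized expression. Control sampling is governed by an explicit
seed, so scores are reproducible and the same seed gives bit-identical
output. The defaults follow common single-cell practice; both are exposed
because small panels on small gene universes can exhaust bins. Because the
score is a difference of means over fixed gene sets, adding any constant to
the whole matrix leaves it unchanged, which the tests assert.

Expression enters as `ln(1 + count/total * 1e4)` per observation
(`normalizeLogNorm()`); observations with zero totals are an error that
names the offending barcodes, and normalizing an already-normalized layer
is a type error rather than a silent double transform.

# Single-sample GSEA

For one observation, genes are ranked by expression descending. Rank
weights are $r_j = N - \mathrm{position}_j + 1$; tied expression values
receive the average of their positions' weights, while the walk order
itself is made deterministic by breaking ties on the gene symbol. The
enrichment score integrates the difference between the weighted in-set
ECDF and the uniform out-of-set ECDF:

$$ES = \sum_{i=1}^{N} \big(P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i)\big),
\qquad
P_{\mathrm{in}}(i) = \frac{\sum_{j \le i,\, j \in S} r_j^{\tau}}
                          {\sum_{j \in S} r_j^{\tau}},\quad
P_{\mathrm{out}}(i) = \frac{\#\{j \le i,\ j \notin S\}}{N - |S|}.$$

The exponent defaults to $\tau = 0.25$, the customary compromise between
rank-only ($\tau = 0$) and strongly expression-weighted scoring. Optional
normalization divides each signature's scores by their range across
observations — a monotone per-signature rescaling that does not affect any
rank-based downstream statistic. A set equal to the whole universe has no
complement and is an error, as is a set with no detected member. The
implementation is checked against an independent brute-force enumeration
oracle to $10^{-12}$ on hundreds of random instances.

# Shared statistics

Group comparison and correlation route through the standard R machinery,
wrapped behind a uniform `TestResult`: Mann–Whitney
(`wilcox.test`; exact enumeration for combined $n \le 25$, otherwise the
tie-corrected normal approximation with continuity correction),
Kruskal–Wallis (`kruskal.test`, tie-corrected $H$, $\chi^2_{k-1}$),
Spearman (`cor.test`, $t$ approximation with $n-2$ df), and
Benjamini–Hochberg (`p.adjust`). Dunn's post hoc test is implemented
directly (no installed package provides it): pairwise
$z = (\bar R_i - \bar R_j)\big/\sqrt{\big(\tfrac{N(N+1)}{12} -
\tfrac{\sum(t^3-t)}{12(N-1)}\big)\,(\tfrac1{n_i}+\tfrac1{n_j})}$
on pooled tie-corrected ranks, two-sided, BH-adjusted across all
$k(k-1)/2$ pairs. All tests are two-sided; degenerate all-identical input
yields $H = 0$, $p = 1$ with a warning instead of NaN. A vectorized
row-wise Mann–Whitney (validated against `wilcox.test` row by row) powers
genome-wide marker tables.

# Transcription-factor activity and resistance ranking

Regulon activity is ssGSEA over each surviving regulon. Ferroptosis
*resistance* is defined as the arithmetic negation of the ferroptosis
score: scores are differences of means and can be negative, so negation is
the only well-defined reading of "inverse", and it makes the resistance
ranking the exact reverse of the susceptibility ranking (asserted as an
identity in the tests). Correlations are computed per observation;
regulators whose activity is constant yield NA rows without failing the
others, and BH adjustment runs across regulators.

# Virtual knockout

The knockout model is deliberately linear and transparent. Spearman
correlations between the regulator and every other gene (vectorized
rank-then-Pearson with the $t$ p-value, identical numerics to the per-pair
test) give per-gene weights. The target mask keeps genes with
$|\rho| > 0.1$ and raw $p < 0.05$, both strict; BH-adjusted p-values are
reported alongside but do not enter the mask, which keeps the designation
criterion exactly as stated while still surfacing multiplicity-aware
values. Zero-variance genes have undefined correlation and are never
masked.

The per-cell delta is

$$\Delta_c = -\frac{1}{m}\, \mathbf{z}_c \cdot \mathbf{w}_{\mathrm{mask}}$$

with $\mathbf z$ the per-gene standardized expression, $m$ the number of
masked genes, and the negation encoding regulator loss: a cell whose masked
positively-correlated targets are highly expressed is predicted to lose
the most ferroptosis activity when the regulator disappears, hence a more
negative delta. Standardization puts genes on comparable scales (the raw
dot product would be dominated by highly expressed genes); both the
z-scoring and the $1/m$ normalization are config-exposed
(`zscore`, `normalizeByM`) because neither choice is forced by the model.
Axis deltas apply the same formula restricted to masked genes inside each
axis set; axes with no masked genes are reported absent with a warning
rather than fabricated as zero.

Aggregation reports mean delta per cell type for types with at least 5
cells (inclusive), listing exclusions. Responders are the top and bottom
quartile of the delta distribution (quantiles by linear interpolation,
type 7; ties at a threshold fall on the extreme side), requiring at least
8 observations so the quartiles are distinct; markers between high and low
responders use the row-wise Mann–Whitney normal approximation with BH
correction, with direction the sign of the median difference.

# Survival stratification

The risk score is the linear form $\sum_i \beta_i \cdot \mathrm{expr}_i$
over signature genes. Under the default `available_genes` policy, genes a
platform does not measure contribute zero and are always listed in the
result — the realistic cross-platform situation where only a subset of a
signature is detectable — while the `fail` policy makes any absence an
error. The median split assigns scores equal to the median to the low
group (a deterministic convention; the split itself uses the interpolated
median). Kaplan–Meier estimation, the log-rank test and Harrell's
concordance wrap the `survival` package (`survfit`, `survdiff`,
`concordance` with `reverse = TRUE` so that higher risk scores are
expected to fail earlier); the tests check them against closed forms and
an explicit pair-enumeration oracle. Time-dependent ROC and calibration
curves are out of scope.

# Spatial analysis

Spots are scored with literally the same code path as cells (asserted
bit-for-bit in the tests). The neighbour graph connects each spot to its
`k = 6` nearest Euclidean neighbours in array coordinates with
deterministic spot-ID tie-breaks, then symmetrises by union, so minimum
degree is at least $k$; the construction is invariant under rigid
transforms. Physical spot spacing is metadata only.

Clustering uses seeded multilevel greedy modularity maximisation
(`igraph::cluster_louvain`) — a deterministic community-detection contract
under a fixed seed, chosen over the single-pass agglomerative variant
because the latter's dendrogram cut misbehaves on small or complete graphs
(a 3-spot triangle should be one community). The scientific content
downstream is the score-vs-region contrast, not the particular partitioner,
so externally computed labels (e.g. a Leiden run) can be injected directly.
Heterogeneity across clusters or regions is the Kruskal–Wallis test with
per-label medians reported.

# The synthetic-data generator

The generator exists so that every downstream stage has recoverable ground
truth; its defaults are the package's study conditions and are not tuned
per analysis.

**Single cell.** Counts are
$\mathrm{NB}\!\big(\mu = L_c \cdot \mathrm{softmax}(b_g + \text{program} +
\lambda_g \xi_{gc}),\ \theta\big)$ with $\theta = 10$ (variance
$\mu + \mu^2/\theta$, a realistic single-cell overdispersion), library
sizes lognormal around 5000, 800 genes, and three cell types
(epithelial/immune/stromal at 0.5/0.3/0.2 with 2-fold 15-gene programs).
One latent activity $a_c \sim N(0,1)$ loads on the regulator and, through
a shared-factor construction
$\xi_{gc} = \rho' a_c + \sqrt{1-\rho'^2}\,\varepsilon_{gc}$, on each
target gene. Planting a Spearman correlation through counts requires two
corrections, both fixed once at design time: the Gaussian-scale
correlation is $\rho' = 2\sin(\pi\rho/6) \times 1.42$ — Greiner's relation
times an empirical inflation cancelling the attenuation from NB sampling
at the default depth — and the loading amplitude is kept at 1.0 so the
planted program stays a small fraction of library mass; softmax
compositionality otherwise bleeds visible anticorrelation into unrelated
genes. The achieved correlation is validated empirically (median absolute
error < 0.1 at $n = 2000$), not claimed exact. When coupling is restricted
to particular cell types, the coupled cells also receive a +0.6 log-mean
program shift: a regulator actively driving a program in a type elevates
its mean there, and this is what makes per-type knockout deltas
separable — a purely covariance-level coupling would leave type means
equal by construction. A companion scenario builder
(`simulateSuppressorScenario()`) plants one regulon coupled positively and
a ferroptosis panel coupled negatively to the same latent activity among
decoy regulons of unrelated genes.

**Spatial.** A square grid partitioned by Chebyshev radius thirds into
core, margin ring and stroma. Ferroptosis panel genes have NB mean
`gradientLow` in the core, `gradientHigh` at the margin and the midpoint in
the stroma; 400 background genes carry no gradient and have lognormal
per-gene baselines around 2 — large enough that library-size normalization
does not cancel the panel gradient, varied enough that every expression
bin has control genes. Equal gradients give a calibrated null; an inverted
gradient is a parameter error because the modelled geometry is a positive
margin contrast.

**Survival.** Signature gene expression is standard normal; event times
are exponential with hazard $h_0 \exp(\text{effectScale} \cdot
\text{risk})$, $h_0 = 0.1$; censoring is an independent exponential clock
with rate $h_0\,r/(1-r)$ for requested rate $r$, which achieves the target
fraction approximately (exactly under a null effect). Proportional hazards
hold by construction, so expected concordance rises monotonically in the
effect scale — checked by simulation.

**What is not emulated.** Ambient RNA, doublets, batch effects, gene–gene
correlation beyond the planted program, spatial autocorrelation beyond the
region means, and informative censoring. Passing tests on these
simulations therefore demonstrate correctness of the procedures under
their stated assumptions, not robustness to the artifacts of real data.

```{r sim-demo}
cfg <- simConfig(nCells = 400, seed = 1)
sim <- simulateSingleCell(cfg)
se <- normalizeLogNorm(sim$se)
scores <- scoreCollection(se, ferroptosisGeneSets(), seed = 1)
summary(scoreMatrix(scores)[, "ferroptosis_all"])
```

# Seeds and determinism

Every stochastic step takes an explicit seed, and the pipeline expands one
global seed into per-stage substreams through a counter-based hash, so
enabling or disabling a stage never perturbs another stage's stream. RNG
state is saved and restored around every seeded computation, leaving the
caller's stream untouched. The bundled demo configuration reruns
byte-identically, which the test suite asserts on the emitted files.

# Problem sizes

The test suite and the acceptance script run the recovery and calibration
studies at 2000 cells × 800 genes (10–20 seeds per property), 500
replicates for test calibration, and 100–200 seeds for the 8×8 spatial
grid — sizes at which the planted effects are comfortably identifiable and
a full run completes in a few minutes on one CPU.

# Known limitations

The knockout is a linear, correlation-based surrogate: it propagates no
network structure and cannot distinguish direct from indirect targets.
Masking uses raw p-values by design, so at genome scale the mask's false
positives are controlled by the correlation threshold rather than the FDR.
ssGSEA significance is not assessed by permutation (scores are used for
ranking and correlation, not hypothesis tests). The bundled gene sets and
signature coefficients are synthetic reconstructions for demonstration —
conclusions about real tissue require user-supplied curations.
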