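# ferroscope

Ferroptosis — iron-dependent cell death driven by lipid peroxidation — is
heterogeneously regulated across tumors, cell types and tissue regions, and
tumor cells frequently escape it through NRF2 (*NFE2L2*)-driven antioxidant
programs. `ferroscope` is an R package for quantifying that landscape in
bulk, single-cell and spatial transcriptomics. It is aimed at computational
biologists who want to score ferroptosis pathway activity, ask which
transcription factors track ferroptosis resistance, predict the effect of
deleting a regulator in silico, and carry a ferroptosis gene signature into
survival analysis — with every stage testable against synthetic data with
planted ground truth.

## What it computes

**Five-axis module scores.** For a gene set *S*, the per-cell module score
is the binned-control statistic used in single-cell work:
genes are binned by mean expression, each set gene draws expression-matched
control genes from its bin, and

  score(c) = mean_{g∈S} x_gc − mean_{g∈ctrl} x_gc

applied to five axes: overall ferroptosis (80-gene union), iron metabolism,
lipid peroxidation, antioxidant defense, and the system Xc⁻/GSH/GPX4 axis.

**Single-sample GSEA.** Per observation, genes are ranked by expression and
the enrichment score is the summed difference between the rank-weighted
in-set ECDF and the out-of-set ECDF,

  ES = Σ_i ( P_in(i) − P_out(i) ),  P_in(i) = Σ_{j≤i, j∈S} r_j^τ / Σ_{j∈S} r_j^τ,

with τ = 0.25 by default. Transcription-factor regulon activity is ssGSEA
over regulon target sets (scored only when ≥ 5 targets are detected), and
regulators are ranked by Spearman correlation of activity with ferroptosis
*resistance*, defined as the negated ferroptosis score.

**Virtual knockout.** Genome-wide Spearman correlations of every gene with
the regulator define correlation weights; genes with |ρ| > 0.1 and p < 0.05
are designated regulatory targets. Each cell's KO delta is the negated dot
product of its (per-gene standardized) expression with the masked weights,
scaled by the number of masked genes — negative deltas predict ferroptosis
suppression upon regulator loss. Deltas are computed per ferroptosis axis,
aggregated by cell type (≥ 5 cells), and cells in the top/bottom delta
quartile are contrasted with a Mann–Whitney + Benjamini–Hochberg marker
test.

**Risk-score survival stratification.** A linear signature
Risk = Σᵢ βᵢ·Expressionᵢ (genes absent from a platform contribute zero and
are reported), median split into high/low groups, Kaplan–Meier curves,
log-rank test and Harrell's C-index.

**Spatial scoring.** Visium-style spots are scored with the same module
score code path, connected in a k = 6 nearest-neighbour graph, clustered by
seeded modularity maximisation, and tested for score heterogeneity across
clusters or regions with a Kruskal–Wallis test.

**Synthetic data with planted truth.** A negative-binomial single-cell
generator (counts = NB(libsize · softmax(baseline + cell-type program +
latent loading), θ)) plants a chosen Spearman correlation between one
regulator and a target set, optionally restricted to one cell type; a
spatial generator plants a core-to-margin gradient on an n×n grid; a
survival generator draws exponential event times under a proportional
hazard in the risk score. Every generator records its ground truth.

## Worked example

```r
library(ferroscope)

cfg <- simConfig(nCells = 2000, seed = 1)      # plants rho = 0.5 NFE2L2->targets
sim <- simulateSingleCell(cfg)
se  <- normalizeLogNorm(sim$se)

scores <- scoreCollection(se, ferroptosisGeneSets(), method = "module", seed = 1)
scores
#> ScoreTable (module_score): 2000 observation(s) x 5 signature(s)
#>   signatures: iron_metabolism, lipid_peroxidation, antioxidant_defense, gpx4_axis, ferroptosis_all

ko <- virtualKO(se, "NFE2L2")
ko$weights
#> CorrelationWeights for NFE2L2: 799 gene(s), 15 masked (|rho| > 0.1, p < 0.05)
ko$result
#> KOResult (NFE2L2): 2000 observation(s), 15 masked gene(s)
#>   axes: iron_metabolism, antioxidant_defense, gpx4_axis, ferroptosis_all
#>   responders: 500 high / 500 low

sig <- prognosticSignature()                   # bundled synthetic 16-gene model
coh <- simulateSurvivalCohort(400, sig, effectScale = 1,
                              censoringRate = 0.3, seed = 2)$cohort
res <- survivalStratification(coh, sig)
sprintf("C-index %.3f, log-rank chi2 %.1f (p = %.3g)",
        res$cindex, res$logrank$statistic, res$logrank$p_value)
#> "C-index 0.699, log-rank chi2 87.9 (p = 6.73e-21)"
```

The 15 masked genes are the 12 planted NRF2 targets plus a handful of
borderline genes; the responder split is the top/bottom delta quartile
(500 cells each at n = 2000). The survival example shows a strong planted
effect (effectScale = 1) being recovered; with `effectScale = 0` the C-index
sits at chance (≈ 0.5).

A full run of every stage from one YAML config:

```r
runPipeline(demoConfig(), outdir = "demo_out")   # writes CSV/JSON + manifest
```

Bundled gene sets (`ferroptosisGeneSets()`, `tfRegulons()`,
`immuneSignatures()`, `prognosticSignature()`) are *synthetic
reconstructions* for demonstration and testing — supply your own curated
GMT/CSV files for real analyses.

## Vignette

`vignettes/ferroscope.Rmd` documents the models, the parameter choices and
their defaults, what the synthetic generator does and does not emulate, and
the package's numerical conventions.
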