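# follimap

Cross-modality analysis of single-cell and spatial transcriptomes for
developmental tissue studies: QC and log-normalization of UMI count
matrices, group-versus-rest marker detection, **multimodal intersection
analysis (MIA)** linking scRNA-seq cell types to spatially defined tissue
regions, and **ligand–receptor interaction scoring** between cell types
across developmental time points with an empirical permutation null.

The package targets the analyst who has (i) an annotated scRNA-seq count
matrix (cells × time points × cell types, e.g. thyroid follicular cell
subtypes, myeloid populations) and (ii) a spatial transcriptomics section
with region labels (e.g. central vs peripheral gland), and wants to answer:
*which cell types occupy which regions, and which ligand–receptor channels
between cell types strengthen or fade with age?* A synthetic-data generator
with planted ground truth makes every stage testable without external data.

## The statistics at the core

**MIA.** For a cell-type marker set of size *m* (genes with higher
expression in that type than in the rest, two-tailed t test, P < 10⁻²⁰), a
region set of size *n* (same test per region, P < 0.001) and an overlap of
*k* genes over a background universe of *N* genes,

- enrichment p: `P(X ≥ k)`, `X ~ Hypergeometric(N, m, n)`,
- enrichment score: `−log10(P)`, depletion score: `−log10(1 − P)`,

with both tails computed directly in log space (the depletion tail is
summed directly, never formed as `1 − P`, which underflows exactly where
depletion is strongest).

**Ligand–receptor score.** For pair (L, R), sender type A and receiver type
B at time point t,

    score = ½ · ( mean log-expr of L over A-cells at t
                + mean log-expr of R over B-cells at t ),

compared against a null built by jointly shuffling the (cell-type,
time-point) labels (default B = 1000); the empirical p is the proportion of
null scores ≥ the observed score, BH-adjusted across records.

## Worked example

The bundled demo simulates both modalities at reduced scale (120 cells per
time point, 600 genes, 100 spots), runs QC → normalization → marker sets →
MIA → interactions, and writes every artifact plus a run manifest:

```r
library(follimap)
res <- runPipeline(demoPipelineConfig(seed = 1), "demo_out")

miaTable(res$mia)[c("type", "region", "k", "m", "n", "N", "p", "enrichment")]
#>  type     region k  m  n   N         p enrichment
#>  TFC1    central 6 10 40 580 1.270e-05      4.896
#>  TFC1 peripheral 0 10 40 580 1.000e+00      0.000
#>  TFC2    central 0 11 40 580 1.000e+00      0.000
#>  TFC2 peripheral 6 11 40 580 2.652e-05      4.576
#>  ...
```

Reading: of the 10 marker genes recovered for cell type TFC1 (*m* = 10,
shown bracket-style beside MIA heatmap axes), 6 also appear among the 40
marker genes of the central region (*n* = 40) over a 580-gene common
background — an overlap with hypergeometric P ≈ 1.3 × 10⁻⁵, enrichment
score 4.9. TFC1 maps to the central region, TFC2 to the peripheral one:
the planted correspondence, recovered.

```r
significantInteractionCounts(res$interactions)
#>  receiver time_point n_significant
#>      TFC1         d5             6
#>      TFC1        d10             6
#>      TFC1        d20             2
#>      TFC1        d30             0
```

The count of significant ligand–receptor interactions targeting the TFC1
receiver falls monotonically across the four time points — the generator
plants receptor effects decaying 2.0 → 0.5, and the permutation test
recovers the decline.

Re-running the same configuration reproduces byte-identical outputs; the
manifest (`demo_out/manifest.json`) records the config hash, per-stage
counts and per-file checksums.

A command-line wrapper over the same functions ships in
`inst/scripts/follimap.R`
(`Rscript inst/scripts/follimap.R run --config inst/extdata/demo_config.yaml
--out demo_out/`), with subcommands for each stage.

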