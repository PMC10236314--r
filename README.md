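# cnvcoex — CNV-conditioned gene co-expression network layers

Cancer gene co-expression networks lose long-range *cis* co-expression:
strong interactions concentrate in small chromosomal neighborhoods
instead of spreading along the chromosome. `cnvcoex` implements a
pipeline for testing whether copy-number variation (CNV) explains that
reorganization on a single chromosome:

1. **Layers.** For each conditioning gene *k* with a per-sample
   copy-number profile, build a complete co-expression network over all
   gene pairs *(i, j)* weighted by plug-in conditional mutual
   information, `CMI(gᵢ ; gⱼ | CNVₖ)`, estimated from equal-frequency
   discretized expression (B = ⌈N^⅓⌉ bins) and integer copy-number
   states. One network per conditioning gene — the layers of a
   multi-CNVs co-expression network.
2. **Comparison.** Truncate every layer to its top-k strongest edges
   (default k = 3500) and compare all layer pairs with the two-sample
   Kolmogorov–Smirnov statistic `D = sup |F₁ − F₂|`, with the rejection
   rule `D > c(α)·√((n+m)/(n·m))`, `c(α) = √(−ln(α/2)/2)`. If CNVs do
   not drive co-expression, no layer pair should differ significantly.
3. **Edge geography.** Classify edges as intra-cytoband /
   inter-cytoband / inter-arm, accumulate growth curves in CMI rank
   order, and summarize per-gene degree and per-cytoband hotspots.
4. **Synthetic data.** A block-covariance generator with band structure,
   integer CNV states and a switchable CNV→co-expression coupling, so
   the null ("CNVs don't matter") and the alternative ("they do") are
   both constructible ground truth.

It is aimed at computational biologists studying co-expression structure
who need the conditioning, comparison and geography machinery as tested,
reusable functions rather than one-off scripts.

## Worked example

Simulate a null dataset (co-expression independent of CNV by
construction), build and truncate the layers, and compare them:

```r
library(cnvcoex)

cfg <- syntheticConfig(nGenes = 200, nSamples = 300, nConditioning = 10,
                       coupling = 0, seed = 1)
ds  <- generateDataset(cfg)
ds
#> CNVCoexDataset | 200 genes x 300 samples | 10 conditioning genes | 6 cytobands

net <- truncateTopK(buildMultilayer(exprMatrix(ds), cnvMatrix(ds)), 3500)
dsm <- compareAllLayers(net)
summary(dsm)
#>   n_pairs      max_D min_offdiag_D n_rejected alpha
#> 1      45 0.06057143    0.01371429          0  0.05
```

The 10 layers differ only through estimation noise: the largest of the
45 pairwise D statistics (0.061) stays below the rejection threshold
`ksCriticalValue(0.05, 300, 300)` = 0.111, so no pair is significant —
the analysis correctly reports that CNVs do not influence co-expression
here. Rebuilding the same dataset with a strong CNV→co-expression
coupling flips the verdict — the layer conditioned on the driver gene
separates:

```r
cfgC <- syntheticConfig(nGenes = 200, nSamples = 300, nConditioning = 10,
                        coupling = 0.45, seed = 1)
dsC  <- generateDataset(cfgC)
netC <- truncateTopK(buildMultilayer(exprMatrix(dsC), cnvMatrix(dsC)), 3500)
summary(compareAllLayers(netC))
#>   n_pairs     max_D min_offdiag_D n_rejected alpha
#> 1      45 0.1117143    0.01314286          1  0.05
```

Edge geography of the coupled dataset shows the localized structure:

```r
l1 <- layers(netC)[[1]]
categoryCountsAtCutoffs(l1, geneAnnotation(dsC))
#>   cutoff intra_cytoband inter_cytoband inter_arm
#> 1    100            100              0         0
#> 2    500            500              0         0
#> 3   1000           1000              0         0
#> 4   1500           1500              0         0

head(cytobandHotspots(l1, geneAnnotation(dsC), topFraction = 0.01), 3)
#>   cytoband n_genes n_edges_within mean_cmi_within top_share
#> 1    q24.3      33            528       0.5308879         1
#> 2    p23.1      34            538       0.3341523         0
#> 3    p21.3      34            520       0.3265785         0
```

All of the strongest 1% of edges fall inside the boosted q24.3 band — a
co-expression hotspot — and the top-1500 edges are all intra-cytoband.

`runPipeline()` orchestrates the same steps end to end from a config
(R list or YAML), writing per-stage TSV outputs, an MD5 manifest and a
run-info sidecar under one directory; re-running an unchanged config is
a no-op.

## Package layout

* `R/io.R` — TSV / BED / cytoband readers and writers, sample alignment
* `R/cmi.R` — discretization, CNV state binning, MI / CMI, all-pairs CMI
* `R/layers.R` — layer and multilayer construction, top-k truncation,
  persistence
* `R/ks.R` — KS statistic, rejection threshold, all-pairs comparison
* `R/geography.R` — edge classification, growth curves, degrees, hotspots
* `R/synthetic.R` — generator, presets, dataset writer
* `R/pipeline.R` — staged orchestration with manifest and resume
* `vignettes/cnv-conditioned-coexpression.Rmd` — model, estimator
  behavior, design decisions and limitations
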