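annFixture <- function() {
    ds <- generateDataset(tinyConfig())
    geneAnnotation(ds)    # g001..g005 on p21.3, g006..g010 on q24.3
}

test_that("edge classification partitions same-chromosome pairs", {
    ann <- annFixture()
    expect_identical(as.character(classifyEdges("g006", "g007", ann)),
                     "intra_cytoband")
    expect_identical(as.character(classifyEdges("g001", "g005", ann)),
                     "intra_cytoband")
    expect_identical(as.character(classifyEdges("g001", "g007", ann)),
                     "inter_arm")
    ## symmetry
    expect_identical(classifyEdges("g002", "g009", ann),
                     classifyEdges("g009", "g002", ann))
    expect_error(classifyEdges("g001", "missing", ann), "missing annotation")
})

test_that("inter_cytoband requires same arm, different band", {
    cfg <- syntheticConfig(nGenes = 9L, nSamples = 40L, nConditioning = 2L,
                           bandLayout = data.frame(
                               arm = c("q", "q", "q"),
                               band = c("q24.1", "q24.2", "q24.3"),
                               nGenes = c(3L, 3L, 3L)),
                           hotspotBands = "q24.3")
    ann <- geneAnnotation(generateDataset(cfg))
    expect_identical(as.character(classifyEdges("g01", "g04", ann)),
                     "inter_cytoband")
    expect_identical(as.character(classifyEdges("g04", "g05", ann)),
                     "intra_cytoband")
})

test_that("cross-chromosome pairs are rejected (cis-only analysis)", {
    ann <- annFixture()
    other <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1000, 2000))
    names(other) <- "gX"
    S4Vectors::mcols(other)$arm <- "p"
    S4Vectors::mcols(other)$cytoband <- "p11"
    both <- suppressWarnings(c(ann, other))  # distinct seqlevels on purpose
    expect_error(classifyEdges("g001", "gX", both),
                 "different chromosomes")
})

test_that("growth curves accumulate a partition of ranks", {
    ann <- annFixture()
    ## hand-built layer whose top 5 edges all sit inside q24.3
    intra <- data.frame(
        gene_i = c("g006", "g006", "g007", "g008", "g009"),
        gene_j = c("g007", "g008", "g009", "g010", "g010"),
        cmi = c(0.9, 0.8, 0.7, 0.6, 0.5))
    l <- makeLayer(intra, sprintf("g%03d", 1:10), k = 5L)
    gc <- growthCurves(l, ann, 5L)
    expect_identical(gc$intra_cytoband, 1:5)
    expect_identical(gc$inter_cytoband, rep(0L, 5L) + 0L)
    expect_identical(gc$inter_arm, rep(0L, 5L) + 0L)

    ## partition + cumsum oracle on a real 45-edge layer
    ds <- generateDataset(tinyConfig(seed = 19))
    lr <- buildLayer(exprMatrix(ds), cnvMatrix(ds), "cnv01")
    g <- growthCurves(lr, geneAnnotation(ds), 45L)
    expect_identical(g$intra_cytoband + g$inter_cytoband + g$inter_arm,
                     g$rank)
    e <- edgeTable(lr)
    cats <- classifyEdges(e$gene_i, e$gene_j, geneAnnotation(ds))
    for (cc in levels(cats))
        expect_identical(g[[cc]], cumsum(cats == cc))
    expect_warning(growthCurves(lr, geneAnnotation(ds), 100L), "exceeds")
})

test_that("cutoff snapshots sample the growth curve monotonically", {
    ds <- generateDataset(tinyConfig(seed = 20))
    l <- buildLayer(exprMatrix(ds), cnvMatrix(ds), "cnv01")
    ann <- geneAnnotation(ds)
    cc <- categoryCountsAtCutoffs(l, ann, cutoffs = c(10L, 25L, 45L))
    expect_identical(cc$cutoff, c(10L, 25L, 45L))
    for (cat in c("intra_cytoband", "inter_cytoband", "inter_arm"))
        expect_true(all(diff(cc[[cat]]) >= 0))
    one <- categoryCountsAtCutoffs(l, ann, cutoffs = 1L)
    expect_identical(sum(one$intra_cytoband, one$inter_cytoband,
                         one$inter_arm), 1L)
    expect_error(categoryCountsAtCutoffs(l, ann, cutoffs = c(5L, 5L)),
                 "ascending")
})

test_that("degree profiles obey the handshake identity", {
    ## star: hub g01 connected to 6 leaves
    leaves <- sprintf("g%02d", 2:7)
    star <- data.frame(gene_i = "g01", gene_j = leaves,
                       cmi = seq(0.9, 0.4, by = -0.1))
    l <- makeLayer(star, c("g01", leaves, "g08"), k = 6L)
    dp <- degreeProfile(l)
    expect_identical(dp$degree[dp$gene_id == "g01"], 6L)
    expect_true(all(dp$degree[dp$gene_id %in% leaves] == 1L))
    expect_identical(dp$degree[dp$gene_id == "g08"], 0L)
    expect_identical(sum(dp$degree), 12L)

    ## naive incidence-count oracle on a real truncated layer
    ds <- generateDataset(tinyConfig(seed = 22))
    lt <- truncateTopK(buildLayer(exprMatrix(ds), cnvMatrix(ds), "cnv01"),
                       20L)
    dp2 <- degreeProfile(lt, geneAnnotation(ds))
    e <- edgeTable(lt)
    for (g in geneUniverse(lt))
        expect_identical(dp2$degree[dp2$gene_id == g],
                         sum(e$gene_i == g) + sum(e$gene_j == g))
    expect_identical(sum(dp2$degree), 2L * nrow(e))
})

test_that("hotspot ranking concentrates on the boosted band", {
    ann <- annFixture()
    intra <- data.frame(
        gene_i = c("g006", "g006", "g001"),
        gene_j = c("g007", "g008", "g004"),
        cmi = c(0.9, 0.8, 0.2))
    l <- makeLayer(intra, sprintf("g%03d", 1:10), k = 3L)
    hs <- cytobandHotspots(l, ann, topFraction = 0.6)
    expect_identical(hs$cytoband[1L], "q24.3")
    expect_identical(hs$top_share[1L], 1)      # both top-2 edges in q24.3

    ## cancer-like synthetic: hotspot band must rank first
    ds <- cancerLike(tinyConfig(seed = 25))
    lr <- buildLayer(exprMatrix(ds), cnvMatrix(ds), "cnv01")
    hs2 <- cytobandHotspots(lr, geneAnnotation(ds), topFraction = 0.2)
    expect_identical(hs2$cytoband[1L], "q24.3")
    expect_error(cytobandHotspots(lr, geneAnnotation(ds), 0), "topFraction")
})
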