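test_that("generated annotation tiles bands with ordered genes", {
    cfg <- tinyConfig()
    ann <- generateAnnotation(cfg)
    expect_identical(length(ann$genes), 10L)
    expect_identical(unname(table(S4Vectors::mcols(ann$genes)$cytoband)
                            [c("p21.3", "q24.3")]),
                     c(5L, 5L), ignore_attr = TRUE)
    ## p precedes q; starts strictly increasing
    starts <- GenomicRanges::start(ann$genes)
    expect_true(all(diff(starts) > 0))
    expect_identical(S4Vectors::mcols(ann$genes)$arm, rep(c("p", "q"), each = 5L))
    ## bands tile without gaps
    expect_identical(ann$cytobands$start[-1L],
                     ann$cytobands$end[-nrow(ann$cytobands)])
})

test_that("written files round-trip through the io readers", {
    ds <- generateDataset(tinyConfig(seed = 33))
    d <- tempfile()
    paths <- writeDataset(ds, d)
    expr <- readExpressionMatrix(paths[["expression"]])
    cnv <- readCNVMatrix(paths[["cnv"]])
    expect_equal(expr, exprMatrix(ds), tolerance = 1e-9)
    expect_equal(cnv, cnvMatrix(ds), tolerance = 1e-12)
    ann <- readGeneAnnotation(paths[["bed"]], paths[["cytoband"]])
    expect_identical(names(ann), names(geneAnnotation(ds)))
    expect_identical(S4Vectors::mcols(ann)$cytoband,
                     S4Vectors::mcols(geneAnnotation(ds))$cytoband)
    expect_identical(S4Vectors::mcols(ann)$arm,
                     S4Vectors::mcols(geneAnnotation(ds))$arm)
})

test_that("generation is bit-identical under a fixed seed", {
    a <- generateDataset(tinyConfig(seed = 41))
    b <- generateDataset(tinyConfig(seed = 41))
    expect_identical(exprMatrix(a), exprMatrix(b))
    expect_identical(cnvMatrix(a), cnvMatrix(b))
    c <- generateDataset(tinyConfig(seed = 42))
    expect_false(identical(exprMatrix(a), exprMatrix(c)))
    ## CNV states drawn from the configured support
    expect_true(all(cnvMatrix(a) %in% 1:3))
})

test_that("empirical covariance converges to the block target", {
    frob <- function(N, seed) {
        cfg <- syntheticConfig(nGenes = 30L, nSamples = N,
                               nConditioning = 2L,
                               bandLayout = data.frame(
                                   arm = c("p", "p", "p", "q", "q", "q"),
                                   band = c("p23.1", "p21.3", "p11.2",
                                            "q13", "q22", "q24.3"),
                                   nGenes = rep(5L, 6L)),
                               seed = seed)
        ds <- generateDataset(cfg)
        ## target correlation rebuilt independently of the generator
        tgt <- matrix(cfg$backgroundCorr, 30L, 30L)
        bandOf <- rep(1:6, each = 5L)
        for (b in 1:6) {
            cb <- if (b == 6L) cfg$hotspotCorr else cfg$blockCorr
            tgt[bandOf == b, bandOf == b] <- cb
        }
        diag(tgt) <- 1
        norm(stats::cor(t(exprMatrix(ds))) - tgt, "F")
    }
    expect_lt(frob(1000L, 51), frob(100L, 51))
    expect_lt(frob(1000L, 52), frob(100L, 52))
})

test_that("the coupling mechanism modulates within-band correlation", {
    cfg <- tinyConfig(seed = 61, nSamples = 400L, coupling = 0.45)
    ds <- generateDataset(cfg)
    driver <- cnvMatrix(ds)[1L, ]
    hot <- names(geneAnnotation(ds))[
        S4Vectors::mcols(geneAnnotation(ds))$cytoband == "q24.3"]
    bandCor <- function(state) {
        e <- exprMatrix(ds)[hot, driver == state, drop = FALSE]
        cm <- stats::cor(t(e))
        mean(cm[upper.tri(cm)])
    }
    ## hotspot correlation increases with the driver state (0.25/0.7/0.99)
    expect_lt(bandCor(1), bandCor(2))
    expect_lt(bandCor(2), bandCor(3))

    ## with coupling = 0, stratified correlations are statistically flat
    ds0 <- generateDataset(tinyConfig(seed = 61, nSamples = 400L))
    d0 <- cnvMatrix(ds0)[1L, ]
    bc0 <- function(s) {
        e <- exprMatrix(ds0)[hot, d0 == s, drop = FALSE]
        cm <- stats::cor(t(e)); mean(cm[upper.tri(cm)])
    }
    expect_lt(abs(bc0(1) - bc0(3)), 0.15)
})

test_that("a coupling that breaks positive semi-definiteness is refused", {
    cfg <- tinyConfig(coupling = 5)
    expect_error(generateDataset(cfg), "smaller coupling")
})

test_that("presets produce homogeneous vs localized top edges", {
    base <- tinyConfig(seed = 71, nSamples = 200L)
    h <- healthyLike(base)
    ca <- cancerLike(base)
    intraShare <- function(ds) {
        l <- truncateTopK(buildLayer(exprMatrix(ds), cnvMatrix(ds), "cnv01"),
                          10L)
        mean(classifyEdges(edgeTable(l)$gene_i, edgeTable(l)$gene_j,
                           geneAnnotation(ds)) == "intra_cytoband")
    }
    expect_gt(intraShare(ca), intraShare(h))
    ## presets honor the seed
    expect_identical(exprMatrix(healthyLike(base)), exprMatrix(h))
})

test_that("config validation rejects inconsistent layouts", {
    expect_error(syntheticConfig(nGenes = 11L, bandLayout = tinyLayout()),
                 "sum to nGenes")
    expect_error(syntheticConfig(backgroundCorr = 0.6, blockCorr = 0.5),
                 "backgroundCorr <= blockCorr")
    expect_error(tinyConfig(cnvStateProbs = c(0.5, 0.5)), "probability")
    badLayout <- data.frame(arm = c("q", "p"), band = c("q24.3", "p21.3"),
                            nGenes = c(5L, 5L))
    expect_error(syntheticConfig(nGenes = 10L, bandLayout = badLayout,
                                 hotspotBands = "q24.3"),
                 "precede")
})
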