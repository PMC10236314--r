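test_that("a layer holds the full sorted edge list and is deterministic", {
    ds <- generateDataset(tinyConfig(seed = 2))
    l1 <- buildLayer(exprMatrix(ds), cnvMatrix(ds), "cnv01")
    expect_identical(nrow(edgeTable(l1)), 45L)     # 10*9/2
    expect_true(is.na(truncationK(l1)))
    l1b <- buildLayer(exprMatrix(ds), cnvMatrix(ds), "cnv01")
    expect_identical(edgeTable(l1), edgeTable(l1b))
    expect_error(buildLayer(exprMatrix(ds), cnvMatrix(ds), "nope"),
                 "not found")
    ## misaligned samples are refused
    expect_error(buildLayer(exprMatrix(ds)[, 1:20], cnvMatrix(ds), "cnv01"),
                 "not aligned")
})

test_that("conditioning on a constant CNV reproduces unconditioned MI", {
    hm <- handMatrices(5L, 40L)
    cnvConst <- matrix(2, 1L, 40L,
                       dimnames = list("flat", colnames(hm$expr)))
    l <- buildLayer(hm$expr, cnvConst, "flat")
    b <- ceiling(40^(1 / 3))
    for (r in seq_len(nrow(edgeTable(l)))) {
        e <- edgeTable(l)[r, ]
        mi <- mutualInformation(discretize(hm$expr[e$gene_i, ], b),
                                discretize(hm$expr[e$gene_j, ], b))
        expect_equal(e$cmi, mi, tolerance = 1e-12)
    }
})

test_that("the multilayer network has one layer per conditioning gene", {
    ds <- generateDataset(tinyConfig(seed = 4))
    cnv5 <- rbind(cnvMatrix(ds),
                  cnvMatrix(ds)[rep(1L, 3L), , drop = FALSE])
    rownames(cnv5) <- c("cnv01", "cnv02", "dupA", "dupB", "dupC")
    net <- buildMultilayer(exprMatrix(ds), cnv5)
    expect_identical(length(layers(net)), 5L)
    expect_identical(layerIds(net), rownames(cnv5))
    expect_true(all(vapply(layers(net),
                           function(l) nrow(edgeTable(l)) == 45L,
                           logical(1))))
    ## identical CNV rows give identical layers (up to the layer id)
    expect_identical(edgeTable(layers(net)[[1L]]),
                     edgeTable(layers(net)[[3L]]))
    expect_error(buildMultilayer(exprMatrix(ds),
                                 cnvMatrix(ds)[1L, , drop = FALSE]),
                 "at least 2")
})

test_that("top-k truncation is a deterministic prefix with min-composition", {
    ds <- generateDataset(tinyConfig(seed = 6))
    l <- buildLayer(exprMatrix(ds), cnvMatrix(ds), "cnv02")
    full <- edgeTable(l)

    t1 <- truncateTopK(l, 1L)
    expect_identical(nrow(edgeTable(t1)), 1L)
    expect_identical(edgeTable(t1)$cmi, max(full$cmi))

    tBig <- truncateTopK(l, 10000L)
    expect_identical(edgeTable(tBig), full)

    ## truncate(truncate(L, a), b) == truncate(L, min(a, b))
    ab <- truncateTopK(truncateTopK(l, 30L), 12L)
    expect_identical(edgeTable(ab), edgeTable(truncateTopK(l, 12L)))
    expect_identical(truncationK(ab), 12L)

    w <- layerWeightDistribution(truncateTopK(l, 20L))
    expect_identical(length(w), 20L)
    expect_true(all(diff(w) <= 0))
    expect_identical(min(w), sort(full$cmi, decreasing = TRUE)[20L])

    expect_error(truncateTopK(l, 0L), "positive")
})

test_that("layer weights are invariant to gene row order", {
    hm <- handMatrices(6L, 30L)
    l <- buildLayer(hm$expr, hm$cnv, "cnv01")
    perm <- c(4L, 1L, 6L, 3L, 2L, 5L)
    lp <- buildLayer(hm$expr[perm, ], hm$cnv, "cnv01")
    ## identical edge naming scheme -> identical sorted tables
    expect_equal(edgeTable(l), edgeTable(lp), tolerance = 1e-12)
})

test_that("layers persist and reload through the manifest", {
    ds <- generateDataset(tinyConfig(seed = 8))
    net <- truncateTopK(buildMultilayer(exprMatrix(ds), cnvMatrix(ds)), 20L)
    d <- tempfile()
    writeLayers(net, d, configHash = "abc")
    net2 <- readLayers(d)
    expect_identical(layerIds(net2), layerIds(net))
    expect_identical(truncationK(net2), 20L)
    expect_identical(vapply(layers(net2), function(l) l@nSamples, integer(1)),
                     rep(40L, 2L))
    ## rounding to 10 significant digits can reorder exact ties, so
    ## compare the tables in pair-name order
    byPair <- function(e) {
        e <- e[order(e$gene_i, e$gene_j, method = "radix"), , drop = FALSE]
        rownames(e) <- NULL
        e
    }
    expect_equal(byPair(edgeTable(layers(net2)[[1L]])),
                 byPair(edgeTable(layers(net)[[1L]])), tolerance = 1e-9)
})
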