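test_that("equal-frequency discretization splits by rank with stable ties", {
    expect_identical(as.integer(discretize(c(5, 1, 3, 2, 4, 6), 2)),
                     c(1L, 0L, 0L, 0L, 1L, 1L))
    ## ties broken by original index: first occurrences fill earlier bins
    lab <- discretize(c(7, 7, 7, 7, 1, 9), 3)
    expect_identical(as.integer(lab), c(0L, 1L, 1L, 2L, 0L, 2L))
    withr::with_seed(5, {
        for (i in 1:20) {
            n <- sample(20:200, 1)
            b <- sample(2:8, 1)
            occ <- tabulate(discretize(rnorm(n), b) + 1L, b)
            expect_lte(diff(range(occ)), 1L)
        }
    })
})

test_that("equal-width discretization covers [min, max] and degenerates safely", {
    expect_identical(as.integer(discretize(c(0, 1, 2, 3), 2, "equal_width")),
                     c(0L, 0L, 1L, 1L))
    expect_message(lab <- discretize(c(7, 7, 7, 7), 2, "equal_width"),
                   "constant")
    expect_identical(as.integer(lab), rep(0L, 4))
    expect_error(discretize(1:3, 5), "exceed")
})

test_that("joint distribution matches empirical frequencies and margins", {
    jd <- jointDistribution(c(0, 1), c(0, 1), c(0, 0))
    expect_equal(jd[1, 1, 1], 0.5)
    expect_equal(jd[2, 2, 1], 0.5)
    expect_equal(sum(jd), 1)

    jd2 <- jointDistribution(rep(0L, 4), rep(0L, 4), rep(0L, 4))
    expect_identical(dim(jd2), c(1L, 1L, 1L))
    expect_equal(jd2[1, 1, 1], 1)

    withr::with_seed(11, {
        tr <- randomTriple(60)
        jd3 <- jointDistribution(tr$x, tr$y, tr$z)
        expect_equal(sum(jd3), 1, tolerance = 1e-12)
        ## marginalizing over y recovers the empirical (x, z) table exactly
        n <- length(tr$x)
        empXZ <- unclass(table(factor(tr$x, 0:max(tr$x)),
                               factor(tr$z, 0:max(tr$z)))) / n
        expect_equal(apply(jd3, c(1, 3), sum), empXZ, tolerance = 1e-15,
                     ignore_attr = TRUE)
    })
})

test_that("mutual information matches direct summation and textbook cases", {
    expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1), "bits"), 1)
    expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 1, 0, 1), "bits"), 0)
    x <- c(0, 0, 1, 1, 0, 1); y <- c(0, 1, 0, 1, 1, 1)
    expect_equal(mutualInformation(x, y), naiveMI(x, y), tolerance = 1e-14)
})

test_that("CMI reproduces conditioning identities", {
    ## irrelevant Z preserves I(X;Y): all four (x,z) combinations equally
    x <- c(0, 0, 1, 1); z <- c(0, 1, 0, 1)
    expect_equal(conditionalMutualInformation(x, x, z, "bits"), 1)
    ## XOR synergy: marginally independent, conditionally determined
    y <- c(0, 1, 0, 1); zx <- bitwXor(x, y)
    expect_equal(mutualInformation(x, y, "bits"), 0)
    expect_equal(conditionalMutualInformation(x, y, zx, "bits"), 1)
    ## conditioning on a constant equals plain MI, exactly
    withr::with_seed(3, {
        for (i in 1:10) {
            tr <- randomTriple(50)
            expect_identical(
                conditionalMutualInformation(tr$x, tr$y, rep(0L, 50)),
                mutualInformation(tr$x, tr$y))
        }
    })
})

test_that("CMI equals the naive triple-loop evaluation on random tables", {
    withr::with_seed(17, {
        for (i in 1:150) {
            tr <- randomTriple(sample(10:80, 1))
            expect_equal(conditionalMutualInformation(tr$x, tr$y, tr$z),
                         naiveCMI(tr$x, tr$y, tr$z), tolerance = 1e-12)
        }
    })
})

test_that("CMI obeys the chain rule, symmetry and non-negativity", {
    withr::with_seed(23, {
        for (i in 1:60) {
            tr <- randomTriple(60, maxBins = 3L)
            cmi <- conditionalMutualInformation(tr$x, tr$y, tr$z)
            ## symmetry in x and y, exact
            expect_identical(cmi,
                             conditionalMutualInformation(tr$y, tr$x, tr$z))
            expect_gte(cmi, 0)
            ## chain rule: I(X;Y|Z) = I(X;(Y,Z)) - I(X;Z), via the oracle
            yz <- tr$y * (max(tr$z) + 1L) + tr$z
            expect_equal(cmi, naiveMI(tr$x, yz) - naiveMI(tr$x, tr$z),
                         tolerance = 1e-10)
        }
    })
})

test_that("pairwiseCMI enumerates G(G-1)/2 pairs consistent with the scalar path", {
    hm <- handMatrices(4L, 30L)
    el <- pairwiseCMI(hm$expr, hm$cnv[1L, ])
    expect_identical(nrow(el), 6L)
    expect_true(all(el$gene_i < el$gene_j))
    ## sorted by descending weight, ties by pair
    expect_identical(order(el$cmi, el$gene_i, el$gene_j,
                           decreasing = c(TRUE, FALSE, FALSE),
                           method = "radix"),
                     seq_len(nrow(el)))
    ## every weight equals the scalar CMI on the same discretized vectors
    b <- ceiling(30^(1 / 3))
    z <- binCNVStates(hm$cnv[1L, ])
    for (r in seq_len(nrow(el))) {
        xi <- discretize(hm$expr[el$gene_i[r], ], b)
        yj <- discretize(hm$expr[el$gene_j[r], ], b)
        expect_equal(el$cmi[r], conditionalMutualInformation(xi, yj, z),
                     tolerance = 1e-12)
    }
})

test_that("CNV state binning merges rare states into the nearest neighbor", {
    v <- c(rep(2, 40), rep(3, 9), rep(1.1, 3))   # 1 is rare (3 < 5)
    z <- binCNVStates(v)
    expect_identical(attr(z, "states"), c(2L, 3L))
    expect_identical(attr(z, "nBins"), 2L)
    ## the rare 1s were absorbed into state 2 (nearest)
    expect_identical(unique(unclass(z)[v < 2]), 0L)
    ## equal-frequency alternative yields balanced strata
    zf <- binCNVStates(runif(90), method = "equal_frequency", nBins = 3L)
    expect_identical(tabulate(zf + 1L, 3L), rep(30L, 3))
})
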