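## Small programmatic fixtures shared across test files.

writeTempTSV <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}

## a tiny two-band annotation: 5 genes on p21.3, 5 on q24.3
tinyLayout <- function() {
    data.frame(arm = c("p", "q"), band = c("p21.3", "q24.3"),
               nGenes = c(5L, 5L))
}

tinyConfig <- function(seed = 1L, ...) {
    args <- utils::modifyList(
        list(nGenes = 10L, nSamples = 40L, nConditioning = 2L,
             bandLayout = tinyLayout(), hotspotBands = "q24.3", seed = seed),
        list(...))
    do.call(syntheticConfig, args)
}

## deterministic expression/cnv pair without the generator (for io tests)
handMatrices <- function(nGenes = 4L, nSamples = 10L, seed = 99L) {
    withr::with_seed(seed, {
        expr <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
                       dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                       sprintf("s%02d", seq_len(nSamples))))
        cnv <- matrix(sample(1:3, 2L * nSamples, replace = TRUE), 2L,
                      dimnames = list(c("cnv01", "cnv02"), colnames(expr)))
    })
    list(expr = expr, cnv = cnv)
}

## hand-built CMILayer with explicit edges (valid: sorted, gene_i < gene_j)
makeLayer <- function(edges, universe, conditioning = "cnvX", k = NA_integer_,
                      nSamples = 50L) {
    edges <- edges[order(edges$cmi, edges$gene_i, edges$gene_j,
                         decreasing = c(TRUE, FALSE, FALSE),
                         method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
    new("CMILayer", conditioningGene = conditioning, edges = edges,
        truncationK = as.integer(k),
        geneUniverse = sort(universe, method = "radix"),
        nSamples = as.integer(nSamples))
}
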