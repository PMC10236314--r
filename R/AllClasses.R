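#' One CNV-conditioned co-expression layer
#'
#' A `CMILayer` holds the weighted edge list of a single co-expression
#' network: all unordered gene pairs of a shared gene universe, weighted by
#' the plug-in conditional mutual information of the two genes' discretized
#' expression given the discretized copy-number state of one conditioning
#' gene. Edges are stored once per unordered pair with `gene_i < gene_j`
#' (C-locale lexicographic) and kept strictly sorted by decreasing weight,
#' ties broken by the pair names, so a layer is a deterministic function of
#' its inputs.
#'
#' @slot conditioningGene single gene identifier whose CNV profile was the
#'   conditioning variable.
#' @slot edges `data.frame` with columns `gene_i`, `gene_j`, `cmi`.
#' @slot truncationK integer; number of top edges kept, or `NA` for the
#'   full \eqn{G(G-1)/2} edge list.
#' @slot geneUniverse character vector of all gene identifiers the layer
#'   was built over (needed e.g. to give degree 0 to unconnected genes).
#' @slot nSamples integer; number of samples the weights were estimated
#'   from (the effective sample size behind every weight).
#'
#' @seealso [buildLayer()], [truncateTopK()], [layerWeightDistribution()]
#' @exportClass CMILayer
setClass("CMILayer",
    representation(
        conditioningGene = "character",
        edges            = "data.frame",
        truncationK      = "integer",
        geneUniverse     = "character",
        nSamples         = "integer"
    ),
    prototype(truncationK = NA_integer_, nSamples = NA_integer_)
)

setValidity("CMILayer", function(object) {
    e <- object@edges
    msgs <- character()
    if (!all(c("gene_i", "gene_j", "cmi") %in% names(e)))
        return("edges must have columns gene_i, gene_j, cmi")
    if (length(object@conditioningGene) != 1L)
        msgs <- c(msgs, "conditioningGene must be a single identifier")
    if (nrow(e) > 0L) {
        if (any(e$cmi < 0))
            msgs <- c(msgs, "edge weights must be non-negative")
        if (any(e$gene_i >= e$gene_j))
            msgs <- c(msgs, "pairs must satisfy gene_i < gene_j")
        ord <- order(e$cmi, e$gene_i, e$gene_j,
                     decreasing = c(TRUE, FALSE, FALSE), method = "radix")
        if (!identical(ord, seq_len(nrow(e))))
            msgs <- c(msgs, "edges must be sorted by (-cmi, gene_i, gene_j)")
        if (!all(c(e$gene_i, e$gene_j) %in% object@geneUniverse))
            msgs <- c(msgs, "edge endpoints must belong to geneUniverse")
    }
    G <- length(object@geneUniverse)
    full <- G * (G - 1L) / 2L
    k <- object@truncationK
    if (!is.na(k)) {
        if (nrow(e) != min(k, full))
            msgs <- c(msgs, sprintf(
                "truncated layer must have min(k, G(G-1)/2) = %d edges, has %d",
                min(k, full), nrow(e)))
    } else if (nrow(e) != full) {
        msgs <- c(msgs, sprintf(
            "full layer must have G(G-1)/2 = %d edges, has %d", full, nrow(e)))
    }
    if (length(msgs)) msgs else TRUE
})

#' Multi-CNVs co-expression network
#'
#' Ordered collection of [CMILayer-class] objects over a shared gene
#' universe, one layer per conditioning gene — the "multi-CNVs
#' co-expression network" whose layers are compared with the
#' Kolmogorov-Smirnov statistic.
#'
#' @slot layers list of `CMILayer`, all sharing `geneUniverse` and
#'   truncation.
#' @slot geneUniverse character vector of gene identifiers.
#'
#' @seealso [buildMultilayer()], [compareAllLayers()]
#' @exportClass MultiLayerNetwork
setClass("MultiLayerNetwork",
    representation(layers = "list", geneUniverse = "character")
)

setValidity("MultiLayerNetwork", function(object) {
    msgs <- character()
    if (!all(vapply(object@layers, is, logical(1), class2 = "CMILayer")))
        return("layers must all be CMILayer objects")
    ids <- vapply(object@layers, function(l) l@conditioningGene, character(1))
    if (anyDuplicated(ids))
        msgs <- c(msgs, "conditioning gene ids must be unique")
    if (length(object@layers)) {
        sameU <- vapply(object@layers, function(l)
            identical(l@geneUniverse, object@geneUniverse), logical(1))
        if (!all(sameU))
            msgs <- c(msgs, "all layers must share the network's gene universe")
        ks <- vapply(object@layers, function(l) l@truncationK, integer(1))
        if (length(unique(ks)) > 1L)
            msgs <- c(msgs, "all layers must share the same truncation")
    }
    if (length(msgs)) msgs else TRUE
})

#' All-pairs Kolmogorov-Smirnov comparison of layers
#'
#' Symmetric matrix of two-sample KS statistics \eqn{D_{n,m}} between the
#' edge-weight distributions of every unordered pair of layers, together
#' with the rejection mask of the asymptotic criterion
#' \eqn{D_{n,m} > c(\alpha)\sqrt{(n+m)/(nm)}}.
#'
#' @slot layerIds character; conditioning gene ids, in layer order.
#' @slot dValues numeric symmetric matrix, zero diagonal, values in
#'   \eqn{[0,1]}.
#' @slot reject logical symmetric matrix (diagonal `FALSE`).
#' @slot alpha significance level used for the rejection mask.
#' @slot nWeights integer; length of each layer's weight vector (the `n`
#'   and `m` of the threshold).
#'
#' @seealso [compareAllLayers()], [ksStatistic()], [ksCriticalValue()]
#' @exportClass DStatMatrix
setClass("DStatMatrix",
    representation(
        layerIds = "character",
        dValues  = "matrix",
        reject   = "matrix",
        alpha    = "numeric",
        nWeights = "integer"
    )
)

setValidity("DStatMatrix", function(object) {
    d <- object@dValues
    msgs <- character()
    L <- length(object@layerIds)
    if (!all(dim(d) == c(L, L)))
        return("dValues must be layer x layer")
    if (!identical(unname(d), unname(t(d))))
        msgs <- c(msgs, "dValues must be exactly symmetric")
    if (any(diag(d) != 0))
        msgs <- c(msgs, "diagonal must be zero")
    if (any(d < 0) || any(d > 1))
        msgs <- c(msgs, "D statistics must lie in [0, 1]")
    if (!identical(dim(object@reject), dim(d)))
        msgs <- c(msgs, "reject mask must match dValues")
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
        msgs <- c(msgs, "alpha must be a single value in (0, 1)")
    if (length(object@nWeights) != L)
        msgs <- c(msgs, "nWeights must have one entry per layer")
    if (length(msgs)) msgs else TRUE
})

#' Bundled synthetic or loaded dataset
#'
#' Container tying together an expression matrix (genes x samples), a
#' copy-number matrix (conditioning genes x samples, same samples), the
#' gene annotation as a `GRanges` (with `arm` and `cytoband` metadata
#' columns) and the cytoband table it was classified against.
#'
#' @slot expression numeric matrix, genes x samples, finite values.
#' @slot cnv numeric matrix, conditioning genes x samples, non-negative.
#' @slot annotation `GRanges` named by gene id with mcols `arm`, `cytoband`.
#' @slot cytobands data.frame with columns chrom, start, end, band, stain
#'   (UCSC cytoBand.txt layout, 0-based half-open).
#' @slot config list; generator or load settings (including the seed for
#'   synthetic data).
#'
#' @seealso [generateDataset()], [alignSamples()]
#' @exportClass CNVCoexDataset
setClass("CNVCoexDataset",
    representation(
        expression = "matrix",
        cnv        = "matrix",
        annotation = "GRanges",
        cytobands  = "data.frame",
        config     = "list"
    )
)

setValidity("CNVCoexDataset", function(object) {
    msgs <- character()
    if (!is.numeric(object@expression) || !all(is.finite(object@expression)))
        msgs <- c(msgs, "expression must be a finite numeric matrix")
    if (!is.numeric(object@cnv) || any(object@cnv < 0))
        msgs <- c(msgs, "cnv values must be non-negative")
    if (!identical(colnames(object@expression), colnames(object@cnv)))
        msgs <- c(msgs, "expression and cnv must share identical sample ids")
    if (anyDuplicated(rownames(object@expression)))
        msgs <- c(msgs, "duplicate gene ids in expression")
    gn <- rownames(object@expression)
    if (length(names(object@annotation)) &&
        !all(gn %in% names(object@annotation)))
        msgs <- c(msgs, "every expression gene must be annotated")
    if (length(msgs)) msgs else TRUE
})
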