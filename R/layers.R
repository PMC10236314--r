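## Assembly of CNV-conditioned co-expression layers and the top-k
## truncation applied before distribution comparison and geography.

#' Build one CNV-conditioned co-expression layer
#'
#' Runs [pairwiseCMI()] for the expression matrix against the named
#' conditioning gene's copy-number profile and wraps the full
#' \eqn{G(G-1)/2} edge list in a [CMILayer-class] (no truncation yet).
#'
#' @param expr expression matrix, genes x samples.
#' @param cnv copy-number matrix, conditioning genes x samples, sample
#'   columns aligned with `expr` (see [alignSamples()]).
#' @param conditioningGene row name of `cnv` to condition on.
#' @param ... estimator settings passed to [pairwiseCMI()] (`nBins`,
#'   `strategy`, `base`, `zMethod`, `zBins`).
#' @return a [CMILayer-class] with the full edge list.
#' @export
buildLayer <- function(expr, cnv, conditioningGene, ...) {
    stopifnot(is.matrix(expr), is.matrix(cnv))
    if (!identical(colnames(expr), colnames(cnv)))
        stop("expression and CNV samples are not aligned; run alignSamples()",
             call. = FALSE)
    if (!conditioningGene %in% rownames(cnv))
        stop(sprintf("conditioning gene '%s' not found in the CNV matrix",
                     conditioningGene), call. = FALSE)
    edges <- pairwiseCMI(expr, cnv[conditioningGene, ], ...)
    new("CMILayer",
        conditioningGene = conditioningGene,
        edges = edges,
        truncationK = NA_integer_,
        geneUniverse = sort(rownames(expr), method = "radix"),
        nSamples = ncol(expr))
}

#' Build the multi-CNVs co-expression network
#'
#' One [CMILayer-class] per row of the copy-number matrix, in row order.
#'
#' @inheritParams buildLayer
#' @param verbose log per-layer progress and timing. Default `FALSE`.
#' @return a [MultiLayerNetwork-class].
#' @export
buildMultilayer <- function(expr, cnv, ..., verbose = FALSE) {
    stopifnot(is.matrix(cnv))
    if (nrow(cnv) < 2L)
        stop("need at least 2 conditioning genes for a multilayer network",
             call. = FALSE)
    ls <- vector("list", nrow(cnv))
    for (i in seq_len(nrow(cnv))) {
        t0 <- proc.time()[["elapsed"]]
        ls[[i]] <- buildLayer(expr, cnv, rownames(cnv)[i], ...)
        if (verbose)
            message(sprintf("layer %d/%d (%s): %d edges in %.1fs",
                            i, nrow(cnv), rownames(cnv)[i],
                            nrow(ls[[i]]@edges),
                            proc.time()[["elapsed"]] - t0))
    }
    new("MultiLayerNetwork", layers = ls,
        geneUniverse = sort(rownames(expr), method = "radix"))
}

#' Keep the k strongest edges of a layer
#'
#' Edges are already sorted by decreasing weight with deterministic
#' tie-breaking by pair name, so truncation is a prefix: the result is
#' identical however the layer was computed. `k` at or above the edge
#' count returns the layer unchanged except for the recorded truncation.
#' Applied to a [MultiLayerNetwork-class] it truncates every layer.
#'
#' @param layer a [CMILayer-class] or [MultiLayerNetwork-class].
#' @param k number of edges to keep, >= 1.
#' @return object of the same class, truncated.
#' @export
truncateTopK <- function(layer, k) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L)
        stop("k must be a positive integer", call. = FALSE)
    if (is(layer, "MultiLayerNetwork")) {
        layer@layers <- lapply(layer@layers, truncateTopK, k = k)
        validObject(layer)
        return(layer)
    }
    stopifnot(is(layer, "CMILayer"))
    keep <- min(k, nrow(layer@edges))
    layer@edges <- layer@edges[seq_len(keep), , drop = FALSE]
    prev <- layer@truncationK
    layer@truncationK <- if (is.na(prev)) k else min(prev, k)
    validObject(layer)
    layer
}

#' Edge-weight distribution of a layer
#'
#' The vector of CMI weights in descending order — the object the
#' Kolmogorov-Smirnov comparison operates on. For a truncated layer its
#' length is the truncation k (the "first k links").
#'
#' @param layer a [CMILayer-class].
#' @return numeric vector, descending.
#' @export
layerWeightDistribution <- function(layer) {
    stopifnot(is(layer, "CMILayer"))
    if (nrow(layer@edges) == 0L)
        stop("layer has no edges", call. = FALSE)
    layer@edges$cmi
}

#' Persist / restore network layers as edge-list files
#'
#' `writeLayers` writes one edge-list TSV per layer plus a manifest
#' (`layers_manifest.tsv`: conditioning_gene, file, n_edges, truncation_k,
#' config_hash). `readLayers` rebuilds the [MultiLayerNetwork-class] from
#' a manifest. Existing per-layer files whose manifest row matches
#' `configHash` are treated as valid, which allows interrupted runs to
#' resume.
#'
#' @param net a [MultiLayerNetwork-class].
#' @param dir output directory (created if needed).
#' @param configHash short string identifying the estimator settings.
#' @return `writeLayers`: the manifest path, invisibly. `readLayers`: a
#'   [MultiLayerNetwork-class].
#' @export
writeLayers <- function(net, dir, configHash = "") {
    stopifnot(is(net, "MultiLayerNetwork"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ids <- layerIds(net)
    files <- sprintf("layer_%s.tsv", ids)
    for (i in seq_along(ids))
        writeEdgeList(net@layers[[i]]@edges, file.path(dir, files[i]))
    writeLines(sort(net@geneUniverse, method = "radix"),
               file.path(dir, "gene_universe.txt"))
    k <- truncationK(net)
    man <- data.frame(conditioning_gene = ids, file = files,
                      n_edges = vapply(net@layers, function(l)
                          nrow(l@edges), integer(1)),
                      n_samples = vapply(net@layers, function(l)
                          l@nSamples, integer(1)),
                      truncation_k = if (is.na(k)) "full" else k,
                      config_hash = configHash)
    utils::write.table(man, file.path(dir, "layers_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file.path(dir, "layers_manifest.tsv"))
}

#' @rdname writeLayers
#' @export
readLayers <- function(dir) {
    manPath <- file.path(dir, "layers_manifest.tsv")
    if (!file.exists(manPath))
        stop("no layers_manifest.tsv in ", dir, call. = FALSE)
    man <- utils::read.delim(manPath, colClasses = "character")
    universe <- readLines(file.path(dir, "gene_universe.txt"))
    k <- if (identical(man$truncation_k[1L], "full")) NA_integer_
         else as.integer(man$truncation_k[1L])
    ls <- lapply(seq_len(nrow(man)), function(i) {
        e <- readEdgeList(file.path(dir, man$file[i]))
        ## weights are stored at 10 significant digits; rounding can turn
        ## near-ties into exact ties, so re-apply the canonical sort
        e <- e[order(e$cmi, e$gene_i, e$gene_j,
                     decreasing = c(TRUE, FALSE, FALSE), method = "radix"), ,
               drop = FALSE]
        rownames(e) <- NULL
        new("CMILayer",
            conditioningGene = man$conditioning_gene[i],
            edges = e,
            truncationK = k,
            geneUniverse = universe,
            nSamples = as.integer(man$n_samples[i]))
    })
    new("MultiLayerNetwork", layers = ls, geneUniverse = universe)
}
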