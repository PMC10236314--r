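#' @name accessors
#' @title Accessors for cnvcoex classes
#'
#' @description Slot accessors: `conditioningGene()` and `edgeTable()` for a
#' [CMILayer-class]; `layers()` and `geneUniverse()` for a
#' [MultiLayerNetwork-class]; `layerIds()`, `dValues()`, `rejectMatrix()` and
#' `alphaLevel()` for a [DStatMatrix-class]; `exprMatrix()`, `cnvMatrix()`,
#' `geneAnnotation()`, `cytobandTable()` and `datasetConfig()` for a
#' [CNVCoexDataset-class]. `truncationK()` works on both layer types.
#'
#' @param x object of the corresponding class.
#' @return the slot contents (see class documentation).
#' @examples
#' cfg <- syntheticConfig(nGenes = 10, nSamples = 40, nConditioning = 2,
#'                        bandLayout = data.frame(arm = c("p", "q"),
#'                                                band = c("p21.3", "q24.3"),
#'                                                nGenes = c(5, 5)),
#'                        hotspotBands = "q24.3", seed = 1)
#' ds <- generateDataset(cfg)
#' dim(exprMatrix(ds))
NULL

#' @rdname accessors
#' @export
setGeneric("conditioningGene", function(x) standardGeneric("conditioningGene"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("truncationK", function(x) standardGeneric("truncationK"))
#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname accessors
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))
#' @rdname accessors
#' @export
setGeneric("layerIds", function(x) standardGeneric("layerIds"))
#' @rdname accessors
#' @export
setGeneric("dValues", function(x) standardGeneric("dValues"))
#' @rdname accessors
#' @export
setGeneric("rejectMatrix", function(x) standardGeneric("rejectMatrix"))
#' @rdname accessors
#' @export
setGeneric("alphaLevel", function(x) standardGeneric("alphaLevel"))
#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setGeneric("cnvMatrix", function(x) standardGeneric("cnvMatrix"))
#' @rdname accessors
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))
#' @rdname accessors
#' @export
setGeneric("cytobandTable", function(x) standardGeneric("cytobandTable"))
#' @rdname accessors
#' @export
setGeneric("datasetConfig", function(x) standardGeneric("datasetConfig"))

#' @rdname accessors
setMethod("conditioningGene", "CMILayer", function(x) x@conditioningGene)
#' @rdname accessors
setMethod("edgeTable", "CMILayer", function(x) x@edges)
#' @rdname accessors
setMethod("truncationK", "CMILayer", function(x) x@truncationK)
#' @rdname accessors
setMethod("geneUniverse", "CMILayer", function(x) x@geneUniverse)
#' @rdname accessors
setMethod("layers", "MultiLayerNetwork", function(x) x@layers)
#' @rdname accessors
setMethod("geneUniverse", "MultiLayerNetwork", function(x) x@geneUniverse)
#' @rdname accessors
setMethod("truncationK", "MultiLayerNetwork", function(x) {
    if (length(x@layers)) x@layers[[1L]]@truncationK else NA_integer_
})
#' @rdname accessors
setMethod("layerIds", "MultiLayerNetwork", function(x)
    vapply(x@layers, conditioningGene, character(1)))
#' @rdname accessors
setMethod("layerIds", "DStatMatrix", function(x) x@layerIds)
#' @rdname accessors
setMethod("dValues", "DStatMatrix", function(x) x@dValues)
#' @rdname accessors
setMethod("rejectMatrix", "DStatMatrix", function(x) x@reject)
#' @rdname accessors
setMethod("alphaLevel", "DStatMatrix", function(x) x@alpha)
#' @rdname accessors
setMethod("exprMatrix", "CNVCoexDataset", function(x) x@expression)
#' @rdname accessors
setMethod("cnvMatrix", "CNVCoexDataset", function(x) x@cnv)
#' @rdname accessors
setMethod("geneAnnotation", "CNVCoexDataset", function(x) x@annotation)
#' @rdname accessors
setMethod("cytobandTable", "CNVCoexDataset", function(x) x@cytobands)
#' @rdname accessors
setMethod("datasetConfig", "CNVCoexDataset", function(x) x@config)

setMethod("show", "CMILayer", function(object) {
    k <- object@truncationK
    cat(sprintf("CMILayer | conditioning gene: %s | %d edges (%s) | %d genes\n",
                object@conditioningGene, nrow(object@edges),
                if (is.na(k)) "full" else sprintf("top-%d", k),
                length(object@geneUniverse)))
    if (nrow(object@edges)) {
        cat("strongest edges:\n")
        print(utils::head(object@edges, 3L), row.names = FALSE)
    }
    invisible(NULL)
})

setMethod("show", "MultiLayerNetwork", function(object) {
    k <- truncationK(object)
    cat(sprintf(
        "MultiLayerNetwork | %d layers | %d genes | truncation: %s\n",
        length(object@layers), length(object@geneUniverse),
        if (is.na(k)) "full" else as.character(k)))
    invisible(NULL)
})

setMethod("show", "DStatMatrix", function(object) {
    s <- summary(object)
    cat(sprintf(
        paste0("DStatMatrix | %d layers, %d unordered comparisons | ",
               "max D = %.4g, min off-diagonal D = %.4g | ",
               "%d rejected at alpha = %g\n"),
        length(object@layerIds), s$n_pairs, s$max_D, s$min_offdiag_D,
        s$n_rejected, object@alpha))
    invisible(NULL)
})

setMethod("show", "CNVCoexDataset", function(object) {
    cat(sprintf(
        "CNVCoexDataset | %d genes x %d samples | %d conditioning genes | %d cytobands\n",
        nrow(object@expression), ncol(object@expression),
        nrow(object@cnv), nrow(object@cytobands)))
    invisible(NULL)
})

#' Summarize an all-pairs layer comparison
#'
#' @param object a [DStatMatrix-class].
#' @param ... ignored.
#' @return one-row `data.frame` with `n_pairs` (number of unordered layer
#'   pairs), `max_D`, `min_offdiag_D`, `n_rejected` and `alpha`. The
#'   diagonal (self-comparison) is excluded.
#' @export
setMethod("summary", "DStatMatrix", function(object, ...) {
    d <- object@dValues
    off <- d[upper.tri(d)]
    data.frame(
        n_pairs       = length(off),
        max_D         = if (length(off)) max(off) else NA_real_,
        min_offdiag_D = if (length(off)) min(off) else NA_real_,
        n_rejected    = sum(object@reject[upper.tri(d)]),
        alpha         = object@alpha
    )
})
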