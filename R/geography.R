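## Chromosomal geography of co-expression edges: classification into
## intra-cytoband / inter-cytoband / inter-arm, cumulative growth curves in
## CMI rank order, degree profiles and cytoband hotspot summaries. This
## analysis is cis-only: both endpoints must lie on the same chromosome.

.edgeCategories <- c("intra_cytoband", "inter_cytoband", "inter_arm")

.annLookup <- function(ann, genes) {
    if (is.null(names(ann)))
        stop("annotation GRanges must be named by gene id", call. = FALSE)
    missing <- setdiff(genes, names(ann))
    if (length(missing))
        stop("missing annotation for gene(s): ",
             paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    idx <- match(genes, names(ann))
    data.frame(gene = genes,
               chrom = as.character(GenomicRanges::seqnames(ann))[idx],
               arm = S4Vectors::mcols(ann)$arm[idx],
               cytoband = S4Vectors::mcols(ann)$cytoband[idx])
}

#' Classify edges by chromosomal relationship
#'
#' Two genes in the same cytoband form an `intra_cytoband` edge; same arm
#' but different cytobands, `inter_cytoband`; different arms, `inter_arm`.
#' The three categories partition all same-chromosome pairs; pairs on
#' different chromosomes are an error (the analysis is cis-only).
#'
#' @param geneI,geneJ character vectors of gene ids (recycled to a common
#'   length; symmetric in the two arguments).
#' @param ann annotation `GRanges` from [readGeneAnnotation()] or
#'   [generateDataset()].
#' @return factor with levels `intra_cytoband`, `inter_cytoband`,
#'   `inter_arm`.
#' @export
classifyEdges <- function(geneI, geneJ, ann) {
    n <- max(length(geneI), length(geneJ))
    geneI <- rep_len(geneI, n); geneJ <- rep_len(geneJ, n)
    ai <- .annLookup(ann, geneI)
    aj <- .annLookup(ann, geneJ)
    trans <- ai$chrom != aj$chrom
    if (any(trans))
        stop(sprintf(
            "cis-only analysis: %d edge(s) join different chromosomes (e.g. %s/%s)",
            sum(trans), geneI[which(trans)[1L]], geneJ[which(trans)[1L]]),
            call. = FALSE)
    cat <- ifelse(ai$cytoband == aj$cytoband, "intra_cytoband",
           ifelse(ai$arm == aj$arm, "inter_cytoband", "inter_arm"))
    factor(cat, levels = .edgeCategories)
}

#' Cumulative category growth along the CMI ranking
#'
#' Walks the layer's edges in decreasing CMI order ("order of appearance"
#' of the links) and accumulates, at every rank, how many edges so far
#' fall in each of the three categories. At any rank the three counts sum
#' to the rank.
#'
#' @param layer a [CMILayer-class] (sorted by construction).
#' @param ann annotation `GRanges`.
#' @param maxEdges number of top edges to walk; default 10000. Values
#'   beyond the edge count are truncated with a warning.
#' @return data.frame with columns `rank`, `intra_cytoband`,
#'   `inter_cytoband`, `inter_arm` (cumulative counts).
#' @export
growthCurves <- function(layer, ann, maxEdges = 10000L) {
    stopifnot(is(layer, "CMILayer"))
    maxEdges <- as.integer(maxEdges)
    if (maxEdges < 1L)
        stop("maxEdges must be >= 1", call. = FALSE)
    e <- layer@edges
    if (maxEdges > nrow(e)) {
        warning(sprintf("maxEdges %d exceeds edge count %d; truncating",
                        maxEdges, nrow(e)))
        maxEdges <- nrow(e)
    }
    e <- e[seq_len(maxEdges), , drop = FALSE]
    cat <- classifyEdges(e$gene_i, e$gene_j, ann)
    out <- data.frame(rank = seq_len(maxEdges))
    for (cc in .edgeCategories)
        out[[cc]] <- cumsum(cat == cc)
    out
}

#' Category counts of the top-k edges at several cutoffs
#'
#' Snapshot of [growthCurves()] at the given cutoffs: for each cutoff k,
#' how many of the k strongest edges are intra-cytoband, inter-cytoband
#' and inter-arm.
#'
#' @param layer a [CMILayer-class].
#' @param ann annotation `GRanges`.
#' @param cutoffs ascending positive integers; default
#'   `c(100, 500, 1000, 1500)`.
#' @return data.frame `cutoff`, `intra_cytoband`, `inter_cytoband`,
#'   `inter_arm`.
#' @export
categoryCountsAtCutoffs <- function(layer, ann,
                                    cutoffs = c(100L, 500L, 1000L, 1500L)) {
    cutoffs <- as.integer(cutoffs)
    if (any(cutoffs < 1L) || is.unsorted(cutoffs, strictly = TRUE))
        stop("cutoffs must be positive and strictly ascending", call. = FALSE)
    gc <- growthCurves(layer, ann,
                       maxEdges = min(max(cutoffs), nrow(layer@edges)))
    rows <- pmin(cutoffs, nrow(gc))
    out <- gc[rows, , drop = FALSE]
    names(out)[1L] <- "cutoff"
    out$cutoff <- cutoffs
    rownames(out) <- NULL
    out
}

#' Per-gene degree in a truncated layer
#'
#' Incident-edge counts over the layer's (typically truncated) edge set;
#' genes of the universe absent from every edge get degree 0. Degrees sum
#' to twice the edge count.
#'
#' @param layer a [CMILayer-class].
#' @param ann optional annotation `GRanges`; when supplied, each gene's
#'   cytoband is attached.
#' @return data.frame `gene_id`, `degree` (and `cytoband` if annotated),
#'   sorted by decreasing degree then gene id.
#' @export
degreeProfile <- function(layer, ann = NULL) {
    stopifnot(is(layer, "CMILayer"))
    genes <- layer@geneUniverse
    deg <- table(factor(c(layer@edges$gene_i, layer@edges$gene_j),
                        levels = genes))
    out <- data.frame(gene_id = genes, degree = as.integer(deg))
    if (!is.null(ann))
        out$cytoband <- .annLookup(ann, genes)$cytoband
    out <- out[order(out$degree, out$gene_id,
                     decreasing = c(TRUE, FALSE), method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Cytoband hotspot summary
#'
#' For every cytoband holding at least one gene of the universe: the
#' number of layer edges with both endpoints inside the band, their mean
#' CMI, and the band's share of the layer's strongest edges (the top
#' `topFraction` of the edge list). Bands are ranked by that share — a
#' band concentrating a disproportionate share of the strongest edges is
#' a co-expression hotspot.
#'
#' @param layer a [CMILayer-class].
#' @param ann annotation `GRanges`.
#' @param topFraction fraction of strongest edges defining "top"; default
#'   0.01, must be in (0, 1].
#' @return data.frame `cytoband`, `n_genes`, `n_edges_within`,
#'   `mean_cmi_within`, `top_share`, sorted by decreasing `top_share`.
#' @export
cytobandHotspots <- function(layer, ann, topFraction = 0.01) {
    stopifnot(is(layer, "CMILayer"))
    if (!is.numeric(topFraction) || topFraction <= 0 || topFraction > 1)
        stop("topFraction must be in (0, 1]", call. = FALSE)
    lk <- .annLookup(ann, layer@geneUniverse)
    bands <- sort(unique(lk$cytoband), method = "radix")
    e <- layer@edges
    bi <- lk$cytoband[match(e$gene_i, lk$gene)]
    bj <- lk$cytoband[match(e$gene_j, lk$gene)]
    within <- ifelse(bi == bj, bi, NA_character_)
    m <- max(1L, as.integer(ceiling(topFraction * nrow(e))))
    topBand <- within[seq_len(min(m, nrow(e)))]
    out <- data.frame(
        cytoband = bands,
        n_genes = as.integer(table(factor(lk$cytoband, levels = bands))),
        n_edges_within = as.integer(table(factor(within, levels = bands))),
        mean_cmi_within = vapply(bands, function(b) {
            w <- e$cmi[!is.na(within) & within == b]
            if (length(w)) mean(w) else NA_real_
        }, numeric(1)),
        top_share = as.integer(table(factor(topBand, levels = bands))) /
            length(topBand)
    )
    out <- out[order(out$top_share, out$n_edges_within,
                     decreasing = c(TRUE, TRUE), method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
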