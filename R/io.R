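## Tabular readers/writers for the pipeline's plain-text formats.
## All matrices are genes x samples TSV with a header row of sample ids and
## a first column of gene ids; outputs use 10 significant digits.

.readMatrixTSV <- function(path, what) {
    if (!file.exists(path))
        stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "")
    if (ncol(df) < 2L)
        stop(sprintf("%s file must have gene ids plus >= 1 sample column", what),
             call. = FALSE)
    ids <- df[[1L]]
    samples <- colnames(df)[-1L]
    if (anyDuplicated(ids))
        stop(sprintf("duplicate gene id(s) in %s file: %s", what,
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             call. = FALSE)
    if (anyDuplicated(samples))
        stop(sprintf("duplicate sample id(s) in %s file: %s", what,
                     paste(unique(samples[duplicated(samples)]), collapse = ", ")),
             call. = FALSE)
    body <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
    bad <- which(!is.finite(num), arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf(
            "cannot parse value '%s' in %s file at gene '%s', sample '%s'",
            body[bad[1L, 1L], bad[1L, 2L]], what,
            ids[bad[1L, 1L]], samples[bad[1L, 2L]]), call. = FALSE)
    }
    dimnames(num) <- list(ids, samples)
    num
}

#' Read a gene expression matrix
#'
#' Reads a tab-separated genes x samples table: first row holds sample ids,
#' first column gene ids, body numeric. Values are used as supplied
#' (normalization is assumed done upstream); set `log2p1 = TRUE` to apply
#' a `log2(x + 1)` transform on load. Because downstream discretization is
#' rank-based within each gene, the transform does not change
#' equal-frequency results; it is offered for equal-width binning and for
#' inspection.
#'
#' @param path path to the TSV file.
#' @param log2p1 apply `log2(x + 1)` after validation. Default `FALSE`.
#' @return numeric matrix with gene row names and sample column names, in
#'   file order. At least 2 genes and 8 samples are required.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(16), 2, 8,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
#' writeMatrixTSV(m, tf)
#' identical(dim(readExpressionMatrix(tf)), c(2L, 8L))
#' @export
readExpressionMatrix <- function(path, log2p1 = FALSE) {
    m <- .readMatrixTSV(path, "expression")
    if (nrow(m) < 2L)
        stop("expression matrix needs at least 2 genes", call. = FALSE)
    if (ncol(m) < 8L)
        stop("expression matrix needs at least 8 samples for CMI estimation",
             call. = FALSE)
    if (log2p1) {
        if (any(m < 0))
            stop("log2(x+1) transform requires non-negative expression values",
                 call. = FALSE)
        m <- log2(m + 1)
    }
    m
}

#' Read a copy-number matrix
#'
#' Same layout as [readExpressionMatrix()]: conditioning genes in rows,
#' samples in columns. Values must be non-negative (copy-number states or
#' continuous copy-number estimates). Sample sets need not match the
#' expression matrix at load time; [alignSamples()] reconciles them.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, conditioning genes x samples.
#' @export
readCNVMatrix <- function(path) {
    m <- .readMatrixTSV(path, "CNV")
    if (any(m < 0)) {
        bad <- which(m < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative copy-number value at gene '%s', sample '%s'",
                     rownames(m)[bad[1L]], colnames(m)[bad[2L]]),
             call. = FALSE)
    }
    m
}

#' Write a numeric matrix as TSV
#'
#' Counterpart of the matrix readers: header row of sample ids, first
#' column of gene ids, values at 10 significant digits.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
    stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
    fm <- apply(m, 2L, function(col) sprintf("%.10g", col))
    if (!is.matrix(fm)) fm <- matrix(fm, nrow = nrow(m))
    lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
               paste(rownames(m), apply(fm, 1L, paste, collapse = "\t"),
                     sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Read gene annotation from BED and a UCSC cytoband file
#'
#' Genes come from a BED file (>= 4 columns: chrom, start, end, name;
#' 0-based half-open) and are assigned the cytoband whose interval contains
#' the gene's start coordinate. A gene whose start equals a band's end falls
#' in the following band (half-open convention); a gene spanning a band
#' boundary belongs to the band of its start. The chromosome arm is the
#' first character of the band name.
#'
#' @param bedPath BED file of gene positions (name column = gene id).
#' @param cytobandPath UCSC `cytoBand.txt`-format file: chrom, start, end,
#'   band name, Giemsa stain; no header; 0-based half-open.
#' @return `GRanges` named by gene id with metadata columns `arm` ("p" or
#'   "q") and `cytoband` (band name, e.g. "q24.3").
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' cyt <- tempfile()
#' writeLines("chr8\t100\t900\tMYGENE", bed)
#' writeLines("chr8\t0\t2300000\tp23.3\tgneg", cyt)
#' ann <- readGeneAnnotation(bed, cyt)
#' S4Vectors::mcols(ann)["MYGENE", "cytoband"]  # "p23.3"
#' @export
readGeneAnnotation <- function(bedPath, cytobandPath) {
    if (!file.exists(bedPath))
        stop("BED file not found: ", bedPath, call. = FALSE)
    if (!file.exists(cytobandPath))
        stop("cytoband file not found: ", cytobandPath, call. = FALSE)
    gr <- rtracklayer::import(bedPath, format = "BED")
    if (is.null(gr$name) || anyNA(gr$name))
        stop("BED file must have a name column (>= 4 columns)", call. = FALSE)
    if (anyDuplicated(gr$name))
        stop("duplicate gene ids in BED file", call. = FALSE)
    bands <- readCytobands(cytobandPath)
    ## rtracklayer gives 1-based starts; recover the BED 0-based start
    gstart0 <- GenomicRanges::start(gr) - 1L
    gchrom <- as.character(GenomicRanges::seqnames(gr))
    idx <- rep(NA_integer_, length(gr))
    for (chr in unique(gchrom)) {
        sel <- gchrom == chr
        b <- bands[bands$chrom == chr, , drop = FALSE]
        if (nrow(b) == 0L)
            stop(sprintf(
                "gene(s) on chromosome '%s' have no cytoband rows: %s",
                chr, paste(gr$name[sel], collapse = ", ")), call. = FALSE)
        b <- b[order(b$start), , drop = FALSE]
        pos <- findInterval(gstart0[sel], b$start)
        hit <- pos >= 1L & gstart0[sel] < b$end[pmax(pos, 1L)]
        if (!all(hit))
            stop(sprintf("gene start not covered by any cytoband: %s",
                         paste(gr$name[sel][!hit], collapse = ", ")),
                 call. = FALSE)
        idx[sel] <- as.integer(rownames(b))[pos]
    }
    band <- bands$band[idx]
    arm <- substr(band, 1L, 1L)
    if (!all(arm %in% c("p", "q")))
        stop("cytoband names must start with arm letter 'p' or 'q'",
             call. = FALSE)
    out <- GenomicRanges::GRanges(gchrom,
                                  IRanges::IRanges(GenomicRanges::start(gr),
                                                   GenomicRanges::end(gr)))
    names(out) <- gr$name
    S4Vectors::mcols(out)$arm <- arm
    S4Vectors::mcols(out)$cytoband <- band
    out
}

#' Read a UCSC cytoBand.txt-format table
#'
#' @param path cytoband file (chrom, start, end, band, stain; no header).
#' @return data.frame with those five columns; `start < end` enforced.
#' @export
readCytobands <- function(path) {
    bands <- utils::read.table(path, sep = "\t", header = FALSE,
                               col.names = c("chrom", "start", "end",
                                             "band", "stain"),
                               colClasses = c("character", "integer",
                                              "integer", "character",
                                              "character"))
    if (any(bands$start >= bands$end))
        stop("cytoband intervals must satisfy start < end", call. = FALSE)
    rownames(bands) <- as.character(seq_len(nrow(bands)))
    bands
}

#' Restrict expression and CNV matrices to their shared samples
#'
#' Columns are intersected by sample id (not position) and reordered
#' identically — expression column order wins. Idempotent. A message
#' reports how many samples were dropped from each matrix.
#'
#' @param expr expression matrix (genes x samples).
#' @param cnv copy-number matrix (conditioning genes x samples).
#' @param minShared minimum acceptable intersection size; below it the
#'   pairing is considered broken and an error is raised. Default 8, the
#'   floor for CMI estimation.
#' @return list with elements `expr` and `cnv`, columns aligned.
#' @export
alignSamples <- function(expr, cnv, minShared = 8L) {
    shared <- intersect(colnames(expr), colnames(cnv))
    if (length(shared) < minShared)
        stop(sprintf(
            "only %d sample(s) shared between expression and CNV matrices (need >= %d)",
            length(shared), minShared), call. = FALSE)
    shared <- colnames(expr)[colnames(expr) %in% shared]
    dropE <- ncol(expr) - length(shared)
    dropC <- ncol(cnv) - length(shared)
    if (dropE + dropC > 0L)
        message(sprintf("alignSamples: dropped %d expression and %d CNV sample(s)",
                        dropE, dropC))
    list(expr = expr[, shared, drop = FALSE],
         cnv  = cnv[, shared, drop = FALSE])
}

#' Write / read a weighted edge list
#'
#' Edge lists are TSV with header `gene_i  gene_j  cmi`, sorted by
#' descending weight then pair name, weights at 10 significant digits.
#'
#' @param edges data.frame with columns `gene_i`, `gene_j`, `cmi` (as from
#'   [pairwiseCMI()] or `edgeTable()` of a layer).
#' @param path file path.
#' @return `writeEdgeList`: `path` invisibly; `readEdgeList`: the
#'   data.frame.
#' @export
writeEdgeList <- function(edges, path) {
    stopifnot(all(c("gene_i", "gene_j", "cmi") %in% names(edges)))
    lines <- c("gene_i\tgene_j\tcmi",
               sprintf("%s\t%s\t%.10g", edges$gene_i, edges$gene_j,
                       edges$cmi))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           "numeric"))
    names(df) <- c("gene_i", "gene_j", "cmi")
    df
}

#' Write a D-statistic matrix and its long form
#'
#' `writeDMatrix` writes the layer x layer matrix with a leading id column;
#' `dMatrixLongTable` returns (and optionally writes) the plot-ready long
#' format with one row per unordered layer pair.
#'
#' @param dsm a [DStatMatrix-class].
#' @param path file path (optional for `dMatrixLongTable`).
#' @return `writeDMatrix`: `path` invisibly. `dMatrixLongTable`:
#'   data.frame `layer_i`, `layer_j`, `D`, `rejected`.
#' @export
writeDMatrix <- function(dsm, path) {
    d <- dValues(dsm)
    ids <- layerIds(dsm)
    lines <- c(paste(c("layer", ids), collapse = "\t"),
               vapply(seq_along(ids), function(i)
                   paste(c(ids[i], sprintf("%.10g", d[i, ])),
                         collapse = "\t"), character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeDMatrix
#' @export
dMatrixLongTable <- function(dsm, path = NULL) {
    d <- dValues(dsm)
    ids <- layerIds(dsm)
    ut <- which(upper.tri(d), arr.ind = TRUE)
    out <- data.frame(layer_i  = ids[ut[, 1L]],
                      layer_j  = ids[ut[, 2L]],
                      D        = d[ut],
                      rejected = rejectMatrix(dsm)[ut])
    out <- out[order(out$layer_i, out$layer_j, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(path)) {
        utils::write.table(format(out, digits = 10, scientific = FALSE,
                                  trim = TRUE),
                           path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    out
}

## generic TSV writer for the geography tables (numbers at 10 sig digits)
.writeTSV <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1)) &
        !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
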