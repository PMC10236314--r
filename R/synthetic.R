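## Synthetic expression / CNV / annotation generator. Expression is drawn
## from a multivariate Gaussian with a block (per-cytoband) correlation
## structure over a homogeneous background; copy-number states are drawn
## independently per conditioning gene and sample. An optional coupling
## makes the hotspot-band correlation depend on the first conditioning
## gene's state, so CNV-dependent co-expression can be switched on and off.

#' Configuration for the synthetic dataset generator
#'
#' Validates and freezes all generator settings. The covariance implied by
#' the correlation parameters is a homogeneous background `backgroundCorr`
#' with within-band blocks raised to `blockCorr` (`hotspotCorr` for bands
#' named in `hotspotBands`); this nested structure is positive
#' semi-definite whenever `0 <= backgroundCorr <= blockCorr <= hotspotCorr
#' < 1`, which is enforced here.
#'
#' With `coupling > 0` the hotspot-band correlation of each sample is
#' shifted by `coupling * (state - median(cnvStates))` where `state` is
#' that sample's copy-number state of the *first* conditioning gene (the
#' designated driver), truncated to `[0, 0.99]`. A shift that would push
#' the band correlation below the background breaks positive
#' semi-definiteness and raises an error advising a smaller coupling.
#'
#' @param nGenes number of expression genes (must equal the sum of the
#'   band layout's gene counts).
#' @param nSamples number of samples (>= 8).
#' @param nConditioning number of conditioning genes (copy-number rows).
#' @param bandLayout data.frame with columns `arm` ("p"/"q"), `band`
#'   (name, first character = arm) and `nGenes`; p bands must precede q
#'   bands. Default: six bands of ten genes on a chromosome-8-like layout
#'   (p23.1, p21.3, p11.2, q13, q22, q24.3).
#' @param backgroundCorr between-band correlation, in `[0, 1)`.
#' @param blockCorr within-band correlation, `>= backgroundCorr`, `< 1`.
#' @param hotspotBands band names whose block correlation is boosted;
#'   conditioning genes are placed in the first of these. Default
#'   `"q24.3"`.
#' @param hotspotCorr correlation inside hotspot bands, `>= blockCorr`,
#'   `< 1`.
#' @param cnvStates integer copy-number states, default `1:3`.
#' @param cnvStateProbs sampling probabilities per state, default
#'   `c(0.2, 0.6, 0.2)` (weighted toward the diploid state).
#' @param coupling strength of the CNV-to-co-expression modulation,
#'   `>= 0`; 0 (default) makes co-expression independent of CNV.
#' @param noiseSd marginal standard deviation of expression, > 0.
#' @param seed integer RNG seed.
#' @return validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 60L, nSamples = 150L,
                            nConditioning = 10L,
                            bandLayout = NULL,
                            backgroundCorr = 0.2, blockCorr = 0.5,
                            hotspotBands = "q24.3", hotspotCorr = 0.7,
                            cnvStates = 1:3,
                            cnvStateProbs = c(0.2, 0.6, 0.2),
                            coupling = 0, noiseSd = 1, seed = 1L) {
    if (is.null(bandLayout)) {
        bandLayout <- data.frame(
            arm = c("p", "p", "p", "q", "q", "q"),
            band = c("p23.1", "p21.3", "p11.2", "q13", "q22", "q24.3"),
            nGenes = rep(nGenes %/% 6L, 6L))
        rem <- nGenes - sum(bandLayout$nGenes)
        if (rem > 0L)
            bandLayout$nGenes[seq_len(rem)] <-
                bandLayout$nGenes[seq_len(rem)] + 1L
    }
    stopifnot(is.data.frame(bandLayout),
              all(c("arm", "band", "nGenes") %in% names(bandLayout)))
    if (sum(bandLayout$nGenes) != nGenes)
        stop("band layout gene counts must sum to nGenes", call. = FALSE)
    if (!all(bandLayout$arm %in% c("p", "q")))
        stop("arms must be 'p' or 'q'", call. = FALSE)
    if (!identical(bandLayout$arm, substr(bandLayout$band, 1L, 1L)))
        stop("each band name must start with its arm letter", call. = FALSE)
    if (is.unsorted(match(bandLayout$arm, c("p", "q"))))
        stop("p bands must precede q bands", call. = FALSE)
    if (anyDuplicated(bandLayout$band))
        stop("duplicate band names", call. = FALSE)
    if (!all(hotspotBands %in% bandLayout$band))
        stop("hotspotBands must be band names of the layout", call. = FALSE)
    if (!(backgroundCorr >= 0 && backgroundCorr <= blockCorr &&
          blockCorr <= hotspotCorr && hotspotCorr < 1))
        stop("need 0 <= backgroundCorr <= blockCorr <= hotspotCorr < 1",
             call. = FALSE)
    if (nSamples < 8L)
        stop("need at least 8 samples", call. = FALSE)
    if (nConditioning < 1L)
        stop("need at least 1 conditioning gene", call. = FALSE)
    cnvStates <- as.integer(cnvStates)
    if (length(cnvStates) != length(cnvStateProbs) ||
        any(cnvStateProbs < 0) ||
        abs(sum(cnvStateProbs) - 1) > 1e-8)
        stop("cnvStateProbs must be a probability vector over cnvStates",
             call. = FALSE)
    if (any(cnvStates < 0))
        stop("cnvStates must be non-negative", call. = FALSE)
    if (coupling < 0) stop("coupling must be >= 0", call. = FALSE)
    if (noiseSd <= 0) stop("noiseSd must be positive", call. = FALSE)
    structure(list(
        nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
        nConditioning = as.integer(nConditioning),
        bandLayout = bandLayout,
        backgroundCorr = backgroundCorr, blockCorr = blockCorr,
        hotspotBands = hotspotBands, hotspotCorr = hotspotCorr,
        cnvStates = cnvStates, cnvStateProbs = cnvStateProbs,
        coupling = coupling, noiseSd = noiseSd,
        seed = as.integer(seed)),
        class = "SyntheticConfig")
}

.bandLength <- 2000000L

#' Generate the synthetic gene and cytoband annotation
#'
#' Bands tile one chromosome (2 Mb each, p arm first, centromere implicit
#' between the arms); genes sit at evenly spaced, strictly increasing
#' start positions inside their band. Gene ids are zero-padded so
#' lexicographic order equals genomic order.
#'
#' @param cfg a [syntheticConfig()].
#' @param chromosome chromosome name; default "chr8".
#' @return list with `genes` (annotation `GRanges` with `arm`/`cytoband`
#'   metadata) and `cytobands` (UCSC-layout data.frame).
#' @export
generateAnnotation <- function(cfg, chromosome = "chr8") {
    stopifnot(inherits(cfg, "SyntheticConfig"))
    bl <- cfg$bandLayout
    nb <- nrow(bl)
    bandStart <- (seq_len(nb) - 1L) * .bandLength
    cyt <- data.frame(chrom = chromosome, start = bandStart,
                      end = bandStart + .bandLength, band = bl$band,
                      stain = "gneg")
    width <- 1000L
    starts0 <- unlist(lapply(seq_len(nb), function(b) {
        n <- bl$nGenes[b]
        if (n == 0L) return(integer())
        bandStart[b] + as.integer(round(seq_len(n) * .bandLength / (n + 1L)))
    }))
    ids <- sprintf("g%0*d", nchar(cfg$nGenes) + 1L, seq_len(cfg$nGenes))
    gr <- GenomicRanges::GRanges(chromosome,
                                 IRanges::IRanges(start = starts0 + 1L,
                                                  width = width))
    names(gr) <- ids
    S4Vectors::mcols(gr)$arm <- rep(bl$arm, bl$nGenes)
    S4Vectors::mcols(gr)$cytoband <- rep(bl$band, bl$nGenes)
    list(genes = gr, cytobands = cyt)
}

.bandCorrelation <- function(cfg, hotspotShift = 0) {
    bl <- cfg$bandLayout
    bandOf <- rep(seq_len(nrow(bl)), bl$nGenes)
    cBand <- ifelse(bl$band %in% cfg$hotspotBands,
                    cfg$hotspotCorr, cfg$blockCorr)
    hot <- bl$band %in% cfg$hotspotBands
    cBand[hot] <- pmin(pmax(cBand[hot] + hotspotShift, 0), 0.99)
    if (any(cBand[hot] < cfg$backgroundCorr))
        stop(paste("coupling shift pushes a band correlation below the",
                   "background, breaking positive semi-definiteness;",
                   "use a smaller coupling"), call. = FALSE)
    G <- cfg$nGenes
    S <- matrix(cfg$backgroundCorr, G, G)
    for (b in seq_len(nrow(bl))) {
        idx <- which(bandOf == b)
        S[idx, idx] <- cBand[b]
    }
    diag(S) <- 1
    S
}

#' Generate a synthetic expression / CNV / annotation dataset
#'
#' Copy-number states are sampled independently per conditioning gene and
#' sample from `cnvStateProbs`. Expression is multivariate Gaussian with
#' the block correlation structure of the config (see [syntheticConfig()]
#' for the coupling mechanism); the same underlying standard-normal draw
#' is reused across coupling strata, so datasets differing only in
#' `coupling` share their noise and the whole generation is bit-identical
#' under a fixed seed.
#'
#' @param cfg a [syntheticConfig()].
#' @return a [CNVCoexDataset-class].
#' @export
generateDataset <- function(cfg) {
    stopifnot(inherits(cfg, "SyntheticConfig"))
    ann <- generateAnnotation(cfg)
    G <- cfg$nGenes; N <- cfg$nSamples; K <- cfg$nConditioning
    sampleIds <- sprintf("s%0*d", nchar(N) + 1L, seq_len(N))
    condIds <- sprintf("cnv%02d", seq_len(K))
    withr::with_seed(cfg$seed, {
        cnv <- matrix(sample(cfg$cnvStates, K * N, replace = TRUE,
                             prob = cfg$cnvStateProbs),
                      nrow = K, dimnames = list(condIds, sampleIds))
        z0 <- matrix(rnorm(G * N), G, N)
    }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
       .rng_sample_kind = "Rejection")
    expr <- matrix(0, G, N, dimnames = list(names(ann$genes), sampleIds))
    if (cfg$coupling == 0) {
        R <- chol(.bandCorrelation(cfg))
        expr[, ] <- crossprod(R, z0)
    } else {
        med <- stats::median(cfg$cnvStates)
        driver <- cnv[1L, ]
        for (s in sort(unique(driver))) {
            cols <- which(driver == s)
            R <- chol(.bandCorrelation(cfg,
                                       hotspotShift = cfg$coupling * (s - med)))
            expr[, cols] <- crossprod(R, z0[, cols, drop = FALSE])
        }
    }
    expr <- expr * cfg$noiseSd
    new("CNVCoexDataset", expression = expr, cnv = cnv,
        annotation = ann$genes, cytobands = ann$cytobands,
        config = unclass(cfg))
}

#' Homogeneous ("healthy-like") and localized ("cancer-like") presets
#'
#' `healthyLike` sets a moderate background correlation with blocks only
#' slightly above it and no hotspot boost — co-expression spread
#' homogeneously along the chromosome. `cancerLike` sets a near-zero
#' background with strong within-band blocks and a boosted hotspot band —
#' the strongest co-expression confined to specific cytobands. Both are
#' thin overrides of [generateDataset()] and honor the config seed.
#'
#' @param cfg a base [syntheticConfig()]; its correlation fields are
#'   replaced by the preset.
#' @return a [CNVCoexDataset-class].
#' @export
healthyLike <- function(cfg = syntheticConfig()) {
    cfg$backgroundCorr <- 0.35
    cfg$blockCorr <- 0.45
    cfg$hotspotCorr <- 0.45
    generateDataset(cfg)
}

#' @rdname healthyLike
#' @export
cancerLike <- function(cfg = syntheticConfig()) {
    cfg$backgroundCorr <- 0.05
    cfg$blockCorr <- 0.5
    cfg$hotspotCorr <- 0.7
    generateDataset(cfg)
}

#' Write a dataset in the pipeline's input formats
#'
#' Emits exactly the files the readers consume — `expression.tsv`,
#' `cnv.tsv`, `genes.bed` (BED4, 0-based half-open), `cytoBand.txt` — plus
#' a `config.json` sidecar recording the full generator configuration.
#'
#' @param ds a [CNVCoexDataset-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeDataset <- function(ds, dir) {
    stopifnot(is(ds, "CNVCoexDataset"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(expression = file.path(dir, "expression.tsv"),
               cnv = file.path(dir, "cnv.tsv"),
               bed = file.path(dir, "genes.bed"),
               cytoband = file.path(dir, "cytoBand.txt"),
               config = file.path(dir, "config.json"))
    writeMatrixTSV(ds@expression, paths[["expression"]])
    writeMatrixTSV(ds@cnv, paths[["cnv"]])
    g <- ds@annotation
    writeLines(sprintf("%s\t%d\t%d\t%s",
                       as.character(GenomicRanges::seqnames(g)),
                       GenomicRanges::start(g) - 1L,
                       GenomicRanges::end(g), names(g)),
               paths[["bed"]])
    writeLines(do.call(sprintf,
                       c(list("%s\t%d\t%d\t%s\t%s"),
                         unname(as.list(ds@cytobands)))),
               paths[["cytoband"]])
    cfg <- ds@config
    cfg$bandLayout <- as.list(cfg$bandLayout)
    jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                         digits = NA)
    invisible(paths)
}
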