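## End-to-end orchestration: simulate (optional) -> layers -> compare ->
## geography, with per-stage outputs under one directory, a manifest of
## file checksums, and resume on unchanged configuration. Each stage reads
## its inputs from files written by the previous one, so running stages
## separately is bit-identical to a single run.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `synthetic` (generator preset and overrides) or `inputs`
#' (paths to expression TSV, CNV TSV, BED and cytoband files) must be
#' given.
#'
#' @param outputDir directory all stages write under.
#' @param synthetic `NULL`, or a list with optional `preset`
#'   (`"default"`, `"healthy_like"`, `"cancer_like"`) and any
#'   [syntheticConfig()] override (`nGenes`, `nSamples`, `coupling`, ...).
#' @param inputs `NULL`, or a list with paths `expression`, `cnv`, `bed`,
#'   `cytoband`.
#' @param cmi estimator settings: `nBins` (`NULL` = `ceiling(N^(1/3))`),
#'   `strategy`, `base`, `zMethod`, `zBins` (see [pairwiseCMI()]), and
#'   `log2p1` applied at expression load.
#' @param truncationK top-k truncation applied to every layer before
#'   comparison; default 3500.
#' @param geographyCutoffs cutoffs for the category-count table; default
#'   `c(100, 500, 1000, 1500)`.
#' @param maxCurveEdges rank range of the growth curves; default 10000.
#' @param alpha KS significance level; default 0.05.
#' @param seed RNG seed (synthetic data only).
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outputDir,
                           synthetic = NULL, inputs = NULL,
                           cmi = list(), truncationK = 3500L,
                           geographyCutoffs = c(100L, 500L, 1000L, 1500L),
                           maxCurveEdges = 10000L, alpha = 0.05,
                           seed = 1L) {
    if (is.null(synthetic) == is.null(inputs))
        stop("exactly one of 'synthetic' or 'inputs' must be specified",
             call. = FALSE)
    if (!is.null(inputs)) {
        need <- c("expression", "cnv", "bed", "cytoband")
        if (!all(need %in% names(inputs)))
            stop("inputs must name files: ",
                 paste(need, collapse = ", "), call. = FALSE)
    }
    if (!is.null(synthetic)) {
        synthetic$preset <- match.arg(
            if (is.null(synthetic$preset)) "default" else synthetic$preset,
            c("default", "healthy_like", "cancer_like"))
    }
    cmiDefaults <- list(nBins = NULL, strategy = "equal_frequency",
                        base = "nats", zMethod = "integer_states",
                        zBins = 3L, log2p1 = FALSE)
    unknown <- setdiff(names(cmi), names(cmiDefaults))
    if (length(unknown))
        stop("unknown cmi setting(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    cmi <- utils::modifyList(cmiDefaults, cmi)
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must be in (0, 1)", call. = FALSE)
    truncationK <- as.integer(truncationK)
    if (truncationK < 1L) stop("truncationK must be >= 1", call. = FALSE)
    geographyCutoffs <- as.integer(geographyCutoffs)
    if (any(geographyCutoffs < 1L) ||
        is.unsorted(geographyCutoffs, strictly = TRUE))
        stop("geographyCutoffs must be positive ascending", call. = FALSE)
    structure(list(outputDir = outputDir, synthetic = synthetic,
                   inputs = inputs, cmi = cmi, truncationK = truncationK,
                   geographyCutoffs = geographyCutoffs,
                   maxCurveEdges = as.integer(maxCurveEdges),
                   alpha = alpha, seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipelineConfig()].
#'
#' @param path YAML file.
#' @return validated `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    known <- setdiff(names(formals(pipelineConfig)), "...")
    unknown <- setdiff(names(y), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    do.call(pipelineConfig, y)
}

.configHash <- function(cfg) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), "outputDir")],
                                auto_unbox = TRUE, digits = NA,
                                null = "null"), tmp)
    unname(tools::md5sum(tmp))
}

.syntheticFromPipeline <- function(cfg) {
    s <- cfg$synthetic
    overrides <- s[setdiff(names(s), "preset")]
    overrides$seed <- cfg$seed
    scfg <- do.call(syntheticConfig, overrides)
    switch(s$preset,
           default = generateDataset(scfg),
           healthy_like = healthyLike(scfg),
           cancer_like = cancerLike(scfg))
}

.inputPaths <- function(cfg) {
    if (!is.null(cfg$inputs)) return(cfg$inputs)
    d <- file.path(cfg$outputDir, "dataset")
    list(expression = file.path(d, "expression.tsv"),
         cnv = file.path(d, "cnv.tsv"),
         bed = file.path(d, "genes.bed"),
         cytoband = file.path(d, "cytoBand.txt"))
}

.requireFiles <- function(paths, stage) {
    miss <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(miss))
        stop(sprintf("stage '%s' requires missing file(s): %s",
                     stage, paste(miss, collapse = ", ")), call. = FALSE)
}

#' Run individual pipeline stages
#'
#' Each stage reads the previous stage's files under the config's output
#' directory and writes its own, so stages can be (re)run independently:
#' `pipelineSimulate` writes the synthetic dataset, `pipelineLayers` the
#' per-conditioning-gene edge lists (skipping layers already on disk from
#' an identical configuration), `pipelineCompare` the D-statistic matrix,
#' long table and summary, and `pipelineGeography` the growth-curve,
#' cutoff-count, degree and hotspot tables for the first (representative)
#' layer.
#'
#' @param cfg a [pipelineConfig()].
#' @return `pipelineSimulate`: the [CNVCoexDataset-class], invisibly;
#'   `pipelineLayers`: the truncated [MultiLayerNetwork-class], invisibly;
#'   `pipelineCompare`: the [DStatMatrix-class], invisibly;
#'   `pipelineGeography`: list of the four tables, invisibly.
#' @export
pipelineSimulate <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    if (is.null(cfg$synthetic))
        stop("stage 'simulate' needs a synthetic configuration", call. = FALSE)
    ds <- .syntheticFromPipeline(cfg)
    writeDataset(ds, file.path(cfg$outputDir, "dataset"))
    invisible(ds)
}

#' @rdname pipelineSimulate
#' @export
pipelineLayers <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    paths <- .inputPaths(cfg)
    .requireFiles(paths, "layers")
    expr <- readExpressionMatrix(paths$expression, log2p1 = cfg$cmi$log2p1)
    cnv <- readCNVMatrix(paths$cnv)
    al <- alignSamples(expr, cnv)
    hash <- .configHash(cfg)
    dir <- file.path(cfg$outputDir, "layers")
    manPath <- file.path(dir, "layers_manifest.tsv")
    if (file.exists(manPath)) {
        man <- utils::read.delim(manPath, colClasses = "character")
        if (all(man$config_hash == hash) &&
            all(file.exists(file.path(dir, man$file))) &&
            setequal(man$conditioning_gene, rownames(al$cnv))) {
            message("pipelineLayers: layers up to date, nothing to do")
            return(invisible(readLayers(dir)))
        }
    }
    net <- buildMultilayer(al$expr, al$cnv,
                           nBins = cfg$cmi$nBins,
                           strategy = cfg$cmi$strategy,
                           base = cfg$cmi$base,
                           zMethod = cfg$cmi$zMethod,
                           zBins = cfg$cmi$zBins,
                           verbose = TRUE)
    net <- truncateTopK(net, cfg$truncationK)
    writeLayers(net, dir, configHash = hash)
    invisible(net)
}

#' @rdname pipelineSimulate
#' @export
pipelineCompare <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir <- file.path(cfg$outputDir, "layers")
    .requireFiles(list(file.path(dir, "layers_manifest.tsv")), "compare")
    net <- readLayers(dir)
    dsm <- compareAllLayers(net, alpha = cfg$alpha)
    out <- file.path(cfg$outputDir, "compare")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    writeDMatrix(dsm, file.path(out, "dmatrix.tsv"))
    dMatrixLongTable(dsm, file.path(out, "dmatrix_long.tsv"))
    .writeTSV(summary(dsm), file.path(out, "ks_summary.tsv"))
    invisible(dsm)
}

#' @rdname pipelineSimulate
#' @export
pipelineGeography <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir <- file.path(cfg$outputDir, "layers")
    paths <- .inputPaths(cfg)
    .requireFiles(c(list(file.path(dir, "layers_manifest.tsv")),
                    paths[c("bed", "cytoband")]), "geography")
    net <- readLayers(dir)
    ann <- readGeneAnnotation(paths$bed, paths$cytoband)
    layer <- net@layers[[1L]]
    out <- file.path(cfg$outputDir, "geography")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    gc <- growthCurves(layer, ann,
                       maxEdges = min(cfg$maxCurveEdges, nrow(layer@edges)))
    long <- data.frame(rank = rep(gc$rank, 3L),
                       category = rep(.edgeCategories, each = nrow(gc)),
                       cumulative_count = c(gc$intra_cytoband,
                                            gc$inter_cytoband,
                                            gc$inter_arm))
    .writeTSV(long, file.path(out, "growth_curves.tsv"))
    cc <- categoryCountsAtCutoffs(layer, ann,
                                  cutoffs = cfg$geographyCutoffs[
                                      cfg$geographyCutoffs <=
                                          nrow(layer@edges)])
    .writeTSV(cc, file.path(out, "cutoff_counts.tsv"))
    dp <- degreeProfile(layer, ann)
    .writeTSV(dp, file.path(out, "degrees.tsv"))
    hs <- cytobandHotspots(layer, ann)
    .writeTSV(hs, file.path(out, "hotspots.tsv"))
    invisible(list(growth = gc, cutoffs = cc, degrees = dp, hotspots = hs))
}

#' Run the full pipeline
#'
#' Runs simulate (synthetic configs only), layers, compare and geography
#' in sequence, then writes `manifest.tsv` (every output file with its
#' MD5 checksum) and `run_info.json` (configuration hash, seed, package
#' version, per-stage timings). Re-running with an unchanged
#' configuration over a completed output directory is a no-op. A failing
#' stage aborts with the stage named; partial outputs are retained.
#'
#' @param cfg a [pipelineConfig()], or the path to a YAML file for
#'   [readPipelineConfig()].
#' @return data.frame manifest (file, md5), invisibly.
#' @export
runPipeline <- function(cfg) {
    if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
    stopifnot(inherits(cfg, "PipelineConfig"))
    hash <- .configHash(cfg)
    infoPath <- file.path(cfg$outputDir, "run_info.json")
    manPath <- file.path(cfg$outputDir, "manifest.tsv")
    if (file.exists(infoPath) && file.exists(manPath)) {
        info <- jsonlite::read_json(infoPath)
        man <- utils::read.delim(manPath, colClasses = "character")
        if (identical(info$config_hash, hash) &&
            all(file.exists(file.path(cfg$outputDir, man$file)))) {
            message("runPipeline: outputs up to date, nothing to do")
            return(invisible(man))
        }
    }
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    stages <- c(if (!is.null(cfg$synthetic)) "simulate",
                "layers", "compare", "geography")
    fns <- list(simulate = pipelineSimulate, layers = pipelineLayers,
                compare = pipelineCompare, geography = pipelineGeography)
    timings <- numeric(0)
    for (st in stages) {
        t0 <- proc.time()[["elapsed"]]
        tryCatch(fns[[st]](cfg), error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s",
                         st, conditionMessage(e)), call. = FALSE))
        timings[st] <- round(proc.time()[["elapsed"]] - t0, 3)
    }
    files <- list.files(cfg$outputDir, recursive = TRUE)
    files <- setdiff(files, c("manifest.tsv", "run_info.json"))
    man <- data.frame(file = files,
                      md5 = unname(tools::md5sum(
                          file.path(cfg$outputDir, files))))
    utils::write.table(man, manPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
        list(config_hash = hash, seed = cfg$seed,
             package_version = as.character(utils::packageVersion("cnvcoex")),
             stage_seconds = as.list(timings)),
        infoPath, auto_unbox = TRUE, digits = NA)
    invisible(man)
}
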