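#' Default run configuration
#'
#' All tunables of the pipeline with their defaults; the effective
#' configuration is echoed verbatim into every run report so a run is
#' reproducible from its report alone.
#'
#' @param ... overrides for any field.
#' @return named list: \code{alpha} (0.05), \code{norm} ("L2"),
#'   \code{dist} ("normal"), \code{resampler} ("jackknife"), \code{nBoot}
#'   (200), \code{recomputeScores} (TRUE), \code{rcondThreshold} (1e-10),
#'   \code{maxMissing} (0.2), \code{sides} (1), \code{K} (4), \code{E}
#'   (5), \code{seed} (1).
#' @export
placaConfig <- function(...) {
    cfg <- list(alpha = 0.05, norm = "L2", dist = "normal",
        resampler = "jackknife", nBoot = 200L, recomputeScores = TRUE,
        rcondThreshold = 1e-10, maxMissing = 0.2, sides = 1,
        K = 4L, E = 5L, seed = 1L)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
}

#' Run inference on one experiment and write all artifacts
#'
#' Loads the expression + panel tables (or takes a ready
#' \linkS4class{PerturbationExperiment}), runs the full pipeline
#' ([inferNetwork()]), and writes the edge TSV, the SIF export, and a JSON
#' run report capturing the configuration, seeds, per-stage summaries and
#' any unresolvable pairs.
#'
#' @param expression path to the expression table, or a
#'   \linkS4class{PerturbationExperiment}.
#' @param panel path to the panel table (ignored when \code{expression} is
#'   already a dataset).
#' @param outDir output directory (created if needed).
#' @param layout expression table layout, see [readExpressionTable()].
#' @param config a [placaConfig()] list.
#' @param prefix file-name prefix for the artifacts.
#' @return invisibly, a list with the \linkS4class{EdgeSet}, the dataset
#'   and the written paths.
#' @export
runInference <- function(expression, panel = NULL, outDir = ".",
        layout = "replicates", config = placaConfig(), prefix = "placa") {
    pe <- if (is(expression, "PerturbationExperiment")) expression
        else readExpressionTable(expression, panel, layout = layout)
    edges <- inferNetwork(pe, alpha = config$alpha, norm = config$norm,
        dist = config$dist, resampler = config$resampler,
        nBoot = config$nBoot, recomputeScores = config$recomputeScores,
        rcondThreshold = config$rcondThreshold,
        maxMissing = config$maxMissing, sides = config$sides)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(outDir, paste0(prefix,
        c("_edges.tsv", ".sif", "_report.json")))
    writeEdgeTable(edges, paths[1], pe = pe)
    writeSIF(edges, paths[2])
    tab <- edgeTable(edges)
    report <- list(
        config = config,
        input = if (is.character(expression)) expression else "in-memory",
        nGenes = nrow(pe),
        components = componentNames(edges),
        nResamples = edges@params$nResamples,
        nSignificant = sum(tab$significant),
        unresolvablePairs = tab[tab$unresolvable, c("source", "target")],
        seed = S4Vectors::metadata(pe)$seed)
    jsonlite::write_json(report, paths[3], auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(list(edges = edges, dataset = pe, paths = paths))
}

#' Combine per-experiment edge lists into a consensus network
#'
#' @param edgeSets list of \linkS4class{EdgeSet}s, or character paths to
#'   edge TSVs written by [writeEdgeTable()] (then \code{components} is
#'   required).
#' @param K minimum supporting experiments.
#' @param outDir,prefix where to write the consensus TSV/SIF and report;
#'   no files are written when \code{outDir} is NULL.
#' @param components component panel for file input.
#' @return the \linkS4class{ConsensusNetwork} (invisibly when writing).
#' @export
runConsensus <- function(edgeSets, K, outDir = NULL, prefix = "consensus",
        components = NULL) {
    if (is.character(edgeSets)) {
        if (is.null(components))
            stop("components must be given when reading edge lists from files")
        edgeSets <- lapply(edgeSets, readEdgeTable, components = components)
    }
    if (length(edgeSets) < 2L)
        stop("consensus needs at least 2 edge sets")
    cons <- consensusNetwork(edgeSets, K = K)
    if (is.null(outDir)) return(cons)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(outDir, paste0(prefix,
        c("_edges.tsv", ".sif", "_report.json")))
    writeEdgeTable(cons, paths[1])
    writeSIF(cons, paths[2])
    jsonlite::write_json(list(
        K = cons@K, E = cons@E, components = cons@components,
        nEdges = nrow(edgeTable(cons)),
        dropped = cons@dropped), paths[3], auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(cons)
}
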