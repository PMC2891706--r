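#' Write an edge list as TSV
#'
#' Columns: source, target, sign, mean_coeff, sd_coeff, zratio,
#' significant, support_count (consensus input only; NA otherwise) and
#' top_genes (the leading supporting genes per edge, comma-separated, when
#' a dataset is supplied).
#'
#' @param x an \linkS4class{EdgeSet} or \linkS4class{ConsensusNetwork}.
#' @param path output TSV path.
#' @param pe optional \linkS4class{PerturbationExperiment}; when given (for
#'   an EdgeSet), the \code{nTop} leading genes from [geneContributions()]
#'   are listed per edge.
#' @param nTop number of supporting genes to list (default 3).
#' @param significantOnly for an EdgeSet, write only sign-consistent edges
#'   (default TRUE).
#' @return invisibly, the written data.frame.
#' @export
writeEdgeTable <- function(x, path, pe = NULL, nTop = 3L,
        significantOnly = TRUE) {
    if (is(x, "ConsensusNetwork")) {
        tab <- x@table
        out <- data.frame(
            source = tab$source, target = tab$target, sign = tab$sign,
            mean_coeff = if (nrow(tab)) rowMeans(x@perExperiment,
                na.rm = TRUE) else numeric(0),
            sd_coeff = NA_real_, zratio = NA_real_,
            significant = rep(TRUE, nrow(tab)),
            support_count = tab$support,
            stringsAsFactors = FALSE)
    } else if (is(x, "EdgeSet")) {
        tab <- if (significantOnly) significantEdges(x) else edgeTable(x)
        out <- data.frame(
            source = tab$source, target = tab$target, sign = tab$sign,
            mean_coeff = tab$mean, sd_coeff = tab$sd, zratio = tab$zratio,
            significant = tab$significant,
            support_count = NA_integer_,
            stringsAsFactors = FALSE)
    } else stop("unsupported object: ", class(x)[1])
    if (!is.null(pe) && nrow(out)) {
        scoresFull <- scoreGenes(pe)
        out$top_genes <- vapply(seq_len(nrow(out)), function(k) {
            gc <- geneContributions(pe, out$source[k], out$target[k],
                scores = scoresFull)
            paste(gc$gene[seq_len(min(nTop, nrow(gc)))], collapse = ",")
        }, character(1))
    } else out$top_genes <- rep(NA_character_, nrow(out))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out)
}

#' Write a network in SIF format
#'
#' One line per edge: \code{source relation target}, with relation
#' \code{functional-activation} or \code{functional-inhibition} (functional
#' interactions: the two components affect a shared gene set, not
#' necessarily each other biochemically).
#'
#' @inheritParams writeEdgeTable
#' @return invisibly, the written lines.
#' @export
writeSIF <- function(x, path, significantOnly = TRUE) {
    tab <- if (is(x, "ConsensusNetwork")) edgeTable(x)
        else if (significantOnly) significantEdges(x) else edgeTable(x)
    rel <- ifelse(tab$sign > 0, "functional-activation",
        "functional-inhibition")
    lines <- sprintf("%s\t%s\t%s", tab$source, rel, tab$target)
    writeLines(lines, path)
    invisible(lines)
}

#' Read an edge table written by [writeEdgeTable()]
#'
#' Reconstructs a minimal \linkS4class{EdgeSet} (statistics only, no raw
#' resamples) so edge lists from independent experiments can be combined
#' with [consensusNetwork()] without re-running inference.
#'
#' @param path TSV path.
#' @param components the full component panel (needed because a written
#'   table may only contain the significant pairs).
#' @param alpha,sides the filter settings the table was produced with.
#' @return an \linkS4class{EdgeSet}.
#' @export
readEdgeTable <- function(path, components, alpha = 0.05, sides = 1) {
    raw <- read.table(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE)
    n <- length(components)
    pairs <- which(diag(n) == 0, arr.ind = TRUE)
    tab <- data.frame(
        source = components[pairs[, 2]], target = components[pairs[, 1]],
        mean = 0, sd = NA_real_, zratio = NA_real_, sign = 0,
        significant = FALSE, fracMissing = 0, unresolvable = FALSE,
        stringsAsFactors = FALSE)
    key <- paste(tab$source, tab$target)
    hit <- match(paste(raw$source, raw$target), key)
    if (any(is.na(hit)))
        stop("edge table contains components outside the given panel")
    tab$mean[hit] <- raw$mean_coeff
    tab$sd[hit] <- raw$sd_coeff
    tab$zratio[hit] <- raw$zratio
    tab$sign[hit] <- raw$sign
    tab$significant[hit] <- as.logical(raw$significant)
    new("EdgeSet", components = as.character(components),
        samples = array(NA_real_, c(1, n, n),
            dimnames = list(NULL, components, components)),
        table = tab, alpha = alpha, sides = sides,
        params = list(resampler = "file", nResamples = 0L))
}
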