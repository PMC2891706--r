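#' Construct a perturbation expression dataset from condition summaries
#'
#' Assembles the genes x conditions replicate summaries (arithmetic mean,
#' log-mean, log-SE, replicate count) plus the perturbation panel into the
#' container every downstream step consumes. The baseline condition must be
#' one of the columns; the remaining columns map, in order, onto the panel's
#' components.
#'
#' @param activity,logActivity,logSE,nRep genes x conditions numeric
#'   matrices, identical dimnames; \code{activity} strictly positive,
#'   \code{logSE} non-negative, \code{nRep} >= 2.
#' @param panel a [PerturbationPanel] with one component per non-baseline
#'   column.
#' @param baseline name (or index) of the baseline column.
#' @return a \linkS4class{PerturbationExperiment}.
#' @seealso [readExpressionTable()] to load from files,
#'   [summarizeReplicates()] for the per-condition summary,
#'   [simulateExperiment()] to generate one from a known network.
#' @export
PerturbationExperiment <- function(activity, logActivity, logSE, nRep,
        panel, baseline = "baseline") {
    activity <- as.matrix(activity)
    if (is.character(baseline)) {
        b <- match(baseline, colnames(activity))
        if (is.na(b))
            stop("baseline condition '", baseline, "' not found")
    } else b <- as.integer(baseline)
    nc <- ncol(activity)
    if (nc != length(panel) + 1L)
        stop("need exactly one condition per panel component plus a baseline (",
            length(panel) + 1L, " columns, got ", nc, ")")
    role <- rep("perturbation", nc)
    role[b] <- "baseline"
    comp <- sign <- lab <- rep(NA, nc)
    comp[-b] <- componentNames(panel)
    sign[-b] <- panel@sign
    lab[-b] <- panel@label
    cd <- S4Vectors::DataFrame(
        condition = colnames(activity),
        role = role,
        component = as.character(comp),
        sign = as.integer(ifelse(is.na(sign), 0L, sign)),
        label = as.character(lab),
        row.names = colnames(activity))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(
            activity = activity,
            logActivity = as.matrix(logActivity),
            logSE = as.matrix(logSE),
            nRep = as.matrix(nRep)),
        colData = cd)
    new("PerturbationExperiment", se)
}

#' Construct a dataset from raw replicate values
#'
#' @param replicates named list with one element per condition (baseline
#'   included), each a genes x replicates matrix of strictly positive raw
#'   activities (>= 2 replicates). All elements must share row names.
#' @inheritParams PerturbationExperiment
#' @return a \linkS4class{PerturbationExperiment}.
#' @export
perturbationExperimentFromReplicates <- function(replicates, panel,
        baseline = "baseline") {
    if (is.null(names(replicates)))
        stop("replicates must be a named list, one element per condition")
    genes <- rownames(replicates[[1]])
    if (is.null(genes))
        stop("replicate matrices must have gene rownames")
    summ <- lapply(names(replicates), function(cond) {
        mat <- as.matrix(replicates[[cond]])
        if (!identical(rownames(mat), genes))
            stop("gene panel mismatch across conditions (condition '",
                cond, "')")
        t(vapply(seq_len(nrow(mat)),
            function(i) summarizeReplicates(mat[i, ]),
            numeric(4)))
    })
    pull <- function(j) {
        out <- vapply(summ, function(s) s[, j], numeric(length(genes)))
        dimnames(out) <- list(genes, names(replicates))
        out
    }
    PerturbationExperiment(
        activity = pull(1), logActivity = pull(2),
        logSE = pull(3), nRep = pull(4),
        panel = panel, baseline = baseline)
}

#' @rdname PerturbationExperiment-class
#' @param x a \linkS4class{PerturbationExperiment}.
#' @export
setMethod("perturbationPanel", "PerturbationExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    p <- cd[cd$role == "perturbation", ]
    PerturbationPanel(p$component, p$sign, p$label)
})

#' Genes measured in a dataset
#' @param x a \linkS4class{PerturbationExperiment}.
#' @return character vector of gene identifiers.
#' @export
geneNames <- function(x) rownames(x)

#' Index of the baseline condition
#' @param x a \linkS4class{PerturbationExperiment}.
#' @return integer column index of the unperturbed condition.
#' @export
baselineIndex <- function(x)
    which(SummarizedExperiment::colData(x)$role == "baseline")

## Internal: unpack a PerturbationExperiment into the plain matrices the
## scoring math uses. Perturbation rows are ordered as in the panel.
## A, LogA, dA: length m (genes); G, LogG, dG: n x m.
.placaData <- function(pe) {
    b <- baselineIndex(pe)
    cd <- SummarizedExperiment::colData(pe)
    act <- SummarizedExperiment::assay(pe, "activity")
    la <- SummarizedExperiment::assay(pe, "logActivity")
    se <- SummarizedExperiment::assay(pe, "logSE")
    nr <- SummarizedExperiment::assay(pe, "nRep")
    pidx <- which(cd$role == "perturbation")
    list(
        genes = rownames(pe),
        components = cd$component[pidx],
        s = cd$sign[pidx],
        A = act[, b], LogA = la[, b], dA = se[, b], nA = nr[, b],
        G = t(act[, pidx, drop = FALSE]),
        LogG = t(la[, pidx, drop = FALSE]),
        dG = t(se[, pidx, drop = FALSE]),
        nG = t(nr[, pidx, drop = FALSE]))
}

setMethod("show", "PerturbationExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    n <- sum(cd$role == "perturbation")
    cat("PerturbationExperiment:", nrow(object), "early genes,",
        n, "perturbations + baseline\n")
    cat("  components:",
        paste(cd$component[cd$role == "perturbation"], collapse = ", "), "\n")
    cat("  replicates:",
        paste(range(SummarizedExperiment::assay(object, "nRep")),
            collapse = "-"), "per measurement\n")
})
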