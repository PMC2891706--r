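.sepFor <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a perturbation panel table
#'
#' The panel table is TSV/CSV with columns \code{condition},
#' \code{component}, \code{sign} and optionally \code{label}. Exactly one
#' row -- the baseline -- has sign 0 (or an empty component); every other
#' row names the component its condition perturbs and the direction
#' (-1 inhibition, +1 activation).
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when NULL
#'   (.csv = comma, otherwise tab). Decimal separator is always the period.
#' @return list with elements \code{panel} (a [PerturbationPanel]),
#'   \code{baseline} (baseline condition name) and \code{conditions}
#'   (condition name per component, panel order).
#' @export
readPerturbationPanel <- function(path, sep = NULL) {
    tab <- read.table(path, header = TRUE, sep = .sepFor(path, sep),
        stringsAsFactors = FALSE, check.names = TRUE)
    need <- c("condition", "component", "sign")
    if (!all(need %in% colnames(tab)))
        stop("panel table must have columns: ", paste(need, collapse = ", "))
    if (is.null(tab$label)) tab$label <- tab$component
    isBase <- tab$sign == 0 | is.na(tab$component) | tab$component == ""
    if (sum(isBase) != 1L)
        stop("missing baseline condition: the panel needs exactly one row ",
            "with sign 0 / empty component (found ", sum(isBase), ")")
    pert <- tab[!isBase, , drop = FALSE]
    list(
        panel = PerturbationPanel(pert$component, pert$sign, pert$label),
        baseline = tab$condition[isBase],
        conditions = pert$condition)
}

#' Read an early-gene expression table
#'
#' Loads a genes-in-rows TSV/CSV expression table together with its
#' perturbation panel and returns a validated
#' \linkS4class{PerturbationExperiment}. Two layouts are supported:
#' \describe{
#'   \item{\code{"replicates"}}{a \code{gene} column followed by one column
#'     per replicate, the header repeating the condition name; raw positive
#'     activities, >= 2 replicates per condition, summarized via
#'     [summarizeReplicates()].}
#'   \item{\code{"summaries"}}{four columns per condition, named
#'     \code{<condition>.mean}, \code{<condition>.logMean},
#'     \code{<condition>.logSD} and \code{<condition>.n}; the log-SD is the
#'     sample SD of log activities and is converted to a standard error
#'     using \code{n}.}
#' }
#'
#' @param path expression table path.
#' @param panel path to the panel table (see [readPerturbationPanel()]), or
#'   the list that function returns.
#' @param layout \code{"replicates"} or \code{"summaries"}.
#' @param sep field separator; inferred from the extension when NULL.
#' @return a \linkS4class{PerturbationExperiment}.
#' @export
readExpressionTable <- function(path, panel,
        layout = c("replicates", "summaries"), sep = NULL) {
    layout <- match.arg(layout)
    if (is.character(panel)) panel <- readPerturbationPanel(panel)
    tab <- read.table(path, header = TRUE, sep = .sepFor(path, sep),
        stringsAsFactors = FALSE, check.names = FALSE)
    if (!"gene" %in% colnames(tab)[1])
        stop("first column of the expression table must be 'gene'")
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes)) stop("duplicate gene identifiers")
    ## keep the raw header: [.data.frame would repair duplicated names
    cn <- colnames(tab)[-1]
    tab <- tab[, -1, drop = FALSE]
    conds <- c(panel$baseline, panel$conditions)
    if (layout == "replicates") {
        missing <- setdiff(conds, unique(cn))
        if (length(missing))
            stop("conditions missing from the expression table: ",
                paste(missing, collapse = ", "))
        reps <- lapply(conds, function(cond) {
            mat <- as.matrix(tab[, cn == cond, drop = FALSE])
            if (ncol(mat) < 2L)
                stop("replicate count < 2 for condition '", cond, "'")
            rownames(mat) <- genes
            mat
        })
        names(reps) <- conds
        pe <- perturbationExperimentFromReplicates(reps, panel$panel,
            baseline = panel$baseline)
    } else {
        grab <- function(suffix) {
            cols <- paste0(conds, ".", suffix)
            missing <- setdiff(cols, colnames(tab))
            if (length(missing))
                stop("summary columns missing: ",
                    paste(missing, collapse = ", "))
            mat <- as.matrix(tab[, cols, drop = FALSE])
            dimnames(mat) <- list(genes, conds)
            mat
        }
        meanMat <- grab("mean")
        logMean <- grab("logMean")
        logSD <- grab("logSD")
        nMat <- grab("n")
        if (any(meanMat <= 0))
            stop("non-positive activity in the expression table")
        pe <- PerturbationExperiment(
            activity = meanMat, logActivity = logMean,
            logSE = logSD / sqrt(nMat), nRep = nMat,
            panel = panel$panel, baseline = panel$baseline)
    }
    ## condition columns ordered baseline-first to match the panel
    pe
}

#' Write an expression dataset (and companion panel) to disk
#'
#' The summaries layout is always available; the replicates layout needs
#' the raw replicate draws, which simulated datasets carry in their
#' metadata. Files written here round-trip through [readExpressionTable()].
#'
#' @param pe a \linkS4class{PerturbationExperiment}.
#' @param path expression table destination.
#' @param panelPath optional destination for the companion panel table.
#' @param layout \code{"summaries"} or \code{"replicates"}.
#' @param sep field separator; inferred from the extension when NULL.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTable <- function(pe, path, panelPath = NULL,
        layout = c("summaries", "replicates"), sep = NULL) {
    layout <- match.arg(layout)
    sep <- .sepFor(path, sep)
    cd <- SummarizedExperiment::colData(pe)
    conds <- cd$condition
    if (layout == "summaries") {
        nMat <- SummarizedExperiment::assay(pe, "nRep")
        blocks <- lapply(seq_along(conds), function(j) {
            out <- data.frame(
                SummarizedExperiment::assay(pe, "activity")[, j],
                SummarizedExperiment::assay(pe, "logActivity")[, j],
                SummarizedExperiment::assay(pe, "logSE")[, j] *
                    sqrt(nMat[, j]),
                nMat[, j])
            colnames(out) <- paste0(conds[j],
                c(".mean", ".logMean", ".logSD", ".n"))
            out
        })
        tab <- cbind(data.frame(gene = rownames(pe)), do.call(cbind, blocks))
    } else {
        reps <- S4Vectors::metadata(pe)$replicates
        if (is.null(reps))
            stop("no raw replicates stored in this dataset; ",
                "use layout = 'summaries'")
        mats <- lapply(conds, function(cond) as.matrix(reps[[cond]]))
        wide <- do.call(cbind, mats)
        colnames(wide) <- rep(conds, vapply(mats, ncol, 1L))
        tab <- data.frame(gene = rownames(pe), wide, check.names = FALSE)
    }
    write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
    if (!is.null(panelPath)) {
        ptab <- data.frame(
            condition = conds,
            component = ifelse(cd$role == "baseline", "", cd$component),
            sign = cd$sign,
            label = ifelse(cd$role == "baseline", "none", cd$label))
        write.table(ptab, panelPath, sep = .sepFor(panelPath, NULL),
            quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}
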