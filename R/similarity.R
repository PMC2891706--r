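## Status (-1 / 0 / +1) and coefficient per ordered pair, from any of the
## network representations the package produces.
.pairStatus <- function(x, comps) {
    n <- length(comps)
    status <- matrix(0, n, n, dimnames = list(comps, comps))
    coef <- status
    fill <- function(tab, coefCol) {
        for (k in seq_len(nrow(tab))) {
            i <- match(tab$target[k], comps)
            j <- match(tab$source[k], comps)
            status[i, j] <<- tab$sign[k]
            coef[i, j] <<- if (!is.null(coefCol)) tab[[coefCol]][k] else
                tab$sign[k]
        }
    }
    if (is(x, "ConsensusNetwork")) {
        tab <- x@table
        if (nrow(tab)) {
            tab$meanCoef <- rowMeans(x@perExperiment, na.rm = TRUE)
            fill(tab, "meanCoef")
        }
    } else if (is(x, "EdgeSet")) {
        fill(significantEdges(x), "mean")
    } else if (is(x, "SyntheticModel")) {
        r <- x@interactions
        status <- sign(r); diag(status) <- 0
        coef <- r; diag(coef) <- 0
    } else if (is(x, "InteractionMatrix") || is.matrix(x)) {
        r <- if (is.matrix(x)) x else x@coefficients
        status <- sign(r); diag(status) <- 0
        coef <- r; diag(coef) <- 0
    } else stop("unsupported network representation: ", class(x)[1])
    list(status = status, coef = coef)
}

#' Similarity between an inferred network and the generating truth
#'
#' Each ordered component pair has a status: absent, positive, or negative.
#' The sign score is the fraction of the n(n-1) ordered pairs whose
#' inferred status matches the truth (so both correctly detected edges and
#' correctly absent edges count). The value score is the Pearson
#' correlation between inferred and true coefficient values over the pairs
#' where the truth has an edge (an undetected true edge contributes an
#' inferred value of 0); it is NA when fewer than 3 true edges exist or a
#' side is constant.
#'
#' @param inferred a \linkS4class{ConsensusNetwork}, \linkS4class{EdgeSet}
#'   (its significant edges), \linkS4class{InteractionMatrix}, or a signed
#'   numeric matrix.
#' @param truth a \linkS4class{SyntheticModel} (or any representation
#'   above).
#' @param ... unused.
#' @return a \linkS4class{SimilarityReport}.
#' @export
setMethod("networkSimilarity", signature("ANY", "ANY"),
    function(inferred, truth, ...) {
    comps <- if (is(truth, "SyntheticModel")) truth@components
        else if (is(inferred, "ConsensusNetwork") || is(inferred, "EdgeSet"))
            componentNames(inferred)
        else rownames(.pairStatus(truth, NULL)$status)
    inf <- .pairStatus(inferred, comps)
    tru <- .pairStatus(truth, comps)
    off <- row(tru$status) != col(tru$status)
    signScore <- mean(inf$status[off] == tru$status[off])
    present <- off & tru$status != 0
    valueScore <- NA_real_
    if (sum(present) >= 3 &&
        sd(tru$coef[present]) > 0 && sd(inf$coef[present]) > 0)
        valueScore <- cor(inf$coef[present], tru$coef[present])
    n <- length(comps)
    idx <- which(off, arr.ind = TRUE)
    tab <- data.frame(
        source = comps[idx[, 2]], target = comps[idx[, 1]],
        trueStatus = tru$status[off], inferredStatus = inf$status[off],
        match = inf$status[off] == tru$status[off],
        stringsAsFactors = FALSE)
    new("SimilarityReport", signScore = signScore, valueScore = valueScore,
        table = tab)
})

#' @rdname networkSimilarity
#' @param x a \linkS4class{SimilarityReport}.
#' @export
signScore <- function(x) {
    stopifnot(is(x, "SimilarityReport"))
    x@signScore
}

#' @rdname networkSimilarity
#' @export
valueScore <- function(x) {
    stopifnot(is(x, "SimilarityReport"))
    x@valueScore
}

setMethod("show", "SimilarityReport", function(object) {
    cat(sprintf("SimilarityReport: sign score %.3f (%d/%d pairs), value score %s\n",
        object@signScore, sum(object@table$match), nrow(object@table),
        ifelse(is.na(object@valueScore), "NA",
            sprintf("%.3f", object@valueScore))))
})
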