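#' Per-gene contributions to an inferred interaction
#'
#' The response of target component j to the perturbation of source
#' component i is the weighted sum \code{R[j, i] = sum_k W[j, k] *
#' (G[i, k] - A[k])}; each term \code{c_k = W[j, k] * (G[i, k] - A[k])} is
#' the contribution of gene k to the evidence for the i -> j interaction.
#' The terms partition R[j, i] exactly, so ranking them identifies the
#' genes that detect the functional interaction -- the natural candidates
#' for follow-up validation experiments. Genes are ranked with those
#' supporting the observed response direction first (contribution times the
#' sign of R[j, i], descending); e.g. after an inhibitory perturbation of
#' the source, a positive leading term marks a gene reporting functional
#' inhibition of the target by the source.
#'
#' @param pe a \linkS4class{PerturbationExperiment}.
#' @param source,target component names (or indices), source != target.
#' @param scores optional \linkS4class{ScoreSet}; defaults recomputed when
#'   NULL.
#' @return data.frame with columns \code{gene}, \code{contribution},
#'   ordered as described; the attribute \code{"response"} holds the
#'   response-matrix entry \code{R[target, source]} the terms sum to.
#' @export
geneContributions <- function(pe, source, target, scores = NULL) {
    if (is.null(scores)) scores <- scoreGenes(pe)
    d <- .placaData(pe)
    comps <- d$components
    resolve <- function(x, what) {
        if (is.character(x)) {
            idx <- match(x, comps)
            if (is.na(idx)) stop("unknown component name: ", x)
            idx
        } else as.integer(x)
    }
    i <- resolve(source)
    j <- resolve(target)
    if (i == j) stop("source and target must differ")
    contrib <- scores@W[j, ] * (d$G[i, ] - d$A)
    resp <- sum(contrib)
    dir <- if (resp != 0) sign(resp) else 1
    ord <- order(dir * contrib, decreasing = TRUE)
    out <- data.frame(gene = d$genes[ord], contribution = unname(contrib[ord]),
        stringsAsFactors = FALSE)
    attr(out, "response") <- resp
    out
}
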