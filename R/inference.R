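#' Estimate signaling-component activities from gene weights
#'
#' The estimated activity of component i after perturbation j is the
#' weighted sum of the gene activities, \code{S = W %*% t(G)} (so
#' \code{S[i, j] = sum_k W[i, k] * G[j, k]}); the unperturbed estimate is
#' \code{S0[i] = sum_k W[i, k] * A[k]}. Their difference, column-wise, is
#' the global response matrix R handed to [mra()]. Note the estimates carry
#' an unknown per-component scale (each gene contributes through an unknown
#' proportionality constant), which is why downstream inference only trusts
#' the response *pattern* and, after resampling, the coefficient signs.
#'
#' @param pe a \linkS4class{PerturbationExperiment}.
#' @param scores a \linkS4class{ScoreSet} from [scoreGenes()]; computed with
#'   defaults when NULL.
#' @return an \linkS4class{ActivityEstimate}.
#' @export
estimateActivity <- function(pe, scores = NULL) {
    if (is.null(scores)) scores <- scoreGenes(pe)
    d <- .placaData(pe)
    if (!identical(scores@genes, d$genes))
        stop("score set and dataset disagree on the gene panel")
    W <- scores@W
    S <- W %*% t(d$G)
    S0 <- drop(W %*% d$A)
    R <- S - S0
    dimnames(S) <- dimnames(R) <- list(d$components, d$components)
    new("ActivityEstimate", S = S, S0 = setNames(S0, d$components), R = R,
        components = d$components)
}

#' @rdname ActivityEstimate-class
#' @param x an \linkS4class{ActivityEstimate}.
#' @export
setMethod("responseMatrix", "ActivityEstimate", function(x) x@R)

#' @rdname ActivityEstimate-class
#' @export
activityMatrix <- function(x) {
    stopifnot(is(x, "ActivityEstimate"))
    x@S
}

#' @rdname ActivityEstimate-class
#' @export
baselineActivity <- function(x) {
    stopifnot(is(x, "ActivityEstimate"))
    x@S0
}

setMethod("show", "ActivityEstimate", function(object) {
    cat("ActivityEstimate for", length(object@components), "components\n")
    cat("  response matrix R (components x perturbations):\n")
    print(signif(object@R, 4))
})

## Plain-matrix MRA core shared by the S4 method and the resampling loop.
.mraCore <- function(R, rcondThreshold = 1e-10) {
    if (nrow(R) != ncol(R)) stop("R must be square")
    rc <- rcond(R)
    if (!is.finite(rc) || rc < rcondThreshold)
        stop(sprintf(paste0("response matrix is singular or ill-conditioned ",
            "(reciprocal condition number %.3g < %.3g); MRA would amplify ",
            "noise without bound"), rc, rcondThreshold))
    Rinv <- solve(R)
    dg <- diag(Rinv)
    if (any(dg == 0))
        stop("zero diagonal entry in R^-1; local coefficients are undefined")
    r <- -Rinv / dg  # row i scaled by 1/Rinv[i,i]
    diag(r) <- -1
    r
}

#' @rdname mra
#' @export
setMethod("mra", "matrix", function(R, rcondThreshold = 1e-10, ...) {
    r <- .mraCore(R, rcondThreshold)
    comps <- rownames(R)
    if (is.null(comps)) comps <- paste0("S", seq_len(nrow(R)))
    dimnames(r) <- list(comps, comps)
    new("InteractionMatrix", coefficients = r, components = comps)
})

#' @rdname mra
#' @export
setMethod("mra", "ActivityEstimate", function(R, ...) {
    mra(R@R, ...)
})

#' @rdname mra
#' @export
setMethod("mra", "PerturbationExperiment", function(R, scores = NULL, ...) {
    mra(estimateActivity(R, scores), ...)
})

#' @rdname InteractionMatrix-class
#' @param x an \linkS4class{InteractionMatrix}.
#' @export
setMethod("interactionCoefficients", "InteractionMatrix",
    function(x) x@coefficients)

setMethod("show", "InteractionMatrix", function(object) {
    cat("InteractionMatrix (local MRA coefficients, diag -1):\n")
    print(signif(object@coefficients, 4))
})
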