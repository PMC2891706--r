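#' @rdname PerturbationPanel-class
#' @param x,object an object.
#' @param ... further arguments.
#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))

#' @rdname PerturbationPanel-class
#' @export
setGeneric("perturbationSigns", function(x) standardGeneric("perturbationSigns"))

#' @rdname PerturbationPanel-class
#' @export
setGeneric("perturbationLabels",
    function(x) standardGeneric("perturbationLabels"))

#' @rdname PerturbationExperiment-class
#' @export
setGeneric("perturbationPanel",
    function(x) standardGeneric("perturbationPanel"))

#' @rdname ScoreSet-class
#' @export
setGeneric("weightMatrix", function(x, ...) standardGeneric("weightMatrix"))

#' @rdname ActivityEstimate-class
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' @rdname InteractionMatrix-class
#' @export
setGeneric("interactionCoefficients",
    function(x) standardGeneric("interactionCoefficients"))

#' Invert a global response matrix into local interaction coefficients
#'
#' Modular response analysis (MRA): given the global response matrix R
#' (change in the steady-state activity of component i after a perturbation
#' of component j), the local interaction coefficients are
#' \code{r = -[dg(R^-1)]^-1 R^-1}, where dg() keeps the diagonal. The
#' normalization forces \code{diag(r) = -1}; the off-diagonal \code{r[i, j]}
#' is the direct effect of component j on component i, with all other
#' components held fixed. Exact for linear systems near steady state.
#'
#' @param R an n x n response matrix, an [ActivityEstimate], or a numeric
#'   matrix.
#' @param ... passed on to methods.
#' @param rcondThreshold refuse inversion when the reciprocal condition
#'   number of R falls below this (default 1e-10): MRA amplifies noise
#'   through the inverse, so a near-singular R yields meaningless
#'   coefficients.
#' @return an [InteractionMatrix].
#' @examples
#' r <- rbind(c(-1, .5, 0), c(.3, -1, 0), c(0, -.4, -1))
#' R <- -solve(r) %*% diag(c(1.2, .8, 1))
#' interactionCoefficients(mra(R))  # recovers r
#' @export
setGeneric("mra", function(R, ...) standardGeneric("mra"))

#' @rdname networkSimilarity
#' @export
setGeneric("networkSimilarity",
    function(inferred, truth, ...) standardGeneric("networkSimilarity"))

#' @rdname EdgeSet-class
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))

#' @rdname EdgeSet-class
#' @export
setGeneric("significantEdges",
    function(x, ...) standardGeneric("significantEdges"))
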