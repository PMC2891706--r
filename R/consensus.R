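#' Consensus network across independent experiments
#'
#' Post-processing across E independent experiments: an ordered component
#' pair is retained only when it is significant *with the same sign* in at
#' least K of the E edge sets. This majority filter trades a little
#' sensitivity for a large drop in false interactions. A pair whose two
#' signs both reach K (possible only when K <= E/2) is contradictory: it is
#' dropped and reported in the \code{dropped} slot.
#'
#' @param edgeSets list of \linkS4class{EdgeSet}s over the same component
#'   panel (>= 2).
#' @param K minimum number of supporting experiments, \code{1 <= K <= E}.
#' @return a \linkS4class{ConsensusNetwork}.
#' @examples
#' ## typical use: five independent experiments, majority-plus-one support
#' ## consensusNetwork(list(e1, e2, e3, e4, e5), K = 4)
#' @export
consensusNetwork <- function(edgeSets, K) {
    E <- length(edgeSets)
    if (E < 1L) stop("need at least one edge set")
    K <- as.integer(K)
    if (K < 1L || K > E)
        stop("K must satisfy 1 <= K <= E (got K = ", K, ", E = ", E, ")")
    comps <- componentNames(edgeSets[[1]])
    for (es in edgeSets)
        if (!identical(componentNames(es), comps))
            stop("edge sets disagree on the component panel")
    key <- function(tab) paste(tab$source, tab$target, sep = "\r")
    base <- edgeSets[[1]]@table[, c("source", "target")]
    ord <- key(base)
    means <- vapply(edgeSets, function(es) {
        tab <- es@table
        tab$mean[match(ord, key(tab))]
    }, numeric(nrow(base)))
    sigsign <- vapply(edgeSets, function(es) {
        tab <- tab0 <- es@table
        tab <- tab[match(ord, key(tab)), ]
        ifelse(tab$significant, tab$sign, 0)
    }, numeric(nrow(base)))
    means <- matrix(means, nrow = nrow(base))
    sigsign <- matrix(sigsign, nrow = nrow(base))
    colnames(means) <- colnames(sigsign) <- paste0("exp", seq_len(E))
    nPos <- rowSums(sigsign > 0)
    nNeg <- rowSums(sigsign < 0)
    conflict <- nPos >= K & nNeg >= K
    keep <- !conflict & (nPos >= K | nNeg >= K)
    tab <- data.frame(
        source = base$source[keep], target = base$target[keep],
        sign = ifelse(nPos[keep] >= K, 1, -1),
        support = pmax(nPos, nNeg)[keep],
        stringsAsFactors = FALSE)
    dropped <- data.frame(
        source = base$source[conflict], target = base$target[conflict],
        nPositive = nPos[conflict], nNegative = nNeg[conflict],
        stringsAsFactors = FALSE)
    if (nrow(dropped))
        warning(nrow(dropped), " pair(s) reached K with both signs and ",
            "were dropped")
    new("ConsensusNetwork", components = comps, K = K, E = as.integer(E),
        table = tab, perExperiment = means[keep, , drop = FALSE],
        dropped = dropped)
}

#' @rdname ConsensusNetwork-class
#' @param x a \linkS4class{ConsensusNetwork}.
#' @param ... unused.
#' @export
setMethod("edgeTable", "ConsensusNetwork", function(x, ...) x@table)

#' @rdname ConsensusNetwork-class
#' @export
setMethod("componentNames", "ConsensusNetwork", function(x) x@components)

#' @rdname ConsensusNetwork-class
#' @export
perExperimentMeans <- function(x) {
    stopifnot(is(x, "ConsensusNetwork"))
    x@perExperiment
}

setMethod("show", "ConsensusNetwork", function(object) {
    cat(sprintf("ConsensusNetwork: %d edges kept at >= %d of %d experiments\n",
        nrow(object@table), object@K, object@E))
    tab <- object@table
    if (nrow(tab)) {
        rel <- ifelse(tab$sign > 0, "->(+)", "->(-)")
        for (i in seq_len(nrow(tab)))
            cat(sprintf("  %s %s %s  [%d/%d]\n", tab$source[i], rel[i],
                tab$target[i], tab$support[i], object@E))
    }
})
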