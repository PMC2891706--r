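#' Full inference pipeline for one experiment
#'
#' Convenience wrapper running scoring, activity estimation, leave-one-out
#' resampling of the MRA coefficients, and the sign-consistency filter on
#' one dataset. The result is the per-experiment signed edge set; with
#' several independent experiments, feed the edge sets to
#' [consensusNetwork()].
#'
#' @inheritParams jackknifeEdges
#' @return an \linkS4class{EdgeSet} with significance flags at
#'   \code{alpha}.
#' @examples
#' pe <- simulateExperiment(fourComponentModel(noiseFraction = 0), seed = 1)
#' significantEdges(inferNetwork(pe))
#' @export
inferNetwork <- function(pe, alpha = 0.05, ...) {
    jackknifeEdges(pe, alpha = alpha, ...)
}

#' Noise-robustness sweep over replicate noise levels
#'
#' For each noise level: simulate \code{E} independent experiments from the
#' model, run the full pipeline on each, form a K-of-E consensus, and score
#' the consensus against the generating truth; repeat \code{reps} times
#' with an independent seed schedule. This is the benchmark establishing up
#' to which replicate noise (as a fraction of the condition mean) the
#' majority consensus still reconstructs the true signed edge structure.
#'
#' @param model a \linkS4class{SyntheticModel}; its noise fraction is
#'   overridden per level.
#' @param noiseFractions numeric vector of noise levels (SD / mean).
#' @param E experiments per consensus (default 5).
#' @param K minimum supporting experiments (default 3: majority of 5).
#' @param reps sweep repetitions per level (default 10).
#' @param seed master seed; all per-experiment seeds derive from it, so the
#'   full table is reproducible from (model, arguments, seed).
#' @param alpha sign-consistency level per experiment.
#' @return data.frame with columns \code{noiseFraction}, \code{rep},
#'   \code{signScore}, \code{valueScore}, \code{nEdges}; the attribute
#'   \code{"summary"} holds the per-level mean scores and the attribute
#'   \code{"seeds"} the seed schedule.
#' @export
noiseSweep <- function(model, noiseFractions = c(0, 0.1, 0.2, 0.3, 0.5),
        E = 5L, K = 3L, reps = 10L, seed = 1L, alpha = 0.05) {
    stopifnot(is(model, "SyntheticModel"), E >= 1L, reps >= 1L)
    nlev <- length(noiseFractions)
    seeds <- .withSeed(seed,
        matrix(sample.int(2^31 - 1, nlev * reps * E), ncol = E))
    rownames(seeds) <- paste(rep(noiseFractions, each = reps),
        rep(seq_len(reps), nlev), sep = "/")
    out <- vector("list", nlev * reps)
    row <- 0L
    for (l in seq_len(nlev)) {
        lev <- model
        lev@noiseFraction <- noiseFractions[l]
        for (r in seq_len(reps)) {
            row <- row + 1L
            edgeSets <- lapply(seq_len(E), function(e)
                inferNetwork(
                    simulateExperiment(lev, seed = seeds[row, e]),
                    alpha = alpha))
            cons <- consensusNetwork(edgeSets, K = K)
            sim <- networkSimilarity(cons, model)
            out[[row]] <- data.frame(
                noiseFraction = noiseFractions[l], rep = r,
                signScore = signScore(sim), valueScore = valueScore(sim),
                nEdges = nrow(edgeTable(cons)))
        }
    }
    tab <- do.call(rbind, out)
    summ <- do.call(rbind, lapply(split(tab, tab$noiseFraction), function(s)
        data.frame(noiseFraction = s$noiseFraction[1],
            meanSignScore = mean(s$signScore),
            meanValueScore = mean(s$valueScore, na.rm = TRUE),
            meanEdges = mean(s$nEdges))))
    rownames(summ) <- NULL
    attr(tab, "summary") <- summ[order(summ$noiseFraction), ]
    attr(tab, "seeds") <- seeds
    tab
}
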