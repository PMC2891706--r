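## Run scoring -> activity estimation -> MRA on a gene subset (plain-matrix
## hot path); NULL when the subsample's response matrix is singular.
.mraOnSubset <- function(d, keep, norm, dist, recomputeScores, fullW,
        rcondThreshold) {
    sub <- .subsetData(d, keep)
    W <- if (recomputeScores) .scoreData(sub, norm, dist)$W
        else fullW[, keep, drop = FALSE]
    ## R = W G^T - W A, column-wise
    R <- W %*% t(sub$G) - drop(W %*% sub$A)
    tryCatch(.mraCore(R, rcondThreshold), error = function(e) NULL)
}

#' Resampled interaction coefficients with sign-consistency statistics
#'
#' The MRA coefficients carry unknown per-component scale factors, so their
#' magnitudes cannot be thresholded directly -- but their *signs* can be
#' tested for stability under resampling of the gene panel. The default
#' resampler is the leave-one-gene-out jackknife: each gene is removed in
#' turn and the whole pipeline (scoring on the remaining genes, activity
#' estimation, MRA) is re-run, yielding m coefficient samples per ordered
#' component pair. Per pair, the sample mean, sample SD, and the
#' \code{|mean|/SD} ratio feed the sign-consistency filter ([signFilter()],
#' applied here at level \code{alpha}).
#'
#' Resamples whose response matrix is singular are recorded as missing; a
#' pair missing more than \code{maxMissing} of its samples is flagged
#' unresolvable.
#'
#' @param pe a \linkS4class{PerturbationExperiment} with at least n + 1
#'   genes.
#' @param alpha sign-consistency level for the initial significance flags
#'   (default 0.05, i.e. 95% confidence).
#' @param norm,dist scoring options, see [scoreGenes()].
#' @param resampler \code{"jackknife"} (leave-one-out, default) or
#'   \code{"bootstrap"} (\code{nBoot} resamples of m genes with
#'   replacement; an alternative for larger panels).
#' @param nBoot bootstrap resample count.
#' @param recomputeScores recompute the scoring pipeline per resample
#'   (default TRUE; the per-gene normalizations depend on the gene set).
#'   FALSE reuses the full-data weights, for sensitivity analysis.
#' @param rcondThreshold passed to [mra()].
#' @param maxMissing maximum tolerated fraction of failed resamples per
#'   pair before it is reported unresolvable (default 0.2).
#' @param sides 1 (default) for the one-sided sign-consistency test, 2 for
#'   two-sided.
#' @return an \linkS4class{EdgeSet}.
#' @export
jackknifeEdges <- function(pe, alpha = 0.05, norm = c("L2", "L1"),
        dist = c("normal", "t"), resampler = c("jackknife", "bootstrap"),
        nBoot = 200L, recomputeScores = TRUE, rcondThreshold = 1e-10,
        maxMissing = 0.2, sides = 1) {
    norm <- match.arg(norm)
    dist <- match.arg(dist)
    resampler <- match.arg(resampler)
    m <- nrow(pe)
    d <- .placaData(pe)
    n <- length(d$components)
    if (m < n + 1L)
        stop("need at least n + 1 = ", n + 1L, " genes for leave-one-out ",
            "resampling, got ", m)
    fullW <- if (recomputeScores) NULL else .scoreData(d, norm, dist)$W
    subsets <- if (resampler == "jackknife") {
        lapply(seq_len(m), function(g) setdiff(seq_len(m), g))
    } else {
        lapply(seq_len(nBoot), function(b) sample.int(m, m, replace = TRUE))
    }
    samples <- array(NA_real_, dim = c(length(subsets), n, n),
        dimnames = list(NULL, d$components, d$components))
    for (b in seq_along(subsets)) {
        r <- .mraOnSubset(d, subsets[[b]], norm, dist, recomputeScores,
            fullW, rcondThreshold)
        if (!is.null(r)) samples[b, , ] <- r
    }
    pairs <- which(diag(n) == 0, arr.ind = TRUE)  # (target i, source j)
    tab <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        x <- samples[, i, j]
        ok <- !is.na(x)
        mu <- if (any(ok)) mean(x[ok]) else NA_real_
        sdv <- if (sum(ok) > 1) sd(x[ok]) else NA_real_
        data.frame(
            source = d$components[j], target = d$components[i],
            mean = mu, sd = sdv,
            zratio = NA_real_, sign = sign(ifelse(is.na(mu), 0, mu)),
            significant = FALSE,
            fracMissing = mean(!ok),
            unresolvable = mean(!ok) > maxMissing,
            stringsAsFactors = FALSE)
    }))
    rownames(tab) <- NULL
    es <- new("EdgeSet", components = d$components, samples = samples,
        table = tab, alpha = alpha, sides = sides,
        params = list(norm = norm, dist = dist, resampler = resampler,
            recomputeScores = recomputeScores, nResamples = length(subsets),
            rcondThreshold = rcondThreshold, maxMissing = maxMissing))
    signFilter(es, alpha = alpha, sides = sides)
}

#' Flag edges whose coefficient sign is consistent under resampling
#'
#' Assuming the resampled coefficients are approximately normal, a pair's
#' sign is consistent at level \code{1 - alpha} when
#' \code{|mean| / SD >= qnorm(1 - alpha)} (one-sided by default: the
#' question is whether the sign is stable, not whether the coefficient
#' differs from any value). A zero SD with a nonzero mean is perfectly
#' consistent; a zero mean never is. Pairs flagged unresolvable (too many
#' failed resamples) are never significant.
#'
#' @param edges an \linkS4class{EdgeSet}.
#' @param alpha significance level (default 0.05, i.e. 95% confidence).
#' @param sides 1 (default) or 2.
#' @return the \linkS4class{EdgeSet} with updated \code{zratio},
#'   \code{significant} flags, \code{alpha} and \code{sides}.
#' @export
signFilter <- function(edges, alpha = 0.05, sides = 1) {
    stopifnot(is(edges, "EdgeSet"))
    tab <- edges@table
    crit <- qnorm(1 - alpha / sides)
    z <- abs(tab$mean) / tab$sd
    sig <- !is.na(tab$mean) & tab$mean != 0 &
        ((!is.na(tab$sd) & tab$sd == 0) | (!is.na(z) & z >= crit))
    sig[tab$unresolvable] <- FALSE
    tab$zratio <- z
    tab$significant <- sig
    tab$sign <- sign(ifelse(is.na(tab$mean), 0, tab$mean))
    edges@table <- tab
    edges@alpha <- alpha
    edges@sides <- sides
    edges
}

#' @rdname EdgeSet-class
#' @param x an \linkS4class{EdgeSet}.
#' @param ... unused.
#' @export
setMethod("edgeTable", "EdgeSet", function(x, ...) x@table)

#' @rdname EdgeSet-class
#' @export
setMethod("significantEdges", "EdgeSet", function(x, ...) {
    x@table[x@table$significant, , drop = FALSE]
})

#' @rdname EdgeSet-class
#' @export
setMethod("componentNames", "EdgeSet", function(x) x@components)

#' @rdname EdgeSet-class
#' @export
coefficientSamples <- function(x) {
    stopifnot(is(x, "EdgeSet"))
    x@samples
}

setMethod("show", "EdgeSet", function(object) {
    tab <- object@table
    cat(sprintf(paste0("EdgeSet: %d components, %d resamples (%s), ",
        "%d/%d ordered pairs sign-consistent at %.0f%%\n"),
        length(object@components), object@params$nResamples,
        object@params$resampler, sum(tab$significant), nrow(tab),
        100 * (1 - object@alpha)))
    sig <- tab[tab$significant, , drop = FALSE]
    if (nrow(sig)) {
        rel <- ifelse(sig$sign > 0, "->(+)", "->(-)")
        cat("  ", paste(sprintf("%s %s %s", sig$source, rel, sig$target),
            collapse = ", "), "\n")
    }
})
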