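#' Change-in-activity matrix
#'
#' For every perturbation j and gene k, the change in mean activity relative
#' to baseline, \code{C[j, k] = A[k] - G[j, k]} (baseline minus perturbed: a
#' decrease after the perturbation gives a positive entry).
#'
#' @param pe a \linkS4class{PerturbationExperiment}.
#' @return an n x m matrix (perturbations x genes).
#' @export
changeMatrix <- function(pe) {
    d <- .placaData(pe)
    C <- sweep(-d$G, 2, d$A, "+")
    dimnames(C) <- list(d$components, d$genes)
    C
}

#' Activity scores
#'
#' The change in activity of each gene under each perturbation, multiplied
#' by the perturbation sign and normalized per gene across the n
#' perturbations, so the score measures the *relative* magnitude of the
#' change: it favors neither weakly expressed genes (as fold-change would)
#' nor highly expressed ones (as the absolute change would). With the
#' default Euclidean norm each gene's score column has unit L2 norm (or is
#' all zero when the gene never changes).
#'
#' @param pe a \linkS4class{PerturbationExperiment}.
#' @param norm \code{"L2"} (default; unit Euclidean norm per gene) or
#'   \code{"L1"}.
#' @return an n x m matrix D with \code{D[j, k] = s_j * C[j, k] / ||C[, k]||}.
#' @export
activityScores <- function(pe, norm = c("L2", "L1")) {
    norm <- match.arg(norm)
    C <- changeMatrix(pe)
    s <- .placaData(pe)$s
    nrm <- if (norm == "L2") sqrt(colSums(C^2)) else colSums(abs(C))
    nrm[nrm == 0] <- 1  # all-zero column stays all-zero
    sweep(C * s, 2, nrm, "/")
}

#' Two-sample Z values in log space
#'
#' Expression replicates are near log-normal, so significance of the change
#' is assessed on the log scale: \code{Z[j, k] =
#' (LogA[k] - LogG[j, k]) / sqrt(dA[k]^2 + dG[j, k]^2)}, with the log-SEs
#' playing the role of the t-test denominator. The sign convention matches
#' the change matrix (a decrease after perturbation gives a positive Z).
#' When both SEs are zero the statistic is 0 for equal means and a +/-Inf
#' sentinel otherwise ("certainly changed"; its P-score is 1).
#'
#' @param pe a \linkS4class{PerturbationExperiment}.
#' @return an n x m matrix of Z values (possibly +/-Inf).
#' @export
zMatrix <- function(pe) {
    d <- .placaData(pe)
    num <- sweep(-d$LogG, 2, d$LogA, "+")
    den <- sqrt(sweep(d$dG^2, 2, d$dA^2, "+"))
    Z <- num / den
    Z[den == 0 & num == 0] <- 0
    zv <- den == 0 & num != 0
    Z[zv] <- sign(num[zv]) * Inf
    dimnames(Z) <- list(d$components, d$genes)
    Z
}

#' P-score of a Z value
#'
#' The probability that the observed change is not noise: twice the
#' standard-normal CDF from zero to |Z|, i.e. \code{2 * (pnorm(|Z|) - 1/2)}.
#' 0 for no change, approaching 1 for changes far beyond the replicate
#' noise; infinite sentinel Z values map to exactly 1. A Student-t variant
#' (Welch-Satterthwaite degrees of freedom, supplied via \code{df}) is
#' available for small replicate counts.
#'
#' @param Z numeric vector/matrix of Z values.
#' @param dist \code{"normal"} (default) or \code{"t"}.
#' @param df degrees of freedom (recycled over Z) when \code{dist = "t"}.
#' @return P-scores in [0, 1], same shape as Z.
#' @export
pScore <- function(Z, dist = c("normal", "t"), df = Inf) {
    dist <- match.arg(dist)
    a <- abs(Z)
    P <- if (dist == "normal") 2 * (pnorm(a) - 0.5) else {
        df <- df + 0 * a  # recycle to Z's shape
        ifelse(is.finite(df), 2 * (pt(a, df) - 0.5), 2 * (pnorm(a) - 0.5))
    }
    P[is.infinite(Z)] <- 1
    P
}

#' Entropy-based information score
#'
#' Quantifies how specific a gene's response is to a single perturbation.
#' The squared Z values of the gene are normalized to a probability vector
#' \code{zt = Z^2 / sum(Z^2)} and scored by Shannon entropy:
#' \code{I = ln(n) - H(zt)} with \code{H = -sum(zt * ln(zt))} (0 ln 0 = 0).
#' I is 0 exactly when the gene changes equally significantly under all n
#' perturbations, and reaches the maximum ln(n) exactly when it responds to
#' one perturbation only. A gene with an all-zero Z column is uninformative
#' and scores 0. Infinite sentinel Z values (zero replicate variance with
#' differing means) take all the mass; among themselves it is split in
#' proportion to the squared log-changes when those are supplied -- the
#' limit of Z = change/SE as all SEs shrink at the same rate -- and
#' uniformly otherwise.
#'
#' @param Z a length-n numeric vector (one gene) or an n x m matrix; for a
#'   matrix the score is computed per column (gene).
#' @param changes optional log-changes (same shape as Z) used to weight
#'   infinite sentinel entries; [scoreGenes()] passes LogA - LogG.
#' @return a single score, or a length-m vector for matrix input; always in
#'   [0, ln n].
#' @export
informationScore <- function(Z, changes = NULL) {
    scoreCol <- function(z, ch) {
        n <- length(z)
        z2 <- z^2
        if (any(is.infinite(z2))) {
            inf <- is.infinite(z2)
            zt <- rep(0, n)
            zt[inf] <- if (!is.null(ch)) ch[inf]^2 else 1
            if (sum(zt) == 0) zt[inf] <- 1
            zt <- zt / sum(zt)
        } else {
            tot <- sum(z2)
            if (tot == 0) return(0)
            zt <- z2 / tot
        }
        ## uniform mass is the exact zero of the score; return it without
        ## accumulating entropy round-off
        if (all(zt == zt[1])) return(0)
        H <- -sum(ifelse(zt > 0, zt * log(zt), 0))
        min(max(log(n) - H, 0), log(n))
    }
    if (is.matrix(Z)) {
        vapply(seq_len(ncol(Z)), function(k)
            scoreCol(Z[, k], changes[, k]), numeric(1))
    } else scoreCol(as.numeric(Z), changes)
}

#' Compute all gene scores and the weight matrix
#'
#' Runs the full scoring stage: change matrix, activity scores, Z values,
#' P-scores, information scores, and the weight matrix
#' \code{W[i, k] = D[i, k] * P[i, k] * I[k] / A[k]} (the three scores are
#' multiplied as independent quantities, then divided by the unperturbed
#' activity so highly expressed genes do not dominate the activity
#' estimates). Row i of W is the gene-weight vector used to estimate
#' component i, the scores being taken at perturbation i since each
#' component is perturbed exactly once.
#'
#' @param pe a \linkS4class{PerturbationExperiment}.
#' @param norm activity-score normalization, \code{"L2"} or \code{"L1"}.
#' @param dist P-score null distribution, \code{"normal"} or \code{"t"}
#'   (Welch-Satterthwaite degrees of freedom from the replicate counts).
#' @return a \linkS4class{ScoreSet}.
#' @seealso [estimateActivity()] for the next stage.
#' @export
scoreGenes <- function(pe, norm = c("L2", "L1"),
        dist = c("normal", "t")) {
    norm <- match.arg(norm)
    dist <- match.arg(dist)
    d <- .placaData(pe)
    s <- .scoreData(d, norm, dist)
    new(Class = "ScoreSet", C = s$C, D = s$D, Z = s$Z, P = s$P,
        info = s$info, W = s$W,
        genes = d$genes, components = d$components,
        params = list(norm = norm, dist = dist))
}

## Core scoring math on the plain-matrix representation produced by
## .placaData(); the hot path for resampling (no S4 overhead).
.scoreData <- function(d, norm = "L2", dist = "normal") {
    dn <- list(d$components, d$genes)
    C <- sweep(-d$G, 2, d$A, "+")
    nrm <- if (norm == "L2") sqrt(colSums(C^2)) else colSums(abs(C))
    nrm[nrm == 0] <- 1
    D <- sweep(C * d$s, 2, nrm, "/")
    num <- sweep(-d$LogG, 2, d$LogA, "+")
    den <- sqrt(sweep(d$dG^2, 2, d$dA^2, "+"))
    Z <- num / den
    Z[den == 0 & num == 0] <- 0
    zv <- den == 0 & num != 0
    Z[zv] <- sign(num[zv]) * Inf
    df <- Inf
    if (dist == "t") {
        ## Welch-Satterthwaite df from the two log-scale SEs
        vA <- matrix(d$dA^2, nrow(Z), ncol(Z), byrow = TRUE)
        nA <- matrix(d$nA, nrow(Z), ncol(Z), byrow = TRUE)
        v <- vA + d$dG^2
        df <- v^2 / (vA^2 / (nA - 1) + d$dG^4 / (d$nG - 1))
        df[v == 0] <- Inf
    }
    P <- pScore(Z, dist, df)
    info <- informationScore(Z, changes = num)
    W <- sweep(sweep(D * P, 2, info, "*"), 2, d$A, "/")
    dimnames(C) <- dimnames(D) <- dimnames(Z) <- dimnames(P) <-
        dimnames(W) <- dn
    list(C = C, D = D, Z = Z, P = P, info = info, W = W)
}

## Subset the plain-matrix representation to a gene subset.
.subsetData <- function(d, keep) {
    list(genes = d$genes[keep], components = d$components, s = d$s,
        A = d$A[keep], LogA = d$LogA[keep], dA = d$dA[keep], nA = d$nA[keep],
        G = d$G[, keep, drop = FALSE], LogG = d$LogG[, keep, drop = FALSE],
        dG = d$dG[, keep, drop = FALSE], nG = d$nG[, keep, drop = FALSE])
}

#' @rdname ScoreSet-class
#' @param x a \linkS4class{ScoreSet}.
#' @export
setMethod("weightMatrix", "ScoreSet", function(x, ...) x@W)

#' @rdname ScoreSet-class
#' @export
setMethod("weightMatrix", "PerturbationExperiment",
    function(x, ...) scoreGenes(x, ...)@W)

#' @rdname ScoreSet-class
#' @param which one of "C", "D", "Z", "P", "info", "W".
#' @export
scores <- function(x, which = c("W", "C", "D", "Z", "P", "info")) {
    stopifnot(is(x, "ScoreSet"))
    slot(x, match.arg(which))
}

#' @rdname ScoreSet-class
#' @export
informationScores <- function(x) {
    stopifnot(is(x, "ScoreSet"))
    setNames(x@info, x@genes)
}

setMethod("show", "ScoreSet", function(object) {
    cat("ScoreSet:", length(object@genes), "genes x",
        length(object@components), "perturbations",
        sprintf("(norm %s, %s P-scores)\n",
            object@params$norm, object@params$dist))
    top <- order(object@info, decreasing = TRUE)[seq_len(min(3,
        length(object@genes)))]
    cat("  most specific genes:",
        paste(sprintf("%s (I=%.3f)", object@genes[top], object@info[top]),
            collapse = ", "), "\n")
})

#' Dump all score matrices as TSV files for audit
#'
#' Writes C, D, Z, P, W (genes x perturbations) and the information scores
#' to \code{<prefix><name>.tsv}.
#'
#' @param x a \linkS4class{ScoreSet}.
#' @param prefix path prefix for the output files.
#' @return invisibly, the written file paths.
#' @export
writeScoreTables <- function(x, prefix) {
    stopifnot(is(x, "ScoreSet"))
    paths <- character(0)
    for (nm in c("C", "D", "Z", "P", "W")) {
        p <- paste0(prefix, nm, ".tsv")
        write.table(t(slot(x, nm)), p, sep = "\t", quote = FALSE,
            col.names = NA)
        paths <- c(paths, p)
    }
    p <- paste0(prefix, "info.tsv")
    write.table(data.frame(gene = x@genes, info = x@info), p, sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(c(paths, p))
}
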