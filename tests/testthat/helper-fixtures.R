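## Small in-code fixtures shared across test files.

## A dataset built directly from summary matrices: m genes, n perturbations,
## with controllable means and log-scale SEs.
makeSummaryDataset <- function(A, G, logSE = 0.05, nRep = 3L,
        signs = rep(-1L, nrow(G))) {
    m <- length(A)
    n <- nrow(G)
    genes <- paste0("g", seq_len(m))
    comps <- paste0("K", seq_len(n))
    act <- cbind(baseline = A, t(G))
    colnames(act) <- c("baseline", comps)
    rownames(act) <- genes
    se <- matrix(logSE, m, n + 1L, dimnames = dimnames(act))
    PerturbationExperiment(
        activity = act, logActivity = log(act), logSE = se,
        nRep = matrix(nRep, m, n + 1L, dimnames = dimnames(act)),
        panel = PerturbationPanel(comps, signs),
        baseline = "baseline")
}

## n disjoint perfect reporters duplicated `dup` times: gene (i, d) responds
## only to perturbation i, with a clear fold change.
makeReporterDataset <- function(n = 3L, dup = 2L, fold = 0.4,
        logSE = 0.02) {
    m <- n * dup
    A <- rep(10, m)
    G <- matrix(rep(A, each = n), n, m)
    for (i in seq_len(n))
        for (d in seq_len(dup))
            G[i, (i - 1L) * dup + d] <- 10 * fold
    makeSummaryDataset(A, G, logSE = logSE)
}

## Replicate matrices for a toy 3-gene, 2-perturbation design.
makeToyReplicates <- function() {
    genes <- c("fos", "egr1", "klf4")
    reps <- function(...) {
        mat <- rbind(...)
        rownames(mat) <- genes
        mat
    }
    list(
        baseline = reps(c(10, 11, 12), c(5, 5.5, 5.2), c(2, 2.1, 1.9)),
        inhA = reps(c(4, 4.2, 4.4), c(5.1, 5.3, 5.2), c(2.05, 2, 1.95)),
        inhB = reps(c(9.8, 10.4, 10.0), c(2.0, 2.2, 2.1), c(1.0, 1.1, 0.9)))
}

makeToyDataset <- function() {
    perturbationExperimentFromReplicates(
        makeToyReplicates(),
        PerturbationPanel(c("A", "B"), c(-1L, -1L)),
        baseline = "baseline")
}

## A known random MRA system: r with diag -1, R = -r^-1 %*% diag(p).
makeMRASystem <- function(n, seed) {
    set.seed(seed)
    repeat {
        r <- matrix(runif(n * n, -0.5, 0.5), n, n)
        diag(r) <- -1
        if (abs(det(r)) > 0.05) break
    }
    p <- runif(n, 0.5, 2) * sample(c(-1, 1), n, replace = TRUE)
    list(r = r, p = p, R = -solve(r) %*% diag(p))
}
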