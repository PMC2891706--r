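test_that("change matrix is baseline minus perturbed", {
    ## no change anywhere
    A <- c(2, 3, 4)
    G <- rbind(A, A)
    pe <- makeSummaryDataset(A, G)
    expect_true(all(changeMatrix(pe) == 0))

    ## A = 2, G = 0.5 -> C = 1.5; and a 2x2 hand case
    pe <- makeSummaryDataset(c(2, 1), rbind(c(0.5, 1), c(2, 3)))
    C <- changeMatrix(pe)
    expect_equal(unname(C[1, ]), c(1.5, 0))
    expect_equal(unname(C[2, ]), c(0, -2))

    pe <- makeSummaryDataset(c(1, 1), rbind(c(2, 1), c(1, 3)))
    expect_equal(unname(changeMatrix(pe)), rbind(c(-1, 0), c(0, -2)))
})

test_that("activity scores are sign-adjusted unit-norm columns", {
    ## gene 1 changes under one perturbation only; gene 2: C = (3, 4)
    A <- c(10, 10)
    G <- rbind(c(6, 7), c(10, 6))
    pe <- makeSummaryDataset(A, G, signs = c(1L, 1L))
    D <- activityScores(pe)
    expect_equal(abs(unname(D[, 1])), c(1, 0))
    expect_equal(unname(D[, 2]), c(0.6, 0.8))

    ## signs (-1, +1) flip the first row
    pe <- makeSummaryDataset(A, G, signs = c(-1L, 1L))
    D <- activityScores(pe)
    expect_equal(unname(D[, 2]), c(-0.6, 0.8))

    ## column norms are 0 or 1 (L2), and L1 normalization sums to 1
    model <- fourComponentModel(noiseFraction = 0.2)
    sim <- simulateExperiment(model, seed = 3)
    D <- activityScores(sim)
    expect_equal(unname(colSums(D^2)), rep(1, ncol(D)), tolerance = 1e-12)
    D1 <- activityScores(sim, norm = "L1")
    expect_equal(unname(colSums(abs(D1))), rep(1, ncol(D1)),
        tolerance = 1e-12)
})

test_that("z values reproduce hand-computed two-sample statistics", {
    ## build one gene per case via summary matrices
    A <- exp(c(1, 0, 2))
    G <- rbind(exp(c(0, 2, 2)))
    act <- cbind(baseline = A, K1 = drop(G), K2 = A)  # K2: no change
    genes <- paste0("g", 1:3)
    dimnames(act) <- list(genes, colnames(act))
    se <- act * 0
    se[, "baseline"] <- c(0.6, 1, 0.3)
    se[, "K1"] <- c(0.8, 1, 0.4)
    se[, "K2"] <- c(0.6, 1, 0.3)
    pe <- PerturbationExperiment(act, log(act), se,
        matrix(3, 3, 3, dimnames = dimnames(act)),
        PerturbationPanel(c("K1", "K2"), c(-1L, -1L)), "baseline")
    Z <- zMatrix(pe)
    expect_equal(unname(Z["K1", ]), c(1 / sqrt(0.36 + 0.64), -sqrt(2), 0))
    expect_equal(unname(Z["K2", ]), c(0, 0, 0))
})

test_that("zero-variance pairs give sentinel Z and P-score 1", {
    A <- c(2, 5)
    G <- rbind(c(1, 5), c(4, 5))
    pe <- makeSummaryDataset(A, G, logSE = 0)
    Z <- zMatrix(pe)
    expect_equal(unname(Z[, 1]), c(Inf, -Inf))
    expect_equal(unname(Z[, 2]), c(0, 0))
    expect_equal(unname(pScore(Z)[, 1]), c(1, 1))
    expect_equal(unname(pScore(Z)[, 2]), c(0, 0))
})

test_that("P-score is the folded normal CDF and is monotone in |Z|", {
    expect_equal(pScore(0), 0)
    expect_equal(pScore(1.959964), 0.95, tolerance = 1e-6)
    expect_equal(pScore(-1), 0.6826895, tolerance = 1e-6)
    z <- seq(0, 6, by = 0.05)
    expect_true(all(diff(pScore(z)) > 0))
    expect_true(all(pScore(c(z, -z)) >= 0 & pScore(c(z, -z)) < 1))
    ## t variant approaches the normal as df grows
    expect_lt(pScore(1.5, dist = "t", df = 4), pScore(1.5))
    expect_equal(pScore(1.5, dist = "t", df = 1e9), pScore(1.5),
        tolerance = 1e-6)
})

test_that("information score hits the entropy endpoints exactly", {
    for (n in 2:6) {
        expect_equal(informationScore(rep(1.7, n)), 0)
        expect_equal(informationScore(rep(-0.3, n)), 0)
        z <- rep(0, n); z[sample(n, 1)] <- rnorm(1) + 3
        expect_equal(informationScore(z), log(n))
    }
    expect_equal(informationScore(rep(0, 4)), 0)
    ## n = 2, Z = (1, sqrt(3)): ztilde = (1/4, 3/4)
    expect_equal(informationScore(c(1, sqrt(3))),
        log(2) - (-0.25 * log(0.25) - 0.75 * log(0.75)))
    expect_equal(informationScore(c(1, sqrt(3))), 0.1308, tolerance = 1e-4)
})

test_that("information score bounds and sign/permutation invariance hold", {
    set.seed(42)
    for (i in 1:25) {
        n <- sample(2:7, 1)
        z <- rnorm(n) * sample(c(0, 1), n, replace = TRUE)
        I <- informationScore(z)
        expect_gte(I, 0)
        expect_lte(I, log(n))
        expect_equal(informationScore(sample(z)), I)
        expect_equal(informationScore(-z), I)
    }
})

test_that("weights multiply the three scores over unperturbed activity", {
    ## gene 1 responds only to perturbation 1; gene 2 never changes
    A <- c(2, 7)
    G <- rbind(c(0.5, 7), c(2, 7), c(2, 7))
    se <- 0.3827
    pe <- makeSummaryDataset(A, G, logSE = se, signs = rep(1L, 3))
    ss <- scoreGenes(pe)
    Z11 <- (log(2) - log(0.5)) / sqrt(2 * se^2)
    W <- weightMatrix(ss)
    expect_equal(unname(W[1, 1]),
        1 * pScore(Z11) * log(3) / 2, tolerance = 1e-10)
    expect_equal(unname(W[2:3, 1]), c(0, 0))
    expect_equal(unname(W[, 2]), rep(0, 3))  # all-zero Z column
    expect_equal(unname(informationScores(ss)[["g2"]]), 0)
})

test_that("per-gene rescaling leaves scores unchanged and scales W by 1/c", {
    model <- fourComponentModel(noiseFraction = 0.15)
    pe <- simulateExperiment(model, seed = 9)
    cvec <- c(0.2, 1, 3, 10, 0.5, 2, 7, 0.1, 1.5, 4)
    scaled <- pe
    for (a in c("activity")) {
        mat <- SummarizedExperiment::assay(scaled, a) * cvec
        SummarizedExperiment::assay(scaled, a) <- mat
    }
    la <- SummarizedExperiment::assay(scaled, "logActivity") + log(cvec)
    SummarizedExperiment::assay(scaled, "logActivity") <- la
    s1 <- scoreGenes(pe)
    s2 <- scoreGenes(scaled)
    expect_equal(scores(s2, "D"), scores(s1, "D"), tolerance = 1e-10)
    expect_equal(scores(s2, "Z"), scores(s1, "Z"), tolerance = 1e-10)
    expect_equal(scores(s2, "P"), scores(s1, "P"), tolerance = 1e-10)
    expect_equal(informationScores(s2), informationScores(s1),
        tolerance = 1e-10)
    expect_equal(weightMatrix(s2), sweep(weightMatrix(s1), 2, cvec, "/"),
        tolerance = 1e-10)
    ## so the estimated activities are invariant
    expect_equal(responseMatrix(estimateActivity(scaled, s2)),
        responseMatrix(estimateActivity(pe, s1)), tolerance = 1e-9)
})
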