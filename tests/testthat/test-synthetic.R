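test_that("the benchmark model has the declared size and edge set", {
    model <- fourComponentModel()
    expect_equal(length(model@components), 4L)
    expect_equal(length(model@genes), 10L)
    te <- trueEdgeTable(model)
    expect_setequal(paste(te$source, te$target, te$sign),
        c("S1 S2 1", "S2 S1 1", "S2 S3 -1", "S1 S4 -1", "S2 S4 -1"))
    ## every gene regulated by at least one component
    expect_true(all(colSums(model@regulation != 0) > 0))
})

test_that("model validity rejects unstable or malformed networks", {
    r <- diag(-1, 3)
    r[1, 2] <- r[2, 1] <- 1.2  # spectral radius > 1
    w <- matrix(0.3, 3, 4)
    expect_error(SyntheticModel(r, w, rep(1, 4)), "unstable")
    r2 <- diag(-1, 3)
    w2 <- w; w2[, 2] <- 0
    expect_error(SyntheticModel(r2, w2, rep(1, 4)), "regulated")
    expect_error(SyntheticModel(r2, w, c(1, -1, 1, 1)), "positive")
})

test_that("true responses solve the linear fixed point", {
    model <- fourComponentModel()
    dS <- trueResponses(model)
    r <- interactionCoefficients(model)
    p <- diag(rep(model@perturbationFold - 1, 4))
    ## r %*% dS + p = 0 at the fixed point
    expect_equal(r %*% dS, -p, ignore_attr = TRUE, tolerance = 1e-12)
    ## perturbing a component with no outgoing edges moves only itself
    sinks <- which(colSums(r != 0) == 1)  # only the diagonal entry
    for (j in sinks) {
        moved <- which(abs(dS[, j]) > 1e-12)
        expect_equal(moved, j, ignore_attr = TRUE)
    }
})

test_that("perturbing a sink component changes only its reporter genes", {
    model <- fourComponentModel(noiseFraction = 0)
    pe <- simulateExperiment(model, seed = 1)
    act <- SummarizedExperiment::assay(pe, "activity")
    r <- interactionCoefficients(model)
    sinks <- model@components[colSums(r != 0) == 1]
    expect_true(length(sinks) >= 1)
    for (s in sinks) {
        changed <- abs(act[, s] - act[, "baseline"]) > 1e-9
        reporters <- model@regulation[s, ] != 0
        expect_equal(unname(changed), unname(reporters))
    }
})

test_that("simulation is deterministic and honours the noise model", {
    model <- fourComponentModel(noiseFraction = 0.2)
    a <- simulateExperiment(model, seed = 7)
    b <- simulateExperiment(model, seed = 7)
    expect_identical(SummarizedExperiment::assay(a, "activity"),
        SummarizedExperiment::assay(b, "activity"))
    expect_identical(S4Vectors::metadata(a)$replicates,
        S4Vectors::metadata(b)$replicates)
    c2 <- simulateExperiment(model, seed = 8)
    expect_false(identical(SummarizedExperiment::assay(a, "activity"),
        SummarizedExperiment::assay(c2, "activity")))

    ## noise-free replicates all equal their condition mean
    m0 <- fourComponentModel(noiseFraction = 0)
    pe0 <- simulateExperiment(m0, seed = 1)
    reps <- S4Vectors::metadata(pe0)$replicates
    for (cond in names(reps))
        expect_true(all(reps[[cond]] == reps[[cond]][, 1]))
    expect_true(all(SummarizedExperiment::assay(pe0, "logSE") == 0))

    ## simulating must not disturb the caller's RNG stream
    set.seed(123); x1 <- rnorm(1)
    set.seed(123); invisible(simulateExperiment(model, seed = 5))
    x2 <- rnorm(1)
    expect_identical(x1, x2)

    ## log-normal noise keeps roughly the requested CV
    ml <- fourComponentModel(noiseFraction = 0.2, nRep = 500L,
        noiseModel = "lognormal")
    pel <- simulateExperiment(ml, seed = 3)
    reps <- S4Vectors::metadata(pel)$replicates$baseline
    cv <- apply(reps, 1, sd) / rowMeans(reps)
    expect_equal(unname(cv), rep(0.2, 10), tolerance = 0.05)
})

test_that("similarity scoring counts matched statuses over ordered pairs", {
    model <- fourComponentModel()
    ## truth against itself
    expect_equal(signScore(networkSimilarity(model, model)), 1)
    ## all-absent inferred vs 5 true edges among 12 ordered pairs
    empty <- matrix(0, 4, 4, dimnames = list(model@components,
        model@components))
    sim <- networkSimilarity(empty, model)
    expect_equal(signScore(sim), 7 / 12)
    ## empty truth vs empty inferred: vacuous perfection, value NA
    noEdge <- SyntheticModel(diag(-1, 4), model@regulation,
        model@baselineGene)
    sim2 <- networkSimilarity(empty, noEdge)
    expect_equal(signScore(sim2), 1)
    expect_true(is.na(valueScore(sim2)))
    ## value score is 1 when inferred coefficients equal the truth
    simT <- networkSimilarity(interactionCoefficients(model), model)
    expect_equal(valueScore(simT), 1)
})

test_that("noise-free inference recovers the exact true edge structure", {
    model <- fourComponentModel(noiseFraction = 0)
    pe <- simulateExperiment(model, seed = 1)
    es <- inferNetwork(pe)
    sig <- significantEdges(es)
    te <- trueEdgeTable(model)
    expect_setequal(paste(sig$source, sig$target, sig$sign),
        paste(te$source, te$target, te$sign))
    expect_equal(signScore(networkSimilarity(
        consensusNetwork(list(es), K = 1), model)), 1)
})

test_that("noise sweep returns a reproducible per-level table", {
    model <- fourComponentModel()
    tab <- noiseSweep(model, noiseFractions = c(0, 0.3), E = 2, K = 2,
        reps = 2, seed = 5)
    expect_equal(nrow(tab), 4L)
    expect_named(tab, c("noiseFraction", "rep", "signScore", "valueScore",
        "nEdges"))
    expect_true(all(tab$signScore >= 0 & tab$signScore <= 1))
    summ <- attr(tab, "summary")
    expect_equal(summ$noiseFraction, c(0, 0.3))
    expect_equal(summ$meanSignScore[1], 1)  # noise-free recovery
    tab2 <- noiseSweep(model, noiseFractions = c(0, 0.3), E = 2, K = 2,
        reps = 2, seed = 5)
    expect_identical(tab, tab2)
})

test_that("recovery degrades with noise on average", {
    model <- fourComponentModel()
    tab <- noiseSweep(model, noiseFractions = c(0, 0.5), E = 3, K = 2,
        reps = 10, seed = 99)
    summ <- attr(tab, "summary")
    expect_gte(summ$meanSignScore[summ$noiseFraction == 0],
        summ$meanSignScore[summ$noiseFraction == 0.5])
})
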