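test_that("activity estimation is the weighted gene sum", {
    pe <- makeToyDataset()
    ss <- scoreGenes(pe)
    ## null weights -> null estimate
    ssZero <- ss
    ssZero@W[] <- 0
    ae <- estimateActivity(pe, ssZero)
    expect_true(all(activityMatrix(ae) == 0))
    expect_true(all(responseMatrix(ae) == 0))

    ## no-perturbation dataset: G = A for every condition -> R = 0
    A <- c(4, 6, 8)
    pe0 <- makeSummaryDataset(A, rbind(A, A))
    ae0 <- estimateActivity(pe0)
    expect_equal(max(abs(responseMatrix(ae0))), 0)

    ## S = W G^T and S0 = W A, written out
    ae1 <- estimateActivity(pe, ss)
    d <- placa:::.placaData(pe)
    expect_equal(unname(activityMatrix(ae1)),
        unname(weightMatrix(ss) %*% t(d$G)))
    expect_equal(unname(baselineActivity(ae1)),
        unname(drop(weightMatrix(ss) %*% d$A)))
})

test_that("mra recovers generating coefficients from linear systems", {
    sys <- makeMRASystem(4, seed = 1)
    r <- interactionCoefficients(mra(sys$R))
    expect_equal(unname(r), sys$r, tolerance = 1e-10)
    expect_identical(unname(diag(r)), rep(-1, 4))

    ## decoupled system: diagonal R -> no interactions
    R <- diag(c(2, -1, 0.5))
    r <- interactionCoefficients(mra(R))
    expect_equal(unname(r), -diag(3))
})

test_that("mra refuses singular or ill-conditioned responses", {
    R <- rbind(c(1, 2), c(2, 4))
    expect_error(mra(R), "condition number")
    R <- rbind(c(1, 1 + 1e-13), c(1, 1))
    expect_error(mra(R), "condition number")
    expect_error(mra(matrix(1:6, 2, 3)), "square")
})

test_that("jackknife yields m samples per pair with shared-sign redundancy", {
    pe <- makeReporterDataset(n = 3, dup = 2)
    es <- jackknifeEdges(pe)
    expect_equal(dim(coefficientSamples(es)), c(6L, 3L, 3L))
    tab <- edgeTable(es)
    expect_equal(nrow(tab), 6L)
    ## disjoint perfect reporters duplicated: every pair's samples share a sign
    samp <- coefficientSamples(es)
    for (k in seq_len(nrow(tab))) {
        i <- match(tab$target[k], componentNames(es))
        j <- match(tab$source[k], componentNames(es))
        x <- samp[, i, j]
        x <- x[!is.na(x)]
        expect_true(all(sign(x) == sign(x[1])),
            info = paste(tab$source[k], "->", tab$target[k]))
    }
})

test_that("singular leave-one-out subproblems are recorded, not fatal", {
    ## one component has a single reporter: leaving that gene out makes the
    ## subproblem's response matrix singular, so that resample is missing
    A <- rep(10, 4)
    G <- matrix(10, 3, 4)
    G[1, 1] <- G[1, 2] <- 4   # two reporters for K1
    G[2, 3] <- 4              # single reporter for K2
    G[3, 4] <- 4              # single reporter for K3
    pe <- makeSummaryDataset(A, G, logSE = 0.02)
    es <- jackknifeEdges(pe)
    tab <- edgeTable(es)
    expect_true(all(tab$fracMissing >= 2 / 4))
    expect_true(all(tab$unresolvable))
    expect_false(any(tab$significant))
    ## a looser missing tolerance lets the pairs resolve again
    es2 <- jackknifeEdges(pe, maxMissing = 0.6)
    expect_false(any(edgeTable(es2)$unresolvable))
})

test_that("sign filter applies the one-sided normal threshold inclusively", {
    pe <- makeReporterDataset(n = 2, dup = 2)
    es <- jackknifeEdges(pe)
    tab <- es@table
    tab$mean <- c(0, 1.644854)
    tab$sd <- c(1, 1)
    es@table <- tab
    out <- edgeTable(signFilter(es, alpha = 0.05))
    expect_false(out$significant[1])  # zero mean never significant
    expect_true(out$significant[2])   # boundary ratio included

    tab$mean <- c(1, -2)
    tab$sd <- c(1, 0)
    es@table <- tab
    out <- edgeTable(signFilter(es, alpha = 0.05))
    expect_false(out$significant[1])  # 1.0 < 1.645
    expect_true(out$significant[2])   # zero SD, nonzero mean
    expect_equal(out$sign, c(1, -1))

    ## two-sided option is stricter
    tab$mean <- c(1.8, 1.8); tab$sd <- c(1, 1)
    es@table <- tab
    expect_true(all(edgeTable(signFilter(es, alpha = 0.05))$significant))
    expect_false(any(edgeTable(
        signFilter(es, alpha = 0.05, sides = 2))$significant))
})

test_that("consensus keeps K-of-E same-sign significant edges only", {
    mkEdge <- function(means, sigs) {
        pe <- makeReporterDataset(n = 2, dup = 2)
        es <- jackknifeEdges(pe)
        tab <- es@table
        tab$mean <- means
        tab$sign <- sign(means)
        tab$significant <- sigs
        es@table <- tab
        es
    }
    ## edge 1 significant-positive everywhere; edge 2 in only 3 of 5
    sets <- c(
        replicate(3, mkEdge(c(0.5, 0.4), c(TRUE, TRUE)), simplify = FALSE),
        replicate(2, mkEdge(c(0.5, 0.4), c(TRUE, FALSE)), simplify = FALSE))
    cons <- consensusNetwork(sets, K = 5)
    expect_equal(nrow(edgeTable(cons)), 1L)
    expect_equal(edgeTable(cons)$support, 5L)
    cons4 <- consensusNetwork(sets, K = 3)
    expect_equal(nrow(edgeTable(cons4)), 2L)
    ## K - 1 support -> dropped
    cons5 <- consensusNetwork(sets, K = 4)
    expect_equal(nrow(edgeTable(cons5)), 1L)

    ## positive-significant in 3, negative-significant in 2, K = 4 -> dropped
    sets2 <- c(
        replicate(3, mkEdge(c(0.5, 0.4), c(TRUE, TRUE)), simplify = FALSE),
        replicate(2, mkEdge(c(-0.5, 0.4), c(TRUE, TRUE)), simplify = FALSE))
    cons6 <- consensusNetwork(sets2, K = 4)
    expect_false("K1" %in% edgeTable(cons6)$source[
        edgeTable(cons6)$target == "K2"])

    ## conflicting signs both reaching K <= E/2 are dropped with a warning
    expect_warning(consensusNetwork(sets2, K = 2), "both signs")
    expect_error(consensusNetwork(sets, K = 9), "K must satisfy")
})

test_that("consensus at K = 1 is the union and is monotone in K", {
    model <- fourComponentModel(noiseFraction = 0.25)
    sets <- lapply(1:3, function(s)
        inferNetwork(simulateExperiment(model, seed = 40 + s)))
    sig <- unique(do.call(rbind, lapply(sets, function(es)
        significantEdges(es)[, c("source", "target")])))
    consU <- edgeTable(suppressWarnings(consensusNetwork(sets, K = 1)))
    agree <- !vapply(seq_len(nrow(sig)), function(k) {
        ## pairs with conflicting signs across experiments are dropped,
        ## everything else must appear
        signs <- vapply(sets, function(es) {
            tb <- significantEdges(es)
            hit <- tb$source == sig$source[k] & tb$target == sig$target[k]
            if (any(hit)) tb$sign[hit] else 0
        }, numeric(1))
        length(unique(signs[signs != 0])) > 1
    }, logical(1))
    expect_true(all(paste(sig$source, sig$target)[agree] %in%
        paste(consU$source, consU$target)))
    ## monotone non-increasing in K (above K = 1, where conflicting-sign
    ## pairs are dropped rather than counted, so sizes can dip)
    sizes <- vapply(2:3, function(K)
        nrow(edgeTable(suppressWarnings(consensusNetwork(sets, K = K)))),
        integer(1))
    expect_true(all(diff(sizes) <= 0))
})

test_that("gene contributions partition the response entry exactly", {
    model <- fourComponentModel(noiseFraction = 0.2)
    pe <- simulateExperiment(model, seed = 11)
    ss <- scoreGenes(pe)
    R <- responseMatrix(estimateActivity(pe, ss))
    comps <- componentNames(perturbationPanel(pe))
    for (i in comps) for (j in comps) {
        if (i == j) next
        gc <- geneContributions(pe, i, j, scores = ss)
        expect_equal(sum(gc$contribution), R[j, i],
            tolerance = 1e-9, ignore_attr = TRUE)
    }
    ## zero weight means zero contribution
    ssz <- ss; ssz@W["S2", ] <- 0
    gc <- geneContributions(pe, "S1", "S2", scores = ssz)
    expect_true(all(gc$contribution == 0))
    expect_error(geneContributions(pe, "S1", "S1"), "differ")
    expect_error(geneContributions(pe, "nope", "S1"), "unknown component")
})

test_that("gene order permutation changes nothing downstream of W", {
    model <- fourComponentModel(noiseFraction = 0.15)
    pe <- simulateExperiment(model, seed = 21)
    set.seed(77)
    perm <- sample(nrow(pe))
    pe2 <- pe[perm, ]
    expect_equal(responseMatrix(estimateActivity(pe2)),
        responseMatrix(estimateActivity(pe)), tolerance = 1e-12)
    t1 <- edgeTable(inferNetwork(pe))
    t2 <- edgeTable(inferNetwork(pe2))
    expect_equal(t2$mean, t1$mean, tolerance = 1e-12)
    expect_equal(t2$significant, t1$significant)
})
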