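## Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

#' Construct a synthetic signaling-network model
#'
#' @param interactions n x n true local-coefficient matrix: diagonal -1,
#'   entry (i, j) the signed effect of component j on component i. The
#'   off-diagonal part must be stable (spectral radius of
#'   \code{interactions + I} below 1) so the perturbation responses reach a
#'   linear fixed point.
#' @param regulation n x m signed weights from components (rows) to early
#'   genes (columns); every gene needs at least one regulator.
#' @param baselineGene length-m positive baseline gene activities
#'   (arbitrary units).
#' @param perturbationFold multiplicative change applied directly to a
#'   perturbed component before network propagation (default 0.2, i.e. an
#'   inhibitor that leaves 20% residual activity).
#' @param perturbationSign direction recorded in the panel per component
#'   (default all -1: inhibitors).
#' @param noiseFraction replicate noise SD as a fraction of the condition
#'   mean (default 0.1).
#' @param noiseModel \code{"gaussian"} (default; truncated at a positive
#'   floor) or \code{"lognormal"} (matching mean and CV -- closer to real
#'   expression replicates).
#' @param nRep replicates per condition (default 4).
#' @param floorEps positive floor for simulated means and replicates,
#'   relative to the baseline (default 1e-6).
#' @return a \linkS4class{SyntheticModel}.
#' @seealso [fourComponentModel()] for the benchmark instance,
#'   [simulateExperiment()].
#' @export
SyntheticModel <- function(interactions, regulation, baselineGene,
        perturbationFold = 0.2, perturbationSign = NULL,
        noiseFraction = 0.1, noiseModel = c("gaussian", "lognormal"),
        nRep = 4L, floorEps = 1e-6) {
    interactions <- as.matrix(interactions)
    regulation <- as.matrix(regulation)
    n <- nrow(interactions)
    m <- ncol(regulation)
    comps <- rownames(interactions)
    if (is.null(comps)) comps <- paste0("S", seq_len(n))
    genes <- colnames(regulation)
    if (is.null(genes)) genes <- paste0("G", seq_len(m))
    dimnames(interactions) <- list(comps, comps)
    dimnames(regulation) <- list(comps, genes)
    if (is.null(perturbationSign))
        perturbationSign <- rep(-1L, n)
    new("SyntheticModel",
        components = comps, genes = genes,
        interactions = interactions, regulation = regulation,
        baselineGene = setNames(as.numeric(baselineGene), genes),
        perturbationFold = perturbationFold,
        perturbationSign = as.integer(perturbationSign),
        noiseFraction = noiseFraction,
        noiseModel = match.arg(noiseModel),
        nRep = as.integer(nRep), floorEps = floorEps)
}

#' The four-component / ten-gene benchmark network
#'
#' A fixed synthetic model assembled from standard network motifs (a
#' positive feedback pair acting as a bi-fan master regulator, feed-forward
#' inhibition, and a few single-input reporter genes). The component edges
#' are: S1 and S2 activate each other; S2 inhibits S3; S1 and S2 both
#' inhibit S4. The gene wiring follows the same reporting structure used to
#' validate the inference: G1, G2, G4 and G6 report S1 and S2; G6-G9 report
#' S3 (G9 with a negative-regulation "exception"); G3 and G5 report S4; G7
#' is shared between S2/S3/S4; G10 is a single-input S1 reporter. All four
#' perturbations are inhibitions.
#'
#' @param noiseFraction replicate noise SD as a fraction of the mean
#'   (default 0.1; set 0 for noise-free data).
#' @param nRep replicates per condition (default 4).
#' @param noiseModel \code{"gaussian"} or \code{"lognormal"}.
#' @return a \linkS4class{SyntheticModel} with n = 4 components and m = 10
#'   genes.
#' @examples
#' model <- fourComponentModel(noiseFraction = 0)
#' pe <- simulateExperiment(model, seed = 1)
#' @export
fourComponentModel <- function(noiseFraction = 0.1, nRep = 4L,
        noiseModel = "gaussian") {
    comps <- paste0("S", 1:4)
    r <- diag(-1, 4)
    dimnames(r) <- list(comps, comps)
    r["S2", "S1"] <- 0.054   # S1 activates S2
    r["S1", "S2"] <- 0.050   # S2 activates S1
    r["S3", "S2"] <- -0.439  # S2 inhibits S3
    r["S4", "S1"] <- -0.498  # S1 inhibits S4
    r["S4", "S2"] <- -0.580  # S2 inhibits S4
    genes <- paste0("G", 1:10)
    ## regulation weights are calibrated so that the propagated responses of
    ## each downstream component into the upstream estimates are balanced by
    ## the opposite-signed shared-reporter terms: that balance is what makes
    ## the signed edge set exactly identifiable from noise-free data (see
    ## the methods vignette)
    w <- matrix(0, 4, 10, dimnames = list(comps, genes))
    w["S1", "G1"] <- 0.353; w["S2", "G1"] <- 0.121
    w["S1", "G2"] <- 0.357; w["S2", "G2"] <- 0.487
    w["S4", "G3"] <- 0.150
    w["S1", "G4"] <- 0.597; w["S2", "G4"] <- 0.600
    w["S4", "G5"] <- 0.600
    w["S1", "G6"] <- 0.020; w["S2", "G6"] <- 0.290; w["S3", "G6"] <- 0.124
    w["S2", "G7"] <- 0.403; w["S3", "G7"] <- 0.225; w["S4", "G7"] <- 0.129
    w["S3", "G8"] <- 0.599
    w["S3", "G9"] <- -0.216  # the exception: negative regulation
    w["S1", "G10"] <- 0.343
    base <- c(10, 8, 12, 9, 11, 10, 7, 9, 13, 8)
    SyntheticModel(r, w, base,
        noiseFraction = noiseFraction, nRep = nRep, noiseModel = noiseModel)
}

#' True component responses of a synthetic model
#'
#' The linear fixed-point responses: perturbing component j changes its
#' direct activity by \code{p_j = perturbationFold - 1} (relative units),
#' and the change propagates through the interaction network to
#' \code{dS = -r^-1 %*% diag(p)} (column j = response to perturbation j).
#'
#' @param model a \linkS4class{SyntheticModel}.
#' @return an n x n matrix of true activity changes.
#' @export
trueResponses <- function(model) {
    stopifnot(is(model, "SyntheticModel"))
    n <- length(model@components)
    p <- rep(model@perturbationFold - 1, n)
    dS <- -solve(model@interactions) %*% diag(p)
    dimnames(dS) <- list(model@components, model@components)
    dS
}

#' @rdname SyntheticModel-class
#' @param x a \linkS4class{SyntheticModel}.
#' @export
setMethod("interactionCoefficients", "SyntheticModel",
    function(x) x@interactions)

#' True signed edge list of a synthetic model
#'
#' @param model a \linkS4class{SyntheticModel}.
#' @return data.frame with \code{source}, \code{target}, \code{sign} and
#'   \code{coefficient} for every nonzero off-diagonal interaction.
#' @export
trueEdgeTable <- function(model) {
    stopifnot(is(model, "SyntheticModel"))
    r <- model@interactions
    idx <- which(r != 0 & row(r) != col(r), arr.ind = TRUE)
    out <- data.frame(
        source = model@components[idx[, 2]],
        target = model@components[idx[, 1]],
        sign = sign(r[idx]),
        coefficient = r[idx],
        stringsAsFactors = FALSE)
    out[order(out$source, out$target), , drop = FALSE]
}

#' Simulate one perturbation-panel experiment from a synthetic model
#'
#' Computes the linear fixed-point component responses ([trueResponses()]),
#' maps them to condition means \code{mean_jk = baseline_k * (1 + sum_i
#' w[i, k] * dS[i, j])} (floored at a small positive epsilon; clamps are
#' counted in the metadata), draws \code{nRep} noisy replicates per gene
#' and condition, and packages the replicate summaries as a fully valid
#' \linkS4class{PerturbationExperiment}. The raw replicate draws are kept
#' in the metadata so the dataset can be written in the replicates layout.
#' With \code{noiseFraction = 0} every replicate equals its condition mean.
#'
#' @param model a \linkS4class{SyntheticModel}.
#' @param seed integer seed; the same (model, seed) always yields the
#'   identical dataset, and the caller's RNG state is left untouched.
#' @return a \linkS4class{PerturbationExperiment}.
#' @export
simulateExperiment <- function(model, seed = 1L) {
    stopifnot(is(model, "SyntheticModel"))
    n <- length(model@components)
    m <- length(model@genes)
    dS <- trueResponses(model)
    base <- model@baselineGene
    eps <- model@floorEps
    ## condition means: baseline + one column per perturbation
    means <- matrix(0, m, n + 1L,
        dimnames = list(model@genes, c("baseline", model@components)))
    means[, 1] <- base
    clamped <- 0L
    for (j in seq_len(n)) {
        f <- 1 + drop(crossprod(model@regulation, dS[, j]))
        low <- f < eps
        clamped <- clamped + sum(low)
        f[low] <- eps
        means[, j + 1L] <- base * f
    }
    drawn <- .withSeed(seed, {
        lapply(colnames(means), function(cond) {
            mu <- means[, cond]
            reps <- if (model@noiseFraction == 0) {
                matrix(rep(mu, model@nRep), m, model@nRep)
            } else if (model@noiseModel == "gaussian") {
                matrix(rnorm(m * model@nRep, mean = mu,
                    sd = model@noiseFraction * mu), m, model@nRep)
            } else {
                sdlog <- sqrt(log(1 + model@noiseFraction^2))
                matrix(rlnorm(m * model@nRep,
                    meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog),
                    m, model@nRep)
            }
            reps[reps < eps * mu] <- eps * mu[row(reps)[reps < eps * mu]]
            rownames(reps) <- model@genes
            reps
        })
    })
    names(drawn) <- colnames(means)
    panel <- PerturbationPanel(model@components, model@perturbationSign,
        label = paste0("perturbation of ", model@components))
    pe <- perturbationExperimentFromReplicates(drawn, panel,
        baseline = "baseline")
    S4Vectors::metadata(pe)$replicates <- drawn
    S4Vectors::metadata(pe)$seed <- seed
    S4Vectors::metadata(pe)$clampedMeans <- clamped
    S4Vectors::metadata(pe)$trueModel <- list(
        interactions = model@interactions, noiseFraction = model@noiseFraction)
    pe
}

setMethod("show", "SyntheticModel", function(object) {
    cat(sprintf(paste0("SyntheticModel: %d components, %d genes, ",
        "%d%% replicate noise (%s), %d replicates\n"),
        length(object@components), length(object@genes),
        round(100 * object@noiseFraction), object@noiseModel, object@nRep))
    te <- trueEdgeTable(object)
    rel <- ifelse(te$sign > 0, "->(+)", "->(-)")
    cat("  true edges:", paste(sprintf("%s %s %s", te$source, rel,
        te$target), collapse = ", "), "\n")
})
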