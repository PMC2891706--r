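#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats pnorm pt qnorm rnorm rlnorm sd cor setNames
#' @importFrom utils read.table write.table
NULL

#' Perturbation panel: which component each condition perturbs, and how
#'
#' An ordered set of signaling components, each perturbed in exactly one
#' experimental condition, together with the direction of the perturbation
#' (inhibition = -1, activation = +1) and a free-text description of the
#' perturbagen (e.g. the chemical inhibitor used).
#'
#' @slot component character vector of unique component names (length n >= 2).
#' @slot sign integer vector in {-1, +1}; the perturbation direction.
#' @slot label character vector describing each perturbagen.
#'
#' @seealso [PerturbationPanel()] for the constructor,
#'   [PerturbationExperiment] for the dataset the panel annotates.
#' @exportClass PerturbationPanel
setClass("PerturbationPanel",
    representation(
        component = "character",
        sign = "integer",
        label = "character"
    )
)

setValidity("PerturbationPanel", function(object) {
    msg <- NULL
    n <- length(object@component)
    if (n < 2L)
        msg <- c(msg, "a perturbation panel needs at least 2 components")
    if (anyDuplicated(object@component))
        msg <- c(msg, "component names must be unique")
    if (length(object@sign) != n || length(object@label) != n)
        msg <- c(msg, "component, sign and label must have equal length")
    if (!all(object@sign %in% c(-1L, 1L)))
        msg <- c(msg, "every perturbation sign must be -1 or +1")
    if (is.null(msg)) TRUE else msg
})

#' Early-gene perturbation expression dataset
#'
#' A \linkS4class{SummarizedExperiment} subclass holding per-condition
#' replicate summaries of early-gene activity: one unperturbed baseline
#' condition plus one condition per perturbed signaling component. Four
#' assays are required, all genes x conditions:
#' \describe{
#'   \item{\code{activity}}{arithmetic mean of the raw replicate activities
#'     (strictly positive; the unit is whatever the table carries --
#'     fold-change, concentration, copy number -- the algorithm is
#'     unit-agnostic per gene).}
#'   \item{\code{logActivity}}{mean of the natural-log replicate activities.}
#'   \item{\code{logSE}}{standard error of the log activities (sample SD of
#'     logs / sqrt(n replicates)); non-negative.}
#'   \item{\code{nRep}}{replicate count per measurement (>= 2).}
#' }
#' \code{colData} carries \code{condition}, \code{role} ("baseline" or
#' "perturbation"), \code{component}, \code{sign} and \code{label}; exactly
#' one column is the baseline.
#'
#' @seealso [PerturbationExperiment()] (constructor),
#'   [readExpressionTable()], [summarizeReplicates()], [scoreGenes()].
#' @exportClass PerturbationExperiment
setClass("PerturbationExperiment",
    contains = "SummarizedExperiment"
)

setValidity("PerturbationExperiment", function(object) {
    msg <- NULL
    need <- c("activity", "logActivity", "logSE", "nRep")
    have <- SummarizedExperiment::assayNames(object)
    if (!all(need %in% have))
        return(paste("missing assay(s):",
            paste(setdiff(need, have), collapse = ", ")))
    cd <- SummarizedExperiment::colData(object)
    needCols <- c("condition", "role", "component", "sign")
    if (!all(needCols %in% colnames(cd)))
        return(paste("colData must contain:", paste(needCols, collapse = ", ")))
    if (sum(cd$role == "baseline") != 1L)
        msg <- c(msg, "exactly one condition must have role 'baseline'")
    pert <- cd$role == "perturbation"
    if (sum(pert) < 2L)
        msg <- c(msg, "need at least 2 perturbation conditions")
    if (anyDuplicated(cd$component[pert]))
        msg <- c(msg, "perturbed components must be unique")
    if (!all(cd$sign[pert] %in% c(-1L, 1L)))
        msg <- c(msg, "perturbation signs must be -1 or +1")
    act <- SummarizedExperiment::assay(object, "activity")
    if (any(!is.finite(act)) || any(act <= 0))
        msg <- c(msg, "all mean activities must be finite and strictly positive")
    se <- SummarizedExperiment::assay(object, "logSE")
    if (any(!is.finite(se)) || any(se < 0))
        msg <- c(msg, "all log-SEs must be finite and non-negative")
    nr <- SummarizedExperiment::assay(object, "nRep")
    if (any(nr < 2))
        msg <- c(msg, "every measurement needs at least 2 replicates")
    if (is.null(rownames(object)))
        msg <- c(msg, "genes must be named (rownames)")
    if (is.null(msg)) TRUE else msg
})

#' Per-gene score set and weight matrix
#'
#' The three per-gene, per-perturbation scores and the weight matrix derived
#' from them. All matrices are perturbations x genes (n x m):
#' \code{C} (change in activity, baseline minus perturbed), \code{D}
#' (signed, column-normalized activity score), \code{Z} (two-sample log-space
#' Z value), \code{P} (P-score in [0, 1]); \code{info} is the length-m
#' entropy-based information score in [0, ln n]; \code{W} is the final n x m
#' weight matrix, row i holding the gene weights that estimate component i.
#'
#' @seealso [scoreGenes()], [weightMatrix()], [estimateActivity()].
#' @exportClass ScoreSet
setClass("ScoreSet",
    representation(
        C = "matrix", D = "matrix", Z = "matrix", P = "matrix",
        info = "numeric", W = "matrix",
        genes = "character", components = "character",
        params = "list"
    )
)

setValidity("ScoreSet", function(object) {
    msg <- NULL
    n <- length(object@components)
    m <- length(object@genes)
    for (nm in c("C", "D", "Z", "P", "W")) {
        mat <- slot(object, nm)
        if (!identical(dim(mat), c(n, m)))
            msg <- c(msg, sprintf("%s must be %d x %d", nm, n, m))
    }
    if (length(object@info) != m)
        msg <- c(msg, "info must have one entry per gene")
    if (any(object@P < 0 | object@P > 1))
        msg <- c(msg, "P-scores must lie in [0, 1]")
    if (any(object@info < -1e-12 | object@info > log(n) + 1e-12))
        msg <- c(msg, "information scores must lie in [0, ln n]")
    if (is.null(msg)) TRUE else msg
})

#' Estimated signaling-component activities and global responses
#'
#' \code{S} holds the estimated activity of component i (rows) after the
#' perturbation of component j (columns); \code{S0} the estimated unperturbed
#' activities; \code{R = S - S0} (column-wise) is the global response matrix
#' that modular response analysis inverts.
#'
#' @seealso [estimateActivity()], [mra()].
#' @exportClass ActivityEstimate
setClass("ActivityEstimate",
    representation(
        S = "matrix", S0 = "numeric", R = "matrix",
        components = "character"
    )
)

setValidity("ActivityEstimate", function(object) {
    n <- length(object@components)
    msg <- NULL
    if (!identical(dim(object@S), c(n, n)) || !identical(dim(object@R), c(n, n)))
        msg <- c(msg, "S and R must be n x n")
    if (length(object@S0) != n)
        msg <- c(msg, "S0 must have length n")
    if (max(abs(object@R - (object@S - object@S0))) > 1e-8 * (1 + max(abs(object@S))))
        msg <- c(msg, "R must equal S - S0 (column-wise)")
    if (is.null(msg)) TRUE else msg
})

#' Local interaction coefficients (MRA output)
#'
#' \code{coefficients[i, j]} is the local (direct, network-level) effect of
#' component j on component i; the MRA normalization forces the diagonal to
#' exactly -1.
#'
#' @seealso [mra()].
#' @exportClass InteractionMatrix
setClass("InteractionMatrix",
    representation(coefficients = "matrix", components = "character")
)

setValidity("InteractionMatrix", function(object) {
    n <- length(object@components)
    if (!identical(dim(object@coefficients), c(n, n)))
        return("coefficients must be n x n")
    if (!all(diag(object@coefficients) == -1))
        return("diagonal must equal -1 exactly")
    TRUE
})

#' Directed signed edges with jackknife statistics
#'
#' One row per ordered component pair (source -> target), with the
#' resampling distribution of the corresponding interaction coefficient:
#' mean, sample SD, |mean|/SD ratio, the sign, a significance flag from the
#' sign-consistency filter, and the fraction of resamples lost to singular
#' response matrices. \code{samples} is a resamples x n x n array of raw
#' coefficients (NA where a resample failed).
#'
#' @seealso [jackknifeEdges()], [signFilter()], [consensusNetwork()].
#' @exportClass EdgeSet
setClass("EdgeSet",
    representation(
        components = "character",
        samples = "array",
        table = "data.frame",
        alpha = "numeric",
        sides = "numeric",
        params = "list"
    )
)

setValidity("EdgeSet", function(object) {
    n <- length(object@components)
    d <- dim(object@samples)
    msg <- NULL
    if (length(d) != 3L || d[2] != n || d[3] != n)
        msg <- c(msg, "samples must be a resamples x n x n array")
    if (nrow(object@table) != n * (n - 1L))
        msg <- c(msg, "table must have one row per ordered pair")
    need <- c("source", "target", "mean", "sd", "zratio", "sign",
        "significant", "fracMissing", "unresolvable")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, "table is missing required columns")
    if (is.null(msg)) TRUE else msg
})

#' Consensus network across independent experiments
#'
#' Edges retained because they were significant with the same sign in at
#' least K of E independent experiments, with per-edge support counts and
#' per-experiment mean coefficients.
#'
#' @seealso [consensusNetwork()].
#' @exportClass ConsensusNetwork
setClass("ConsensusNetwork",
    representation(
        components = "character",
        K = "integer", E = "integer",
        table = "data.frame",
        perExperiment = "matrix",
        dropped = "data.frame"
    )
)

setValidity("ConsensusNetwork", function(object) {
    msg <- NULL
    if (object@K < 1L || object@K > object@E)
        msg <- c(msg, "K must satisfy 1 <= K <= E")
    need <- c("source", "target", "sign", "support")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, "table is missing required columns")
    if (nrow(object@table) > 0 && any(object@table$support < object@K))
        msg <- c(msg, "every retained edge needs support >= K")
    if (is.null(msg)) TRUE else msg
})

#' Ground-truth synthetic signaling network model
#'
#' A linear model of n signaling components driving m early genes, used to
#' generate benchmark datasets with known topology. \code{interactions} is
#' the true local-coefficient matrix (diagonal -1; entry (i, j) the signed
#' effect of component j on component i); \code{regulation[i, k]} is the
#' signed regulatory weight of component i on gene k; perturbing component j
#' multiplies its direct activity by \code{perturbationFold} and the change
#' propagates to the network's linear fixed point. Replicates are drawn with
#' SD equal to \code{noiseFraction} of the condition mean (Gaussian,
#' truncated at a positive floor, or log-normal with matching CV).
#'
#' @seealso [fourComponentModel()], [simulateExperiment()], [noiseSweep()].
#' @exportClass SyntheticModel
setClass("SyntheticModel",
    representation(
        components = "character",
        genes = "character",
        interactions = "matrix",
        regulation = "matrix",
        baselineGene = "numeric",
        perturbationFold = "numeric",
        perturbationSign = "integer",
        noiseFraction = "numeric",
        noiseModel = "character",
        nRep = "integer",
        floorEps = "numeric"
    )
)

setValidity("SyntheticModel", function(object) {
    msg <- NULL
    n <- length(object@components)
    m <- length(object@genes)
    if (!identical(dim(object@interactions), c(n, n)))
        msg <- c(msg, "interactions must be n x n")
    else {
        if (!all(diag(object@interactions) == -1))
            msg <- c(msg, "interaction diagonal must be -1")
        a <- object@interactions + diag(n)
        if (max(Mod(eigen(a, only.values = TRUE)$values)) >= 1)
            msg <- c(msg, "unstable component network (spectral radius >= 1)")
    }
    if (!identical(dim(object@regulation), c(n, m)))
        msg <- c(msg, "regulation must be n x m")
    else if (any(colSums(object@regulation != 0) == 0))
        msg <- c(msg, "every gene must be regulated by at least one component")
    if (length(object@baselineGene) != m || any(object@baselineGene <= 0))
        msg <- c(msg, "baseline gene activities must be positive, one per gene")
    if (object@noiseFraction < 0)
        msg <- c(msg, "noiseFraction must be >= 0")
    if (!object@noiseModel %in% c("gaussian", "lognormal"))
        msg <- c(msg, "noiseModel must be 'gaussian' or 'lognormal'")
    if (object@nRep < 2L)
        msg <- c(msg, "nRep must be >= 2")
    if (object@perturbationFold <= 0 || object@perturbationFold == 1)
        msg <- c(msg, "perturbationFold must be positive and != 1")
    if (!all(object@perturbationSign %in% c(-1L, 1L)) ||
        length(object@perturbationSign) != n)
        msg <- c(msg, "perturbationSign must be -1/+1, one per component")
    if (is.null(msg)) TRUE else msg
})

#' Similarity of an inferred network to the generating truth
#'
#' \code{signScore} is the fraction of ordered component pairs whose inferred
#' status (absent / positive / negative) matches the truth; \code{valueScore}
#' is the Pearson correlation between inferred and true coefficient values
#' over the pairs where the truth has an edge (NA when undefined).
#'
#' @seealso [networkSimilarity()].
#' @exportClass SimilarityReport
setClass("SimilarityReport",
    representation(
        signScore = "numeric",
        valueScore = "numeric",
        table = "data.frame"
    )
)

setValidity("SimilarityReport", function(object) {
    if (object@signScore < 0 || object@signScore > 1)
        return("signScore must lie in [0, 1]")
    TRUE
})
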