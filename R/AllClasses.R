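#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors SimpleList
#' @importFrom stats cor phyper prcomp rgamma rlnorm rnorm runif setNames
#' @importFrom utils packageVersion read.delim write.table
NULL

.COMPOSITION_TOL <- 1e-9

#' CytologyTable: compositional substage frequencies per sample
#'
#' Holds the substage-by-sample matrix of cell-type proportions scored from
#' immunolabeled chromatin spreads (the cytology block of the covariance
#' analysis). Each sample column is compositional: proportions of scored germ
#' cells summing to 1. Optionally carries the underlying integer cell counts.
#'
#' @slot frequencies numeric matrix, substages (rows) x samples (columns),
#'   entries in \[0, 1\], every column summing to 1 within 1e-9.
#' @slot counts integer matrix of scored cells with the same dimensions, or a
#'   0x0 matrix when counts were not recorded.
#'
#' @seealso [frequencyTable()], [mergeSubstages()], [simulateCytology()]
#' @export
setClass("CytologyTable",
    representation(frequencies = "matrix", counts = "matrix"),
    prototype(frequencies = matrix(numeric(0), 0, 0),
              counts = matrix(integer(0), 0, 0)))

setValidity("CytologyTable", function(object) {
    f <- object@frequencies
    msg <- character(0)
    if (is.null(rownames(f)) || is.null(colnames(f)))
        msg <- c(msg, "frequencies must have substage rownames and sample colnames")
    if (anyDuplicated(rownames(f)) || anyDuplicated(colnames(f)))
        msg <- c(msg, "substage and sample ids must be unique")
    if (length(f) && (any(!is.finite(f)) || any(f < 0) || any(f > 1)))
        msg <- c(msg, "frequencies must be finite and in [0, 1]")
    if (ncol(f) && any(abs(colSums(f) - 1) > .COMPOSITION_TOL))
        msg <- c(msg, "every sample column of frequencies must sum to 1 (tol 1e-9)")
    cnt <- object@counts
    if (length(cnt)) {
        if (!identical(dim(cnt), dim(f)))
            msg <- c(msg, "counts must match the dimensions of frequencies")
        else if (any(cnt < 0) || any(cnt != round(cnt)))
            msg <- c(msg, "counts must be non-negative integers")
        else {
            tot <- colSums(cnt)
            if (any(tot == 0))
                msg <- c(msg, "every sample must have at least one scored cell")
            else if (max(abs(sweep(cnt, 2, tot, "/") - f)) > 1e-8)
                msg <- c(msg, "frequencies must equal counts / column totals")
        }
    }
    if (length(msg)) msg else TRUE
})

#' ExpressionMatrix: gene-by-sample expression values
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] holding one assay of
#' gene-by-sample expression values together with the scale they are on:
#' `"tpm"` (transcripts per million, non-negative) or `"log2_tpm_plus1"`
#' (after `log2(TPM + 1)`).
#'
#' @slot scale character, `"tpm"` or `"log2_tpm_plus1"`.
#' @seealso [readExpression()], [filterExpressed()], [logTransform()]
#' @export
setClass("ExpressionMatrix",
    contains = "SummarizedExperiment",
    representation(scale = "character"),
    prototype(scale = "tpm"))

setValidity("ExpressionMatrix", function(object) {
    msg <- character(0)
    if (length(object@scale) != 1L ||
        !object@scale %in% c("tpm", "log2_tpm_plus1"))
        msg <- c(msg, "scale must be 'tpm' or 'log2_tpm_plus1'")
    v <- exprValues(object)
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must have gene rownames and sample colnames")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicate sample ids")
    if (length(v) && any(!is.finite(v)))
        msg <- c(msg, "values must be finite")
    if (length(v) && identical(object@scale, "tpm") && any(v < 0))
        msg <- c(msg, "TPM values must be >= 0")
    if (length(msg)) msg else TRUE
})

#' CovarianceDecomposition: SVD of the cytology-expression cross-covariance
#'
#' Stores the substage-by-gene cross-covariance matrix
#' `C = (1/n) X~ Y~^T` of the row-centered cytology (`X~`) and expression
#' (`Y~`) blocks, its singular value decomposition `C = U S V^T`, and the
#' projection basis `P_x = U^T X~` (component-by-sample) onto which both
#' blocks are projected to form patterns. With a compositional cytology
#' matrix one degree of freedom is lost, so at most `n_substages - 1`
#' components are usable.
#'
#' @slot covariance numeric matrix, substage x gene.
#' @slot u numeric matrix of left singular vectors (substage x component).
#' @slot sigma numeric vector of singular values, non-increasing.
#' @slot v numeric matrix of right singular vectors (gene x component).
#' @slot px numeric matrix, component x sample projection basis.
#' @slot nComponentsUsable integer count of non-negligible components.
#' @seealso [pmcaDecompose()], [projectPatterns()]
#' @export
setClass("CovarianceDecomposition",
    representation(covariance = "matrix", u = "matrix", sigma = "numeric",
                   v = "matrix", px = "matrix",
                   nComponentsUsable = "integer"))

setValidity("CovarianceDecomposition", function(object) {
    msg <- character(0)
    d <- object@sigma
    if (length(d) && (any(d < -1e-12) || is.unsorted(-d)))
        msg <- c(msg, "singular values must be non-negative and non-increasing")
    if (nrow(object@u) != nrow(object@covariance))
        msg <- c(msg, "u must have one row per substage")
    if (length(object@nComponentsUsable) != 1L ||
        object@nComponentsUsable < 0L ||
        object@nComponentsUsable > length(d))
        msg <- c(msg, "nComponentsUsable out of range")
    if (length(msg)) msg else TRUE
})

#' PatternMatrices: RMS-normalized cyto- and gene-patterns
#'
#' Projections of the cytology and expression blocks onto the covariance
#' components: `Z_x` (substage x component, the cyto-patterns) and `Z_y`
#' (gene x component, the gene patterns). When `normalized`, every non-zero
#' row has been divided by its root mean square with divisor
#' `n_substages - 1`, so its sum of squares equals `n_substages - 1`.
#' Rows that are exactly zero (zero-variance genes) are left as zeros and
#' listed in `zeroRows`; they are excluded from window matching.
#'
#' @slot zx numeric matrix, substage x component cyto-patterns.
#' @slot zy numeric matrix, gene x component gene patterns.
#' @slot normalized logical flag.
#' @slot zeroRows character vector of gene ids with all-zero patterns.
#' @slot nComponentsUsable integer, inherited from the decomposition.
#' @seealso [projectPatterns()], [matchPatterns()]
#' @export
setClass("PatternMatrices",
    representation(zx = "matrix", zy = "matrix", normalized = "logical",
                   zeroRows = "character", nComponentsUsable = "integer"))

setValidity("PatternMatrices", function(object) {
    msg <- character(0)
    if (ncol(object@zx) != ncol(object@zy))
        msg <- c(msg, "zx and zy must have the same number of components")
    ## the RMS identity applies to the pipeline's square substage projection
    if (isTRUE(object@normalized) && nrow(object@zx) &&
        ncol(object@zx) == nrow(object@zx)) {
        target <- nrow(object@zx) - 1
        ss <- rowSums(object@zx^2)
        bad <- abs(ss - target) > 1e-8 & ss > 1e-16
        if (any(bad))
            msg <- c(msg, "normalized zx rows must have sum of squares n_substages - 1")
    }
    if (length(msg)) msg else TRUE
})

#' AssignmentResult: per-gene substage assignments
#'
#' Window-matching outcome of the PMCA pipeline. A gene is *concordant* with
#' a substage when its normalized pattern lies within `width` of the
#' substage's cyto-pattern on every component up to `depth`, and *negatively
#' concordant* when it lies within `width` of the negated cyto-pattern.
#' Similarity scores (negative truncated Euclidean distance; 0 means
#' identical patterns) are recorded for ranking within lists.
#'
#' @slot concordant logical gene x substage matrix.
#' @slot negative logical gene x substage matrix.
#' @slot similarity numeric gene x substage matrix of scores against the
#'   cyto-patterns.
#' @slot negativeSimilarity numeric gene x substage matrix of scores against
#'   the negated cyto-patterns.
#' @slot depth integer number of components used.
#' @slot width numeric window width on the normalized pattern scale.
#' @slot excluded character vector of gene ids excluded from matching
#'   (all-zero patterns).
#' @seealso [matchPatterns()], [combinationLists()], [assignmentTable()]
#' @export
setClass("AssignmentResult",
    representation(concordant = "matrix", negative = "matrix",
                   similarity = "matrix", negativeSimilarity = "matrix",
                   depth = "integer", width = "numeric",
                   excluded = "character"))

setValidity("AssignmentResult", function(object) {
    msg <- character(0)
    if (!is.logical(object@concordant) || !is.logical(object@negative))
        msg <- c(msg, "concordant and negative must be logical matrices")
    if (!identical(dim(object@concordant), dim(object@negative)))
        msg <- c(msg, "concordant and negative must have equal dimensions")
    if (length(object@width) != 1L || object@width <= 0)
        msg <- c(msg, "width must be a single positive number")
    if (length(object@depth) != 1L || object@depth < 1L)
        msg <- c(msg, "depth must be a positive integer")
    if (length(msg)) msg else TRUE
})

#' WidthSelectionReport: permutation-calibrated window-width choice
#'
#' Grid of estimated false positive rates (FPR) per candidate width and
#' component depth, together with the chosen width: the largest candidate
#' whose FPR at component `jStar` is at most `alpha`. The FPR at a width and
#' depth is the expected fraction of genes receiving any assignment (either
#' polarity, any substage) when expression sample labels are permuted,
#' destroying the cytology-expression covariance.
#'
#' @slot candidateWidths ascending numeric vector of widths.
#' @slot fpr numeric matrix, candidate width (rows) x component depth
#'   (columns), values in \[0, 1\].
#' @slot chosenWidth numeric, the selected width.
#' @slot nPermutations integer.
#' @slot seed integer seed used for the permutations.
#' @slot alpha numeric FPR bound stipulated at component `jStar`.
#' @slot jStar integer component index at which `alpha` is stipulated.
#' @seealso [selectWidth()], [estimateFpr()]
#' @export
setClass("WidthSelectionReport",
    representation(candidateWidths = "numeric", fpr = "matrix",
                   chosenWidth = "numeric", nPermutations = "integer",
                   seed = "integer", alpha = "numeric", jStar = "integer"))

setValidity("WidthSelectionReport", function(object) {
    msg <- character(0)
    f <- object@fpr
    if (any(f < 0) || any(f > 1))
        msg <- c(msg, "fpr values must be in [0, 1]")
    if (nrow(f) != length(object@candidateWidths))
        msg <- c(msg, "fpr must have one row per candidate width")
    if (is.unsorted(object@candidateWidths, strictly = TRUE))
        msg <- c(msg, "candidateWidths must be strictly ascending")
    ## cumulative filtering only removes genes; wider windows only add them
    if (ncol(f) > 1 && any(f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE] > 1e-12))
        msg <- c(msg, "fpr must be non-increasing in component depth")
    if (nrow(f) > 1 && any(f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE] < -1e-12))
        msg <- c(msg, "fpr must be non-decreasing in width")
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic first-wave generator
#'
#' Describes the simulated study: a compositional cytology matrix following
#' first-wave developmental trajectories (an early-dominant, declining
#' spermatogonia-like row; late substages absent early) and a bulk
#' expression matrix produced by mixing per-substage expression programs by
#' composition, with planted concordant and negatively concordant genes and
#' multiplicative log-normal noise.
#'
#' @slot nSubstages integer, number of (merged) substage rows.
#' @slot nSamples integer, number of samples.
#' @slot nTimepoints integer, number of developmental time points over which
#'   samples are spread as replicates.
#' @slot nGenes integer, total genes.
#' @slot genesPerSubstage integer, planted concordant genes per substage.
#' @slot negGenesPerSubstage integer, planted negatively concordant genes per
#'   substage.
#' @slot effectSize numeric > 1, fold elevation of a planted gene's program
#'   in (or, for negative planting, outside) its target substage.
#' @slot noiseSd numeric >= 0, standard deviation of the multiplicative
#'   log-normal noise on the natural-log scale.
#' @slot compositionConcentration numeric, Dirichlet concentration of
#'   replicate jitter around the time-point mean composition.
#' @slot rnaContent numeric vector of per-substage relative RNA content
#'   scale factors (default all 1).
#' @slot seed integer.
#' @seealso [simulationConfig()], [simulateCytology()], [simulateExpression()]
#' @export
setClass("SimulationConfig",
    representation(nSubstages = "integer", nSamples = "integer",
                   nTimepoints = "integer", nGenes = "integer",
                   genesPerSubstage = "integer",
                   negGenesPerSubstage = "integer",
                   effectSize = "numeric", noiseSd = "numeric",
                   compositionConcentration = "numeric",
                   rnaContent = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    pos <- c(nSubstages = object@nSubstages, nSamples = object@nSamples,
             nTimepoints = object@nTimepoints, nGenes = object@nGenes)
    if (any(pos < 1L))
        msg <- c(msg, "all size parameters must be positive")
    if (object@genesPerSubstage < 0L || object@negGenesPerSubstage < 0L)
        msg <- c(msg, "planted gene counts must be non-negative")
    if ((object@genesPerSubstage + object@negGenesPerSubstage) *
        object@nSubstages > object@nGenes)
        msg <- c(msg, "planted genes exceed nGenes")
    if (object@effectSize <= 1)
        msg <- c(msg, "effectSize must be > 1")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (object@compositionConcentration <= 0)
        msg <- c(msg, "compositionConcentration must be > 0")
    if (length(object@rnaContent) != object@nSubstages ||
        any(object@rnaContent <= 0))
        msg <- c(msg, "rnaContent must be positive, one entry per substage")
    if (length(msg)) msg else TRUE
})

#' GroundTruth: planted assignments of a simulated expression matrix
#'
#' @slot concordant logical gene x substage matrix of planted concordant
#'   assignments.
#' @slot negative logical gene x substage matrix of planted negatively
#'   concordant assignments.
#' @slot program numeric gene x substage matrix of expected per-substage
#'   expression (TPM scale) before mixing and noise.
#' @seealso [simulateExpression()], [scoreRecovery()]
#' @export
setClass("GroundTruth",
    representation(concordant = "matrix", negative = "matrix",
                   program = "matrix"))

setValidity("GroundTruth", function(object) {
    msg <- character(0)
    if (!identical(dim(object@concordant), dim(object@negative)) ||
        !identical(dim(object@concordant), dim(object@program)))
        msg <- c(msg, "concordant, negative and program must share dimensions")
    if (length(msg)) msg else TRUE
})
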