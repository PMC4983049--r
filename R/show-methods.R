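setMethod("show", "CytologyTable", function(object) {
    f <- object@frequencies
    cat("CytologyTable:", nrow(f), "substages x", ncol(f), "samples",
        if (length(object@counts)) "(with cell counts)" else "", "\n")
    cat("  substages:", paste(rownames(f), collapse = ", "), "\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object),
        "samples on scale '", object@scale, "'\n", sep = " ")
})

setMethod("show", "CovarianceDecomposition", function(object) {
    cat("CovarianceDecomposition:", nrow(object@covariance), "substages x",
        ncol(object@covariance), "genes\n")
    cat("  singular values:",
        paste(signif(object@sigma, 4), collapse = ", "), "\n")
    cat("  usable components:", object@nComponentsUsable, "\n")
})

setMethod("show", "PatternMatrices", function(object) {
    cat("PatternMatrices:", nrow(object@zx), "cyto-patterns,",
        nrow(object@zy), "gene patterns,", ncol(object@zx), "components",
        if (isTRUE(object@normalized)) "(RMS-normalized)" else "(raw)", "\n")
    if (length(object@zeroRows))
        cat("  zero-pattern genes excluded from matching:",
            length(object@zeroRows), "\n")
})

setMethod("show", "AssignmentResult", function(object) {
    cat("AssignmentResult: width", signif(object@width, 4), ", depth",
        object@depth, "\n")
    cat("  concordant genes:", sum(rowSums(object@concordant) > 0),
        "| negatively concordant:", sum(rowSums(object@negative) > 0),
        "| excluded:", length(object@excluded), "\n")
})

setMethod("show", "WidthSelectionReport", function(object) {
    cat("WidthSelectionReport:", length(object@candidateWidths),
        "candidate widths,", object@nPermutations, "permutations\n")
    cat(sprintf("  chosen width %.6g (FPR <= %g at component %d); seed %d\n",
                object@chosenWidth, object@alpha, object@jStar,
                object@seed))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nSubstages, "substages x",
        object@nSamples, "samples (", object@nTimepoints, "time points ),",
        object@nGenes, "genes\n")
    cat("  planted per substage:", object@genesPerSubstage, "concordant /",
        object@negGenesPerSubstage, "negatively concordant; effect size",
        object@effectSize, "; noise sd", object@noiseSd, "\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", sum(object@concordant), "planted concordant and",
        sum(object@negative), "planted negatively concordant assignments\n")
})
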