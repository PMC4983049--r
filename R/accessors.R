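#' @describeIn CytologyTable-class substage-by-sample proportion matrix.
#' @export
setMethod("frequencies", "CytologyTable", function(object) object@frequencies)

#' @describeIn CytologyTable-class integer cell counts, or NULL when absent.
#' @export
setMethod("cellCounts", "CytologyTable", function(object) {
    if (length(object@counts)) object@counts else NULL
})

#' @describeIn CytologyTable-class substage labels in developmental order.
#' @export
setMethod("substageIds", "CytologyTable",
          function(object) rownames(object@frequencies))

#' @describeIn CytologyTable-class sample ids.
#' @export
setMethod("sampleIds", "CytologyTable",
          function(object) colnames(object@frequencies))

#' @describeIn CytologyTable-class number of substage rows.
#' @export
setMethod("nrow", "CytologyTable", function(x) nrow(x@frequencies))

#' @describeIn CytologyTable-class number of sample columns.
#' @export
setMethod("ncol", "CytologyTable", function(x) ncol(x@frequencies))

#' @describeIn ExpressionMatrix-class the gene-by-sample value matrix.
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(object) SummarizedExperiment::assay(object, "expr"))

#' @describeIn ExpressionMatrix-class `"tpm"` or `"log2_tpm_plus1"`.
#' @export
setMethod("exprScale", "ExpressionMatrix", function(object) object@scale)

#' @describeIn ExpressionMatrix-class gene ids.
#' @export
setMethod("geneIds", "ExpressionMatrix", function(object) rownames(object))

#' @describeIn ExpressionMatrix-class sample ids.
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(object) colnames(object))

#' @describeIn CovarianceDecomposition-class singular values, descending.
#' @export
setMethod("singularValues", "CovarianceDecomposition",
          function(object) object@sigma)

#' @describeIn CovarianceDecomposition-class the component-by-sample
#'   projection basis `P_x = U^T X~`.
#' @export
setMethod("projectionBasis", "CovarianceDecomposition",
          function(object) object@px)

#' @describeIn CovarianceDecomposition-class number of non-negligible
#'   components (at most one less than the number of substages).
#' @export
setMethod("nComponentsUsable", "CovarianceDecomposition",
          function(object) object@nComponentsUsable)

#' @describeIn PatternMatrices-class substage-by-component cyto-patterns.
#' @export
setMethod("cytoPatterns", "PatternMatrices", function(object) object@zx)

#' @describeIn PatternMatrices-class gene-by-component patterns.
#' @export
setMethod("genePatterns", "PatternMatrices", function(object) object@zy)

#' @describeIn PatternMatrices-class usable component count.
#' @export
setMethod("nComponentsUsable", "PatternMatrices",
          function(object) object@nComponentsUsable)

#' @describeIn AssignmentResult-class named list mapping each gene to the
#'   character vector of substages it is concordant with (unassigned genes
#'   map to an empty vector).
#' @export
setMethod("concordantSets", "AssignmentResult", function(object) {
    .rowsToSets(object@concordant)
})

#' @describeIn AssignmentResult-class as `concordantSets`, for negative
#'   concordance.
#' @export
setMethod("negativeSets", "AssignmentResult", function(object) {
    .rowsToSets(object@negative)
})

.rowsToSets <- function(m) {
    labs <- colnames(m)
    out <- apply(m, 1L, function(r) labs[r], simplify = FALSE)
    names(out) <- rownames(m)
    out
}

#' @describeIn WidthSelectionReport-class the selected window width.
#' @export
setMethod("chosenWidth", "WidthSelectionReport",
          function(object) object@chosenWidth)

#' @describeIn WidthSelectionReport-class width-by-depth FPR matrix.
#' @export
setMethod("fprGrid", "WidthSelectionReport", function(object) object@fpr)
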