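#' @rdname CytologyTable-class
#' @param object,x an object.
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname CytologyTable-class
#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))

#' @rdname CytologyTable-class
#' @export
setGeneric("substageIds", function(object) standardGeneric("substageIds"))

#' Sample identifiers of a pmca object
#' @param object a [CytologyTable-class] or [ExpressionMatrix-class].
#' @return character vector of sample ids in stored order.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname ExpressionMatrix-class
#' @param object an object.
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprScale", function(object) standardGeneric("exprScale"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname CovarianceDecomposition-class
#' @param object an object.
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' @rdname CovarianceDecomposition-class
#' @export
setGeneric("projectionBasis", function(object) standardGeneric("projectionBasis"))

#' @rdname CovarianceDecomposition-class
#' @export
setGeneric("nComponentsUsable", function(object) standardGeneric("nComponentsUsable"))

#' @rdname PatternMatrices-class
#' @param object an object.
#' @export
setGeneric("cytoPatterns", function(object) standardGeneric("cytoPatterns"))

#' @rdname PatternMatrices-class
#' @export
setGeneric("genePatterns", function(object) standardGeneric("genePatterns"))

#' @rdname AssignmentResult-class
#' @param object an object.
#' @export
setGeneric("concordantSets", function(object) standardGeneric("concordantSets"))

#' @rdname AssignmentResult-class
#' @export
setGeneric("negativeSets", function(object) standardGeneric("negativeSets"))

#' @rdname WidthSelectionReport-class
#' @param object an object.
#' @export
setGeneric("chosenWidth", function(object) standardGeneric("chosenWidth"))

#' @rdname WidthSelectionReport-class
#' @export
setGeneric("fprGrid", function(object) standardGeneric("fprGrid"))
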