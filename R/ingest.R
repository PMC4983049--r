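## Expression matrix I/O, detection filtering, log transform, and
## sample alignment between the expression and cytology blocks.

#' Construct an ExpressionMatrix
#'
#' @param values numeric gene-by-sample matrix with dimnames.
#' @param scale `"tpm"` or `"log2_tpm_plus1"`.
#' @return an [ExpressionMatrix-class].
#' @export
ExpressionMatrix <- function(values, scale = "tpm") {
    storage.mode(values) <- "double"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(expr = values))
    new("ExpressionMatrix", se, scale = scale)
}

#' Read and write expression matrices
#'
#' Tab-separated gene-by-sample matrix: header row of sample ids, first
#' column of gene ids. Values read as TPM.
#'
#' @param path file path.
#' @return `readExpression` returns an [ExpressionMatrix-class] with
#'   `exprScale(.) == "tpm"`, row and column order preserved from the file;
#'   `writeExpression` invisibly returns `path`.
#' @export
readExpression <- function(path) {
    df <- tryCatch(
        read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
        warning = function(w) stop("malformed expression file ", path, ": ",
                                   conditionMessage(w), call. = FALSE))
    if (ncol(df) < 2L)
        stop("expression file must have a gene column and >= 1 sample column",
             call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric expression values in ", path, call. = FALSE)
    rownames(m) <- as.character(df[[1L]])
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene id(s) in ", path, ": ",
             paste(unique(rownames(m)[duplicated(rownames(m))]),
                   collapse = ", "), call. = FALSE)
    ExpressionMatrix(m, scale = "tpm")
}

#' @rdname readExpression
#' @param m an [ExpressionMatrix-class].
#' @export
writeExpression <- function(m, path) {
    v <- exprValues(m)
    df <- data.frame(gene_id = rownames(v),
                     format(v, digits = 10, trim = TRUE),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.requireScale <- function(m, scale, op) {
    if (!identical(exprScale(m), scale))
        stop(op, " requires values on the '", scale, "' scale (got '",
             exprScale(m), "')", call. = FALSE)
}

#' Detection filter on the TPM scale
#'
#' Keeps exactly the genes whose maximum TPM across samples reaches
#' `tpmMin` (inclusive) in at least one sample; gene order is preserved.
#' Applied before the log transform, on raw TPM.
#'
#' @param m an [ExpressionMatrix-class] on the `"tpm"` scale.
#' @param tpmMin detection threshold (default 3).
#' @return the filtered [ExpressionMatrix-class].
#' @export
filterExpressed <- function(m, tpmMin = 3) {
    .requireScale(m, "tpm", "filterExpressed")
    keep <- apply(exprValues(m), 1L, max) >= tpmMin
    m[keep, ]
}

#' log2(TPM + 1) transform
#'
#' @param m an [ExpressionMatrix-class] on the `"tpm"` scale.
#' @return an [ExpressionMatrix-class] on the `"log2_tpm_plus1"` scale.
#' @export
logTransform <- function(m) {
    .requireScale(m, "tpm", "logTransform")
    out <- ExpressionMatrix(log2(exprValues(m) + 1),
                            scale = "log2_tpm_plus1")
    out
}

#' Align samples between expression and cytology data
#'
#' Restricts both blocks to their shared sample ids, minus an explicit
#' exclusion list, in a common order (the expression matrix's order).
#' Outlier samples (e.g. failed libraries) are removed by naming them in
#' `exclude`; ids in `exclude` absent from both blocks raise a warning but
#' are not fatal.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param cyto a [CytologyTable-class].
#' @param exclude character vector of sample ids to drop.
#' @return list with elements `expression` and `cytology`, sample-aligned.
#' @export
alignSamples <- function(expr, cyto, exclude = character(0)) {
    es <- sampleIds(expr)
    cs <- sampleIds(cyto)
    unknown <- setdiff(exclude, union(es, cs))
    if (length(unknown))
        warning("exclusion id(s) not present in either block: ",
                paste(unknown, collapse = ", "), call. = FALSE)
    shared <- setdiff(intersect(es, cs), exclude)
    if (!length(shared))
        stop("no shared samples remain after exclusions", call. = FALSE)
    shared <- es[es %in% shared]      # expression order
    list(expression = expr[, shared],
         cytology = CytologyTable(
             frequencies(cyto)[, shared, drop = FALSE],
             counts = if (is.null(cellCounts(cyto))) NULL
                      else cellCounts(cyto)[, shared, drop = FALSE]))
}
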