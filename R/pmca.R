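## Maximum covariance analysis core: row centering, cross-covariance, SVD,
## pattern projection with RMS normalization, and window-based matching of
## gene patterns to substage cyto-patterns.

.RANK_TOL <- 1e-8

#' Subtract each row's mean
#'
#' Centers every row of a matrix across samples, the first step of the
#' covariance analysis. Requires at least two columns (a single sample
#' carries no covariance information).
#'
#' @param m numeric matrix.
#' @return matrix of the same shape with zero row means.
#' @export
centerRows <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) < 2L)
        stop("centerRows requires >= 2 columns", call. = FALSE)
    m - rowMeans(m)
}

#' Cross-covariance of the centered cytology and expression blocks
#'
#' `C = (1/n) X~ Y~^T`, where `X~` (substage x sample) and `Y~` (gene x
#' sample) are the row-centered blocks sharing `n` sample columns. The
#' result is substage x gene: entry (i, k) is the sample covariance of
#' substage i's frequency with gene k's expression.
#'
#' @param xCentered row-centered substage-by-sample matrix.
#' @param yCentered row-centered gene-by-sample matrix.
#' @return substage-by-gene covariance matrix.
#' @export
crossCovariance <- function(xCentered, yCentered) {
    if (ncol(xCentered) != ncol(yCentered))
        stop("xCentered and yCentered must share the sample dimension",
             call. = FALSE)
    tcrossprod(xCentered, yCentered) / ncol(xCentered)
}

#' Singular value decomposition of the cross-covariance
#'
#' Full SVD `C = U S V^T` plus the projection basis `P_x = U^T X~`. Columns
#' of `U` are deterministically oriented so each column's largest-magnitude
#' entry is positive (`V` flipped in step), making outputs reproducible;
#' downstream matching is invariant to these signs. When the raw cytology
#' columns each sum to a common constant, row-centering leaves the column
#' sums of `X~` at zero, so `C` loses one degree of freedom: at most
#' `n_substages - 1` singular values are non-negligible.
#'
#' @param c substage-by-gene covariance matrix.
#' @param xCentered the row-centered cytology block (same row count as `c`).
#' @return a [CovarianceDecomposition-class].
#' @export
pmcaDecompose <- function(c, xCentered) {
    if (nrow(c) != nrow(xCentered))
        stop("covariance and xCentered must have the same number of rows",
             call. = FALSE)
    sv <- svd(c, nu = nrow(c), nv = min(dim(c)))
    u <- sv$u
    v <- sv$v
    for (j in seq_len(ncol(u))) {      # orient: largest |entry| positive
        i <- which.max(abs(u[, j]))
        if (u[i, j] < 0) {
            u[, j] <- -u[, j]
            if (j <= ncol(v)) v[, j] <- -v[, j]
        }
    }
    d <- c(sv$d, numeric(ncol(u)))[seq_len(ncol(u))]  # pad if cols < rows
    usable <- min(sum(d > .RANK_TOL * d[1L]), nrow(c) - 1L)
    px <- crossprod(u, xCentered)
    dimnames(px) <- list(paste0("C", seq_len(nrow(px))), colnames(xCentered))
    rownames(u) <- rownames(c)
    rownames(v) <- colnames(c)
    new("CovarianceDecomposition", covariance = c, u = u, sigma = d, v = v,
        px = px, nComponentsUsable = as.integer(usable))
}

#' Project both blocks onto the covariance components
#'
#' Computes the cyto-patterns `Z_x = X P_x^T` (substage x component) and
#' gene patterns `Z_y = Y P_x^T` (gene x component), then divides every row
#' by its root mean square with divisor `n_substages - 1`, so each non-zero
#' normalized row has sum of squares `n_substages - 1` and patterns are
#' directly comparable. By default the centered blocks are projected
#' (`useCentered = TRUE`), which preserves the sign symmetry that defines
#' negative concordance; `useCentered = FALSE` projects the raw matrices.
#' Rows that are exactly zero (zero-variance genes) are left as zeros and
#' flagged for exclusion from matching.
#'
#' @param x substage-by-sample cytology matrix (raw scale).
#' @param y gene-by-sample expression matrix (raw scale).
#' @param decomp a [CovarianceDecomposition-class].
#' @param useCentered logical; project row-centered blocks (default TRUE).
#' @param normalize logical; apply the RMS normalization (default TRUE).
#' @return a [PatternMatrices-class].
#' @export
projectPatterns <- function(x, y, decomp, useCentered = TRUE,
                            normalize = TRUE) {
    px <- projectionBasis(decomp)
    x <- as.matrix(x); y <- as.matrix(y)
    if (ncol(x) != ncol(px) || ncol(y) != ncol(px))
        stop("sample dimension of x/y does not match the projection basis",
             call. = FALSE)
    if (useCentered) {
        x <- centerRows(x)
        y <- centerRows(y)
    }
    zx <- tcrossprod(x, px)
    zy <- tcrossprod(y, px)
    zero <- character(0)
    if (normalize) {
        div <- nrow(x) - 1L
        normRows <- function(z) {
            ss <- rowSums(z^2)
            rms <- sqrt(ss / div)
            nz <- ss > 0
            z[nz, ] <- z[nz, , drop = FALSE] / rms[nz]
            list(z = z, zero = rownames(z)[!nz])
        }
        nx <- normRows(zx); zx <- nx$z
        ny <- normRows(zy); zy <- ny$z
        zero <- ny$zero
    }
    new("PatternMatrices", zx = zx, zy = zy, normalized = normalize,
        zeroRows = zero, nComponentsUsable = nComponentsUsable(decomp))
}

#' Similarity score between a gene pattern and a cyto-pattern
#'
#' Negative Euclidean distance over the first `depth` components: 0 iff the
#' truncated patterns are identical, more negative the further apart. Used
#' only to rank genes within an assignment list; any strictly decreasing
#' function of the distance ranks identically.
#'
#' @param genePattern,cytoPattern numeric component vectors of length >=
#'   `depth`.
#' @param depth number of leading components scored.
#' @return a single non-positive number.
#' @export
similarityScore <- function(genePattern, cytoPattern, depth) {
    stopifnot(depth >= 1L, length(genePattern) >= depth,
              length(cytoPattern) >= depth)
    j <- seq_len(depth)
    -sqrt(sum((genePattern[j] - cytoPattern[j])^2))
}

#' Window matching of gene patterns to substage cyto-patterns
#'
#' Gene k is *concordant* with substage i iff
#' `|z_y[k, j] - z_x[i, j]| <= width` for every component `j = 1..depth`,
#' and *negatively concordant* iff `|z_y[k, j] + z_x[i, j]| <= width` for
#' every such `j`. Matching is cumulative: all components up to `depth`
#' must pass, so lists get finer as depth grows. A gene may match several
#' substages. Genes flagged as zero-pattern are never matched.
#'
#' @param patterns a normalized [PatternMatrices-class].
#' @param width positive window width on the normalized pattern scale.
#' @param depth number of leading components that must pass
#'   (1 <= depth <= `nComponentsUsable(patterns)`).
#' @return an [AssignmentResult-class].
#' @export
matchPatterns <- function(patterns, width, depth = nComponentsUsable(patterns)) {
    stopifnot(is(patterns, "PatternMatrices"))
    if (!isTRUE(patterns@normalized))
        stop("matchPatterns requires normalized patterns", call. = FALSE)
    if (length(width) != 1L || !is.finite(width) || width <= 0)
        stop("width must be a single positive number", call. = FALSE)
    nUse <- nComponentsUsable(patterns)
    if (depth < 1L || depth > nUse)
        stop("depth must be in 1..", nUse, call. = FALSE)
    zx <- cytoPatterns(patterns)
    zy <- genePatterns(patterns)
    j <- seq_len(depth)
    nGenes <- nrow(zy); nSub <- nrow(zx)
    dn <- list(rownames(zy), rownames(zx))
    conc <- neg <- matrix(FALSE, nGenes, nSub, dimnames = dn)
    sim <- nsim <- matrix(NA_real_, nGenes, nSub, dimnames = dn)
    eligible <- !(rownames(zy) %in% patterns@zeroRows)
    zyd <- zy[, j, drop = FALSE]
    for (i in seq_len(nSub)) {
        dPlus <- abs(sweep(zyd, 2, zx[i, j], "-"))
        dMinus <- abs(sweep(zyd, 2, -zx[i, j], "-"))
        conc[, i] <- eligible & .rowMaxs(dPlus) <= width
        neg[, i] <- eligible & .rowMaxs(dMinus) <= width
        sim[, i] <- -sqrt(rowSums(dPlus^2))
        nsim[, i] <- -sqrt(rowSums(dMinus^2))
    }
    new("AssignmentResult", concordant = conc, negative = neg,
        similarity = sim, negativeSimilarity = nsim,
        depth = as.integer(depth), width = width,
        excluded = patterns@zeroRows)
}

.rowMaxs <- function(m) {
    out <- m[, 1L]
    for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, j])
    out
}

#' Group assigned genes by their exact substage set
#'
#' Partitions the assigned genes by the exact set of substages they match:
#' singleton sets give substage-specific lists, multi-substage sets give
#' shared lists (e.g. genes shared between consecutive substages).
#' Every assigned gene appears in exactly one list; unassigned genes appear
#' in none.
#'
#' @param result an [AssignmentResult-class].
#' @param polarity `"concordant"` or `"negative"`.
#' @return named list of character vectors of gene ids; names are substage
#'   sets joined with `" + "` in cyto-pattern row order.
#' @export
combinationLists <- function(result, polarity = c("concordant", "negative")) {
    polarity <- match.arg(polarity)
    m <- if (polarity == "concordant") result@concordant else result@negative
    assigned <- rowSums(m) > 0
    if (!any(assigned)) return(list())
    labs <- colnames(m)
    key <- apply(m[assigned, , drop = FALSE], 1L,
                 function(r) paste(labs[r], collapse = " + "))
    split(rownames(m)[assigned], key)
}

#' Flat per-gene assignment table
#'
#' One row per gene with its concordant and negatively concordant substage
#' sets (comma-separated), best similarity score among matched substages,
#' and the matching depth and width — the tabular form written by the
#' pipeline.
#'
#' @param result an [AssignmentResult-class].
#' @return data.frame with columns `gene_id`, `concordant`,
#'   `negatively_concordant`, `best_similarity`, `depth`, `width`.
#' @export
assignmentTable <- function(result) {
    m <- result@concordant
    labs <- colnames(m)
    collapse <- function(mm) apply(mm, 1L, function(r)
        paste(labs[r], collapse = ","))
    best <- rep(NA_real_, nrow(m))
    any1 <- result@concordant | result@negative
    simBoth <- pmax(ifelse(result@concordant, result@similarity, -Inf),
                    ifelse(result@negative, result@negativeSimilarity, -Inf))
    hit <- rowSums(any1) > 0
    best[hit] <- apply(simBoth[hit, , drop = FALSE], 1L, max)
    data.frame(gene_id = rownames(m),
               concordant = collapse(result@concordant),
               negatively_concordant = collapse(result@negative),
               best_similarity = best,
               depth = result@depth,
               width = result@width,
               stringsAsFactors = FALSE)
}

#' Run the full covariance analysis on aligned data
#'
#' Convenience wrapper: center both blocks, form the cross-covariance,
#' decompose, project, and (when `width` is given) match. Expects the
#' cytology table already merged to analysis groups and the expression
#' matrix filtered and log-transformed.
#'
#' @param cyto a [CytologyTable-class].
#' @param expr an [ExpressionMatrix-class] (log scale recommended).
#' @param width optional window width; when NULL only patterns are returned.
#' @param depth matching depth; defaults to all usable components.
#' @param useCentered see [projectPatterns()].
#' @return list with elements `decomposition` ([CovarianceDecomposition-class]),
#'   `patterns` ([PatternMatrices-class]) and, when `width` is supplied,
#'   `assignment` ([AssignmentResult-class]).
#' @export
pmcaFit <- function(cyto, expr, width = NULL, depth = NULL,
                    useCentered = TRUE) {
    stopifnot(is(cyto, "CytologyTable"), is(expr, "ExpressionMatrix"))
    if (!identical(sampleIds(cyto), sampleIds(expr)))
        stop("cytology and expression samples are not aligned; ",
             "run alignSamples() first", call. = FALSE)
    x <- frequencies(cyto)
    y <- exprValues(expr)
    xc <- centerRows(x)
    yc <- centerRows(y)
    dec <- pmcaDecompose(crossCovariance(xc, yc), xc)
    pat <- projectPatterns(x, y, dec, useCentered = useCentered)
    out <- list(decomposition = dec, patterns = pat)
    if (!is.null(width)) {
        if (is.null(depth)) depth <- nComponentsUsable(dec)
        out$assignment <- matchPatterns(pat, width = width, depth = depth)
    }
    out
}
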