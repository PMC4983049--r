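## Permutation-based calibration of the matching window width via the
## estimated false positive rate (FPR).

#' Default candidate window widths
#'
#' 20 widths geometrically spaced in \[0.05, 2\] on the normalized pattern
#' scale.
#'
#' @param n number of widths.
#' @param from,to range endpoints.
#' @return ascending numeric vector.
#' @export
defaultWidthGrid <- function(n = 20L, from = 0.05, to = 2) {
    exp(seq(log(from), log(to), length.out = n))
}

## For one pattern set, the per-gene, per-depth matching statistic:
## s[g, j] = min over substages and polarities of the cumulative max over
## components 1..j of |z_y[g, ] -/+ z_x[i, ]|. Gene g receives an
## assignment at depth j and width w iff s[g, j] <= w, so one pass yields
## the assignment fraction for every width and depth at once.
.matchStat <- function(zx, zy, nUse, polarity = "both") {
    jj <- seq_len(nUse)
    zyd <- zy[, jj, drop = FALSE]
    s <- NULL
    for (i in seq_len(nrow(zx))) {
        for (sgn in c(1, -1)) {
            if (polarity == "concordant" && sgn < 0) next
            if (polarity == "negative" && sgn > 0) next
            d <- abs(sweep(zyd, 2, sgn * zx[i, jj], "-"))
            for (j in jj[-1L]) d[, j] <- pmax(d[, j - 1L], d[, j])
            s <- if (is.null(s)) d else pmin(s, d)
        }
    }
    s
}

## Centered-pipeline re-run for one column permutation, returning the
## match statistic matrix for the eligible (non-degenerate) genes.
.nullMatchStat <- function(x, xc, yc, perm, polarity) {
    ycp <- yc[, perm, drop = FALSE]
    dec <- pmcaDecompose(crossCovariance(xc, ycp), xc)
    pat <- projectPatterns(x, ycp, dec, useCentered = TRUE)
    zy <- genePatterns(pat)
    keep <- !(rownames(zy) %in% pat@zeroRows)
    list(s = .matchStat(cytoPatterns(pat), zy[keep, , drop = FALSE],
                        nComponentsUsable(pat), polarity),
         nUse = nComponentsUsable(pat))
}

.fprGrid <- function(cyto, expr, widths, nPermutations, seed,
                     polarity = "both") {
    stopifnot(is(cyto, "CytologyTable"), is(expr, "ExpressionMatrix"))
    if (!identical(sampleIds(cyto), sampleIds(expr)))
        stop("cytology and expression samples are not aligned", call. = FALSE)
    if (nPermutations < 1L)
        stop("nPermutations must be >= 1", call. = FALSE)
    x <- frequencies(cyto)
    y <- exprValues(expr)
    yc <- centerRows(y)
    if (all(abs(yc) < 1e-12))
        stop("degenerate input: all expression rows are constant",
             call. = FALSE)
    xc <- centerRows(x)
    nSamp <- ncol(x)
    set.seed(seed)
    acc <- NULL
    nUse <- NA_integer_
    for (p in seq_len(nPermutations)) {
        perm <- sample.int(nSamp)
        ns <- .nullMatchStat(x, xc, yc, perm, polarity)
        nUse <- ns$nUse
        ## fraction of eligible genes assigned, per width x depth
        frac <- vapply(widths, function(w)
            colMeans(ns$s <= w), numeric(ncol(ns$s)))
        acc <- if (is.null(acc)) frac else acc + frac
    }
    fpr <- acc / nPermutations
    if (is.null(dim(fpr))) fpr <- matrix(fpr, nrow = 1L)  # nUse == 1
    fpr <- t(fpr)                            # width x depth
    dimnames(fpr) <- list(format(widths, digits = 6, trim = TRUE),
                          paste0("depth", seq_len(nUse)))
    fpr
}

#' Estimate per-component false positive rates at a given width
#'
#' For each of `nPermutations` permutations of the expression sample
#' labels, the full pipeline (centering, cross-covariance, SVD, projection,
#' window matching) is re-run and the fraction of non-degenerate genes
#' receiving any assignment (to any substage) at each depth `j` is
#' recorded; the FPR at depth `j` is the mean fraction over permutations.
#' Re-estimating the patterns per permutation makes the null reflect
#' pattern re-fitting, not just matching.
#'
#' @param cyto a [CytologyTable-class] (sample-aligned with `expr`).
#' @param expr an [ExpressionMatrix-class].
#' @param width positive window width.
#' @param nPermutations number of sample-label permutations.
#' @param seed integer seed; identical seed and inputs give identical
#'   estimates.
#' @param polarity count genes assigned with either polarity (`"both"`,
#'   default) or restricted to one.
#' @return numeric vector of FPRs, one per usable component depth.
#' @export
estimateFpr <- function(cyto, expr, width, nPermutations = 100L, seed = 1L,
                        polarity = c("both", "concordant", "negative")) {
    polarity <- match.arg(polarity)
    if (length(width) != 1L || width <= 0)
        stop("width must be a single positive number", call. = FALSE)
    drop(.fprGrid(cyto, expr, width, nPermutations, seed, polarity))
}

#' Select the matching window width by permutation-estimated FPR
#'
#' Evaluates the FPR grid over `candidateWidths` and returns the largest
#' candidate whose estimated FPR at component `jStar` is at most `alpha`
#' (largest feasible width maximizes sensitivity subject to the error
#' bound). Because matching is cumulative, the FPR at depths beyond
#' `jStar` can only be lower. Errors with class
#' `"pmca_no_feasible_width"` when every candidate exceeds `alpha`.
#'
#' @param cyto a [CytologyTable-class] (sample-aligned with `expr`).
#' @param expr an [ExpressionMatrix-class].
#' @param candidateWidths ascending positive widths
#'   (default [defaultWidthGrid()]).
#' @param alpha FPR bound stipulated at component `jStar` (default 0.05).
#' @param jStar component index for the stipulation (default 3).
#' @param nPermutations permutations per width evaluation (default 100).
#' @param seed integer seed.
#' @param polarity see [estimateFpr()].
#' @return a [WidthSelectionReport-class].
#' @export
selectWidth <- function(cyto, expr, candidateWidths = defaultWidthGrid(),
                        alpha = 0.05, jStar = 3L, nPermutations = 100L,
                        seed = 1L,
                        polarity = c("both", "concordant", "negative")) {
    polarity <- match.arg(polarity)
    if (!length(candidateWidths) || any(candidateWidths <= 0) ||
        is.unsorted(candidateWidths, strictly = TRUE))
        stop("candidateWidths must be non-empty, positive, strictly ascending",
             call. = FALSE)
    fpr <- .fprGrid(cyto, expr, candidateWidths, nPermutations, seed,
                    polarity)
    if (jStar < 1L || jStar > ncol(fpr))
        stop("jStar must be in 1..", ncol(fpr), call. = FALSE)
    feasible <- which(fpr[, jStar] <= alpha)
    if (!length(feasible)) {
        cond <- simpleError(sprintf(
            "no candidate width attains FPR <= %g at component %d (min FPR %.4g)",
            alpha, jStar, min(fpr[, jStar])))
        class(cond) <- c("pmca_no_feasible_width", class(cond))
        stop(cond)
    }
    new("WidthSelectionReport",
        candidateWidths = candidateWidths, fpr = fpr,
        chosenWidth = candidateWidths[max(feasible)],
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed), alpha = alpha, jStar = as.integer(jStar))
}
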