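## Validation statistics: independent-PCA concordance of the two blocks,
## hypergeometric gene-list enrichment, overlap fractions, and annotation
## count summaries.

#' Concordance of independent PCAs of cytology and expression
#'
#' Runs a separate PCA on each block (samples as observations, variables
#' standardized to unit variance, i.e. `prcomp(..., scale. = TRUE)`), then
#' linearly rescales PC1 and PC2 scores of both blocks to the common range
#' \[0, 1\] per component so the score clouds are directly comparable.
#' Zero-variance variables are dropped before standardization. Because the
#' sign of a principal component is arbitrary, the PC1 concordance is
#' reported as `|cor|` with the orientation recorded.
#'
#' @param cyto a [CytologyTable-class].
#' @param expr an [ExpressionMatrix-class] (log scale), sample-aligned
#'   with `cyto`.
#' @return list with elements `cytoScores` and `exprScores` (sample x 2
#'   matrices of rescaled PC1/PC2 scores), `pc1Correlation` (`|cor|` of the
#'   PC1 scores), and `pc1Orientation` (sign of the raw correlation).
#' @export
pcaConcordance <- function(cyto, expr) {
    stopifnot(is(cyto, "CytologyTable"), is(expr, "ExpressionMatrix"))
    if (!identical(sampleIds(cyto), sampleIds(expr)))
        stop("cytology and expression samples are not aligned", call. = FALSE)
    if (ncol(frequencies(cyto)) < 3L)
        stop("pcaConcordance requires at least 3 samples", call. = FALSE)
    scores2 <- function(m) {
        obs <- t(m)                              # samples x variables
        ## drop (near-)constant variables: unit-variance scaling would blow
        ## pure floating-point jitter up to full weight
        keep <- apply(obs, 2L, function(v)
            stats::sd(v) > 1e-10 * (abs(mean(v)) + stats::sd(v)))
        if (sum(keep) < 2L)
            stop("fewer than 2 variable (non-constant) features",
                 call. = FALSE)
        p <- prcomp(obs[, keep, drop = FALSE], scale. = TRUE)
        p$x[, 1:2, drop = FALSE]
    }
    cs <- scores2(frequencies(cyto))
    es <- scores2(exprValues(expr))
    rescale01 <- function(v) (v - min(v)) / (max(v) - min(v))
    raw <- cor(cs[, 1L], es[, 1L])
    list(cytoScores = apply(cs, 2L, rescale01),
         exprScores = apply(es, 2L, rescale01),
         pc1Correlation = abs(raw),
         pc1Orientation = sign(raw))
}

#' Hypergeometric enrichment of a gene list in a reference set
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between `listA` and `reference` when drawing `|listA|` genes
#' from `universe` without replacement — the standard over-representation
#' test. Both sets must be subsets of the universe.
#'
#' @param listA,reference,universe character vectors of gene ids
#'   (duplicates ignored).
#' @return list with `overlap`, `listSize`, `referenceSize`,
#'   `universeSize`, `pValue`.
#' @export
hypergeometricEnrichment <- function(listA, reference, universe) {
    listA <- unique(listA); reference <- unique(reference)
    universe <- unique(universe)
    if (length(setdiff(listA, universe)) ||
        length(setdiff(reference, universe)))
        stop("listA and reference must be subsets of the universe",
             call. = FALSE)
    k <- length(intersect(listA, reference))
    ## P(X >= k), X ~ Hypergeom(referenceSize, universe - referenceSize, listSize)
    p <- phyper(k - 1L, length(reference),
                length(universe) - length(reference), length(listA),
                lower.tail = FALSE)
    list(overlap = k, listSize = length(listA),
         referenceSize = length(reference),
         universeSize = length(universe), pValue = p)
}

#' Overlap fraction as a percentage
#'
#' @param nRepresented numerator count (0 <= nRepresented <= nTotal).
#' @param nTotal denominator count (> 0).
#' @return numeric percentage `100 * nRepresented / nTotal`, with a
#'   `"display"` attribute giving the integer-rounded form (e.g. `"99 %"`).
#' @examples
#' overlapFraction(3955, 4004)   # 98.78 %, displays "99 %"
#' @export
overlapFraction <- function(nRepresented, nTotal) {
    if (nTotal <= 0) stop("nTotal must be > 0", call. = FALSE)
    if (nRepresented < 0 || nRepresented > nTotal)
        stop("nRepresented must be in [0, nTotal]", call. = FALSE)
    pct <- 100 * nRepresented / nTotal
    structure(pct, display = paste0(round(pct), " %"))
}

#' Annotation counts of assigned genes per substage and polarity
#'
#' Tallies, for each substage, the concordant and negatively concordant
#' genes per annotation label (e.g. chromosome). Genes without an
#' annotation are ignored.
#'
#' @param result an [AssignmentResult-class].
#' @param annotation named character vector mapping gene id to label.
#' @return data.frame with columns `substage`, `label`, `polarity`,
#'   `count` (all substage x label x polarity combinations, zero-filled).
#' @export
annotationCounts <- function(result, annotation) {
    stopifnot(is(result, "AssignmentResult"))
    genes <- rownames(result@concordant)
    ann <- annotation[genes]
    labels <- sort(unique(annotation))
    substages <- colnames(result@concordant)
    grid <- expand.grid(substage = substages, label = labels,
                        polarity = c("concordant", "negative"),
                        stringsAsFactors = FALSE)
    grid$count <- mapply(function(ss, lb, pol) {
        m <- if (pol == "concordant") result@concordant else result@negative
        sum(m[, ss] & !is.na(ann) & ann == lb)
    }, grid$substage, grid$label, grid$polarity)
    grid
}
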