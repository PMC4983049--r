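# Exhaustive enumeration oracle for the upper-tail hypergeometric test:
# over all equally likely draws of |list| elements from the universe, the
# fraction with overlap >= observed.
enumHyper <- function(k, listSize, refSize, uniSize) {
    draws <- combn(uniSize, listSize)
    hits <- colSums(draws <= refSize)    # elements 1..refSize are "reference"
    mean(hits >= k)
}

test_that("hypergeometric enrichment matches hand and enumeration oracles", {
    uni <- paste0("g", 1:10)
    res <- hypergeometricEnrichment(uni[1:2], uni[1:5], uni)
    # drawing 2 from 10 with 5 marked: P(both marked) = C(5,2)/C(10,2)
    expect_equal(res$pValue, choose(5, 2) / choose(10, 2))
    expect_equal(res$overlap, 2L)

    # enumeration oracle over small universes
    for (case in list(c(1, 3, 4, 9), c(2, 5, 6, 12), c(0, 4, 7, 11),
                      c(3, 3, 3, 15))) {
        k <- case[1]; ls <- case[2]; rs <- case[3]; us <- case[4]
        u <- paste0("x", seq_len(us))
        # reference positioned to realize overlap k with the list
        r <- hypergeometricEnrichment(u[seq_len(ls)],
                                      u[(ls - k + 1):(ls - k + rs)], u)
        expect_equal(r$overlap, k)
        expect_equal(r$pValue, enumHyper(r$overlap, ls, rs, us),
                     tolerance = 1e-12)
    }

    # bounds and degenerate certainty
    expect_lte(hypergeometricEnrichment(uni[6:7], uni[1:5], uni)$pValue, 1)
    expect_equal(hypergeometricEnrichment(uni, uni, uni)$pValue, 1)
    expect_error(hypergeometricEnrichment(c(uni, "zz"), uni, uni), "subset")
})

test_that("overlap fractions reproduce printed percentages", {
    lp <- overlapFraction(3955, 4004)
    expect_equal(as.numeric(lp), 100 * 3955 / 4004)
    expect_identical(attr(lp, "display"), "99 %")
    expect_equal(as.numeric(overlapFraction(0, 10)), 0)
    expect_equal(as.numeric(overlapFraction(7, 8)), 87.5)
    # scale invariance
    expect_equal(as.numeric(overlapFraction(7, 8)),
                 as.numeric(overlapFraction(14, 16)))
    expect_error(overlapFraction(1, 0), "nTotal")
    expect_error(overlapFraction(5, 4), "nRepresented")
})

test_that("independent PCAs of a noise-free mixture are concordant", {
    cfg <- simulationConfig(nGenes = 400, genesPerSubstage = 10,
                            negGenesPerSubstage = 10, noiseSd = 0,
                            seed = 31)
    cy <- simulateCytology(cfg)
    sim <- simulateExpression(cfg, cy)
    conc <- pcaConcordance(cy, logTransform(sim$expression))
    expect_gt(conc$pc1Correlation, 0.99)
    # both score matrices rescaled to the same range per component
    expect_equal(apply(conc$cytoScores, 2, function(v) max(v) - min(v)),
                 apply(conc$exprScores, 2, function(v) max(v) - min(v)),
                 tolerance = 1e-9)
})

test_that("PCA concordance of cytology against itself is exact and stable", {
    cfg <- simulationConfig(seed = 19)
    cy <- simulateCytology(cfg)
    selfExpr <- ExpressionMatrix(frequencies(cy) * 100)  # same data as "genes"
    conc <- pcaConcordance(cy, selfExpr)
    expect_equal(conc$pc1Correlation, 1, tolerance = 1e-9)

    # invariant to a joint reordering of the samples
    cfg2 <- simulationConfig(nGenes = 100, genesPerSubstage = 3,
                             negGenesPerSubstage = 3, seed = 23)
    cy2 <- simulateCytology(cfg2)
    ex2 <- logTransform(simulateExpression(cfg2, cy2)$expression)
    base <- pcaConcordance(cy2, ex2)
    perm <- sample(sampleIds(cy2))
    concP <- pcaConcordance(
        CytologyTable(frequencies(cy2)[, perm]), ex2[, perm])
    expect_equal(concP$pc1Correlation, base$pc1Correlation,
                 tolerance = 1e-9)
})

test_that("annotation counts tally per substage, label and polarity", {
    conc <- matrix(FALSE, 5, 2,
                   dimnames = list(paste0("g", 1:5), c("A", "B")))
    neg <- conc
    conc[1:3, "A"] <- TRUE               # three genes concordant with A
    neg[4, "B"] <- TRUE
    res <- new("AssignmentResult", concordant = conc, negative = neg,
               similarity = conc * 0, negativeSimilarity = conc * 0,
               depth = 1L, width = 1, excluded = character(0))
    ann <- c(g1 = "X", g2 = "X", g3 = "X", g4 = "2")   # g5 unannotated

    tab <- annotationCounts(res, ann)
    expect_equal(tab$count[tab$substage == "A" & tab$label == "X" &
                           tab$polarity == "concordant"], 3)
    expect_equal(tab$count[tab$substage == "B" & tab$label == "2" &
                           tab$polarity == "negative"], 1)
    # marginals conserve the annotated assignments
    expect_equal(sum(tab$count), sum(conc[!is.na(ann[rownames(conc)]), ]) +
                                 sum(neg[!is.na(ann[rownames(neg)]), ]))

    # empty assignment gives an all-zero table
    none <- new("AssignmentResult", concordant = conc & FALSE,
                negative = neg & FALSE, similarity = conc * 0,
                negativeSimilarity = conc * 0, depth = 1L, width = 1,
                excluded = character(0))
    expect_true(all(annotationCounts(none, ann)$count == 0))
})
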