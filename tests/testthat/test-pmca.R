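test_that("centerRows subtracts row means and preserves shape", {
    expect_equal(centerRows(rbind(c(1, 2, 3))), rbind(c(-1, 0, 1)))
    expect_equal(centerRows(rbind(c(4, 4, 4, 4))), rbind(c(0, 0, 0, 0)))
    m <- rbind(c(-1, 0, 1), c(2, -2, 0))
    expect_equal(centerRows(centerRows(m)), centerRows(m))  # idempotent
    expect_error(centerRows(cbind(c(1, 2))), ">= 2 columns")
})

test_that("crossCovariance is (1/n) Xc Yc^T with the right shape", {
    expect_equal(crossCovariance(rbind(c(-1, 1)), rbind(c(-2, 2))),
                 rbind(2))
    xc <- centerRows(matrix(runif(12), 3, 4))
    expect_equal(crossCovariance(xc, matrix(0, 5, 4)),
                 matrix(0, 3, 5))
    expect_error(crossCovariance(matrix(0, 2, 3), matrix(0, 2, 4)),
                 "sample dimension")
    # shape contract: substages x genes
    tp <- randomToyPair(6, 9, 40, seed = 5)
    C <- crossCovariance(centerRows(tp$x), centerRows(tp$y))
    expect_equal(dim(C), c(6L, 40L))
})

test_that("pmcaDecompose returns an orthonormal, reconstructing SVD", {
    # diagonal covariance: singular values read off the diagonal
    d <- pmcaDecompose(diag(c(3, 1)), centerRows(matrix(runif(6), 2, 3)))
    expect_equal(singularValues(d), c(3, 1))
    expect_equal(abs(d@u), diag(2), tolerance = 1e-12)

    set.seed(31)
    C <- matrix(rnorm(4 * 50), 4, 50)
    xc <- centerRows(matrix(runif(4 * 50), 4, 50))
    dec <- pmcaDecompose(C, xc)
    u <- dec@u
    expect_equal(crossprod(u), diag(4), tolerance = 1e-8)
    recon <- u %*% diag(singularValues(dec)) %*% t(dec@v)
    expect_lt(norm(recon - C, "F") / norm(C, "F"), 1e-8)
    expect_true(all(diff(singularValues(dec)) <= 1e-12))
    # deterministic sign convention: largest-|entry| of each u column positive
    for (j in 1:4) expect_gt(u[which.max(abs(u[, j])), j], 0)
})

test_that("compositional cytology loses exactly one degree of freedom", {
    tp <- randomToyPair(6, 28, 200, seed = 77)
    xc <- centerRows(tp$x)
    dec <- pmcaDecompose(crossCovariance(xc, centerRows(tp$y)), xc)
    s <- singularValues(dec)
    expect_equal(sum(s > 1e-8 * s[1]), 5L)
    expect_lt(s[6], 1e-8 * s[1])
    expect_equal(nComponentsUsable(dec), 5L)
})

test_that("normalized pattern rows have sum of squares n_substages - 1", {
    for (seed in 1:3) {
        tp <- randomToyPair(6, 12, 40, seed)
        xc <- centerRows(tp$x)
        dec <- pmcaDecompose(crossCovariance(xc, centerRows(tp$y)), xc)
        pat <- projectPatterns(tp$x, tp$y, dec)
        expect_equal(unname(rowSums(cytoPatterns(pat)^2)), rep(5, 6),
                     tolerance = 1e-8)
        zy <- genePatterns(pat)
        nz <- rowSums(zy^2) > 1e-16
        expect_equal(unname(rowSums(zy[nz, ]^2)), rep(5, sum(nz)),
                     tolerance = 1e-8)
    }
})

test_that("a gene row equal to a cytology row yields that substage's pattern", {
    tp <- randomToyPair(5, 10, 8, seed = 2)
    tp$y[3, ] <- tp$x[2, ]
    xc <- centerRows(tp$x)
    dec <- pmcaDecompose(crossCovariance(xc, centerRows(tp$y)), xc)
    pat <- projectPatterns(tp$x, tp$y, dec)
    expect_equal(unname(genePatterns(pat)[3, ]),
                 unname(cytoPatterns(pat)[2, ]), tolerance = 1e-10)
})

test_that("zero-variance genes get flagged zero patterns", {
    tp <- randomToyPair(4, 8, 6, seed = 3)
    tp$y[5, ] <- 7                       # constant expression
    xc <- centerRows(tp$x)
    dec <- pmcaDecompose(crossCovariance(xc, centerRows(tp$y)), xc)
    pat <- projectPatterns(tp$x, tp$y, dec)
    expect_identical(pat@zeroRows, "g5")
    expect_equal(unname(genePatterns(pat)[5, ]), rep(0, 4))
    res <- matchPatterns(pat, width = 100, depth = 3)
    expect_false(any(res@concordant["g5", ]))
    expect_false(any(res@negative["g5", ]))
})

test_that("full pipeline matches the brute-force oracle up to component sign", {
    for (seed in c(11, 12, 13)) {
        tp <- randomToyPair(6, 12, 50, seed)
        orc <- oraclePatterns(tp$x, tp$y)
        xc <- centerRows(tp$x)
        dec <- pmcaDecompose(crossCovariance(xc, centerRows(tp$y)), xc)
        pat <- projectPatterns(tp$x, tp$y, dec)
        expect_equal(singularValues(dec), orc$sigma, tolerance = 1e-8)
        expect_equal(unname(cytoPatterns(pat)),
                     unname(alignColumnSigns(cytoPatterns(pat), orc$zx)),
                     tolerance = 1e-8)
        expect_equal(unname(genePatterns(pat)),
                     unname(alignColumnSigns(genePatterns(pat), orc$zy)),
                     tolerance = 1e-8)
        # matching agrees elementwise with the loop oracle
        res <- matchPatterns(pat, width = 0.8, depth = 3)
        orcM <- oracleMatch(cytoPatterns(pat), genePatterns(pat),
                            width = 0.8, depth = 3)
        expect_equal(unname(res@concordant), orcM$concordant)
        expect_equal(unname(res@negative), orcM$negative)
    }
})

test_that("window matching applies the componentwise inequalities exactly", {
    pat <- new("PatternMatrices",
               zx = rbind(S1 = c(1.0, -0.5)),
               zy = rbind(gA = c(1.2, -0.4), gB = c(-1.0, 0.5)),
               normalized = TRUE, zeroRows = character(0),
               nComponentsUsable = 2L)
    res <- matchPatterns(pat, width = 0.25, depth = 2)
    expect_true(res@concordant["gA", "S1"])    # |0.2| and |0.1| <= 0.25
    res2 <- matchPatterns(pat, width = 0.15, depth = 2)
    expect_false(res2@concordant["gA", "S1"])  # |0.2| > 0.15
    # exact negation is negatively concordant at any width
    expect_true(res2@negative["gB", "S1"])
    expect_false(res2@concordant["gB", "S1"])
    expect_error(matchPatterns(pat, width = 0.25, depth = 3), "depth")
})

test_that("similarity score is negative truncated Euclidean distance", {
    expect_equal(similarityScore(c(1, 2, 3), c(1, 2, 3), depth = 3), 0)
    expect_equal(similarityScore(c(1, 0), c(0, 1), depth = 2), -sqrt(2))
    # ranking is invariant to components beyond depth
    a <- similarityScore(c(1, 0, 99), c(0, 1, -99), depth = 2)
    expect_equal(a, -sqrt(2))
})

test_that("assignments nest in depth, grow with width, ignore component signs", {
    tp <- randomToyPair(6, 12, 60, seed = 21)
    xc <- centerRows(tp$x)
    dec <- pmcaDecompose(crossCovariance(xc, centerRows(tp$y)), xc)
    pat <- projectPatterns(tp$x, tp$y, dec)

    prev <- NULL
    for (depth in 1:5) {
        res <- matchPatterns(pat, width = 0.9, depth = depth)
        if (!is.null(prev)) {
            expect_true(all(res@concordant <= prev@concordant))
            expect_true(all(res@negative <= prev@negative))
        }
        prev <- res
    }
    narrow <- matchPatterns(pat, width = 0.5, depth = 3)
    wide <- matchPatterns(pat, width = 1.5, depth = 3)
    expect_true(all(narrow@concordant <= wide@concordant))
    expect_true(all(narrow@negative <= wide@negative))

    # flipping a singular-vector pair flips zx and zy columns together,
    # leaving assignments unchanged
    flip <- pat
    flip@zx[, 2] <- -flip@zx[, 2]
    flip@zy[, 2] <- -flip@zy[, 2]
    a <- matchPatterns(pat, width = 0.9, depth = 3)
    b <- matchPatterns(flip, width = 0.9, depth = 3)
    expect_identical(a@concordant, b@concordant)
    expect_identical(a@negative, b@negative)
})

test_that("combination lists partition the assigned genes by exact set", {
    tp <- randomToyPair(6, 12, 80, seed = 33)
    xc <- centerRows(tp$x)
    dec <- pmcaDecompose(crossCovariance(xc, centerRows(tp$y)), xc)
    pat <- projectPatterns(tp$x, tp$y, dec)
    res <- matchPatterns(pat, width = 1.2, depth = 2)
    lists <- combinationLists(res)
    genes <- unlist(lists, use.names = FALSE)
    expect_false(anyDuplicated(genes) > 0)   # each gene in exactly one list
    expect_setequal(genes,
                    rownames(res@concordant)[rowSums(res@concordant) > 0])
    # genes in a shared list are not in any singleton list
    sets <- concordantSets(res)
    for (nm in names(lists)) {
        members <- strsplit(nm, " + ", fixed = TRUE)[[1]]
        for (g in lists[[nm]]) expect_setequal(sets[[g]], members)
    }
})

test_that("pmcaFit composes the stages and checks alignment", {
    toy <- toyObjects(nSub = 6, nSamp = 12, nGenes = 40, seed = 8)
    fit <- pmcaFit(toy$cyto, toy$expr, width = 0.8, depth = 3)
    expect_s4_class(fit$decomposition, "CovarianceDecomposition")
    expect_s4_class(fit$assignment, "AssignmentResult")
    wrong <- toy$expr[, rev(sampleIds(toy$expr))]
    expect_error(pmcaFit(toy$cyto, wrong, width = 0.8), "not aligned")
})
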