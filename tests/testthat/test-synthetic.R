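test_that("simulated cytology is compositional, seeded, and wave-shaped", {
    cfg <- simulationConfig(seed = 17)
    cy <- simulateCytology(cfg)
    f <- frequencies(cy)
    expect_equal(dim(f), c(6L, 28L))
    expect_true(all(abs(colSums(f) - 1) < 1e-9))
    expect_true(all(f >= 0 & f <= 1))

    # deterministic under the seed
    expect_identical(frequencies(simulateCytology(cfg)), f)

    # spermatogonia-like first row: dominant early, declining over time
    tp <- sub("_r\\d+$", "", colnames(f))
    first <- f[1, tp == "t01"]
    last <- f[1, tp == max(tp)]
    expect_gt(mean(first), 0.5)
    expect_gt(mean(first), mean(last))
    # the last substage row is absent for the first half of time points
    early <- tp %in% c("t01", "t02", "t03")
    expect_true(all(f[6, early] == 0))
    expect_true(any(f[6, !early] > 0))
})

test_that("simulated expression follows the mixture model exactly at zero noise", {
    cfg <- simulationConfig(nGenes = 50, genesPerSubstage = 1,
                            negGenesPerSubstage = 1, noiseSd = 0, seed = 4)
    cy <- simulateCytology(cfg)
    sim <- simulateExpression(cfg, cy)
    v <- exprValues(sim$expression)
    expect_true(all(v >= 0))
    f <- frequencies(cy)
    pr <- sim$truth@program
    expect_equal(v, pr %*% f)            # exact mixture, no noise

    # a planted concordant gene's profile is affine in its target row:
    # baseline * (1 + (effect - 1) * freq) -> centered profile is a
    # positive multiple of the centered substage frequency
    g1 <- which(sim$truth@concordant[, 1])[1]
    prof <- centerRows(v[g1, , drop = FALSE])
    frow <- centerRows(f[1, , drop = FALSE])
    expect_equal(unname(prof / max(abs(prof))),
                 unname(frow / max(abs(frow))), tolerance = 1e-10)

    # determinism and ground-truth bookkeeping
    sim2 <- simulateExpression(cfg, cy)
    expect_identical(exprValues(sim2$expression), v)
    expect_equal(sum(sim$truth@concordant), 6L)
    expect_equal(sum(sim$truth@negative), 6L)
})

test_that("noise is multiplicative log-normal around the mixture", {
    cfg <- simulationConfig(nGenes = 200, genesPerSubstage = 0,
                            negGenesPerSubstage = 0, noiseSd = 0.1,
                            seed = 21)
    cy <- simulateCytology(cfg)
    sim <- simulateExpression(cfg, cy)
    ratio <- log(exprValues(sim$expression) /
                 (sim$truth@program %*% frequencies(cy)))
    expect_lt(abs(mean(ratio)), 0.01)
    expect_lt(abs(sd(ratio) - 0.1), 0.01)
})

test_that("zero-noise mixtures give near-perfect PCA concordance", {
    cfg <- simulationConfig(nGenes = 300, genesPerSubstage = 5,
                            negGenesPerSubstage = 5, noiseSd = 0, seed = 6)
    cy <- simulateCytology(cfg)
    sim <- simulateExpression(cfg, cy)
    conc <- pcaConcordance(cy, logTransform(sim$expression))
    expect_gt(conc$pc1Correlation, 0.99)
})

test_that("scoreRecovery measures sensitivity and precision correctly", {
    conc <- matrix(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE), 3, 2,
                   dimnames = list(paste0("g", 1:3), c("A", "B")))
    neg <- matrix(FALSE, 3, 2, dimnames = dimnames(conc))
    truth <- new("GroundTruth", concordant = conc, negative = neg,
                 program = matrix(1, 3, 2, dimnames = dimnames(conc)))

    # perfect assignment
    perfect <- new("AssignmentResult", concordant = conc, negative = neg,
                   similarity = conc * 0, negativeSimilarity = conc * 0,
                   depth = 1L, width = 1, excluded = character(0))
    rec <- scoreRecovery(perfect, truth)
    ov <- rec[rec$substage == "overall" & rec$polarity == "concordant", ]
    expect_equal(ov$sensitivity, 1)
    expect_equal(ov$precision, 1)

    # empty assignment: sensitivity 0, precision NaN with a warning
    none <- new("AssignmentResult", concordant = conc & FALSE,
                negative = neg, similarity = conc * 0,
                negativeSimilarity = conc * 0, depth = 1L, width = 1,
                excluded = character(0))
    expect_warning(rec0 <- scoreRecovery(none, truth), "NaN")
    ov0 <- rec0[rec0$substage == "overall" & rec0$polarity == "concordant", ]
    expect_equal(ov0$sensitivity, 0)
    expect_true(is.nan(ov0$precision))

    # mismatched gene universe
    truth2 <- new("GroundTruth", concordant = conc[1:2, ],
                  negative = neg[1:2, ], program = conc[1:2, ] * 1)
    expect_error(scoreRecovery(perfect, truth2), "universe")
})

test_that("random assignment under the null has precision near the planted fraction", {
    set.seed(13)
    nG <- 500; planted <- 100
    conc <- matrix(FALSE, nG, 1, dimnames = list(paste0("g", 1:nG), "A"))
    truth <- conc; truth[seq_len(planted), 1] <- TRUE
    pick <- sample.int(nG, 200)
    called <- conc; called[pick, 1] <- TRUE
    res <- new("AssignmentResult", concordant = called, negative = conc,
               similarity = conc * 0, negativeSimilarity = conc * 0,
               depth = 1L, width = 1, excluded = character(0))
    tr <- new("GroundTruth", concordant = truth, negative = conc,
              program = conc * 1)
    rec <- scoreRecovery(res, tr)
    prec <- rec[rec$substage == "A" & rec$polarity == "concordant",
                "precision"]
    # binomial expectation: planted fraction 0.2
    expect_lt(abs(prec - planted / nG), 3 * sqrt(0.2 * 0.8 / 200))
})
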