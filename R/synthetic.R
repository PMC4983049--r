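## Synthetic paired cytology/expression generator with known ground truth:
## first-wave-like compositional trajectories and planted substage-specific
## expression programs, so the whole pipeline is testable without any
## external data.

#' Build a simulation configuration
#'
#' Defaults emulate the structure of a first-wave juvenile time course: 6
#' merged substage groups, 28 samples spread over 6 time points, a
#' spermatogonia-like group dominant early and declining, late groups
#' absent early. Expression is a composition-weighted mixture of
#' per-substage programs with multiplicative log-normal noise; planted
#' concordant genes have their program elevated `effectSize`-fold in one
#' target substage, planted negatively concordant genes are elevated in
#' every substage except the target.
#'
#' @param nSubstages,nSamples,nTimepoints,nGenes sizes (see
#'   [SimulationConfig-class]).
#' @param genesPerSubstage,negGenesPerSubstage planted genes per substage.
#' @param effectSize fold elevation (> 1) of a planted program.
#' @param noiseSd SD of multiplicative log-normal noise (natural-log scale).
#' @param compositionConcentration Dirichlet concentration of replicate
#'   jitter; roughly the effective number of scored cells.
#' @param rnaContent optional per-substage relative RNA content (default 1).
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nSubstages = 6L, nSamples = 28L,
                             nTimepoints = 6L, nGenes = 2000L,
                             genesPerSubstage = 30L,
                             negGenesPerSubstage = 30L,
                             effectSize = 8, noiseSd = 0.1,
                             compositionConcentration = 300,
                             rnaContent = rep(1, nSubstages),
                             seed = 1L) {
    new("SimulationConfig",
        nSubstages = as.integer(nSubstages), nSamples = as.integer(nSamples),
        nTimepoints = as.integer(nTimepoints), nGenes = as.integer(nGenes),
        genesPerSubstage = as.integer(genesPerSubstage),
        negGenesPerSubstage = as.integer(negGenesPerSubstage),
        effectSize = effectSize, noiseSd = noiseSd,
        compositionConcentration = compositionConcentration,
        rnaContent = rnaContent, seed = as.integer(seed))
}

## Mean composition per time point: rows are substage groups in
## developmental order, columns time points. The first row is dominant
## (> 50 %) at every time point and declines; intermediate groups are
## roughly constant; the later groups appear only at later time points.
.meanTrajectories <- function(nSubstages, nTimepoints) {
    if (nSubstages == 6L) {
        base <- rbind(
            c(0.75, 0.70, 0.62, 0.58, 0.55, 0.52),
            c(0.10, 0.10, 0.09, 0.09, 0.08, 0.08),
            c(0.08, 0.09, 0.08, 0.08, 0.07, 0.06),
            c(0.07, 0.10, 0.13, 0.12, 0.10, 0.09),
            c(0.00, 0.01, 0.08, 0.13, 0.12, 0.12),
            c(0.00, 0.00, 0.00, 0.00, 0.08, 0.13))
        if (nTimepoints == 6L) return(base)
        ## interpolate each row onto the requested number of time points
        tOut <- seq(1, 6, length.out = nTimepoints)
        out <- t(vapply(seq_len(6), function(i)
            stats::approx(1:6, base[i, ], xout = tOut)$y, numeric(nTimepoints)))
        return(sweep(out, 2, colSums(out), "/"))
    }
    ## generic fallback: declining dominant first row, staggered later rows
    tp <- seq_len(nTimepoints)
    out <- matrix(0, nSubstages, nTimepoints)
    out[1L, ] <- 0.75 - 0.25 * (tp - 1) / max(1, nTimepoints - 1)
    for (i in seq_len(nSubstages)[-1L]) {
        onset <- 1 + (i - 2) * nTimepoints / nSubstages
        out[i, ] <- pmax(0, (tp - onset) / nTimepoints)
    }
    rest <- 1 - out[1L, ]
    low <- colSums(out[-1L, , drop = FALSE])
    for (s in tp) {
        if (low[s] > 0) out[-1L, s] <- out[-1L, s] / low[s] * rest[s]
        else out[2L, s] <- rest[s]
    }
    out
}

.substageGroupLabels <- function(n) {
    if (n == 6L)
        c("Spermatogonia", "Preleptonema", "EarlyLeptonema",
          "LateLeptonema/Zygonema", "EarlyPachynema",
          "LatePachynema/Diplonema")
    else paste0("S", seq_len(n))
}

.timepointOfSample <- function(nSamples, nTimepoints) {
    base <- nSamples %/% nTimepoints
    counts <- rep(base, nTimepoints)
    extra <- nSamples - base * nTimepoints
    ## shortfall sits at the earliest time points (mirrors the smaller
    ## earliest-age group after outlier exclusion)
    if (extra > 0)
        counts[seq(nTimepoints - extra + 1L, nTimepoints)] <-
            counts[seq(nTimepoints - extra + 1L, nTimepoints)] + 1L
    rep(seq_len(nTimepoints), counts)
}

#' Simulate a compositional substage frequency table
#'
#' Samples at the same time point share a mean composition trajectory;
#' replicate jitter is Dirichlet (gamma draws with shape
#' `concentration * mean`, renormalized), so columns sum to 1 exactly and
#' substages absent from the mean stay exactly absent.
#'
#' @param config a [SimulationConfig-class].
#' @return a [CytologyTable-class] of `nSubstages` x `nSamples`.
#' @export
simulateCytology <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed)
    mu <- .meanTrajectories(config@nSubstages, config@nTimepoints)
    tpOf <- .timepointOfSample(config@nSamples, config@nTimepoints)
    conc <- config@compositionConcentration
    f <- vapply(seq_len(config@nSamples), function(s) {
        g <- rgamma(config@nSubstages, shape = conc * mu[, tpOf[s]])
        g / sum(g)
    }, numeric(config@nSubstages))
    dimnames(f) <- list(
        .substageGroupLabels(config@nSubstages),
        sprintf("t%02d_r%d", tpOf,
                sequence(tabulate(tpOf, config@nTimepoints))))
    CytologyTable(f)
}

#' Simulate a bulk expression matrix with planted substage programs
#'
#' Each gene has a per-substage program on the TPM scale; the bulk TPM of
#' gene k in sample s is the composition-weighted sum
#' `sum_i freq[i, s] * rnaContent[i] * program[k, i]`, multiplied by
#' log-normal noise `exp(N(0, noiseSd))`. Non-planted genes have flat
#' programs (pure noise after mixing). The first
#' `genesPerSubstage * nSubstages` genes are planted concordant (cycling
#' over substages), the next `negGenesPerSubstage * nSubstages` planted
#' negatively concordant.
#'
#' @param config a [SimulationConfig-class].
#' @param cyto the [CytologyTable-class] from [simulateCytology()] (shape
#'   must match `config`).
#' @return list with elements `expression` (an [ExpressionMatrix-class],
#'   TPM scale) and `truth` (a [GroundTruth-class]).
#' @export
simulateExpression <- function(config, cyto) {
    stopifnot(is(config, "SimulationConfig"), is(cyto, "CytologyTable"))
    f <- frequencies(cyto)
    if (nrow(f) != config@nSubstages || ncol(f) != config@nSamples)
        stop("cytology table shape does not match config", call. = FALSE)
    ## derive the expression stream from the same seed without re-using the
    ## composition stream
    set.seed(config@seed + 1L)
    nG <- config@nGenes; nS <- config@nSubstages
    geneId <- sprintf("gene%05d", seq_len(nG))
    baseline <- rlnorm(nG, meanlog = log(30), sdlog = 0.7)
    program <- matrix(baseline, nG, nS,
                      dimnames = list(geneId, rownames(f)))
    conc <- matrix(FALSE, nG, nS, dimnames = dimnames(program))
    neg <- matrix(FALSE, nG, nS, dimnames = dimnames(program))
    nConc <- config@genesPerSubstage * nS
    nNeg <- config@negGenesPerSubstage * nS
    if (nConc) {
        target <- rep(seq_len(nS), each = config@genesPerSubstage)
        idx <- cbind(seq_len(nConc), target)
        program[idx] <- baseline[seq_len(nConc)] * config@effectSize
        conc[idx] <- TRUE
    }
    if (nNeg) {
        rows <- nConc + seq_len(nNeg)
        target <- rep(seq_len(nS), each = config@negGenesPerSubstage)
        program[rows, ] <- baseline[rows] * config@effectSize
        idx <- cbind(rows, target)
        program[idx] <- baseline[rows]
        neg[idx] <- TRUE
    }
    mixed <- program %*% (f * config@rnaContent)
    tpm <- mixed * exp(matrix(rnorm(nG * ncol(f), 0, config@noiseSd),
                              nG, ncol(f)))
    dimnames(tpm) <- list(geneId, colnames(f))
    list(expression = ExpressionMatrix(tpm, scale = "tpm"),
         truth = new("GroundTruth", concordant = conc, negative = neg,
                     program = program))
}

#' Sensitivity and precision of assignment recovery
#'
#' Compares an [AssignmentResult-class] to the planted ground truth, per
#' polarity and per substage plus an overall row. Sensitivity is the
#' fraction of planted (gene, substage) assignments recovered; precision
#' the fraction of reported assignments that were planted. When nothing is
#' reported, precision is `NaN` (with a warning).
#'
#' @param result an [AssignmentResult-class].
#' @param truth a [GroundTruth-class] over the same gene universe.
#' @return data.frame with columns `substage`, `polarity`, `nPlanted`,
#'   `nRecovered`, `sensitivity`, `nAssigned`, `nCorrect`, `precision`.
#' @export
scoreRecovery <- function(result, truth) {
    stopifnot(is(result, "AssignmentResult"), is(truth, "GroundTruth"))
    if (!identical(rownames(result@concordant), rownames(truth@concordant)))
        stop("assignment and truth cover different gene universes",
             call. = FALSE)
    one <- function(called, planted, substage, polarity) {
        data.frame(substage = substage, polarity = polarity,
                   nPlanted = sum(planted),
                   nRecovered = sum(called & planted),
                   sensitivity = if (sum(planted)) sum(called & planted) /
                                     sum(planted) else NaN,
                   nAssigned = sum(called),
                   nCorrect = sum(called & planted),
                   precision = if (sum(called)) sum(called & planted) /
                                   sum(called) else NaN,
                   stringsAsFactors = FALSE)
    }
    out <- list()
    for (pol in c("concordant", "negative")) {
        called <- if (pol == "concordant") result@concordant else result@negative
        planted <- if (pol == "concordant") truth@concordant else truth@negative
        for (i in seq_len(ncol(called)))
            out[[length(out) + 1L]] <-
                one(called[, i], planted[, i], colnames(called)[i], pol)
        out[[length(out) + 1L]] <- one(called, planted, "overall", pol)
    }
    res <- do.call(rbind, out)
    if (any(is.nan(res$precision) & res$nPlanted > 0))
        warning("no assignments reported; precision is NaN", call. = FALSE)
    res
}
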