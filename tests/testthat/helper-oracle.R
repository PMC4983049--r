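# Independent brute-force reimplementation of the covariance-pattern
# pipeline, written with explicit loops and an eigendecomposition-based SVD
# so it shares no code path with the package implementation. Used as the
# oracle for equivalence tests on small random instances.

oracleCenter <- function(m) {
    out <- m
    for (i in seq_len(nrow(m))) out[i, ] <- m[i, ] - mean(m[i, ])
    out
}

oracleCovariance <- function(xc, yc) {
    n <- ncol(xc)
    C <- matrix(0, nrow(xc), nrow(yc))
    for (i in seq_len(nrow(xc)))
        for (k in seq_len(nrow(yc)))
            C[i, k] <- sum(xc[i, ] * yc[k, ]) / n
    C
}

# Full pattern pipeline: center -> covariance -> SVD (via eigen of C C^T)
# -> P_x -> projections -> RMS normalization with divisor (nSub - 1).
oraclePatterns <- function(x, y) {
    xc <- oracleCenter(x)
    yc <- oracleCenter(y)
    C <- oracleCovariance(xc, yc)
    eg <- eigen(C %*% t(C), symmetric = TRUE)
    U <- eg$vectors
    sigma <- sqrt(pmax(eg$values, 0))
    px <- t(U) %*% xc
    zx <- xc %*% t(px)
    zy <- yc %*% t(px)
    div <- nrow(x) - 1
    normRow <- function(v) {
        ss <- sum(v^2)
        if (ss > 0) v / sqrt(ss / div) else v
    }
    for (i in seq_len(nrow(zx))) zx[i, ] <- normRow(zx[i, ])
    for (k in seq_len(nrow(zy))) zy[k, ] <- normRow(zy[k, ])
    list(sigma = sigma, zx = zx, zy = zy)
}

# Direct loop implementation of cumulative window matching.
oracleMatch <- function(zx, zy, width, depth) {
    conc <- matrix(FALSE, nrow(zy), nrow(zx))
    neg <- matrix(FALSE, nrow(zy), nrow(zx))
    for (k in seq_len(nrow(zy)))
        for (i in seq_len(nrow(zx))) {
            okC <- okN <- TRUE
            for (j in seq_len(depth)) {
                if (abs(zy[k, j] - zx[i, j]) > width) okC <- FALSE
                if (abs(zy[k, j] + zx[i, j]) > width) okN <- FALSE
            }
            conc[k, i] <- okC
            neg[k, i] <- okN
        }
    list(concordant = conc, negative = neg)
}

# Random compositional cytology (columns sum to 1) + expression pair.
randomToyPair <- function(nSub, nSamp, nGenes, seed) {
    set.seed(seed)
    x <- matrix(runif(nSub * nSamp, 0.05, 1), nSub, nSamp)
    x <- sweep(x, 2, colSums(x), "/")
    dimnames(x) <- list(paste0("S", seq_len(nSub)),
                        paste0("smp", seq_len(nSamp)))
    y <- matrix(rlnorm(nGenes * nSamp, log(20), 1), nGenes, nSamp)
    dimnames(y) <- list(paste0("g", seq_len(nGenes)), colnames(x))
    list(x = x, y = y)
}

# Flip the sign of columns of z to match the orientation of ref.
alignColumnSigns <- function(ref, z) {
    for (j in seq_len(ncol(z))) {
        d <- sum(ref[, j] * z[, j])
        if (d < 0) z[, j] <- -z[, j]
    }
    z
}

# Small CytologyTable / ExpressionMatrix pair used across files.
toyObjects <- function(nSub = 4, nSamp = 10, nGenes = 30, seed = 42) {
    tp <- randomToyPair(nSub, nSamp, nGenes, seed)
    list(cyto = CytologyTable(tp$x),
         expr = ExpressionMatrix(tp$y, scale = "tpm"))
}
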