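# Independent oracles used to cross-check the package implementations.
# Each is coded from its own definition, not by calling package internals.

# SIMPLS (de Jong 1993) for a univariate response; returns the regression
# coefficient vector on centered data. Algorithmically distinct from the
# NIPALS-with-deflation path it checks (no X deflation; loading-space
# orthogonalization instead).
simplsOracle <- function(X, y, A) {
    X <- as.matrix(X)
    Xc <- sweep(X, 2, colMeans(X))
    yc <- y - mean(y)
    p <- ncol(Xc)
    S <- crossprod(Xc, yc)
    R <- matrix(0, p, A); Q <- numeric(A); V <- matrix(0, p, A)
    for (a in seq_len(A)) {
        r <- S
        t <- Xc %*% r
        normt <- sqrt(sum(t^2))
        t <- t / normt; r <- r / normt
        pvec <- crossprod(Xc, t)
        Q[a] <- sum(yc * t)
        v <- pvec
        if (a > 1) {
            Vprev <- V[, seq_len(a - 1), drop = FALSE]
            v <- v - Vprev %*% crossprod(Vprev, pvec)
        }
        v <- v / sqrt(sum(v^2))
        S <- S - v %*% crossprod(v, S)
        R[, a] <- r; V[, a] <- v
    }
    drop(R %*% Q)
}

# Two-parameter least squares x ~ a + b*ref via explicit normal equations.
affineLSOracle <- function(x, ref) {
    D <- cbind(1, ref)
    ab <- solve(crossprod(D), crossprod(D, x))
    c(a = ab[1], b = ab[2])
}

# AUC as the Mann-Whitney pairwise concordance over all (pos, neg) pairs.
aucBruteForce <- function(yhat, truth) {
    pos <- yhat[truth == 1]; neg <- yhat[truth == 0]
    total <- 0
    for (pp in pos)
        total <- total + sum(pp > neg) + 0.5 * sum(pp == neg)
    total / (length(pos) * length(neg))
}

# F-distribution quantile via the beta-quantile relation (independent of
# qf): if W ~ F(d1, d2) then d1 W / (d1 W + d2) ~ Beta(d1/2, d2/2).
fQuantileViaBeta <- function(alpha, d1, d2) {
    b <- qbeta(alpha, d1 / 2, d2 / 2)
    (d2 / d1) * b / (1 - b)
}
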