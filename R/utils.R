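## Internal numerical helpers shared across modules.

## Row-wise log-sum-exp of a matrix, guarded against -Inf rows.
logSumExpRows <- function(L) {
    idx <- max.col(L, ties.method = "first")
    m <- L[cbind(seq_len(nrow(L)), idx)]
    m[!is.finite(m)] <- 0
    m + log(rowSums(exp(L - m)))
}

## Log-density of N(mu, Sigma) evaluated at the rows of X (n x d).
## Cholesky-based; never forms an explicit inverse.
mvnLogDensity <- function(X, mu, Sigma) {
    d <- length(mu)
    R <- chol(Sigma)
    Y <- sweep(X, 2L, mu, "-")
    ## Z = solve(t(R)) %*% t(Y): whitened residuals
    Z <- backsolve(R, t(Y), transpose = TRUE)
    logdet <- 2 * sum(log(diag(R)))
    -0.5 * (d * log(2 * pi) + logdet + colSums(Z * Z))
}

## Evaluate an expression with a temporarily fixed RNG state.  The caller's
## .Random.seed is restored afterwards, so library randomness never leaks
## in or out; kind pinned for cross-session reproducibility.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    force(expr)
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Deterministic hash of a master seed and a stage label, kept below
#' 2^31 so it is always a valid R integer seed.  All pipeline stages
#' draw their randomness through this derivation, which makes every
#' stage independently reproducible from the single experiment seed.
#'
#' @param seed master integer seed.
#' @param stage character stage label (e.g. "phantom", "segment_t1w").
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 97)
    as.integer((as.numeric(seed) * 69069 + h) %% 2147483629)
}

## Separable Gaussian smoothing of a 3D array via banded convolution
## matrices with renormalized (replicate-free) edges.
gaussianSmooth3D <- function(a, sigma) {
    if (sigma <= 0) return(a)
    dm <- dim(a)
    smooth1 <- function(n) {
        r <- max(1L, ceiling(3 * sigma))
        x <- outer(seq_len(n), seq_len(n), function(i, j) {
            d <- i - j
            ifelse(abs(d) <= r, exp(-d^2 / (2 * sigma^2)), 0)
        })
        x / rowSums(x)
    }
    K1 <- smooth1(dm[1L]); K2 <- smooth1(dm[2L]); K3 <- smooth1(dm[3L])
    m <- matrix(a, dm[1L], dm[2L] * dm[3L])
    a <- array(K1 %*% m, dm)
    a <- aperm(a, c(2L, 1L, 3L))
    m <- matrix(a, dm[2L], dm[1L] * dm[3L])
    a <- array(K2 %*% m, dm[c(2L, 1L, 3L)])
    a <- aperm(a, c(2L, 1L, 3L))
    a <- aperm(a, c(3L, 1L, 2L))
    m <- matrix(a, dm[3L], dm[1L] * dm[2L])
    a <- array(K3 %*% m, dm[c(3L, 1L, 2L)])
    aperm(a, c(2L, 3L, 1L))
}

## Binary dilation of a logical 3D array by one voxel (26-neighbourhood),
## repeated `iter` times.
dilate3D <- function(mask, iter = 1L) {
    dm <- dim(mask)
    for (k in seq_len(iter)) {
        out <- mask
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
            if (dx == 0 && dy == 0 && dz == 0) next
            xs <- pmin(pmax(seq_len(dm[1L]) + dx, 1L), dm[1L])
            ys <- pmin(pmax(seq_len(dm[2L]) + dy, 1L), dm[2L])
            zs <- pmin(pmax(seq_len(dm[3L]) + dz, 1L), dm[3L])
            out <- out | mask[xs, ys, zs]
        }
        mask <- out
    }
    mask
}

## Monomial basis (no intercept) in coordinates normalized to [-1, 1],
## used by the polynomial bias-field model.  Rows follow `coords`.
polyBasis3D <- function(coords, order) {
    stopifnot(order >= 1)
    cols <- list()
    nms <- character(0)
    for (p in seq_len(order))
        for (i in 0:p) for (j in 0:(p - i)) {
            k <- p - i - j
            cols[[length(cols) + 1L]] <-
                coords[, 1L]^i * coords[, 2L]^j * coords[, 3L]^k
            nms <- c(nms, sprintf("x%dy%dz%d", i, j, k))
        }
    B <- do.call(cbind, cols)
    colnames(B) <- nms
    B
}

## Voxel coordinates of a 3D grid normalized to [-1, 1] per axis.
normalizedCoords <- function(dm) {
    nrm <- function(n) if (n == 1L) 0 else 2 * (seq_len(n) - 1) / (n - 1) - 1
    g <- expand.grid(x = nrm(dm[1L]), y = nrm(dm[2L]), z = nrm(dm[3L]),
                     KEEP.OUT.ATTRS = FALSE)
    as.matrix(g)
}
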