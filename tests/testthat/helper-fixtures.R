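## Shared fixture builders and independent oracles for the test suite.
## Everything is generated in code at test time; heavy pipeline fits are
## memoized within a session so several tests can share one fit.

ACQ_TE <- c(1.48, 2.98, 4.48, 5.98, 7.48)

tinyVolume <- function(dim = c(4, 4, 4), fill = 0, affine = diag(4)) {
    Volume(array(fill, dim), affine = affine)
}

## A reduced phantom for fast EM tests.
smallPhantomSpec <- function(seed, shape = c(32L, 32L, 32L),
                             geometry = list(), ...) {
    g <- utils::modifyList(
        list(margin = 3, csfThickness = 2, gmThickness = 3,
             susceptRadius = 4), geometry)
    phantomSpec(shape = shape, geometry = g, seed = seed, ...)
}

## Independent brute-force Bayes oracle for responsibilities: explicit
## density formula with solve() and det(), normalized per voxel over all
## class/component products.  Deliberately avoids the package's
## Cholesky/log-sum-exp path.
naiveClassPosteriors <- function(X, model, priorMatrix) {
    X <- as.matrix(X)
    n <- nrow(X); d <- ncol(X)
    K <- length(model@classNames)
    post <- matrix(0, n, K)
    for (i in seq_len(n)) {
        x <- X[i, ]
        dens <- numeric(K)
        for (k in seq_len(K)) {
            for (g in model@components[[k]]) {
                S <- g@covariance
                q <- as.numeric(t(x - g@mean) %*% solve(S) %*% (x - g@mean))
                dens[k] <- dens[k] + priorMatrix[i, k] * g@weight *
                    exp(-q / 2) / sqrt((2 * pi)^d * det(S))
            }
        }
        post[i, ] <- dens / sum(dens)
    }
    colnames(post) <- model@classNames
    post
}

## Numerical-integration oracle for the Bhattacharyya distance,
## -ln integral sqrt(p q), on a dense grid (1D or 2D).
numericBhattacharyya <- function(mu1, S1, mu2, S2, lim = 12, n = 401) {
    d <- length(mu1)
    S1 <- as.matrix(S1); S2 <- as.matrix(S2)
    dens <- function(X, mu, S) {
        q <- rowSums((sweep(X, 2, mu) %*% solve(S)) * sweep(X, 2, mu))
        exp(-q / 2) / sqrt((2 * pi)^d * det(S))
    }
    sdm <- sqrt(max(diag(S1), diag(S2)))
    lo <- pmin(mu1, mu2) - lim * sdm
    hi <- pmax(mu1, mu2) + lim * sdm
    if (d == 1L) {
        x <- seq(lo, hi, length.out = n)
        h <- x[2] - x[1]
        f <- sqrt(dens(cbind(x), mu1, S1) * dens(cbind(x), mu2, S2))
        -log(sum(f) * h)
    } else {
        x <- seq(lo[1], hi[1], length.out = n)
        y <- seq(lo[2], hi[2], length.out = n)
        hx <- x[2] - x[1]; hy <- y[2] - y[1]
        G <- as.matrix(expand.grid(x, y))
        f <- sqrt(dens(G, mu1, S1) * dens(G, mu2, S2))
        -log(sum(f) * hx * hy)
    }
}

## Build a GaussianComponent tersely.
gcomp <- function(mean, cov, weight = 1)
    new("GaussianComponent", mean = as.numeric(mean),
        covariance = as.matrix(cov), weight = weight)

## Assemble a fitted TissueModel directly from component lists.
directModel <- function(classNames, comps, classPriors = NULL,
                        channelNames = paste0("ch", seq_along(comps[[1]][[1]]@mean))) {
    if (is.null(classPriors))
        classPriors <- rep(1 / length(classNames), length(classNames))
    multiseg:::newTissueModel(classNames, comps, "stationary",
                              classPriors = classPriors,
                              channelNames = channelNames,
                              fitted = TRUE, seed = 0L)
}

## Trace monotonicity check at the documented tolerance.
expectMonotoneTrace <- function(trace) {
    ll <- trace@logLik
    if (length(ll) > 1L) {
        okSteps <- diff(ll) >= -1e-8 * abs(ll[-length(ll)])
        bad <- setdiff(which(!okSteps) + 1L, trace@interventions)
        expect_length(bad, 0)
    }
    invisible(trace)
}

## Memoized heavy pipeline fits shared across test files.
.fixtureCache <- new.env(parent = emptyenv())
cachedFixture <- function(name, builder) {
    if (!exists(name, envir = .fixtureCache))
        assign(name, builder(), envir = .fixtureCache)
    get(name, envir = .fixtureCache)
}

## Dura/vessel confound phantom with all four channel combinations
## fitted (echo-derived t1w and r2star channels), used by the
## confound-resolution and comparison tests.
confoundStudy <- function() cachedFixture("confoundStudy", function() {
    sp <- phantomSpec(seed = multiseg:::deriveSeed(1L, "phantom"),
                      modalities = c("t1w_multiecho", "flair"))
    r <- suppressMessages(renderChannels(buildLabels(sp)))
    r2 <- suppressMessages(fitR2Star(r$echoes))
    rate <- r2@rate; rate@data[!r2@valid] <- 0
    stack <- stackChannels(c(r$stack@channels, list(rate)),
                           c("t1w", "flair", "r2star"))
    priors <- truthPriors(r$truth)
    combos <- list("t1w", c("t1w", "flair"), c("t1w", "r2star"),
                   c("t1w", "flair", "r2star"))
    fits <- list()
    for (cmb in combos) {
        lbl <- comboLabel(cmb)
        fits[[lbl]] <- suppressMessages(segment(
            subsetChannels(stack, cmb), priors = priors,
            config = list(scale = "r2star" %in% cmb), seed = 3L))
    }
    list(truth = r$truth, stack = stack, priors = priors, fits = fits)
})

## Noiseless and SNR-20 recovery fits at 48^3 (t1w + flair).
recoveryStudy <- function() cachedFixture("recoveryStudy", function() {
    spn <- phantomSpec(seed = 11L, noise = list(model = "none", snr = Inf),
                       contrast = within(defaultContrastTable(), sd <- sd * 0))
    rn <- suppressMessages(renderChannels(buildLabels(spn)))
    fn <- suppressMessages(segment(rn$stack, priors = truthPriors(rn$truth),
                                   seed = 3L))
    sp2 <- phantomSpec(seed = 12L, noise = list(model = "rician", snr = 20))
    r2 <- suppressMessages(renderChannels(buildLabels(sp2)))
    f2 <- suppressMessages(segment(r2$stack, priors = truthPriors(r2$truth),
                                   seed = 3L))
    list(noiseless = list(truth = rn$truth, fit = fn),
         snr20 = list(truth = r2$truth, fit = f2))
})
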