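#' @include volume.R
NULL

#' Tissue class specifications
#'
#' @param name class label.
#' @param nComponents number of Gaussians for the class.
#' @return A \linkS4class{ClassSpec}.
#' @export
classSpec <- function(name, nComponents = 1L)
    new("ClassSpec", name = as.character(name),
        nComponents = as.integer(nComponents))

#' Default class roster: GM(1), WM(1), CSF(2), OTHER(2)
#'
#' Gray and white matter are modeled with one Gaussian each and CSF with
#' a mixture of two, the standard configuration for generative brain
#' segmentation; the additional two-component OTHER class absorbs
#' background and non-brain structures (dura, vessels, connective
#' tissue).
#'
#' @return list of \linkS4class{ClassSpec}.
#' @export
defaultClassSpecs <- function()
    list(classSpec("GM", 1L), classSpec("WM", 1L),
         classSpec("CSF", 2L), classSpec("OTHER", 2L))

#' Parse a class roster string such as "gm:1,wm:1,csf:2,other:2"
#'
#' @param text comma-separated name:count pairs.
#' @return list of \linkS4class{ClassSpec}.
#' @export
parseClassSpecs <- function(text) {
    parts <- strsplit(strsplit(text, ",")[[1L]], ":")
    lapply(parts, function(p)
        classSpec(toupper(p[1L]), as.integer(p[2L])))
}

## ---- internal model plumbing -------------------------------------------

newTissueModel <- function(classNames, components, priorMode,
                           classPriors = numeric(0),
                           priorVolumes = list(),
                           channelNames = character(0),
                           scaling = list(), bias = list(),
                           fitted = FALSE, seed = 0L) {
    new("TissueModel", classNames = classNames, components = components,
        priorMode = priorMode, classPriors = classPriors,
        priorVolumes = priorVolumes, biasCoefficients = bias,
        channelNames = channelNames, scaling = scaling,
        fitted = fitted, seed = as.integer(seed))
}

#' @rdname classNames
#' @param x a \linkS4class{TissueModel} or \linkS4class{TissueProbabilityMaps}.
#' @param class class label.
#' @return \code{classNames}: character labels; \code{classComponents}:
#'   the list of \linkS4class{GaussianComponent}s of one class.
#' @export
setMethod("classNames", "TissueModel", function(x) x@classNames)

#' @rdname classNames
setMethod("classComponents", "TissueModel", function(x, class) {
    k <- match(class, x@classNames)
    if (is.na(k)) stop("unknown class: ", class)
    x@components[[k]]
})

setMethod("show", "TissueModel", function(object) {
    nc <- vapply(object@components, length, 0L)
    cat("TissueModel:",
        paste(sprintf("%s(%d)", object@classNames, nc), collapse = ", "),
        "| channels:", paste(object@channelNames, collapse = ", "),
        "|", if (object@fitted) "fitted" else "unfitted", "\n")
})

## Flatten a TissueModel into parallel vectors/lists over all components.
flattenModel <- function(model) {
    classIdx <- integer(0); w <- numeric(0)
    means <- list(); covs <- list()
    for (k in seq_along(model@components))
        for (g in model@components[[k]]) {
            classIdx <- c(classIdx, k)
            w <- c(w, g@weight)
            means[[length(means) + 1L]] <- g@mean
            covs[[length(covs) + 1L]] <- g@covariance
        }
    list(M = length(w), classIdx = classIdx, w = w,
         means = do.call(rbind, means), covs = covs,
         K = length(model@classNames))
}

rebuildComponents <- function(flat) {
    comps <- vector("list", flat$K)
    for (k in seq_len(flat$K)) {
        js <- which(flat$classIdx == k)
        wk <- flat$w[js] / sum(flat$w[js])
        comps[[k]] <- lapply(seq_along(js), function(i)
            new("GaussianComponent", mean = as.numeric(flat$means[js[i], ]),
                covariance = unname(flat$covs[[js[i]]]), weight = wk[i]))
    }
    comps
}

## Robust per-channel z-scaling parameters (median / 1.4826 MAD).
robustScaling <- function(X) {
    ctr <- apply(X, 2L, stats::median)
    scl <- apply(X, 2L, stats::mad)
    scl[scl <= 0] <- pmax(apply(X, 2L, stats::sd), .Machine$double.eps)[scl <= 0]
    list(center = ctr, scale = scl)
}

applyScaling <- function(X, scaling) {
    if (!length(scaling)) return(X)
    sweep(sweep(X, 2L, scaling$center, "-"), 2L, scaling$scale, "/")
}

## Covariance regularization: 1e-6 x mean per-channel variance, with an
## absolute floor for constant data.
covRegFromData <- function(X, factor = 1e-6) {
    v <- mean(apply(X, 2L, stats::var))
    if (!is.finite(v) || v <= 0) v <- mean(X^2) + 1
    max(factor * v, 1e-12 * (1 + mean(X^2)))
}

## Log prior matrix (n x K) from the model's prior mode.
logPriorMatrix <- function(model, idx, n) {
    K <- length(model@classNames)
    if (model@priorMode == "stationary") {
        matrix(log(pmax(model@classPriors, 1e-300)),
               n, K, byrow = TRUE)
    } else {
        P <- vapply(model@priorVolumes, function(v) v@data[idx], numeric(n))
        if (!is.matrix(P)) P <- matrix(P, nrow = n)
        log(pmax(P, 1e-12))
    }
}

## Current log-bias field (n x d) over masked voxels, zero when unset.
biasField <- function(model, basis, d, n) {
    bc <- model@biasCoefficients
    if (!length(bc) || !length(bc$coefficients) || is.null(basis))
        return(matrix(0, n, d))
    B <- vapply(bc$coefficients, function(cf) as.vector(basis %*% cf),
                numeric(n))
    if (!is.matrix(B)) B <- matrix(B, nrow = n)
    B
}

## E-step: responsibilities + penalized observed-data log-likelihood.
## Component covariances are already regularized by construction
## (init and M-step both add covReg * I), so they are used as-is.
eStep <- function(Y, flat, logPrior, logBias = NULL) {
    n <- nrow(Y)
    L <- matrix(0, n, flat$M)
    for (m in seq_len(flat$M)) {
        L[, m] <- logPrior[, flat$classIdx[m]] + log(flat$w[m]) +
            mvnLogDensity(Y, flat$means[m, ], flat$covs[[m]])
    }
    lse <- logSumExpRows(L)
    if (any(!is.finite(lse)))
        stop("non-finite likelihood: degenerate covariance despite ",
             "regularization")
    ll <- sum(lse)
    if (!is.null(logBias)) ll <- ll - sum(logBias)
    list(resp = exp(L - lse), ll = ll)
}

## ---- user-facing operations --------------------------------------------

#' Initialize a tissue model
#'
#' With spatial priors the initial component parameters are the
#' prior-weighted channel moments of each class; multi-component classes
#' are split along the first principal axis of the class covariance.
#' Without priors, k-means++ seeded k-means on a fixed-seed voxel
#' subsample provides the initial centers, ordered by first-channel
#' intensity and assigned to the component slots in roster order (class
#' identity is then a density slot, not an anatomical guarantee).
#' Deterministic given \code{seed}.
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param specs list of \linkS4class{ClassSpec}; default
#'   \code{defaultClassSpecs()}.
#' @param priors optional list of per-class prior \linkS4class{Volume}s
#'   on the stack grid, summing to 1 per voxel (tolerance 1e-6).
#' @param seed integer.
#' @param scale logical: apply per-channel robust z-scaling before
#'   fitting (for numerically disparate units such as R2* against raw
#'   signal); recorded in the model and reported when active.
#' @param covRegFactor covariance regularization as a fraction of the
#'   mean per-channel variance (default 1e-6).
#' @return An unfitted \linkS4class{TissueModel}.
#' @export
initModel <- function(stack, specs = defaultClassSpecs(), priors = NULL,
                      seed = 1L, scale = FALSE, covRegFactor = 1e-6) {
    X <- channelMatrix(stack)
    idx <- attr(X, "index")
    scaling <- list()
    if (scale) {
        scaling <- robustScaling(X)
        message("per-channel robust z-scaling active")
    }
    X <- applyScaling(X, scaling)
    covReg <- covRegFromData(X, covRegFactor)
    d <- ncol(X)
    K <- length(specs)
    cn <- vapply(specs, function(s) s@name, "")
    ncomp <- vapply(specs, function(s) s@nComponents, 0L)

    ## Split a class density into m components along its first principal
    ## axis; children get the parent covariance with the between-child
    ## variance removed along that axis (kept positive-definite).
    splitAlongPC <- function(mu, Sigma, m) {
        if (m == 1L) return(list(means = list(mu), cov = Sigma))
        e <- eigen(Sigma, symmetric = TRUE)
        v1 <- e$vectors[, 1L]
        l1 <- max(e$values[1L], covReg)
        dirv <- v1 * sqrt(l1)
        offs <- seq(-1, 1, length.out = m)
        child <- Sigma - (1 - 1 / m) * l1 * tcrossprod(v1)
        ec <- eigen((child + t(child)) / 2, symmetric = TRUE)
        child <- ec$vectors %*% diag(pmax(ec$values, covReg),
                                     length(mu)) %*% t(ec$vectors)
        list(means = lapply(offs, function(o) mu + o * dirv),
             cov = (child + t(child)) / 2)
    }

    if (!is.null(priors)) {
        if (length(priors) != K)
            stop("need one prior volume per class")
        P <- vapply(priors, function(v) {
            if (!sameGrid(v, stack@channels[[1L]]))
                stop("prior volume not on the stack grid")
            v@data[idx]
        }, numeric(nrow(X)))
        if (!is.matrix(P)) P <- matrix(P, nrow = nrow(X))
        if (max(abs(rowSums(P) - 1)) > 1e-6)
            stop("prior volumes must sum to 1 per voxel")
        ## Sharpened priors for the initial moments: raising to the 4th
        ## power and renormalizing strips the uniform floor and smoothing
        ## halo off atlas-style priors, so each class's initial moments
        ## come from voxels that predominantly belong to it.  The
        ## unsharpened priors still drive the E-step itself.
        Ps <- P^4
        Ps <- Ps / pmax(rowSums(Ps), 1e-300)
        comps <- vector("list", K)
        for (k in seq_len(K)) {
            w <- Ps[, k]
            sw <- sum(w)
            mu <- colSums(X * w) / sw
            Xc <- sweep(X, 2L, mu, "-")
            Sigma <- crossprod(Xc, Xc * (w / sw)) + diag(covReg, d)
            Sigma <- (Sigma + t(Sigma)) / 2
            sp <- splitAlongPC(mu, Sigma, ncomp[k])
            comps[[k]] <- lapply(sp$means, function(m)
                new("GaussianComponent", mean = as.numeric(m),
                    covariance = unname(sp$cov), weight = 1 / ncomp[k]))
        }
        return(newTissueModel(cn, comps, "voxelwise",
                              priorVolumes = priors,
                              channelNames = channelNames(stack),
                              scaling = scaling, seed = seed))
    }

    ## no priors: k-means++ on a fixed-seed subsample
    M <- sum(ncomp)
    withSeed(seed, {
        ns <- min(5000L, nrow(X))
        sub <- sort(sample.int(nrow(X), ns))
        Xs <- X[sub, , drop = FALSE]
        if (nrow(unique(Xs)) < M)
            stop("more components (", M, ") than distinct voxel values")
        ## k-means++ seeding
        ctr <- Xs[sample.int(ns, 1L), , drop = FALSE]
        for (m in seq_len(M - 1L)) {
            D2 <- apply(Xs, 1L, function(x)
                min(colSums((t(ctr) - x)^2)))
            p <- D2 / sum(D2)
            ctr <- rbind(ctr, Xs[sample.int(ns, 1L, prob = p), ])
        }
        km <- suppressWarnings(stats::kmeans(Xs, centers = ctr,
                                             iter.max = 50L))
        ord <- order(km$centers[, 1L])
        comps <- vector("list", K)
        slot <- 1L
        classMass <- numeric(K)
        for (k in seq_len(K)) {
            lst <- list()
            for (j in seq_len(ncomp[k])) {
                ci <- ord[slot]
                pts <- Xs[km$cluster == ci, , drop = FALSE]
                mu <- km$centers[ci, ]
                Sigma <- if (nrow(pts) > d)
                    stats::cov(pts) + diag(covReg, d)
                else diag(covReg + mean(X^2) * 1e-3, d)
                Sigma <- (Sigma + t(Sigma)) / 2
                lst[[j]] <- new("GaussianComponent", mean = as.numeric(mu),
                                covariance = unname(Sigma), weight = 1)
                classMass[k] <- classMass[k] + km$size[ci]
                slot <- slot + 1L
            }
            nsz <- km$size[ord[(slot - ncomp[k]):(slot - 1L)]]
            for (j in seq_along(lst)) lst[[j]]@weight <- nsz[j] / sum(nsz)
            comps[[k]] <- lst
        }
        newTissueModel(cn, comps, "stationary",
                       classPriors = classMass / sum(classMass),
                       channelNames = channelNames(stack),
                       scaling = scaling, seed = seed)
    })
}

#' Fit a tissue model by expectation-maximization
#'
#' E-step responsibilities are proportional to
#' \code{prior(class, voxel) * weight(component) * N(x; mu, Sigma)},
#' computed with log-sum-exp stabilization; the M-step applies the
#' closed-form updates of weights, means and covariances (plus
#' \code{covReg * I}).  With \code{biasOrder > 0} a per-channel log-bias
#' polynomial in normalized voxel coordinates is re-estimated every
#' iteration by responsibility/precision-weighted least squares on the
#' log-residuals; the update is guarded — it is reverted whenever it
#' would lower the penalized log-likelihood, so the returned trace is
#' monotone.  A component whose responsibility mass falls below
#' \code{minMass} voxels is reinitialized by splitting its heaviest
#' sibling (reported, and flagged in the trace).
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param model a \linkS4class{TissueModel} from \code{\link{initModel}}.
#' @param maxIter maximum EM iterations (default 200); 0 returns the
#'   model unchanged with an empty trace.
#' @param relTol relative log-likelihood change for convergence
#'   (default 1e-6).
#' @param covRegFactor covariance regularization fraction (default 1e-6).
#' @param biasOrder polynomial order of the multiplicative bias model
#'   (default 0 = off).
#' @param minMass component-collapse threshold in voxels (default 10).
#' @return list(model = fitted \linkS4class{TissueModel},
#'   trace = \linkS4class{FitTrace}).
#' @export
emFit <- function(stack, model, maxIter = 200L, relTol = 1e-6,
                  covRegFactor = 1e-6, biasOrder = 0L, minMass = 10L) {
    X <- channelMatrix(stack)
    idx <- attr(X, "index")
    X <- applyScaling(X, model@scaling)
    d <- ncol(X); n <- nrow(X)
    flat <- flattenModel(model)
    if (ncol(flat$means) != d)
        stop("model dimension (", ncol(flat$means),
             ") does not match stack channel count (", d, ")")
    if (maxIter == 0L)
        return(list(model = model,
                    trace = new("FitTrace", logLik = numeric(0),
                                iterations = 0L, converged = FALSE,
                                seed = model@seed,
                                interventions = integer(0))))
    covReg <- covRegFromData(X, covRegFactor)
    logPrior <- logPriorMatrix(model, idx, n)
    stationary <- model@priorMode == "stationary"
    classPriors <- model@classPriors

    basis <- NULL
    if (biasOrder > 0L) {
        coords <- normalizedCoords(dim(stack@channels[[1L]]@data))[idx, ,
                                                                   drop = FALSE]
        basis <- polyBasis3D(coords, biasOrder)
    }
    B <- biasField(model, basis, d, n)
    biasCoef <- model@biasCoefficients$coefficients
    Y <- X * exp(-B)

    llTrace <- numeric(0)
    interventions <- integer(0)
    converged <- FALSE

    for (it in seq_len(maxIter)) {
        es <- eStep(Y, flat, logPrior,
                    logBias = if (biasOrder > 0L) B else NULL)
        llTrace <- c(llTrace, es$ll)
        if (it > 1L) {
            prev <- llTrace[it - 1L]
            if (abs(es$ll - prev) <= relTol * (1 + abs(prev))) {
                converged <- TRUE
                break
            }
        }
        r <- es$resp
        Nm <- colSums(r)

        ## collapsed-component rescue: split the heaviest sibling
        dead <- which(Nm < minMass)
        if (length(dead)) {
            for (m in dead) {
                sibs <- setdiff(which(flat$classIdx == flat$classIdx[m]), m)
                src <- if (length(sibs)) sibs[which.max(Nm[sibs])]
                       else which.max(Nm)
                e <- eigen(flat$covs[[src]], symmetric = TRUE)
                dirv <- e$vectors[, 1L] * sqrt(max(e$values[1L], covReg))
                flat$means[m, ] <- flat$means[src, ] + 0.5 * dirv
                flat$means[src, ] <- flat$means[src, ] - 0.5 * dirv
                flat$covs[[m]] <- flat$covs[[src]]
                tot <- flat$w[m] + flat$w[src]
                flat$w[m] <- flat$w[src] <- tot / 2
            }
            message("reinitialized ", length(dead),
                    " collapsed component(s) at iteration ", it)
            interventions <- c(interventions, it + 1L)
            next
        }

        ## M-step: closed-form updates given responsibilities, for any
        ## candidate bias-corrected data
        mstepFlat <- function(Ydat) {
            fl <- flat
            for (m in seq_len(fl$M)) {
                rm_ <- r[, m]
                mu <- colSums(Ydat * rm_) / Nm[m]
                Yc <- sweep(Ydat, 2L, mu, "-")
                Sigma <- crossprod(Yc, Yc * rm_) / Nm[m] + diag(covReg, d)
                fl$means[m, ] <- mu
                fl$covs[[m]] <- (Sigma + t(Sigma)) / 2
            }
            for (k in seq_len(fl$K)) {
                js <- which(fl$classIdx == k)
                fl$w[js] <- Nm[js] / sum(Nm[js])
            }
            fl
        }
        if (stationary) {
            classMass <- vapply(seq_len(flat$K), function(k)
                sum(Nm[flat$classIdx == k]), 0)
            classPriors <- classMass / sum(classMass)
            logPrior <- matrix(log(pmax(classPriors, 1e-300)), n, flat$K,
                               byrow = TRUE)
        }
        flatBase <- mstepFlat(Y)
        flat <- flatBase

        ## guarded bias re-estimation on the log-residuals.  The log
        ## transform is only trusted where the predicted signal clears
        ## 3x its predicted SD (below that the linearization fails and
        ## E[log x] is dominated by the noise floor); the second-order
        ## Jensen term sigma^2/(2 mu^2) is added back, and residuals are
        ## weighted by the delta-method precision mu^2/sigma^2.
        if (biasOrder > 0L) {
            hatY <- r %*% flatBase$means
            sig2 <- vapply(seq_len(d), function(c_)
                as.vector(r %*% vapply(flatBase$covs, function(S)
                    max(S[c_, c_], covReg), 0)), numeric(n))
            if (!is.matrix(sig2)) sig2 <- matrix(sig2, nrow = n)
            newCoef <- vector("list", d)
            Bnew <- B
            ok <- TRUE
            for (c_ in seq_len(d)) {
                good <- X[, c_] > 0 & hatY[, c_] > 0 &
                    hatY[, c_]^2 > 9 * sig2[, c_]
                if (sum(good) < ncol(basis) + 2L) { ok <- FALSE; break }
                h <- hatY[good, c_]; s2 <- sig2[good, c_]
                tgt <- log(X[good, c_]) - log(h) + s2 / (2 * h^2)
                Wg <- h^2 / s2
                ## fit with an intercept so any DC offset in the
                ## residuals (absorbed by the class means, not the bias)
                ## cannot contort the spatial terms; apply without it.
                ## A trimming pass shields the smooth field from
                ## localized model misfit (e.g. signal-dropout zones
                ## whose residuals are real contrast, not bias):
                ## voxels beyond 3 standardized residuals are dropped
                ## and the field refitted.
                Bg <- cbind(1, basis[good, , drop = FALSE])
                wls <- function(Wv) {
                    A <- crossprod(Bg, Bg * Wv) +
                        diag(1e-8 * sum(Wv), ncol(Bg))
                    solve(A, crossprod(Bg, tgt * Wv))
                }
                cf0 <- wls(Wg)
                z <- (tgt - as.vector(Bg %*% cf0)) * sqrt(Wg)
                huber <- pmin(1, 2.5 / pmax(abs(z), 1e-12))
                cf <- wls(Wg * huber)[-1L]
                newCoef[[c_]] <- as.numeric(cf)
                Bnew[, c_] <- as.vector(basis %*% cf)
            }
            ## accept the proposal only if, after the model parameters
            ## are refitted to the corrected data, the penalized
            ## log-likelihood at least matches the no-update M-step:
            ## this keeps the trace provably monotone while letting the
            ## field take full steps
            if (ok) {
                flatProp <- mstepFlat(X * exp(-Bnew))
                llBase <- eStep(Y, flatBase, logPrior, logBias = B)$ll
                llProp <- eStep(X * exp(-Bnew), flatProp, logPrior,
                                logBias = Bnew)$ll
                if (llProp >= llBase - 1e-9 * (1 + abs(llBase))) {
                    flat <- flatProp
                    B <- Bnew
                    biasCoef <- newCoef
                }
            }
        }
        Y <- X * exp(-B)
    }

    model@components <- rebuildComponents(flat)
    if (stationary) model@classPriors <- classPriors
    if (biasOrder > 0L)
        model@biasCoefficients <- list(order = as.integer(biasOrder),
                                       coefficients = biasCoef)
    model@fitted <- TRUE
    list(model = model,
         trace = new("FitTrace", logLik = llTrace,
                     iterations = length(llTrace),
                     converged = converged, seed = model@seed,
                     interventions = interventions))
}

#' Posterior tissue probability maps
#'
#' Per-voxel class posterior = the sum of the class's component
#' responsibilities under the fitted model (the model's scaling and bias
#' field are applied exactly as at fit time).  Within the mask the maps
#' sum to 1; outside they are 0.
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param model a fitted \linkS4class{TissueModel}.
#' @return A \linkS4class{TissueProbabilityMaps}.
#' @export
posteriorMaps <- function(stack, model) {
    if (!model@fitted)
        stop("model is not fitted; run emFit() first")
    X <- channelMatrix(stack)
    idx <- attr(X, "index")
    X <- applyScaling(X, model@scaling)
    n <- nrow(X); d <- ncol(X)
    flat <- flattenModel(model)
    logPrior <- logPriorMatrix(model, idx, n)
    basis <- NULL
    bc <- model@biasCoefficients
    if (length(bc) && length(bc$coefficients)) {
        coords <- normalizedCoords(dim(stack@channels[[1L]]@data))[idx, ,
                                                                   drop = FALSE]
        basis <- polyBasis3D(coords, bc$order)
    }
    B <- biasField(model, basis, d, n)
    es <- eStep(X * exp(-B), flat, logPrior)
    dm <- dim(stack@channels[[1L]]@data)
    aff <- stack@channels[[1L]]@affine
    maps <- lapply(seq_len(flat$K), function(k) {
        a <- array(0, dm)
        a[idx] <- rowSums(es$resp[, flat$classIdx == k, drop = FALSE])
        Volume(a, affine = aff)
    })
    mask <- array(FALSE, dm); mask[idx] <- TRUE
    new("TissueProbabilityMaps", maps = maps,
        classNames = model@classNames, mask = mask)
}

#' @rdname classNames
setMethod("classNames", "TissueProbabilityMaps", function(x) x@classNames)

#' Extract one class probability map
#'
#' @param x a \linkS4class{TissueProbabilityMaps}.
#' @param class class label.
#' @return A \linkS4class{Volume}.
#' @rdname probMap
#' @export
setMethod("probMap", "TissueProbabilityMaps", function(x, class) {
    k <- match(class, x@classNames)
    if (is.na(k)) stop("unknown class: ", class)
    x@maps[[k]]
})

setMethod("show", "TissueProbabilityMaps", function(object) {
    cat("TissueProbabilityMaps:",
        paste(object@classNames, collapse = ", "), "|",
        paste(dim(object@mask), collapse = " x "),
        sprintf("| %d masked voxels\n", sum(object@mask)))
})

setMethod("show", "FitTrace", function(object) {
    cat(sprintf("FitTrace: %d iterations, %s, logLik %.6g -> %.6g\n",
                object@iterations,
                if (object@converged) "converged" else "not converged",
                if (object@iterations) object@logLik[1L] else NA,
                if (object@iterations)
                    object@logLik[object@iterations] else NA))
})

#' Segment a channel stack
#'
#' Composition of \code{\link{initModel}}, \code{\link{emFit}} and
#' \code{\link{posteriorMaps}} under a single seed.
#'
#' @inheritParams initModel
#' @param config named list of EM options passed through:
#'   \code{maxIter}, \code{relTol}, \code{covRegFactor}, \code{biasOrder},
#'   \code{minMass}, \code{scale}.
#' @return list(model, maps, trace).
#' @examples
#' set.seed(1)
#' a <- array(c(rnorm(500, 0), rnorm(500, 10)), c(10, 10, 10))
#' s <- stackChannels(list(Volume(a)), "t1w")
#' fit <- segment(s, list(classSpec("A"), classSpec("B")), seed = 7)
#' classNames(fit$model)
#' @export
segment <- function(stack, specs = defaultClassSpecs(), priors = NULL,
                    config = list(), seed = 1L) {
    cfg <- utils::modifyList(
        list(maxIter = 200L, relTol = 1e-6, covRegFactor = 1e-6,
             biasOrder = 0L, minMass = 10L, scale = FALSE), config)
    model <- initModel(stack, specs, priors = priors, seed = seed,
                       scale = cfg$scale, covRegFactor = cfg$covRegFactor)
    fit <- emFit(stack, model, maxIter = cfg$maxIter, relTol = cfg$relTol,
                 covRegFactor = cfg$covRegFactor,
                 biasOrder = cfg$biasOrder, minMass = cfg$minMass)
    maps <- posteriorMaps(stack, fit$model)
    list(model = fit$model, maps = maps, trace = fit$trace)
}

#' Serialize a TissueModel to JSON
#'
#' Full-precision JSON round trip of weights, means, covariances, priors
#' (stationary only), scaling, bias coefficients and seed, for the
#' separation module and archival.
#'
#' @param model a \linkS4class{TissueModel}.
#' @param path output path; when NULL the JSON string is returned.
#' @return \code{path} (invisibly) or the JSON string.
#' @export
saveModel <- function(model, path = NULL) {
    obj <- list(
        classNames = model@classNames,
        components = lapply(model@components, function(lst)
            lapply(lst, function(g) list(mean = g@mean,
                                         covariance = g@covariance,
                                         weight = g@weight))),
        priorMode = model@priorMode,
        classPriors = model@classPriors,
        biasCoefficients = model@biasCoefficients,
        channelNames = model@channelNames,
        scaling = model@scaling,
        fitted = model@fitted,
        seed = model@seed)
    js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                           matrix = "rowmajor")
    if (is.null(path)) return(as.character(js))
    writeLines(as.character(js), path)
    invisible(path)
}

#' Deserialize a TissueModel from JSON
#'
#' Voxelwise prior volumes are not serialized; a model saved from a
#' voxelwise fit is restored in stationary mode with uniform priors
#' (sufficient for density-based reports).
#'
#' @param path JSON file path or JSON string.
#' @return A \linkS4class{TissueModel}.
#' @export
loadModel <- function(path) {
    txt <- if (file.exists(path)) paste(readLines(path), collapse = "\n")
           else path
    obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                              simplifyMatrix = TRUE,
                              simplifyDataFrame = FALSE)
    K <- length(obj$classNames)
    comps <- lapply(seq_len(K), function(k) {
        lst <- obj$components[[k]]
        lapply(lst, function(g) {
            cv <- unname(as.matrix(g$covariance))
            new("GaussianComponent", mean = as.numeric(g$mean),
                covariance = cv, weight = as.numeric(g$weight))
        })
    })
    priorMode <- obj$priorMode
    classPriors <- as.numeric(obj$classPriors)
    if (priorMode == "voxelwise") {
        priorMode <- "stationary"
        classPriors <- rep(1 / K, K)
    }
    bias <- obj$biasCoefficients
    if (is.null(bias)) bias <- list()
    scaling <- obj$scaling
    if (is.null(scaling) || !length(scaling)) scaling <- list()
    else scaling <- list(center = as.numeric(scaling$center),
                         scale = as.numeric(scaling$scale))
    newTissueModel(obj$classNames, comps, priorMode,
                   classPriors = classPriors,
                   channelNames = as.character(obj$channelNames),
                   scaling = scaling, bias = bias,
                   fitted = isTRUE(obj$fitted),
                   seed = as.integer(obj$seed))
}

#' Write posterior maps as NIfTI
#'
#' One 3D NIfTI per class (\code{<prefix>_<class>.nii.gz}) plus a 4D
#' stacked file (\code{<prefix>_4d.nii.gz}).
#'
#' @param maps a \linkS4class{TissueProbabilityMaps}.
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
writeMaps <- function(maps, prefix) {
    files <- character(0)
    for (k in seq_along(maps@classNames)) {
        f <- paste0(prefix, "_", tolower(maps@classNames[k]), ".nii.gz")
        writeVolume(maps@maps[[k]], f)
        files <- c(files, f)
    }
    dm <- dim(maps@mask)
    arr4 <- array(0, c(dm, length(maps@maps)))
    for (k in seq_along(maps@maps)) arr4[, , , k] <- maps@maps[[k]]@data
    f4 <- paste0(prefix, "_4d.nii.gz")
    img <- RNifti::asNifti(arr4, datatype = "float")
    img <- RNifti::`sform<-`(img, structure(maps@maps[[1L]]@affine,
                                            code = 2L))
    RNifti::writeNifti(img, f4)
    invisible(c(files, f4))
}
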