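#' @include volume.R
NULL

#' Construct a multi-echo magnitude series
#'
#' @param echoes list of \linkS4class{Volume} magnitude images, one per
#'   echo, on one grid.
#' @param echoTimes numeric echo times in ms, strictly increasing.
#' @return A \linkS4class{MultiEchoSeries}.
#' @export
MultiEchoSeries <- function(echoes, echoTimes) {
    new("MultiEchoSeries", echoes = echoes,
        echoTimes = as.numeric(echoTimes))
}

#' Read a multi-echo series from NIfTI
#'
#' Accepts either one 4D NIfTI (echo along the 4th dimension) or a
#' vector of 3D NIfTI paths in echo order.
#'
#' @param paths one 4D path or several 3D paths.
#' @param echoTimes TE in ms, one per echo.
#' @return A \linkS4class{MultiEchoSeries}.
#' @export
readEchoSeries <- function(paths, echoTimes) {
    if (length(paths) == 1L) {
        if (!file.exists(paths)) stop("file not found: ", paths)
        img <- RNifti::readNifti(paths)
        dm <- dim(img)
        if (length(dm) != 4L)
            stop("expected a 4D NIfTI for a single-file echo series")
        aff <- unclass(RNifti::xform(img))
        attributes(aff) <- list(dim = dim(aff))
        echoes <- lapply(seq_len(dm[4L]), function(e)
            Volume(as.array(img)[, , , e], affine = aff))
    } else {
        echoes <- lapply(paths, readVolume)
    }
    MultiEchoSeries(echoes, echoTimes)
}

#' Estimate R2* by log-linear least squares
#'
#' Fits the mono-exponential magnitude decay
#' \deqn{S(TE) = S_0 e^{-R_2^* TE}} per voxel by least squares on the
#' log-signal, \eqn{\log S = \log S_0 - R_2^* TE}.  With
#' \code{weighted = TRUE} the residuals are weighted by the squared
#' signal (the usual first-order variance correction for log-transformed
#' magnitude data); the default is the plain unweighted estimator.
#'
#' Voxels with any echo at or below \code{minSignal} (or non-finite) are
#' marked invalid — the log transform is undefined there and, for
#' magnitude data, signal near the noise floor is Rician-biased.
#' Negative fitted rates (noise-driven) are retained, not clipped, so the
#' estimator's true distribution reaches downstream density models; their
#' count is reported.
#'
#' @param series a \linkS4class{MultiEchoSeries} with >= 2 echoes.
#' @param minSignal validity threshold in signal units (default 0).
#' @param weighted logical, weight by squared signal.
#' @return An \linkS4class{R2StarMap}: rate (1/ms), s0, valid.
#' @examples
#' te <- c(1.48, 2.98, 4.48, 5.98, 7.48)
#' mk <- function(s) Volume(array(s, c(2, 2, 2)))
#' ser <- MultiEchoSeries(lapply(200 * exp(-0.05 * te), mk), te)
#' fit <- fitR2Star(ser)
#' volData(fit@rate)[1]   # 0.05 /ms
#' @export
fitR2Star <- function(series, minSignal = 0, weighted = FALSE) {
    stopifnot(is(series, "MultiEchoSeries"))
    if (length(series@echoes) < 2L)
        stop("at least 2 echoes are required to fit a decay rate")
    if (minSignal < 0) stop("minSignal must be >= 0")
    te <- series@echoTimes
    dm <- dim(series@echoes[[1L]]@data)
    S <- vapply(series@echoes, function(v) as.vector(v@data),
                numeric(prod(dm)))
    if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
    valid <-rowSums(!is.finite(S) | S <= minSignal | S <= 0) == 0L
    ne <- length(te)
    Y <- log(pmax(S, .Machine$double.xmin))
    if (weighted) W <- S^2 else W <- matrix(1, nrow(S), ne)
    ## per-voxel weighted straight-line fit y = a - r * te, vectorized
    sw  <- W %*% rep(1, ne)
    swt <- W %*% te
    swt2 <- W %*% te^2
    swy <- rowSums(W * Y)
    swty <- rowSums(W * Y * rep(te, each = nrow(Y)))
    det <- sw * swt2 - swt^2
    slope <- (sw * swty - swt * swy) / det
    icpt <- (swt2 * swy - swt * swty) / det
    rate <- -as.vector(slope)
    s0 <- exp(as.vector(icpt))
    rate[!valid] <- NA_real_
    s0[!valid] <- NA_real_
    nneg <- sum(rate[valid] < 0)
    if (nneg > 0)
        message(nneg, " voxel(s) with negative fitted R2* retained")
    aff <- series@echoes[[1L]]@affine
    new("R2StarMap",
        rate = Volume(array(rate, dm), affine = aff),
        s0 = Volume(array(s0, dm), affine = aff),
        valid = array(valid, dm))
}

#' Average echoes into a single T1-weighted image
#'
#' Voxel-wise arithmetic mean across all echoes, on the grid of the
#' first echo — the echo-combined image used as the "t1w" channel (the
#' multi-echo acquisition's standard T1w output).
#'
#' @param series a \linkS4class{MultiEchoSeries}.
#' @return A \linkS4class{Volume}.
#' @export
combineEchoes <- function(series) {
    stopifnot(is(series, "MultiEchoSeries"))
    s <- Reduce("+", lapply(series@echoes, function(v) v@data))
    Volume(s / length(series@echoes),
           affine = series@echoes[[1L]]@affine)
}

#' Convert an R2* map to T2*
#'
#' \eqn{T_2^* = 1 / R_2^*}, floored at \code{rateFloor} to avoid
#' infinities where the fitted rate is zero or negative; invalid voxels
#' become NA.
#'
#' @param map an \linkS4class{R2StarMap}.
#' @param rateFloor positive floor in 1/ms (default 1e-6).
#' @return A \linkS4class{Volume} of T2* in ms.
#' @export
r2starToT2star <- function(map, rateFloor = 1e-6) {
    stopifnot(is(map, "R2StarMap"), rateFloor > 0)
    r <- map@rate@data
    t2 <- 1 / pmax(r, rateFloor)
    t2[!map@valid] <- NA_real_
    Volume(t2, affine = map@rate@affine)
}
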