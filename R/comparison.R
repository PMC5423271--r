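#' @include phantom.R
NULL

checkSameMaps <- function(a, b) {
    if (!identical(a@classNames, b@classNames))
        stop("class rosters differ")
    if (!sameGrid(a@maps[[1L]], b@maps[[1L]]))
        stop("map grids differ")
}

#' Average tissue probability maps
#'
#' Voxel-wise arithmetic mean per class over any number of map sets on
#' one grid with one roster; the result still sums to 1 per voxel.
#'
#' @param mapsList list of \linkS4class{TissueProbabilityMaps}.
#' @return A \linkS4class{TissueProbabilityMaps}.
#' @export
averageMaps <- function(mapsList) {
    if (!length(mapsList)) stop("at least one map set required")
    ref <- mapsList[[1L]]
    for (m in mapsList) checkSameMaps(ref, m)
    maps <- lapply(seq_along(ref@classNames), function(k) {
        a <- Reduce("+", lapply(mapsList, function(m) m@maps[[k]]@data))
        Volume(a / length(mapsList), affine = ref@maps[[k]]@affine)
    })
    mask <- Reduce("&", lapply(mapsList, function(m) m@mask))
    new("TissueProbabilityMaps", maps = maps,
        classNames = ref@classNames, mask = mask)
}

#' Difference of two tissue-probability-map sets
#'
#' Per class, B minus A, plus the integrated per-class volume change in
#' ml — probability mass only moves between compartments, so the class
#' deltas sum to zero at every voxel.
#'
#' @param a,b \linkS4class{TissueProbabilityMaps} on one grid
#'   (configuration A and B).
#' @param labels character(2) configuration labels.
#' @return A \linkS4class{ComparisonResult}.
#' @export
tpmDifference <- function(a, b, labels = c("A", "B")) {
    checkSameMaps(a, b)
    voxMl <- prod(voxelSize(a@maps[[1L]])) / 1000
    diffMaps <- list(); delta <- numeric(0)
    for (k in seq_along(a@classNames)) {
        d <- b@maps[[k]]@data - a@maps[[k]]@data
        diffMaps[[k]] <- Volume(d, affine = a@maps[[k]]@affine)
        delta <- c(delta, sum(d) * voxMl)
    }
    names(delta) <- a@classNames
    new("ComparisonResult", diffMaps = diffMaps, volumeDelta = delta,
        labels = as.character(labels))
}

#' Compartment volume of a tissue class
#'
#' Sum of the class probabilities times the voxel volume, in ml: the
#' soft (probabilistic) volume of the compartment.
#'
#' @param maps a \linkS4class{TissueProbabilityMaps}.
#' @param class class label.
#' @param mask optional logical array restricting the integration
#'   (default: the map set's own mask).
#' @return Volume in ml.
#' @export
compartmentVolume <- function(maps, class, mask = NULL) {
    k <- match(class, maps@classNames)
    if (is.na(k)) stop("unknown class: ", class)
    if (is.null(mask)) mask <- maps@mask
    v <- maps@maps[[k]]
    sum(v@data[mask]) * prod(voxelSize(v)) / 1000
}

#' Dice coefficient against phantom ground truth
#'
#' Dice = 2|P intersect T| / (|P| + |T|) between the thresholded
#' posterior of a class and the ground-truth label mask.  The
#' truth-side labels counted as the class are explicit; the default is
#' the class's own label, so for GM the score measures recovery of
#' normal-signal gray matter (SUSCEPT_GM voxels carry deliberately
#' corrupted signal and are scored separately if desired, e.g.
#' \code{truthLabels = c("GM", "SUSCEPT_GM")}).
#'
#' @param maps a \linkS4class{TissueProbabilityMaps}.
#' @param truth a \linkS4class{PhantomTruth}.
#' @param class class label in \code{maps}.
#' @param threshold posterior threshold in (0, 1), default 0.5.
#' @param truthLabels phantom labels constituting the class; default:
#'   the class name itself.
#' @return Dice score in [0, 1].
#' @export
diceScore <- function(maps, truth, class, threshold = 0.5,
                      truthLabels = NULL) {
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must be in (0, 1)")
    if (is.null(truthLabels)) truthLabels <- class
    tmask <- labelMask(truth, truthLabels)
    if (!any(tmask)) stop("empty truth class: ", class)
    p <- probMap(maps, class)@data > threshold
    diceMasks(p, tmask)
}

#' @rdname diceScore
#' @param p,t logical arrays (prediction, truth) of equal shape.
#' @export
diceMasks <- function(p, t) {
    stopifnot(identical(dim(p), dim(t)))
    denom <- sum(p) + sum(t)
    if (denom == 0) return(1)
    2 * sum(p & t) / denom
}

#' Confound leak rate into a tissue class
#'
#' Operationalizes confound misclassification: the fraction of confound
#' voxels whose class posterior exceeds the threshold, together with the
#' mean posterior over the confound mask (reported because figure-style
#' probability overlays have no hard cutoff).
#'
#' @param classMap a posterior \linkS4class{Volume} (e.g.
#'   \code{probMap(maps, "GM")}).
#' @param confoundMask non-empty logical array on the same grid.
#' @param threshold posterior cutoff, default 0.5.
#' @return list(rate, meanPosterior, n).
#' @export
leakRate <- function(classMap, confoundMask, threshold = 0.5) {
    stopifnot(is(classMap, "Volume"))
    if (!identical(dim(confoundMask), dim(classMap@data)))
        stop("mask grid differs from the map")
    n <- sum(confoundMask)
    if (n == 0) stop("empty confound mask")
    p <- classMap@data[confoundMask]
    list(rate = mean(p > threshold), meanPosterior = mean(p), n = n)
}

#' Fraction of a difference map's negative mass on given labels
#'
#' For a per-class difference volume (B minus A), computes which share
#' of the total negative mass lies on the given phantom labels
#' (optionally dilated by one voxel to absorb boundary discretization).
#'
#' @param diffVol a difference \linkS4class{Volume}.
#' @param truth a \linkS4class{PhantomTruth}.
#' @param labels phantom label names.
#' @param dilate dilation iterations, default 1.
#' @return Fraction in [0, 1].
#' @export
negativeMassFraction <- function(diffVol, truth, labels, dilate = 1L) {
    d <- diffVol@data
    neg <- pmin(d, 0)
    tot <- sum(neg)
    if (tot == 0) return(0)
    m <- labelMask(truth, labels, dilate = dilate)
    sum(neg[m]) / tot
}

#' Aggregate per-replicate metrics as mean and SD
#'
#' Subject-level style report over phantom replicates (e.g. volume
#' deltas in ml across seeds).
#'
#' @param x numeric vector of per-replicate values.
#' @return list(mean, sd, n).
#' @export
replicateSummary <- function(x)
    list(mean = mean(x), sd = stats::sd(x), n = length(x))

setMethod("show", "ComparisonResult", function(object) {
    cat("ComparisonResult:", object@labels[2L], "-", object@labels[1L], "\n")
    for (k in seq_along(object@volumeDelta))
        cat(sprintf("  %s: %+.3f ml\n", names(object@volumeDelta)[k],
                    object@volumeDelta[k]))
})

#' Write a comparison result to disk
#'
#' Difference maps as NIfTI, volume deltas as JSON.
#'
#' @param cmp a \linkS4class{ComparisonResult}.
#' @param dir output directory (created).
#' @return Files written, invisibly.
#' @export
writeComparison <- function(cmp, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    cls <- names(cmp@volumeDelta)
    for (k in seq_along(cmp@diffMaps)) {
        f <- file.path(dir, paste0("diff_", tolower(cls[k]), ".nii.gz"))
        writeVolume(cmp@diffMaps[[k]], f)
        files <- c(files, f)
    }
    f <- file.path(dir, "volume_delta_ml.json")
    writeLines(as.character(jsonlite::toJSON(
        list(labels = cmp@labels, volumeDeltaMl = as.list(cmp@volumeDelta)),
        digits = NA, auto_unbox = TRUE)), f)
    invisible(c(files, f))
}
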