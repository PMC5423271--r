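#' @include AllGenerics.R
NULL

#' Construct a Volume
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world transform in mm; defaults to identity
#'   (1 mm isotropic grid at the origin).
#' @param voxelSize optional length-3 voxel size in mm; derived from the
#'   affine column norms when omitted.
#' @return A \linkS4class{Volume}.
#' @examples
#' v <- Volume(array(0, c(4, 4, 4)))
#' voxelSize(v)
#' @export
Volume <- function(data, affine = diag(4), voxelSize = NULL) {
    data <- as.array(data)
    storage.mode(data) <- "double"
    ## strip any incoming attributes (e.g. niftiImage) down to a bare array
    data <- array(as.vector(data), dim(data))
    affine <- unname(as.matrix(affine))
    if (is.null(voxelSize))
        voxelSize <- sqrt(colSums(affine[1:3, 1:3]^2))
    new("Volume", data = data, affine = affine,
        voxelSize = as.numeric(voxelSize))
}

#' Accessors for Volume geometry and data
#'
#' @param x a \linkS4class{Volume} (or, for some accessors, a
#'   \linkS4class{ChannelStack}).
#' @return \code{volData}: the bare 3D array; \code{volAffine}: the 4x4
#'   affine; \code{voxelSize}: voxel edge lengths in mm.
#' @rdname volData
#' @export
setMethod("volData", "Volume", function(x) x@data)

#' @rdname volData
setMethod("volAffine", "Volume", function(x) x@affine)

#' @rdname volData
setMethod("voxelSize", "Volume", function(x) x@voxelSize)

setMethod("show", "Volume", function(object) {
    cat("Volume", paste(dim(object@data), collapse = " x "),
        sprintf("| voxel %s mm | range [%.4g, %.4g]\n",
                paste(signif(object@voxelSize, 4), collapse = "x"),
                suppressWarnings(min(object@data, na.rm = TRUE)),
                suppressWarnings(max(object@data, na.rm = TRUE))))
})

## Grid compatibility: identical shape, affines equal to GRID_TOL.
sameGrid <- function(a, b, tol = GRID_TOL) {
    identical(dim(a@data), dim(b@data)) &&
        max(abs(a@affine - b@affine)) <= tol
}

#' Read a 3D NIfTI volume
#'
#' Reads NIfTI-1/2 (.nii or .nii.gz).  The format's scale/intercept are
#' applied by the reader; no other rescaling happens.  4D files are
#' rejected here — multi-echo series go through
#' \code{\link{readEchoSeries}}.
#'
#' @param path path to an existing NIfTI file.
#' @return A \linkS4class{Volume}.
#' @export
readVolume <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    dm <- dim(img)
    if (length(dm) == 4L && dm[4L] == 1L) dim(img) <- dm[1:3]
    else if (length(dm) != 3L)
        stop("expected a 3D image, got ", length(dm),
             "D; use readEchoSeries() for echo series")
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = dim(aff))
    Volume(as.array(img), affine = aff)
}

#' Write a Volume as NIfTI
#'
#' @param vol a \linkS4class{Volume}.
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI datatype, default "double" (exact round trip);
#'   use "float" for single precision.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path, datatype = "double") {
    stopifnot(is(vol, "Volume"))
    img <- RNifti::asNifti(vol@data, datatype = datatype)
    img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Stack co-registered volumes into a ChannelStack
#'
#' Enforces grid compatibility (identical shape, affines within 1e-4):
#' a mismatch signals un-co-registered inputs and is an error — the
#' package never resamples.  Non-finite voxels in any channel are
#' excluded from the mask with a reported count.
#'
#' @param volumes list of \linkS4class{Volume}.
#' @param names character labels, unique, one per volume.
#' @param mask optional logical array or Volume; default: all voxels
#'   finite in every channel.
#' @return A \linkS4class{ChannelStack}.
#' @examples
#' v <- Volume(array(rnorm(64), c(4, 4, 4)))
#' s <- stackChannels(list(v, v), c("t1w", "flair"))
#' nChannels(s)
#' @export
stackChannels <- function(volumes, names, mask = NULL) {
    if (length(volumes) != length(names))
        stop("volumes and names must have equal length")
    if (anyDuplicated(names))
        stop("duplicate channel names: ",
             paste(names[duplicated(names)], collapse = ", "))
    ref <- volumes[[1L]]
    for (i in seq_along(volumes))
        if (!sameGrid(volumes[[i]], ref))
            stop("grid mismatch at channel '", names[i],
                 "': inputs must be co-registered on one grid ",
                 "(affine/shape differs beyond 1e-4)")
    if (is(mask, "Volume")) mask <- mask@data > 0
    finite <- Reduce("&", lapply(volumes, function(v) is.finite(v@data)))
    if (is.null(mask)) mask <- finite
    else mask <- mask & finite
    nbad <- sum(!finite)
    if (nbad > 0)
        message(nbad, " non-finite voxel(s) excluded from the mask")
    new("ChannelStack", channels = volumes,
        channelNames = as.character(names), mask = mask)
}

#' Accessors for ChannelStack
#'
#' @param x a \linkS4class{ChannelStack}.
#' @param ... unused.
#' @return \code{channelNames}: labels; \code{nChannels}: count;
#'   \code{stackMask}: logical array; \code{channelMatrix}: the masked
#'   voxels as an n x N matrix (one column per channel) with attribute
#'   \code{"index"} giving their linear voxel indices.
#' @rdname channelNames
#' @export
setMethod("channelNames", "ChannelStack", function(x) x@channelNames)

#' @rdname channelNames
setMethod("nChannels", "ChannelStack", function(x) length(x@channels))

#' @rdname channelNames
setMethod("stackMask", "ChannelStack", function(x) x@mask)

#' @rdname channelNames
setMethod("channelMatrix", "ChannelStack", function(x, ...) {
    idx <- which(x@mask)
    m <- vapply(x@channels, function(v) v@data[idx],
                numeric(length(idx)))
    if (length(idx) == 1L) m <- matrix(m, nrow = 1L)
    colnames(m) <- x@channelNames
    attr(m, "index") <- idx
    m
})

#' Select a subset of channels
#'
#' @param x a \linkS4class{ChannelStack}.
#' @param names channels to keep, in the requested order.
#' @return A new \linkS4class{ChannelStack}.
#' @export
subsetChannels <- function(x, names) {
    i <- match(names, x@channelNames)
    if (anyNA(i)) stop("unknown channel(s): ",
                       paste(names[is.na(i)], collapse = ", "))
    new("ChannelStack", channels = x@channels[i],
        channelNames = x@channelNames[i], mask = x@mask)
}

setMethod("show", "ChannelStack", function(object) {
    cat("ChannelStack:", paste(object@channelNames, collapse = ", "),
        "|", paste(dim(object@channels[[1L]]@data), collapse = " x "),
        sprintf("| %d masked voxels\n", sum(object@mask)))
})
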