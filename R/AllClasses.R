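#' @import methods
NULL

GRID_TOL <- 1e-4

#' Volume: a 3D scalar image with grid geometry
#'
#' The universal carrier for all images in the package: a 3D numeric array
#' together with a 4x4 voxel-to-world affine (mm) and the voxel size
#' derived from it.
#'
#' @slot data 3D numeric array, arbitrary physical units.
#' @slot affine 4x4 voxel-to-world transform in mm (0-based voxel indices).
#' @slot voxelSize length-3 numeric, mm; consistent with the affine
#'   column norms to 1e-4 mm.
#' @exportClass Volume
setClass("Volume", representation(
    data = "array",
    affine = "matrix",
    voxelSize = "numeric"
))

setValidity("Volume", function(object) {
    msg <- character(0)
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3D array")
    else if (any(dim(object@data) < 1L))
        msg <- c(msg, "all dimensions must be >= 1")
    if (!all(dim(object@affine) == c(4L, 4L)))
        msg <- c(msg, "affine must be 4x4")
    else {
        if (abs(det(object@affine)) < .Machine$double.eps * 10)
            msg <- c(msg, "affine must be invertible")
        cn <- sqrt(colSums(object@affine[1:3, 1:3]^2))
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be 3 positive values")
        else if (any(abs(cn - object@voxelSize) > GRID_TOL))
            msg <- c(msg, "voxelSize inconsistent with affine column norms")
    }
    if (length(msg)) msg else TRUE
})

#' ChannelStack: co-registered multichannel voxel data
#'
#' Ordered channels (one \linkS4class{Volume} each) on one common grid,
#' with unique names and an optional logical mask.  Grid compatibility is
#' enforced at construction: shapes identical, affines equal element-wise
#' to 1e-4.  No resampling is ever performed.
#'
#' @slot channels list of Volume.
#' @slot channelNames character, unique labels (e.g. "t1w", "flair").
#' @slot mask optional logical 3D array (NULL = all finite voxels).
#' @exportClass ChannelStack
setClass("ChannelStack", representation(
    channels = "list",
    channelNames = "character",
    mask = "ANY"
))

setValidity("ChannelStack", function(object) {
    msg <- character(0)
    if (length(object@channels) < 1L)
        msg <- c(msg, "at least one channel required")
    if (length(object@channelNames) != length(object@channels))
        msg <- c(msg, "one name per channel required")
    if (anyDuplicated(object@channelNames))
        msg <- c(msg, "channel names must be unique")
    if (length(object@channels) >= 1L) {
        ref <- object@channels[[1L]]
        for (v in object@channels) {
            if (!identical(dim(v@data), dim(ref@data)))
                msg <- c(msg, "channel shapes differ")
            if (max(abs(v@affine - ref@affine)) > GRID_TOL)
                msg <- c(msg, "channel affines differ beyond tolerance")
        }
        if (!is.null(object@mask) &&
            !identical(dim(object@mask), dim(ref@data)))
            msg <- c(msg, "mask shape differs from channels")
    }
    if (length(msg)) unique(msg) else TRUE
})

#' MultiEchoSeries: multi-echo magnitude volumes with echo times
#'
#' @slot echoes list of Volume (magnitude images), one per echo.
#' @slot echoTimes numeric TE in ms, strictly increasing, positive.
#' @exportClass MultiEchoSeries
setClass("MultiEchoSeries", representation(
    echoes = "list",
    echoTimes = "numeric"
))

setValidity("MultiEchoSeries", function(object) {
    msg <- character(0)
    if (length(object@echoes) < 1L)
        msg <- c(msg, "at least one echo required")
    if (length(object@echoTimes) != length(object@echoes))
        msg <- c(msg, "one echo time per echo volume required")
    if (any(object@echoTimes <= 0))
        msg <- c(msg, "echo times must be positive")
    if (is.unsorted(object@echoTimes, strictly = TRUE))
        msg <- c(msg, "echo times must be strictly increasing")
    if (length(object@echoes) > 1L) {
        ref <- object@echoes[[1L]]
        for (v in object@echoes)
            if (!identical(dim(v@data), dim(ref@data)) ||
                max(abs(v@affine - ref@affine)) > GRID_TOL)
                msg <- c(msg, "echo volumes must share one grid")
    }
    if (length(msg)) unique(msg) else TRUE
})

#' R2StarMap: voxelwise mono-exponential decay fit
#'
#' @slot rate Volume, apparent transverse relaxation rate R2* in 1/ms.
#' @slot s0 Volume, extrapolated signal at TE = 0 (arbitrary units).
#' @slot valid logical 3D array, TRUE where the fit succeeded.
#' @exportClass R2StarMap
setClass("R2StarMap", representation(
    rate = "Volume",
    s0 = "Volume",
    valid = "array"
))

setValidity("R2StarMap", function(object) {
    v <- object@valid
    r <- object@rate@data
    s <- object@s0@data
    msg <- character(0)
    if (!is.logical(v) || !identical(dim(v), dim(r)))
        msg <- c(msg, "valid must be a logical array matching rate")
    else {
        if (any(!is.finite(r[v])))
            msg <- c(msg, "rate must be finite wherever valid")
        if (any(s[v] <= 0))
            msg <- c(msg, "s0 must be positive wherever valid")
    }
    if (length(msg)) msg else TRUE
})

#' GaussianComponent: one multivariate Gaussian of a class mixture
#'
#' @slot mean numeric N-vector in channel intensity units.
#' @slot covariance N x N symmetric positive-definite matrix.
#' @slot weight within-class mixing proportion in (0, 1].
#' @exportClass GaussianComponent
setClass("GaussianComponent", representation(
    mean = "numeric",
    covariance = "matrix",
    weight = "numeric"
))

setValidity("GaussianComponent", function(object) {
    msg <- character(0)
    d <- length(object@mean)
    if (!all(dim(object@covariance) == c(d, d)))
        msg <- c(msg, "covariance dimension must match mean")
    else {
        if (max(abs(object@covariance - t(object@covariance))) > 1e-8 *
            (1 + max(abs(object@covariance))))
            msg <- c(msg, "covariance must be symmetric")
        ev <- tryCatch(min(eigen(object@covariance, symmetric = TRUE,
                                 only.values = TRUE)$values),
                       error = function(e) -Inf)
        if (!is.finite(ev) || ev <= 0)
            msg <- c(msg, "covariance must be positive-definite")
    }
    if (length(object@weight) != 1L || object@weight <= 0 ||
        object@weight > 1)
        msg <- c(msg, "weight must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' ClassSpec: a tissue class and its mixture size
#'
#' @slot name class label, e.g. "GM", "WM", "CSF", "OTHER".
#' @slot nComponents number of Gaussians modeling the class (>= 1).
#' @exportClass ClassSpec
setClass("ClassSpec", representation(
    name = "character",
    nComponents = "integer"
))

setValidity("ClassSpec", function(object) {
    if (length(object@nComponents) != 1L || object@nComponents < 1L)
        "nComponents must be >= 1" else TRUE
})

#' TissueModel: per-class Gaussian-mixture intensity densities
#'
#' The fitted density model: for every tissue class a list of
#' \linkS4class{GaussianComponent}s whose weights sum to 1, plus class
#' priors that are either stationary proportions or per-class prior
#' volumes (summing to 1 per voxel), optional per-channel log-bias
#' polynomial coefficients, and the channel scaling applied at fit time.
#'
#' @slot classNames character labels, one per class.
#' @slot components list (per class) of lists of GaussianComponent.
#' @slot priorMode "stationary" or "voxelwise".
#' @slot classPriors numeric per-class proportions (stationary mode).
#' @slot priorVolumes list of Volume per class, or empty list.
#' @slot biasCoefficients list per channel of polynomial coefficients
#'   (empty when no bias model), plus attribute "order".
#' @slot channelNames channels the model was fitted on.
#' @slot scaling list(center, scale) per channel applied before fitting,
#'   or empty list when channels were used as provided.
#' @slot fitted logical, TRUE after EM.
#' @slot seed integer seed used at initialization.
#' @exportClass TissueModel
setClass("TissueModel", representation(
    classNames = "character",
    components = "list",
    priorMode = "character",
    classPriors = "numeric",
    priorVolumes = "list",
    biasCoefficients = "list",
    channelNames = "character",
    scaling = "list",
    fitted = "logical",
    seed = "integer"
))

setValidity("TissueModel", function(object) {
    msg <- character(0)
    K <- length(object@classNames)
    if (length(object@components) != K)
        msg <- c(msg, "one component list per class required")
    for (k in seq_len(K)) {
        w <- vapply(object@components[[k]], function(g) g@weight, 0)
        if (abs(sum(w) - 1) > 1e-9)
            msg <- c(msg, sprintf("component weights of class %s must sum to 1",
                                  object@classNames[k]))
    }
    if (!object@priorMode %in% c("stationary", "voxelwise"))
        msg <- c(msg, "priorMode must be 'stationary' or 'voxelwise'")
    if (object@priorMode == "stationary") {
        if (length(object@classPriors) != K ||
            abs(sum(object@classPriors) - 1) > 1e-6)
            msg <- c(msg, "stationary class priors must sum to 1")
    } else if (length(object@priorVolumes) != K) {
        msg <- c(msg, "one prior volume per class required")
    }
    if (length(msg)) msg else TRUE
})

#' TissueProbabilityMaps: per-class posterior probability volumes
#'
#' One Volume per class with values in [0, 1]; within the mask the class
#' probabilities sum to 1 per voxel (tolerance 1e-6), outside they are 0.
#'
#' @slot maps list of Volume, one per class.
#' @slot classNames character labels.
#' @slot mask logical 3D array of voxels that participated.
#' @exportClass TissueProbabilityMaps
setClass("TissueProbabilityMaps", representation(
    maps = "list",
    classNames = "character",
    mask = "array"
))

setValidity("TissueProbabilityMaps", function(object) {
    msg <- character(0)
    if (length(object@maps) != length(object@classNames))
        msg <- c(msg, "one map per class required")
    if (length(object@maps)) {
        tot <- Reduce("+", lapply(object@maps, function(v) v@data))
        if (any(object@mask) && max(abs(tot[object@mask] - 1)) > 1e-6)
            msg <- c(msg, "class probabilities must sum to 1 within mask")
        rng <- range(vapply(object@maps, function(v)
            range(v@data), numeric(2)))
        if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9)
            msg <- c(msg, "probabilities must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' FitTrace: EM convergence record
#'
#' @slot logLik numeric, observed-data log-likelihood per iteration.
#' @slot iterations integer count of EM iterations run.
#' @slot converged logical.
#' @slot seed integer initialization seed.
#' @slot interventions integer iterations at which a collapsed component
#'   was reinitialized (monotonicity is not guaranteed across these).
#' @exportClass FitTrace
setClass("FitTrace", representation(
    logLik = "numeric",
    iterations = "integer",
    converged = "logical",
    seed = "integer",
    interventions = "integer"
))

setValidity("FitTrace", function(object) {
    ll <- object@logLik
    if (length(ll) > 1L) {
        d <- diff(ll)
        ok <- d >= -1e-8 * abs(ll[-length(ll)])
        bad <- which(!ok)
        bad <- setdiff(bad + 1L, object@interventions)
        if (length(bad))
            return("log-likelihood must be non-decreasing (tol 1e-8 relative)")
    }
    TRUE
})

#' PhantomSpec: parameters of a synthetic multi-contrast phantom
#'
#' @slot shape integer 3-vector grid size.
#' @slot voxelSize numeric 3-vector, mm.
#' @slot geometry named list of geometry parameters (see
#'   \code{\link{phantomSpec}}).
#' @slot contrast data.frame with columns label, modality, mean, sd.
#' @slot modalities character subset of t1w, t1w_multiecho, flair, r2star.
#' @slot echoTimes numeric TE (ms) used when t1w_multiecho is requested.
#' @slot noise list(model = "rician"|"gaussian"|"none", snr > 0).
#' @slot bias list per channel of polynomial coefficients, or empty.
#' @slot seed integer.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
    shape = "integer",
    voxelSize = "numeric",
    geometry = "list",
    contrast = "data.frame",
    modalities = "character",
    echoTimes = "numeric",
    noise = "list",
    bias = "list",
    seed = "integer"
))

setValidity("PhantomSpec", function(object) {
    msg <- character(0)
    if (length(object@shape) != 3L || any(object@shape < 8L))
        msg <- c(msg, "shape must be a 3-vector of sizes >= 8")
    g <- object@geometry
    for (f in c("gmThickness", "csfThickness", "duraThickness"))
        if (!is.null(g[[f]]) && g[[f]] < 1)
            msg <- c(msg, sprintf("%s must be >= 1 voxel", f))
    if (!is.null(object@noise$snr) && object@noise$snr <= 0)
        msg <- c(msg, "SNR must be > 0")
    need <- phantomLabelNames()
    have <- unique(object@contrast$label)
    if (!all(need %in% have))
        msg <- c(msg, "contrast table must cover all geometry labels")
    if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth of a generated phantom
#'
#' @slot labels integer-valued Volume of anatomical labels (codes in
#'   \code{\link{phantomLabelNames}} order, background = 0).
#' @slot spec the PhantomSpec that generated it.
#' @slot trueR2Star named numeric, 1/ms per label.
#' @slot biasFields list per channel of applied multiplicative bias
#'   (3D arrays), empty when none.
#' @slot extras named list (e.g. low-contrast sector mask).
#' @slot seed integer.
#' @exportClass PhantomTruth
setClass("PhantomTruth", representation(
    labels = "Volume",
    spec = "PhantomSpec",
    trueR2Star = "numeric",
    biasFields = "list",
    extras = "list",
    seed = "integer"
))

#' SeparationReport: pairwise Bhattacharyya distances of a fitted model
#'
#' @slot table data.frame with columns classA, componentA, weightA,
#'   classB, componentB, weightB, distance, headline (logical: TRUE for
#'   the largest-weight representative pair of a class pair).
#' @slot configuration label of the channel combination (e.g. "t1w+flair").
#' @slot scaled logical, whether channels were z-scaled at fit time.
#' @exportClass SeparationReport
setClass("SeparationReport", representation(
    table = "data.frame",
    configuration = "character",
    scaled = "logical"
))

setValidity("SeparationReport", function(object) {
    if (nrow(object@table) && any(object@table$distance < -1e-12))
        "distances must be non-negative" else TRUE
})

#' ComparisonResult: difference of two tissue-probability-map sets
#'
#' @slot diffMaps list of Volume per class, values of B minus A in [-1, 1].
#' @slot volumeDelta named numeric, per-class volume change in ml.
#' @slot labels character(2): configuration labels A then B.
#' @exportClass ComparisonResult
setClass("ComparisonResult", representation(
    diffMaps = "list",
    volumeDelta = "numeric",
    labels = "character"
))
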