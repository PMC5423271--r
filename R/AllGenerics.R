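#' @include AllClasses.R
NULL

#' @rdname volData
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname volData
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))

#' @rdname volData
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname channelNames
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname channelNames
#' @export
setGeneric("stackMask", function(x) standardGeneric("stackMask"))

#' @rdname channelNames
#' @export
setGeneric("channelMatrix", function(x, ...) standardGeneric("channelMatrix"))

#' @rdname classNames
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname classNames
#' @export
setGeneric("classComponents", function(x, class) standardGeneric("classComponents"))

#' @rdname probMap
#' @export
setGeneric("probMap", function(x, class) standardGeneric("probMap"))

#' Pairwise Bhattacharyya distance between Gaussian densities
#'
#' For multivariate Gaussians the Bhattacharyya distance has the closed
#' form \deqn{D_B = \frac{1}{8}(\mu_1-\mu_2)^\top \bar\Sigma^{-1}
#' (\mu_1-\mu_2) + \frac{1}{2}\ln\frac{|\bar\Sigma|}
#' {\sqrt{|\Sigma_1||\Sigma_2|}},\qquad
#' \bar\Sigma = \tfrac{1}{2}(\Sigma_1+\Sigma_2).}
#' It is computed through Cholesky factorizations (log-determinants and
#' triangular solves, never an explicit inverse), is symmetric,
#' non-negative, and zero iff the two densities coincide.
#'
#' @param a,b \linkS4class{GaussianComponent}s of equal dimension, or
#'   numeric mean vectors when covariances are passed explicitly.
#' @param ... passed to methods.
#' @return Non-negative scalar distance (dimensionless).
#' @export
setGeneric("bhattacharyya", function(a, b, ...) standardGeneric("bhattacharyya"))
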