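#' @include segmentation.R
NULL

## Stable log-determinant via Cholesky.
chollogdet <- function(S) 2 * sum(log(diag(chol(S))))

#' @rdname bhattacharyya
#' @param covA,covB covariance matrices accompanying numeric means.
#' @export
setMethod("bhattacharyya", signature("GaussianComponent", "GaussianComponent"),
          function(a, b, ...) {
    bhattacharyya(a@mean, b@mean, covA = a@covariance, covB = b@covariance)
})

#' @rdname bhattacharyya
setMethod("bhattacharyya", signature("numeric", "numeric"),
          function(a, b, covA, covB, ...) {
    if (length(a) != length(b))
        stop("dimension mismatch between the two means")
    covA <- as.matrix(covA); covB <- as.matrix(covB)
    d <- length(a)
    if (!all(dim(covA) == d) || !all(dim(covB) == d))
        stop("covariance dimension does not match the means")
    Sbar <- (covA + covB) / 2
    R <- tryCatch(chol(Sbar), error = function(e)
        stop("covariance not positive-definite"))
    dm <- a - b
    z <- backsolve(R, dm, transpose = TRUE)
    term1 <- sum(z * z) / 8
    ld1 <- tryCatch(chollogdet(covA), error = function(e)
        stop("covariance not positive-definite"))
    ld2 <- tryCatch(chollogdet(covB), error = function(e)
        stop("covariance not positive-definite"))
    term2 <- 0.5 * (2 * sum(log(diag(R))) - 0.5 * (ld1 + ld2))
    term1 + term2
})

#' Hellinger distance from a Bhattacharyya distance
#'
#' Convenience transform \eqn{H = \sqrt{1 - e^{-D_B}}}.
#'
#' @param db Bhattacharyya distance(s).
#' @return Hellinger distance(s) in [0, 1).
#' @export
hellinger <- function(db) sqrt(1 - exp(-db))

#' Pairwise separation report of a fitted model
#'
#' Computes Bhattacharyya distances between all components of every
#' class pair.  The headline distance of a class pair is the distance
#' between the largest-weight component of each class (for single
#' Gaussian classes that is the class itself) — the convention used when
#' a heterogeneous compartment such as CSF is modeled as a mixture.
#'
#' @param model a fitted \linkS4class{TissueModel}.
#' @param configuration label stored in the report (default: the
#'   model's channel names joined by "+").
#' @return A \linkS4class{SeparationReport}.
#' @export
classSeparation <- function(model, configuration = NULL) {
    if (!model@fitted)
        stop("model is not fitted; run emFit() first")
    if (is.null(configuration))
        configuration <- paste(sort(tolower(model@channelNames)),
                               collapse = "+")
    cn <- model@classNames
    rows <- list()
    for (ka in seq_along(cn)) for (kb in seq_along(cn)) {
        if (kb <= ka) next
        ca <- model@components[[ka]]
        cb <- model@components[[kb]]
        repA <- which.max(vapply(ca, function(g) g@weight, 0))
        repB <- which.max(vapply(cb, function(g) g@weight, 0))
        for (ia in seq_along(ca)) for (ib in seq_along(cb)) {
            rows[[length(rows) + 1L]] <- data.frame(
                classA = cn[ka],
                componentA = if (length(ca) > 1L)
                    paste0(cn[ka], ia) else cn[ka],
                weightA = ca[[ia]]@weight,
                classB = cn[kb],
                componentB = if (length(cb) > 1L)
                    paste0(cn[kb], ib) else cn[kb],
                weightB = cb[[ib]]@weight,
                distance = bhattacharyya(ca[[ia]], cb[[ib]]),
                headline = (ia == repA && ib == repB),
                stringsAsFactors = FALSE)
        }
    }
    new("SeparationReport",
        table = do.call(rbind, rows),
        configuration = configuration,
        scaled = length(model@scaling) > 0)
}

#' Extract one headline distance from a report
#'
#' @param report a \linkS4class{SeparationReport}.
#' @param classA,classB class labels (order-free).
#' @return The largest-weight-component distance between the two classes.
#' @export
headlineDistance <- function(report, classA, classB) {
    t <- report@table
    sel <- t$headline &
        ((t$classA == classA & t$classB == classB) |
         (t$classA == classB & t$classB == classA))
    if (!any(sel)) stop("no headline distance for ", classA, "-", classB)
    t$distance[sel][1L]
}

setMethod("show", "SeparationReport", function(object) {
    cat("SeparationReport [", object@configuration, "]",
        if (object@scaled) "(z-scaled channels)", "\n")
    h <- object@table[object@table$headline, ]
    for (i in seq_len(nrow(h)))
        cat(sprintf("  %s-%s: %.4g\n", h$componentA[i], h$componentB[i],
                    h$distance[i]))
})

#' Write a separation report as CSV and JSON
#'
#' @param report a \linkS4class{SeparationReport}.
#' @param prefix output path prefix (writes \code{<prefix>.csv} and
#'   \code{<prefix>.json}).
#' @return Files written, invisibly.
#' @export
writeSeparationReport <- function(report, prefix) {
    fcsv <- paste0(prefix, ".csv"); fjson <- paste0(prefix, ".json")
    utils::write.csv(report@table, fcsv, row.names = FALSE)
    writeLines(as.character(jsonlite::toJSON(
        list(configuration = report@configuration,
             scaled = report@scaled, table = report@table),
        digits = NA, auto_unbox = TRUE, dataframe = "rows")), fjson)
    invisible(c(fcsv, fjson))
}

#' Paired comparison of separation across configurations
#'
#' Two-sided paired t-test on a chosen headline distance across matched
#' fits (same replicate order in both lists) — the standard way to ask
#' whether one channel combination separates two tissue densities better
#' than another.
#'
#' @param reportsA,reportsB equal-length lists of
#'   \linkS4class{SeparationReport}, matched by replicate.
#' @param classA,classB the class pair whose headline distance is
#'   compared (default GM vs CSF).
#' @return list(meanDifference, t, p, df, n, degenerate): mean of B - A;
#'   \code{degenerate} is TRUE when all differences are exactly 0 (t is
#'   then reported as 0 with p = 1).
#' @export
pairedSeparationTest <- function(reportsA, reportsB,
                                 classA = "GM", classB = "CSF") {
    if (length(reportsA) != length(reportsB))
        stop("report lists must have equal length")
    n <- length(reportsA)
    if (n < 2L) stop("at least 2 matched replicates are required")
    da <- vapply(reportsA, headlineDistance, 0, classA = classA,
                 classB = classB)
    db <- vapply(reportsB, headlineDistance, 0, classA = classA,
                 classB = classB)
    dif <- db - da
    if (all(dif == 0))
        return(list(meanDifference = 0, t = 0, p = 1, df = n - 1L,
                    n = n, degenerate = TRUE))
    tt <- stats::t.test(dif, alternative = "two.sided")
    list(meanDifference = mean(dif),
         t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), n = n, degenerate = FALSE)
}
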