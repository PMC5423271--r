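test_that("Bhattacharyya closed forms hold exactly", {
    g <- gcomp(c(1, 2), matrix(c(2, 0.3, 0.3, 1), 2))
    expect_equal(bhattacharyya(g, g), 0)
    ## 1D, means 0 and 2, unit variances: (1/8) * 4 = 0.5
    expect_equal(bhattacharyya(gcomp(0, matrix(1)), gcomp(2, matrix(1))),
                 0.5, tolerance = 1e-12)
    ## 1D, equal means, variances 1 and 4: (1/2) ln(2.5/2)
    expect_equal(bhattacharyya(gcomp(0, matrix(1)), gcomp(0, matrix(4))),
                 0.5 * log(2.5 / 2), tolerance = 1e-12)
    expect_lt(abs(0.5 * log(2.5 / 2) - 0.111572), 1e-6)
})

test_that("distance agrees with numerical integration of -ln integral sqrt(pq)", {
    ## 1D cases
    expect_equal(bhattacharyya(gcomp(0, matrix(1)), gcomp(2, matrix(1))),
                 numericBhattacharyya(0, 1, 2, 1), tolerance = 1e-4)
    expect_equal(bhattacharyya(gcomp(0, matrix(1)), gcomp(0, matrix(4))),
                 numericBhattacharyya(0, 1, 0, 4), tolerance = 1e-4)
    ## 2D cases including correlated covariances
    S1 <- matrix(c(1, 0.4, 0.4, 2), 2)
    S2 <- matrix(c(1.5, -0.2, -0.2, 0.8), 2)
    expect_equal(bhattacharyya(gcomp(c(0, 0), S1), gcomp(c(1.5, -1), S2)),
                 numericBhattacharyya(c(0, 0), S1, c(1.5, -1), S2),
                 tolerance = 1e-4)
    expect_equal(bhattacharyya(gcomp(c(2, 1), S2), gcomp(c(2, 1), S1)),
                 numericBhattacharyya(c(2, 1), S2, c(2, 1), S1),
                 tolerance = 1e-4)
})

test_that("distance is symmetric, non-negative, zero iff equal", {
    set.seed(11)
    for (i in 1:20) {
        d <- sample(1:3, 1)
        A <- crossprod(matrix(rnorm(d * d), d)) + diag(0.2, d)
        B <- crossprod(matrix(rnorm(d * d), d)) + diag(0.2, d)
        m1 <- rnorm(d); m2 <- rnorm(d)
        g1 <- gcomp(m1, A); g2 <- gcomp(m2, B)
        dab <- bhattacharyya(g1, g2)
        expect_gte(dab, 0)
        expect_equal(dab, bhattacharyya(g2, g1), tolerance = 1e-12)
    }
    expect_equal(bhattacharyya(gcomp(c(1, 1), diag(2)),
                               gcomp(c(1, 1), diag(2))), 0)
    expect_gt(bhattacharyya(gcomp(c(1, 1), diag(2)),
                            gcomp(c(1, 1), 2 * diag(2))), 0)
})

test_that("dimension and definiteness violations are errors", {
    expect_error(bhattacharyya(c(0, 0), 0, covA = diag(2), covB = matrix(1)),
                 "dimension")
    expect_error(bhattacharyya(c(0, 0), c(1, 1),
                               covA = matrix(c(1, 2, 2, 1), 2),
                               covB = diag(2)),
                 "positive-definite")
})

test_that("distances are invariant to joint affine channel rescaling", {
    set.seed(4)
    A <- matrix(c(3, 0.5, -0.2, 1.4), 2)   # invertible channel mix
    b <- c(10, -5)
    g1 <- gcomp(c(1, 2), matrix(c(2, 0.3, 0.3, 1), 2))
    g2 <- gcomp(c(-1, 4), matrix(c(1, -0.2, -0.2, 3), 2))
    t1 <- gcomp(A %*% g1@mean + b, A %*% g1@covariance %*% t(A))
    t2 <- gcomp(A %*% g2@mean + b, A %*% g2@covariance %*% t(A))
    expect_equal(bhattacharyya(t1, t2), bhattacharyya(g1, g2),
                 tolerance = 1e-8)
})

test_that("hellinger is the bounded transform of the distance", {
    expect_equal(hellinger(0), 0)
    expect_equal(hellinger(0.5), sqrt(1 - exp(-0.5)))
    expect_lt(hellinger(20), 1)
})

test_that("headline distance uses the largest-weight mixture component", {
    ## CSF as a 0.58/0.42 mixture; the 0.58 component carries the headline
    gm <- list(gcomp(5, matrix(1)))
    csf <- list(gcomp(0, matrix(1), 0.58), gcomp(20, matrix(1), 0.42))
    m <- directModel(c("GM", "CSF"), list(gm, csf), channelNames = "t1w")
    rep <- classSeparation(m, configuration = "t1w")
    expect_equal(headlineDistance(rep, "GM", "CSF"),
                 bhattacharyya(gm[[1]], csf[[1]]))
    ## all component pairs are present and labeled
    expect_equal(nrow(rep@table), 2L)
    expect_setequal(rep@table$componentB, c("CSF1", "CSF2"))
    ## identical classes are at distance zero
    m0 <- directModel(c("A", "B"), list(list(gcomp(1, matrix(2))),
                                        list(gcomp(1, matrix(2)))))
    expect_equal(headlineDistance(classSeparation(m0, "x"), "A", "B"), 0)
})

test_that("report survives model serialization", {
    st <- confoundStudy()
    m <- st$fits[["t1w+flair"]]$model
    rep1 <- classSeparation(m, configuration = "t1w+flair")
    f <- tempfile(fileext = ".json")
    saveModel(m, f)
    rep2 <- classSeparation(loadModel(f), configuration = "t1w+flair")
    expect_equal(rep2@table$distance, rep1@table$distance,
                 tolerance = 1e-10)
    ## CSV/JSON writers produce readable tables
    pre <- tempfile()
    files <- writeSeparationReport(rep1, pre)
    tab <- utils::read.csv(files[1])
    expect_equal(nrow(tab), nrow(rep1@table))
})

test_that("paired separation test matches the closed-form paired t", {
    mkRep <- function(d) {
        m <- directModel(c("GM", "CSF"),
                         list(list(gcomp(sqrt(8 * d), matrix(1))),
                              list(gcomp(0, matrix(1)))),
                         channelNames = "t1w")
        classSeparation(m, configuration = "x")
    }
    ## b identical to a: degenerate zero-difference case
    a <- lapply(c(1, 2, 3, 4), mkRep)
    outc <- pairedSeparationTest(a, a)
    expect_equal(outc$meanDifference, 0)
    expect_equal(outc$t, 0)
    expect_true(outc$degenerate)

    ## constructed differences of ~1 with tiny jitter
    jit <- c(1e-3, -1e-3, 5e-4, -5e-4)
    b <- lapply(c(1, 2, 3, 4) + 1 + jit, mkRep)
    out <- pairedSeparationTest(a, b)
    da <- sapply(a, headlineDistance, "GM", "CSF")
    db <- sapply(b, headlineDistance, "GM", "CSF")
    ref <- stats::t.test(db - da)
    expect_equal(out$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(out$p, ref$p.value, tolerance = 1e-10)
    expect_lt(out$p, 1e-3)
    expect_error(pairedSeparationTest(a, b[1:2]), "equal length")
    expect_error(pairedSeparationTest(a[1], b[1]), "at least 2")
})
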