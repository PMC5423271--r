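test_that("default 48^3 phantom contains all eight labels", {
    truth <- buildLabels(phantomSpec(seed = 1))
    counts <- table(volData(truth@labels))
    expect_setequal(as.integer(names(counts)), unname(phantomLabels()))
    expect_true(all(counts > 0))
})

test_that("dura arc fraction 0 removes the dura sheet", {
    truth <- buildLabels(phantomSpec(seed = 1,
                                     geometry = list(duraArcFrac = 0)))
    expect_equal(sum(labelMask(truth, "DURA")), 0L)
    truth2 <- buildLabels(phantomSpec(seed = 1,
                                      geometry = list(vesselCount = 0L)))
    expect_equal(sum(labelMask(truth2, "VESSEL")), 0L)
})

test_that("GM ribbon thickness matches the requested value along radial rays", {
    gt <- 4
    ## plain shells: confounds off so every radial GM run is unbroken
    truth <- buildLabels(phantomSpec(seed = 1,
        geometry = list(gmThickness = gt, susceptRadius = 0,
                        duraArcFrac = 0, vesselCount = 0L)))
    lab <- volData(truth@labels)
    ctr <- (dim(lab) + 1) / 2
    gmCode <- phantomLabels()[["GM"]]
    ## ray-marching oracle: step outward along random directions and
    ## count the contiguous GM run
    set.seed(8)
    runs <- replicate(40, {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        rs <- seq(0, min(dim(lab)) / 2 - 1, by = 0.25)
        pts <- round(outer(rs, u) + rep(ctr, each = length(rs)))
        codes <- lab[pts]
        sum(rle(codes)$lengths[rle(codes)$values == gmCode][1]) * 0.25
    })
    runs <- runs[!is.na(runs)]
    expect_true(all(abs(runs - gt) <= 1.01))
})

test_that("geometry that cannot fit is rejected", {
    expect_error(buildLabels(phantomSpec(shape = c(16L, 16L, 16L))),
                 "does not fit")
})

test_that("phantom generation is bit-deterministic given spec + seed", {
    r1 <- renderChannels(buildLabels(phantomSpec(seed = 33)))
    r2 <- renderChannels(buildLabels(phantomSpec(seed = 33)))
    expect_identical(volData(r1$truth@labels), volData(r2$truth@labels))
    for (i in seq_along(r1$stack@channels))
        expect_identical(volData(r1$stack@channels[[i]]),
                         volData(r2$stack@channels[[i]]))
    r3 <- renderChannels(buildLabels(phantomSpec(seed = 34)))
    expect_false(identical(volData(r1$stack@channels[[1]]),
                           volData(r3$stack@channels[[1]])))
})

test_that("noiseless rendering equals the contrast table exactly", {
    sp <- phantomSpec(seed = 2, noise = list(model = "none", snr = Inf),
                      contrast = within(defaultContrastTable(), sd <- sd * 0))
    r <- renderChannels(buildLabels(sp))
    lab <- volData(r$truth@labels)
    cr <- multiseg:::contrastRow(sp@contrast, "t1w")
    t1 <- volData(r$stack@channels[[1]])
    for (nm in phantomLabelNames()) {
        m <- lab == phantomLabels()[[nm]]
        expect_equal(unique(t1[m]), unname(cr$mean[[nm]]))
    }
})

test_that("default contrasts encode the confound structure", {
    r <- renderChannels(buildLabels(phantomSpec(seed = 3)))
    lab <- volData(r$truth@labels)
    t1 <- volData(r$stack@channels[[1]])
    fl <- volData(r$stack@channels[[2]])
    gm <- lab == phantomLabels()[["GM"]]
    dura <- lab == phantomLabels()[["DURA"]]
    ves <- lab == phantomLabels()[["VESSEL"]]
    ## dura isointense to GM on t1w (within 2%), dark on flair (< 50%)
    expect_lt(abs(mean(t1[dura]) - mean(t1[gm])) / mean(t1[gm]), 0.02)
    expect_lt(mean(fl[dura]), 0.5 * mean(fl[gm]))
    ## vessels bright on t1w (>= 130% of GM)
    expect_gte(mean(t1[ves]), 1.3 * mean(t1[gm]))
    ## susceptibility zone: attenuated t1w, unattenuated flair
    sus <- lab == phantomLabels()[["SUSCEPT_GM"]]
    expect_lt(mean(t1[sus]), 0.7 * mean(t1[gm]))
    expect_gt(mean(fl[sus]), 0.9 * mean(fl[gm]))
})

test_that("multi-echo rendering round-trips through the R2* fit", {
    sp <- phantomSpec(seed = 4, modalities = c("t1w_multiecho", "flair"),
                      noise = list(model = "none", snr = Inf),
                      contrast = within(defaultContrastTable(), sd <- sd * 0))
    r <- renderChannels(buildLabels(sp))
    expect_s4_class(r$echoes, "MultiEchoSeries")
    expect_equal(r$echoes@echoTimes, ACQ_TE)
    fit <- fitR2Star(r$echoes)
    wm <- labelMask(r$truth, "WM")
    expect_equal(unique(round(volData(fit@rate)[wm], 10)), 0.045)
    ## the echo-averaged channel matches the t1w contrast target
    cr <- multiseg:::contrastRow(sp@contrast, "t1w")
    t1 <- volData(r$stack@channels[[1]])
    expect_equal(mean(t1[wm]), unname(cr$mean[["WM"]]), tolerance = 1e-9)
})

test_that("labels are recoverable from noiseless intensities by nearest mean", {
    sp <- phantomSpec(seed = 5, noise = list(model = "none", snr = Inf),
                      contrast = within(defaultContrastTable(), sd <- sd * 0))
    r <- renderChannels(buildLabels(sp))
    lab <- volData(r$truth@labels)
    X <- cbind(as.vector(volData(r$stack@channels[[1]])),
               as.vector(volData(r$stack@channels[[2]])))
    t1m <- multiseg:::contrastRow(sp@contrast, "t1w")$mean
    flm <- multiseg:::contrastRow(sp@contrast, "flair")$mean
    M <- cbind(t1m[phantomLabelNames()], flm[phantomLabelNames()])
    near <- apply(X, 1, function(x)
        phantomLabels()[phantomLabelNames()[
            which.min(colSums((t(M) - x)^2))]])
    expect_equal(unname(near), as.vector(lab))
})

test_that("Rician noise at high SNR concentrates on the label mean", {
    sp <- phantomSpec(seed = 6, noise = list(model = "rician", snr = 50),
                      contrast = within(defaultContrastTable(), sd <- sd * 0))
    r <- renderChannels(buildLabels(sp))
    lab <- volData(r$truth@labels)
    t1 <- volData(r$stack@channels[[1]])
    for (nm in c("GM", "WM", "CSF")) {
        m <- lab == phantomLabels()[[nm]]
        tgt <- multiseg:::contrastRow(sp@contrast, "t1w")$mean[[nm]]
        expect_lt(abs(mean(t1[m]) - tgt) / tgt, 0.01)
    }
})

test_that("the default suite provides four reproducible named phantoms", {
    s1 <- makeDefaultSuite(seed = 9)
    expect_gte(length(s1), 4L)
    expect_setequal(names(s1), c("dura", "vessel", "susceptibility",
                                 "occipital-low-contrast"))
    s2 <- makeDefaultSuite(seed = 9)
    for (nm in names(s1))
        expect_identical(volData(s1[[nm]]$stack@channels[[1]]),
                         volData(s2[[nm]]$stack@channels[[1]]))
    ## occipital variant: t1w GM/WM contrast collapses inside the sector
    occ <- s1[["occipital-low-contrast"]]
    sect <- occ$truth@extras$lowContrastSector
    expect_true(sum(sect) > 0)
    lab <- volData(occ$truth@labels)
    t1 <- volData(occ$stack@channels[[1]])
    fl <- volData(occ$stack@channels[[2]])
    gmS <- sect & lab == phantomLabels()[["GM"]]
    wmS <- sect & lab == phantomLabels()[["WM"]]
    expect_lt(abs(mean(t1[wmS]) - mean(t1[gmS])), 4)     # collapsed
    expect_gt(abs(mean(fl[wmS]) - mean(fl[gmS])), 10)    # retained
})

test_that("a suite phantom segments to completion within the budget", {
    s <- makeDefaultSuite(seed = 10)
    p <- s[["dura"]]
    t0 <- proc.time()[["elapsed"]]
    fit <- suppressMessages(segment(p$stack, priors = truthPriors(p$truth),
                                    config = list(maxIter = 120), seed = 1))
    expect_lt(proc.time()[["elapsed"]] - t0, 60)
    expect_s4_class(fit$maps, "TissueProbabilityMaps")
})

test_that("truth priors sum to 1 per voxel and favor the right tissue", {
    truth <- buildLabels(phantomSpec(seed = 1))
    pri <- truthPriors(truth)
    tot <- Reduce("+", lapply(pri, volData))
    expect_lt(max(abs(tot - 1)), 1e-9)
    gmP <- volData(pri[[1]])
    expect_gt(mean(gmP[labelMask(truth, "GM")]), 0.4)
    ## dura still receives appreciable GM prior mass (the atlas-blur
    ## effect that reproduces the unimodal misclassification)
    expect_gt(mean(gmP[labelMask(truth, "DURA")]), 0.15)
})

test_that("phantoms write to disk with truth metadata", {
    sp <- smallPhantomSpec(seed = 12, modalities = c("t1w", "flair"))
    r <- renderChannels(buildLabels(sp))
    dir <- tempfile("ph_")
    files <- writePhantom(r, dir)
    expect_true(all(file.exists(files)))
    lb <- readVolume(file.path(dir, "labels.nii.gz"))
    expect_equal(volData(lb), volData(r$truth@labels))
    meta <- jsonlite::fromJSON(file.path(dir, "truth.json"))
    expect_equal(meta$seed, 12)
})
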