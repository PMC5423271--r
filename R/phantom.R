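#' @include relaxometry.R
NULL

#' Phantom label codes
#'
#' Integer codes of the ground-truth label volume: BG = 0, WM = 1,
#' GM = 2, CSF = 3, DURA = 4, VESSEL = 5, CONNECTIVE = 6,
#' SUSCEPT_GM = 7 (gray matter inside the susceptibility-dropout zone).
#'
#' @return Named integer vector of codes.
#' @export
phantomLabels <- function()
    c(BG = 0L, WM = 1L, GM = 2L, CSF = 3L, DURA = 4L, VESSEL = 5L,
      CONNECTIVE = 6L, SUSCEPT_GM = 7L)

#' @rdname phantomLabels
#' @export
phantomLabelNames <- function() names(phantomLabels())

#' Default per-label, per-modality contrast table
#'
#' Signal means and SDs (arbitrary units; 1/ms for r2star) chosen to
#' reproduce the confound structure of multimodal brain MRI:
#' dura and connective tissue isointense to gray matter on T1w but dark
#' (under half the GM mean) on FLAIR; vessels bright on T1w (>= 130%%
#' of GM) with a wide spread emulating partial-volume mixing, dark on
#' FLAIR; gray matter in the susceptibility zone attenuated on T1w
#' (x0.6) but not on FLAIR, with elevated R2*; CSF near-nulled on FLAIR.
#' R2* truths (1/ms): CSF 0.001, GM 0.04, WM 0.045, VESSEL 0.15,
#' SUSCEPT_GM 0.12 — plausible-order defaults, recorded here, not
#' literature fits.
#'
#' @return data.frame with columns label, modality, mean, sd.
#' @export
defaultContrastTable <- function() {
    lab <- phantomLabelNames()
    t1w <- data.frame(label = lab, modality = "t1w",
        mean = c(4, 105, 70, 18, 70, 95, 70.5, 42),
        sd   = c(1.5, 6, 6, 3, 5, 18, 5, 6))
    flair <- data.frame(label = lab, modality = "flair",
        mean = c(4, 65, 85, 12, 30, 22, 30, 85),
        sd   = c(1.5, 6, 6, 3, 5, 8, 5, 6))
    r2s <- data.frame(label = lab, modality = "r2star",
        mean = c(0.01, 0.045, 0.04, 0.001, 0.05, 0.15, 0.05, 0.12),
        sd   = c(0.003, 0.004, 0.004, 0.0005, 0.005, 0.01, 0.005, 0.01))
    rbind(t1w, flair, r2s)
}

#' Specify a synthetic multi-contrast phantom
#'
#' Geometry is a nested set of concentric shells (WM core, GM ribbon,
#' CSF shell) with the confound structures threaded in: a dura sheet
#' hugging the outer GM boundary over a polar arc, vessel tubes through
#' the CSF adjacent to GM, connective patches outside the CSF, and a
#' marked susceptibility subregion of GM.
#'
#' @param shape integer 3-vector, grid size (default 48^3).
#' @param voxelSize mm (default 1 mm isotropic).
#' @param geometry named list overriding any of: margin (voxels of
#'   background padding, 4), csfThickness (3), gmThickness (4),
#'   duraThickness (2), duraArcFrac (fraction of the sphere covered by
#'   the dura cap, 0.3), vesselCount (3), vesselRadius (1.2),
#'   connectiveCount (2), connectiveRadius (2.5), susceptRadius (6).
#' @param contrast contrast table as from
#'   \code{\link{defaultContrastTable}}.
#' @param modalities subset of "t1w", "t1w_multiecho", "flair", "r2star"
#'   ("t1w_multiecho" replaces "t1w" by an echo-averaged image computed
#'   from a generated \linkS4class{MultiEchoSeries}).
#' @param echoTimes TE in ms for multi-echo rendering
#'   (default 1.48, 2.98, 4.48, 5.98, 7.48).
#' @param noise list(model = "rician" | "gaussian" | "none", snr);
#'   the noise SD per modality is (GM mean)/snr, applied on top of the
#'   per-label biological SD from the contrast table.
#' @param bias optional list(order, coefficients = named list per
#'   channel) of multiplicative polynomial bias fields (log scale).
#' @param seed integer; generation is bit-reproducible given the spec.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(48L, 48L, 48L), voxelSize = c(1, 1, 1),
                        geometry = list(), contrast = defaultContrastTable(),
                        modalities = c("t1w", "flair"),
                        echoTimes = c(1.48, 2.98, 4.48, 5.98, 7.48),
                        noise = list(model = "rician", snr = 50),
                        bias = list(), seed = 1L) {
    g <- utils::modifyList(
        list(margin = 4, csfThickness = 3, gmThickness = 4,
             duraThickness = 2, duraArcFrac = 0.3, vesselCount = 3L,
             vesselRadius = 1.2, connectiveCount = 2L,
             connectiveRadius = 2.5, susceptRadius = 6), geometry)
    noise <- utils::modifyList(list(model = "rician", snr = 50), noise)
    new("PhantomSpec", shape = as.integer(shape),
        voxelSize = as.numeric(voxelSize), geometry = g,
        contrast = contrast, modalities = modalities,
        echoTimes = as.numeric(echoTimes), noise = noise,
        bias = bias, seed = as.integer(seed))
}

#' Build the ground-truth label volume of a phantom
#'
#' Deterministic given the spec: concentric WM/GM/CSF shells, DURA as a
#' thin sheet carved from the CSF immediately outside the GM boundary
#' over a polar cap, VESSEL tubes (parallel chords through the CSF
#' shell), CONNECTIVE patches outside the CSF, and SUSCEPT_GM as a
#' marked spherical GM subregion on the inferior side.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{PhantomTruth}.
#' @export
buildLabels <- function(spec) {
    g <- spec@geometry
    dm <- spec@shape
    rCSF <- min(dm) / 2 - g$margin
    rGM <- rCSF - g$csfThickness
    rWM <- rGM - g$gmThickness
    if (rWM < 2)
        stop("geometry does not fit: ribbon + margins exceed the radius")
    ctr <- (dm + 1) / 2
    xs <- seq_len(dm[1L]) - ctr[1L]
    ys <- seq_len(dm[2L]) - ctr[2L]
    zs <- seq_len(dm[3L]) - ctr[3L]
    X <- array(xs, dm)
    Y <- array(rep(ys, each = dm[1L]), dm)
    Z <- array(rep(zs, each = dm[1L] * dm[2L]), dm)
    R <- sqrt(X^2 + Y^2 + Z^2)
    lab <- array(phantomLabels()[["BG"]], dm)
    lab[R <= rCSF] <- phantomLabels()[["CSF"]]
    lab[R <= rGM] <- phantomLabels()[["GM"]]
    lab[R <= rWM] <- phantomLabels()[["WM"]]

    ## dura: polar cap of solid-angle fraction duraArcFrac
    if (g$duraArcFrac > 0 && g$duraThickness >= 1) {
        cosT <- ifelse(R > 0, Z / pmax(R, 1e-9), 1)
        cap <- cosT > (1 - 2 * g$duraArcFrac)
        sheet <- R > rGM & R <= rGM + g$duraThickness & cap &
            lab == phantomLabels()[["CSF"]]
        lab[sheet] <- phantomLabels()[["DURA"]]
    }

    ## vessels: chords along y through the CSF shell, lower hemisphere
    nv <- g$vesselCount
    if (nv > 0) {
        for (v in seq_len(nv)) {
            phi <- pi * (v - 1) / nv
            px <- (rGM + 1.5) * cos(phi)
            pz <- -(rGM + 1.5) * sin(phi)
            d2 <- (X - px)^2 + (Z - pz)^2
            tube <- d2 <= g$vesselRadius^2 &
                lab == phantomLabels()[["CSF"]]
            lab[tube] <- phantomLabels()[["VESSEL"]]
        }
    }

    ## connective patches just outside the CSF shell
    ncn <- g$connectiveCount
    if (ncn > 0) {
        dirs <- list(c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(1, 0, 0))
        for (i in seq_len(min(ncn, length(dirs)))) {
            cc <- dirs[[i]] * (rCSF + 1 + g$connectiveRadius / 2)
            d2 <- (X - cc[1L])^2 + (Y - cc[2L])^2 + (Z - cc[3L])^2
            patch <- d2 <= g$connectiveRadius^2 &
                lab == phantomLabels()[["BG"]]
            lab[patch] <- phantomLabels()[["CONNECTIVE"]]
        }
    }

    ## susceptibility zone: inferior GM subregion
    if (g$susceptRadius > 0) {
        sc <- c(0, 0, -(rWM + rGM) / 2)
        d2 <- (X - sc[1L])^2 + (Y - sc[2L])^2 + (Z - sc[3L])^2
        zone <- d2 <= g$susceptRadius^2 & lab == phantomLabels()[["GM"]]
        lab[zone] <- phantomLabels()[["SUSCEPT_GM"]]
    }

    aff <- diag(c(spec@voxelSize, 1))
    r2s <- spec@contrast[spec@contrast$modality == "r2star", ]
    trueR2 <- stats::setNames(r2s$mean, r2s$label)
    new("PhantomTruth", labels = Volume(lab, affine = aff), spec = spec,
        trueR2Star = trueR2, biasFields = list(), extras = list(),
        seed = spec@seed)
}

#' Logical mask of one or more phantom labels
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param labels label name(s) from \code{\link{phantomLabelNames}}.
#' @param dilate dilation iterations (26-neighbourhood) applied to the
#'   mask, default 0.
#' @return Logical 3D array.
#' @export
labelMask <- function(truth, labels, dilate = 0L) {
    codes <- phantomLabels()[labels]
    if (anyNA(codes)) stop("unknown label(s)")
    m <- array(truth@labels@data %in% codes, dim(truth@labels@data))
    if (dilate > 0L) m <- dilate3D(m, dilate)
    m
}

## Contrast lookup helpers.
contrastRow <- function(tab, modality) {
    t <- tab[tab$modality == modality, ]
    if (!nrow(t)) stop("contrast table missing modality: ", modality)
    list(mean = stats::setNames(t$mean, t$label),
         sd = stats::setNames(t$sd, t$label))
}

## Apply the spec noise model on top of clean per-voxel signal.
applyNoise <- function(v, model, sigma) {
    if (model == "none" || sigma <= 0 || !is.finite(sigma)) return(v)
    n <- length(v)
    if (model == "gaussian") return(v + stats::rnorm(n, 0, sigma))
    if (model == "rician")
        return(sqrt((v + stats::rnorm(n, 0, sigma))^2 +
                    stats::rnorm(n, 0, sigma)^2))
    stop("unknown noise model: ", model)
}

#' Render the intensity channels of a phantom
#'
#' Per modality, voxel intensity = label mean + label SD x standard
#' normal, then the magnitude (Rician) transform when the noise model is
#' "rician" (thermal noise SD = GM mean / SNR; the r2star channel, being
#' a derived parametric map, only receives its per-label Gaussian SD).
#' With "t1w_multiecho", echoes are generated as
#' \eqn{S_0(label) e^{-R_2^*(label) TE}} (with the per-voxel S0 spread
#' matching the t1w contrast SD) before noise, and the t1w channel is
#' their voxelwise mean.  Configured bias fields multiply the clean
#' signal.  Bit-reproducible given the spec seed.
#'
#' @param truth a \linkS4class{PhantomTruth} from
#'   \code{\link{buildLabels}}.
#' @param spec a \linkS4class{PhantomSpec}; defaults to the one stored
#'   in \code{truth}.
#' @return list(stack = \linkS4class{ChannelStack},
#'   echoes = \linkS4class{MultiEchoSeries} or NULL,
#'   truth = the input truth with bias fields recorded).
#' @export
renderChannels <- function(truth, spec = truth@spec) {
    lab <- truth@labels@data
    dm <- dim(lab)
    aff <- truth@labels@affine
    labNames <- phantomLabelNames()[match(lab, phantomLabels())]
    mods <- spec@modalities
    noiseModel <- spec@noise$model
    snr <- spec@noise$snr
    chans <- list(); chanNames <- character(0)
    echoes <- NULL

    biasFor <- function(channel) {
        b <- spec@bias
        if (!length(b) || is.null(b$coefficients[[channel]]))
            return(NULL)
        basis <- polyBasis3D(normalizedCoords(dm), b$order)
        array(exp(as.vector(basis %*% b$coefficients[[channel]])), dm)
    }
    biasFields <- list()

    renderDirect <- function(modality, channel, rician = TRUE) {
        cr <- contrastRow(spec@contrast, modality)
        if (!all(labNames %in% names(cr$mean)))
            stop("contrast table missing label(s) for ", modality)
        withSeed(deriveSeed(spec@seed, paste0("render_", channel)), {
            v <- cr$mean[labNames] +
                cr$sd[labNames] * stats::rnorm(length(lab))
            bf <- biasFor(channel)
            if (!is.null(bf)) {
                v <- v * as.vector(bf)
                biasFields[[channel]] <<- bf
            }
            sigma <- cr$mean[["GM"]] / snr
            nm <- if (rician) noiseModel else
                (if (noiseModel == "none") "none" else "gaussian")
            array(applyNoise(v, nm, sigma), dm)
        })
    }

    for (m in mods) {
        if (m == "t1w") {
            chans <- c(chans, list(Volume(renderDirect("t1w", "t1w"),
                                          affine = aff)))
            chanNames <- c(chanNames, "t1w")
        } else if (m == "t1w_multiecho") {
            cr <- contrastRow(spec@contrast, "t1w")
            te <- spec@echoTimes
            r2 <- truth@trueR2Star[labNames]
            edecByLab <- vapply(phantomLabelNames(), function(l)
                mean(exp(-truth@trueR2Star[[l]] * te)), 0)
            s0mean <- cr$mean[labNames] / edecByLab[labNames]
            s0sd <- cr$sd[labNames] / edecByLab[labNames]
            echoVols <- withSeed(
                deriveSeed(spec@seed, "render_multiecho"), {
                s0v <- s0mean + s0sd * stats::rnorm(length(lab))
                bf <- biasFor("t1w")
                if (!is.null(bf)) {
                    s0v <- s0v * as.vector(bf)
                    biasFields[["t1w"]] <<- bf
                }
                sigma <- (cr$mean[["GM"]] / mean(exp(-truth@trueR2Star[["GM"]] * te))) *
                    exp(-truth@trueR2Star[["GM"]] * te[1L]) / snr
                lapply(te, function(t_) {
                    s <- s0v * exp(-r2 * t_)
                    Volume(array(applyNoise(s, noiseModel, sigma), dm),
                           affine = aff)
                })
            })
            echoes <- MultiEchoSeries(echoVols, te)
            chans <- c(chans, list(combineEchoes(echoes)))
            chanNames <- c(chanNames, "t1w")
        } else if (m == "flair") {
            chans <- c(chans, list(Volume(renderDirect("flair", "flair"),
                                          affine = aff)))
            chanNames <- c(chanNames, "flair")
        } else if (m == "r2star") {
            chans <- c(chans, list(Volume(
                renderDirect("r2star", "r2star", rician = FALSE),
                affine = aff)))
            chanNames <- c(chanNames, "r2star")
        } else stop("unknown modality: ", m)
    }
    truth@biasFields <- biasFields
    list(stack = stackChannels(chans, chanNames), echoes = echoes,
         truth = truth)
}

#' Canonical phantom suite
#'
#' Four named phantoms exercising the confounds the package targets:
#' \describe{
#'   \item{dura}{wide dura cap, two vessels.}
#'   \item{vessel}{four vessels, narrow dura cap.}
#'   \item{susceptibility}{enlarged susceptibility-dropout zone.}
#'   \item{occipital-low-contrast}{GM/WM contrast on the t1w channel
#'     reduced to 5%% of its value inside a marked sector while the
#'     flair contrast is retained (recorded in
#'     \code{truth@extras$lowContrastSector}).}
#' }
#'
#' @param seed master seed; each phantom derives its own sub-seed.
#' @param shape grid size, default 48^3.
#' @param modalities channels to render, default t1w + flair.
#' @return Named list of list(stack, echoes, truth).
#' @export
makeDefaultSuite <- function(seed = 1L, shape = c(48L, 48L, 48L),
                             modalities = c("t1w", "flair")) {
    mk <- function(name, geometry = list()) {
        sp <- phantomSpec(shape = shape, geometry = geometry,
                          modalities = modalities,
                          seed = deriveSeed(seed, name))
        renderChannels(buildLabels(sp))
    }
    out <- list(
        dura = mk("dura", list(duraArcFrac = 0.35, vesselCount = 2L)),
        vessel = mk("vessel", list(vesselCount = 4L, duraArcFrac = 0.15)),
        susceptibility = mk("susceptibility", list(susceptRadius = 8)))

    ## occipital-like sector with collapsed t1w GM/WM contrast
    p <- mk("occipital-low-contrast", list())
    lab <- p$truth@labels@data
    dm <- dim(lab)
    ctr <- (dm + 1) / 2
    X <- array(seq_len(dm[1L]) - ctr[1L], dm)
    Y <- array(rep(seq_len(dm[2L]) - ctr[2L], each = dm[1L]), dm)
    Z <- array(rep(seq_len(dm[3L]) - ctr[3L], each = dm[1L] * dm[2L]), dm)
    R <- pmax(sqrt(X^2 + Y^2 + Z^2), 1e-9)
    sector <- (X / R) > 0.5 &
        lab %in% phantomLabels()[c("GM", "WM")]
    cr <- contrastRow(p$truth@spec@contrast, "t1w")
    mid <- (cr$mean[["GM"]] + cr$mean[["WM"]]) / 2
    it1 <- match("t1w", channelNames(p$stack))
    d <- p$stack@channels[[it1]]@data
    d[sector] <- mid + 0.05 * (d[sector] - mid)
    p$stack@channels[[it1]] <- Volume(d, affine = p$truth@labels@affine)
    p$truth@extras <- list(lowContrastSector = sector)
    out[["occipital-low-contrast"]] <- p
    out
}

#' Spatial tissue priors from phantom truth
#'
#' Emulates atlas-style prior maps: one-hot tissue maps with the
#' confound structures folded into the compartments an atlas would place
#' there (DURA and VESSEL into CSF — an atlas does not know them;
#' SUSCEPT_GM into GM; CONNECTIVE and background into OTHER), Gaussian
#' smoothed and mixed with a uniform floor.  The smoothing is what lets
#' gray-matter prior mass leak onto the adjacent dura sheet, so the
#' unimodal misclassification the priors cannot prevent is reproduced.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param classes class labels, default GM, WM, CSF, OTHER.
#' @param sigma smoothing SD in voxels (default 3).
#' @param alpha uniform mixing floor (default 0.2).
#' @return list of prior \linkS4class{Volume}s, one per class, summing
#'   to 1 per voxel.
#' @export
truthPriors <- function(truth, classes = c("GM", "WM", "CSF", "OTHER"),
                        sigma = 3, alpha = 0.2) {
    mapping <- list(GM = c("GM", "SUSCEPT_GM"), WM = "WM",
                    CSF = c("CSF", "DURA", "VESSEL"),
                    OTHER = c("BG", "CONNECTIVE"))
    if (!all(classes %in% names(mapping)))
        stop("classes must be a subset of GM, WM, CSF, OTHER")
    lab <- truth@labels@data
    aff <- truth@labels@affine
    raw <- lapply(classes, function(cl) {
        m <- array(as.numeric(lab %in% phantomLabels()[mapping[[cl]]]),
                   dim(lab))
        gaussianSmooth3D(m, sigma)
    })
    tot <- Reduce("+", raw)
    K <- length(classes)
    lapply(raw, function(a)
        Volume((1 - alpha) * a / pmax(tot, 1e-12) + alpha / K,
               affine = aff))
}

setMethod("show", "PhantomTruth", function(object) {
    tab <- table(factor(phantomLabelNames()[match(object@labels@data,
                                                  phantomLabels())],
                        levels = phantomLabelNames()))
    cat("PhantomTruth", paste(dim(object@labels@data), collapse = " x "),
        "| seed", object@seed, "\n")
    print(tab)
})

#' Write a phantom to disk
#'
#' Labels and channels as NIfTI plus a truth JSON (contrast table,
#' geometry, noise, R2* truths, seed).
#'
#' @param rendered list(stack, echoes, truth) from
#'   \code{\link{renderChannels}}.
#' @param dir output directory (created).
#' @return Files written, invisibly.
#' @export
writePhantom <- function(rendered, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    truth <- rendered$truth
    f <- file.path(dir, "labels.nii.gz")
    writeVolume(truth@labels, f); files <- c(files, f)
    st <- rendered$stack
    for (i in seq_along(st@channels)) {
        f <- file.path(dir, paste0(st@channelNames[i], ".nii.gz"))
        writeVolume(st@channels[[i]], f); files <- c(files, f)
    }
    if (!is.null(rendered$echoes)) {
        for (e in seq_along(rendered$echoes@echoes)) {
            f <- file.path(dir, sprintf("echo_%02d.nii.gz", e))
            writeVolume(rendered$echoes@echoes[[e]], f)
            files <- c(files, f)
        }
    }
    spec <- truth@spec
    meta <- list(shape = spec@shape, voxelSize = spec@voxelSize,
                 geometry = spec@geometry, modalities = spec@modalities,
                 echoTimes = spec@echoTimes, noise = spec@noise,
                 trueR2Star = as.list(truth@trueR2Star),
                 contrast = spec@contrast, seed = spec@seed)
    f <- file.path(dir, "truth.json")
    writeLines(as.character(jsonlite::toJSON(meta, digits = NA,
                                             auto_unbox = TRUE,
                                             dataframe = "rows")), f)
    invisible(c(files, f))
}
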