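# multiseg

Registration-free multimodal brain MRI tissue segmentation with
per-class Gaussian-mixture density models, built for one question:
**what does each added contrast buy you?**

Single-contrast T1-weighted segmentation systematically misclassifies
dura mater, sulcal vessels and connective tissue as cortical gray
matter, because those tissues are isointense to gray matter on T1w —
the error survives any amount of averaging.  Adding co-registered
channels in which the confounds separate (FLAIR, where dura and vessels
are dark and CSF is nulled; R2* relaxation-rate maps, where vessels and
dephased tissue stand out) turns the same per-voxel density
classification into a well-posed problem.  `multiseg` implements the
full comparison pipeline and a synthetic multi-contrast phantom with
ground truth, so every claim is testable without scan data.

## The model

Voxel intensities $x \in \mathbb{R}^N$ (one dimension per co-registered
channel) are modeled per tissue class $k$ as a Gaussian mixture

$$p(x \mid k) = \sum_{j=1}^{m_k} w_{kj}\, \mathcal{N}(x;\ \mu_{kj}, \Sigma_{kj}),$$

combined with stationary or voxelwise class priors and fitted by EM
(log-sum-exp stabilized, covariances regularized by
$10^{-6}\times$ mean channel variance, optional polynomial bias field).
Default roster: GM(1), WM(1), CSF(2), OTHER(2).  Posterior tissue
probability maps sum to 1 per voxel.  Class-density separation is
quantified by the Bhattacharyya distance

$$D_B = \tfrac{1}{8}\,(\mu_1-\mu_2)^\top \bar\Sigma^{-1} (\mu_1-\mu_2)
 + \tfrac{1}{2} \ln \frac{|\bar\Sigma|}{\sqrt{|\Sigma_1||\Sigma_2|}},
 \qquad \bar\Sigma = \tfrac{1}{2}(\Sigma_1 + \Sigma_2),$$

with the headline distance of a mixture class taken to its
largest-weight component.  R2* maps come from a log-linear fit of the
mono-exponential multi-echo decay $S(TE) = S_0 e^{-R_2^* TE}$, and the
echo-averaged image provides the T1w channel.

Modules: NIfTI volume/stack containers (`readVolume`, `stackChannels`),
relaxometry (`fitR2Star`, `combineEchoes`, `r2starToT2star`),
segmentation (`initModel`, `emFit`, `posteriorMaps`, `segment`),
separation (`bhattacharyya`, `classSeparation`,
`pairedSeparationTest`), phantom (`phantomSpec`, `buildLabels`,
`renderChannels`, `makeDefaultSuite`, `truthPriors`), comparison
metrics (`tpmDifference`, `compartmentVolume`, `diceScore`,
`leakRate`), and an end-to-end driver (`runExperiment`).  A thin CLI
wrapper lives at `inst/scripts/multiseg.R`.

## Worked example

Generate a 48³ dura/vessel phantom, segment it with T1w alone and with
T1w+FLAIR, and measure what changes:

```r
library(multiseg)

sp      <- phantomSpec(seed = 42)                  # t1w + flair, Rician SNR 50
phantom <- renderChannels(buildLabels(sp))
phantom$truth
#> PhantomTruth 48 x 48 x 48 | seed 42
#>         BG         WM         GM        CSF       DURA     VESSEL CONNECTIVE SUSCEPT_GM
#>      76920       9328      10912      10220       2452        208        120        432

priors <- truthPriors(phantom$truth)               # atlas-style smoothed priors
fitT1  <- segment(subsetChannels(phantom$stack, "t1w"), priors = priors, seed = 1)
fitMM  <- segment(phantom$stack, priors = priors, seed = 1)

dura <- labelMask(phantom$truth, "DURA")
leakRate(probMap(fitT1$maps, "GM"), dura)$meanPosterior
#> [1] 0.8613865
leakRate(probMap(fitMM$maps, "GM"), dura)$meanPosterior
#> [1] 1.148392e-07
```

Unimodally, dura voxels carry a mean gray-matter posterior of 0.86 —
they are confidently called cortex.  With FLAIR in the stack the same
voxels drop to ~0: the fitted CSF junk component absorbs them.  The
separation report shows why:

```r
classSeparation(fitT1$model, "t1w")
#> SeparationReport [ t1w ]
#>   GM-CSF1: 9.126 ...
classSeparation(fitMM$model, "t1w+flair")
#> SeparationReport [ t1w+flair ]
#>   GM-CSF1: 34.38 ...
```

The GM-CSF Bhattacharyya distance nearly quadruples when FLAIR is
added, and the gray matter the multimodal fit gives up sits on the
confounds:

```r
tpmDifference(fitT1$maps, fitMM$maps, labels = c("t1w", "t1w+flair"))
#> ComparisonResult: t1w+flair - t1w
#>   GM: -1.589 ml
#>   WM: -0.107 ml
#>   CSF: +1.550 ml
#>   OTHER: +0.146 ml

diceScore(fitMM$maps, phantom$truth, "GM")
#> [1] 0.9802336
```

Gray-matter volume decreases and CSF gains almost the same mass — the
misassigned dura/vessel probability moves compartment, it does not
vanish.  `runExperiment(defaultRunConfig(seed = 1))` runs the full
four-combination study (t1w, t1w+flair, t1w+r2star, t1w+flair+r2star,
with R2* fitted from a rendered multi-echo series) and writes models,
maps, separation reports, pairwise comparisons and a reproducibility
manifest.

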