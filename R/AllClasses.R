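#' @import methods
NULL

#' Specification of a synthetic cortical-bone phantom
#'
#' A `PhantomSpec` describes the voxel grid, the lacuna population
#' (ellipsoid volumes, aspect ratios, count), the attenuation of each
#' material and the reference inclusion used for mineral calibration.
#' The grid is ordered `(nz, ny, nx)`; attenuation values are linear
#' attenuation coefficients in 1/mm at the working X-ray energy.
#'
#' @slot gridShape integer(3), voxels `(nz, ny, nx)`.
#' @slot voxelSizeUm isotropic voxel edge in micrometres.
#' @slot nLacunae number of lacunae to place.
#' @slot volumeRangeUm3 numeric(2), truncation range for sampled true
#'   ellipsoid volumes (cubic micrometres).
#' @slot volumeModeUm3 mode of the log-normal volume distribution.
#' @slot volumeSigmaLog log-scale standard deviation of the volume
#'   distribution.
#' @slot aspectRatioRange numeric(2), truncation range for the sampled
#'   short/long axis ratio.
#' @slot aspectMean,aspectSd centre and spread of the aspect-ratio
#'   distribution before truncation.
#' @slot matrixAttenuation,lacunaAttenuation,bathAttenuation linear
#'   attenuation (1/mm) of mineralized matrix, lacunar fluid and the
#'   surrounding bath.
#' @slot referenceInclusion list with elements `material`, `attenuation`
#'   (1/mm) and `knownDensity` (g/cm^3) describing the dense calibration
#'   inclusion placed in the bath.
#' @slot boneCrossSectionMm2 cross-section used for dose bookkeeping (mm^2).
#' @slot seed integer RNG seed; generation is deterministic given the seed.
#' @seealso [defaultBoneSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec", representation(
  gridShape = "integer",
  voxelSizeUm = "numeric",
  nLacunae = "integer",
  volumeRangeUm3 = "numeric",
  volumeModeUm3 = "numeric",
  volumeSigmaLog = "numeric",
  aspectRatioRange = "numeric",
  aspectMean = "numeric",
  aspectSd = "numeric",
  matrixAttenuation = "numeric",
  lacunaAttenuation = "numeric",
  bathAttenuation = "numeric",
  referenceInclusion = "list",
  boneCrossSectionMm2 = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be three positive integers (nz, ny, nx)")
  if (object@voxelSizeUm <= 0) msg <- c(msg, "voxelSizeUm must be > 0")
  att <- c(object@matrixAttenuation, object@lacunaAttenuation,
           object@bathAttenuation)
  if (any(att < 0)) msg <- c(msg, "attenuation values must be >= 0")
  if (object@lacunaAttenuation >= object@matrixAttenuation)
    msg <- c(msg, "lacunaAttenuation must be < matrixAttenuation")
  vr <- object@volumeRangeUm3
  if (length(vr) != 2L || vr[1] <= 0 || vr[2] <= vr[1])
    msg <- c(msg, "volumeRangeUm3 must be an increasing positive pair")
  gridVol <- prod(object@gridShape) * object@voxelSizeUm^3
  if (length(vr) == 2L && vr[2] > gridVol)
    msg <- c(msg, "volumeRangeUm3 max exceeds the grid volume")
  ar <- object@aspectRatioRange
  if (length(ar) != 2L || ar[1] <= 0 || ar[2] > 1 || ar[2] <= ar[1])
    msg <- c(msg, "aspectRatioRange must be increasing within (0, 1]")
  inc <- object@referenceInclusion
  if (!all(c("material", "attenuation", "knownDensity") %in% names(inc)))
    msg <- c(msg, "referenceInclusion needs material, attenuation, knownDensity")
  if (length(msg)) msg else TRUE
})

#' Voxel phantom with known lacuna labels and analytic truth
#'
#' The product of [generatePhantom()]: a 3D attenuation grid (1/mm), an
#' integer label grid (0 = matrix/bath/inclusion, k >= 1 = lacuna k), the
#' analytic truth table for every placed ellipsoid, and the geometry of the
#' bone prism, bath and reference inclusion needed by downstream stages.
#'
#' @slot attenuation 3D numeric array `(nz, ny, nx)`, 1/mm.
#' @slot labels 3D integer array, same shape.
#' @slot truth data.frame with one row per lacuna: `id`, `volume_um3`
#'   (analytic ellipsoid volume), `aspect_ratio` (short/long semi-axis),
#'   `cx`, `cy`, `cz` (micrometres), `voxel_count`.
#' @slot voxelSizeUm voxel edge, micrometres.
#' @slot geometry list describing the bone box, bath reference region and
#'   inclusion placement (voxel indices).
#' @export
setClass("LabeledVolume", representation(
  attenuation = "array",
  labels = "array",
  truth = "data.frame",
  voxelSizeUm = "numeric",
  geometry = "list"
))

setValidity("LabeledVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@attenuation), dim(object@labels)))
    msg <- c(msg, "attenuation and labels must share dimensions")
  ids <- sort(unique(as.integer(object@labels[object@labels > 0L])))
  if (!identical(ids, sort(as.integer(object@truth$id))))
    msg <- c(msg, "label ids and truth-table ids must match one-to-one")
  if (length(msg)) msg else TRUE
})

#' Parallel-beam sinogram of one slice
#'
#' Rows are projection angles, columns detector bins; entries are line
#' integrals of attenuation (dimensionless, mu * mm).  `photonsPerPixel`
#' records the expected incident photon count per detector bin used by the
#' noise model (`Inf` means noiseless).
#'
#' @slot data numeric matrix `n_angles x n_detector`.
#' @slot angles strictly increasing radians in `[0, pi)`.
#' @slot photonsPerPixel expected incident counts I0 (`Inf` = noiseless).
#' @slot sliceIndex axial slice this sinogram came from.
#' @slot pixelSizeUm detector bin / voxel pitch in micrometres.
#' @export
setClass("Sinogram", representation(
  data = "matrix",
  angles = "numeric",
  photonsPerPixel = "numeric",
  sliceIndex = "integer",
  pixelSizeUm = "numeric"
))

setValidity("Sinogram", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@angles))
    msg <- c(msg, "row count must equal the number of angles")
  if (length(object@angles) > 1 && any(diff(object@angles) <= 0))
    msg <- c(msg, "angles must be strictly increasing")
  if (length(object@angles) &&
      (min(object@angles) < 0 || max(object@angles) >= pi))
    msg <- c(msg, "angles must lie in [0, pi)")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "sinogram data must be finite")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' The K sub-reconstructions of one split sinogram stack
#'
#' Unit of Noise2Inverse training and inference: each sub-reconstruction is
#' the filtered back projection of every K-th projection angle, so the K
#' volumes share the signal but carry independent noise realizations.
#'
#' @slot K number of splits (>= 2).
#' @slot subRecons list of K 3D arrays `(nz, n, n)`, 32-bit-style grayscale
#'   attenuation values.
#' @slot angleSets list of K angle vectors; pairwise disjoint, union equal
#'   to the parent angle set.
#' @slot pixelSizeUm voxel pitch in micrometres.
#' @export
setClass("SubReconSet", representation(
  K = "integer",
  subRecons = "list",
  angleSets = "list",
  pixelSizeUm = "numeric"
))

setValidity("SubReconSet", function(object) {
  msg <- character()
  if (object@K < 2L) msg <- c(msg, "K must be >= 2")
  if (length(object@subRecons) != object@K ||
      length(object@angleSets) != object@K)
    msg <- c(msg, "subRecons and angleSets must have length K")
  dims <- lapply(object@subRecons, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) > 1)
    msg <- c(msg, "all sub-reconstructions must share one shape")
  all_angles <- unlist(object@angleSets)
  if (anyDuplicated(all_angles))
    msg <- c(msg, "angle sets must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' Noise2Inverse training hyper-parameters
#'
#' Defaults follow the published training recipe (learning rate 1e-3, input
#' slab of 5 slices, batch size 12, 80/20 train-validation split) with a
#' desk-scale network depth of 20 dilated dense layers.
#'
#' @slot depth number of hidden MSD layers.
#' @slot learningRate Adam step size.
#' @slot slab odd number of adjacent slices fed per target slice.
#' @slot batchSize minibatch size.
#' @slot epochs training epochs.
#' @slot valFraction fraction of slices held out for validation.
#' @slot seed RNG seed for weight init and shuffling.
#' @slot maxDilation dilations cycle 1..maxDilation across layers.
#' @export
setClass("N2IHyperparams", representation(
  depth = "integer",
  learningRate = "numeric",
  slab = "integer",
  batchSize = "integer",
  epochs = "integer",
  valFraction = "numeric",
  seed = "integer",
  maxDilation = "integer"
))

setValidity("N2IHyperparams", function(object) {
  msg <- character()
  if (object@slab < 1L || object@slab %% 2L == 0L)
    msg <- c(msg, "slab must be odd and >= 1")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msg <- c(msg, "valFraction must be in (0, 1)")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@maxDilation < 1L) msg <- c(msg, "maxDilation must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A trained Noise2Inverse denoiser
#'
#' Opaque network weights plus everything needed to reapply them: the
#' hyper-parameters, the per-epoch train/validation loss curves and the
#' global input normalization fixed at training time.
#'
#' @slot weights numeric parameter vector (best validation epoch).
#' @slot hyperparams the [N2IHyperparams-class] used.
#' @slot trainingLog data.frame `epoch`, `train`, `val` (epoch 0 is the
#'   untrained network).
#' @slot normalization numeric(2) `(shift, scale)` applied to inputs and
#'   inverted on outputs.
#' @slot bestEpoch epoch whose weights are stored.
#' @export
setClass("TrainedDenoiser", representation(
  weights = "numeric",
  hyperparams = "N2IHyperparams",
  trainingLog = "data.frame",
  normalization = "numeric",
  bestEpoch = "integer"
))

setValidity("TrainedDenoiser", function(object) {
  msg <- character()
  if (!all(is.finite(object@trainingLog$train)) ||
      !all(is.finite(object@trainingLog$val)))
    msg <- c(msg, "training log losses must be finite")
  if (length(object@normalization) != 2L || object@normalization[2] <= 0)
    msg <- c(msg, "normalization must be (shift, scale) with scale > 0")
  if (length(msg)) msg else TRUE
})

#' Linear gray-value to mineral-density calibration
#'
#' @slot points data.frame with one row per reference material:
#'   `material`, `apparent` (density computed from the image, g/cm^3),
#'   `known` (tabulated density, g/cm^3).
#' @slot slope,intercept coefficients of the map known = slope * apparent +
#'   intercept; exact through the points when fitted to exactly two.
#' @export
setClass("MineralCalibration", representation(
  points = "data.frame",
  slope = "numeric",
  intercept = "numeric"
))

setValidity("MineralCalibration", function(object) {
  msg <- character()
  if (nrow(object@points) < 2L) msg <- c(msg, "need >= 2 reference points")
  if (!is.finite(object@slope) || object@slope == 0)
    msg <- c(msg, "slope must be finite and non-zero")
  if (length(msg)) msg else TRUE
})

#' Paired comparison of per-sample summary statistics
#'
#' Shapiro-Wilk normality of the paired differences and Levene variance
#' homogeneity are reported alongside (not gating) a two-sided paired
#' t-test.  When the paired differences have zero variance the t-test is
#' undefined and the result is flagged degenerate instead of erroring.
#'
#' @slot a,b the paired per-sample values.
#' @slot shapiroP,leveneP,tStatistic,pValue test results (NA when degenerate).
#' @slot modeChangePct percent change of the group means, b vs a.
#' @slot degenerate TRUE when the differences have zero variance.
#' @export
setClass("PairedComparison", representation(
  a = "numeric",
  b = "numeric",
  shapiroP = "numeric",
  leveneP = "numeric",
  tStatistic = "numeric",
  pValue = "numeric",
  modeChangePct = "numeric",
  degenerate = "logical"
))

setValidity("PairedComparison", function(object) {
  msg <- character()
  if (length(object@a) != length(object@b) || length(object@a) < 3L)
    msg <- c(msg, "groups must have equal length >= 3")
  ps <- c(object@shapiroP, object@leveneP, object@pValue)
  ps <- ps[is.finite(ps)]
  if (length(ps) && (any(ps < 0) || any(ps > 1)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Beamline and sample parameters for absorbed-dose estimation
#'
#' @slot energyKeV photon energy (default 24 keV).
#' @slot fluxDensity effective flux density, photons / s / um^2.
#' @slot exposureS exposure per projection, seconds.
#' @slot nProjections projections per full scan.
#' @slot areaMm2 illuminated cross-section of the region of interest, mm^2.
#' @slot sampleMassAtten mass attenuation of the sample, cm^2/g.
#' @slot sampleDensity sample density, g/cm^3.
#' @slot sampleThicknessMm beam path length through the sample, mm.
#' @export
setClass("BeamlineParams", representation(
  energyKeV = "numeric",
  fluxDensity = "numeric",
  exposureS = "numeric",
  nProjections = "numeric",
  areaMm2 = "numeric",
  sampleMassAtten = "numeric",
  sampleDensity = "numeric",
  sampleThicknessMm = "numeric"
))

setValidity("BeamlineParams", function(object) {
  msg <- character()
  pos <- c(energyKeV = object@energyKeV, fluxDensity = object@fluxDensity,
           exposureS = object@exposureS, areaMm2 = object@areaMm2,
           sampleMassAtten = object@sampleMassAtten,
           sampleDensity = object@sampleDensity,
           sampleThicknessMm = object@sampleThicknessMm)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste("must be > 0:", paste(bad, collapse = ", ")))
  if (object@nProjections < 0) msg <- c(msg, "nProjections must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Configuration of a simulated dose experiment
#'
#' @slot phantomSpec the [PhantomSpec-class] to image.
#' @slot nAngles full-dose projection count.
#' @slot photons expected incident photons per detector bin.
#' @slot fractions dose-fraction denominators of the sweep.
#' @slot K sinogram splits for Noise2Inverse.
#' @slot hyperparams network training settings.
#' @slot nSamples samples in the paired experiment.
#' @slot pairedFractions the two dose levels of the paired experiment.
#' @slot seed master seed; every stage seed derives from it.
#' @export
setClass("ExperimentConfig", representation(
  phantomSpec = "PhantomSpec",
  nAngles = "integer",
  photons = "numeric",
  fractions = "numeric",
  K = "integer",
  hyperparams = "N2IHyperparams",
  nSamples = "integer",
  pairedFractions = "numeric",
  seed = "integer"
))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (any(object@fractions < 1)) msg <- c(msg, "fractions must be >= 1")
  if (object@nAngles < 2L) msg <- c(msg, "nAngles must be >= 2")
  if (object@K < 2L) msg <- c(msg, "K must be >= 2")
  if (length(object@pairedFractions) != 2L)
    msg <- c(msg, "pairedFractions must have length 2")
  if (length(msg)) msg else TRUE
})

#' Results of a dose sweep or paired experiment
#'
#' @slot perFraction data.frame with one row per dose fraction: image
#'   quality vs the clean phantom, recovered mode lacunar volume, mode
#'   aspect ratio, mode mineralization and percent changes vs full dose.
#' @slot paired list of [PairedComparison-class] objects (paired experiment
#'   only), one per quantified feature.
#' @slot manifest list of every seed and setting needed to regenerate the
#'   report bit-for-bit.
#' @export
setClass("ExperimentReport", representation(
  perFraction = "data.frame",
  paired = "list",
  manifest = "list"
))
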