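#' @include AllClasses.R
NULL

#' Accessors for the core data classes
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return The slot value; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @rdname accessors
#' @export
setGeneric("nAngles", function(x) standardGeneric("nAngles"))

#' @rdname accessors
#' @export
setGeneric("sinogramData", function(x) standardGeneric("sinogramData"))

#' @rdname accessors
#' @export
setGeneric("photonsPerPixel", function(x) standardGeneric("photonsPerPixel"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("attenuationGrid", function(x) standardGeneric("attenuationGrid"))

#' @rdname accessors
#' @export
setGeneric("labelGrid", function(x) standardGeneric("labelGrid"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setGeneric("subRecons", function(x) standardGeneric("subRecons"))

#' @rdname accessors
#' @export
setGeneric("angleSets", function(x) standardGeneric("angleSets"))

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' @rdname accessors
#' @export
setMethod("angles", "Sinogram", function(x) x@angles)

#' @rdname accessors
#' @export
setMethod("nAngles", "Sinogram", function(x) length(x@angles))

#' @rdname accessors
#' @export
setMethod("sinogramData", "Sinogram", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("photonsPerPixel", "Sinogram", function(x) x@photonsPerPixel)

#' @rdname accessors
#' @export
setMethod("voxelSize", "Sinogram", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("voxelSize", "LabeledVolume", function(x) x@voxelSizeUm)

#' @rdname accessors
#' @export
setMethod("voxelSize", "SubReconSet", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("attenuationGrid", "LabeledVolume", function(x) x@attenuation)

#' @rdname accessors
#' @export
setMethod("labelGrid", "LabeledVolume", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("truthTable", "LabeledVolume", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("subRecons", "SubReconSet", function(x) x@subRecons)

#' @rdname accessors
#' @export
setMethod("angleSets", "SubReconSet", function(x) x@angleSets)

#' @rdname accessors
#' @export
setMethod("trainingLog", "TrainedDenoiser", function(x) x@trainingLog)

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = " x "),
      "voxels @", object@voxelSizeUm, "um\n")
  cat("  lacunae:", object@nLacunae,
      sprintf("| volumes %g-%g um^3 (mode %g)", object@volumeRangeUm3[1],
              object@volumeRangeUm3[2], object@volumeModeUm3),
      sprintf("| aspect ~%g", object@aspectMean), "\n")
  cat(sprintf("  attenuation (1/mm): matrix %.4f, lacuna %.4f, bath %.4f, %s %.4f\n",
              object@matrixAttenuation, object@lacunaAttenuation,
              object@bathAttenuation, object@referenceInclusion$material,
              object@referenceInclusion$attenuation))
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@attenuation)
  cat("LabeledVolume:", paste(d, collapse = " x "), "voxels @",
      object@voxelSizeUm, "um;", nrow(object@truth), "lacunae\n")
})

setMethod("show", "Sinogram", function(object) {
  cat("Sinogram: ", nrow(object@data), " angles x ", ncol(object@data),
      " detector bins (slice ", object@sliceIndex, ")\n", sep = "")
  cat("  photons/pixel:", object@photonsPerPixel,
      "| pixel:", object@pixelSizeUm, "um\n")
})

setMethod("show", "SubReconSet", function(object) {
  d <- dim(object@subRecons[[1]])
  cat("SubReconSet: K =", object@K, "| volumes",
      paste(d, collapse = " x "), "\n")
  cat("  angles per split:",
      paste(vapply(object@angleSets, length, 1L), collapse = ", "), "\n")
})

setMethod("show", "TrainedDenoiser", function(object) {
  hp <- object@hyperparams
  cat("TrainedDenoiser: depth", hp@depth, "| slab", hp@slab,
      "|", length(object@weights), "parameters\n")
  lg <- object@trainingLog
  cat(sprintf("  best epoch %d/%d (val loss %.3g)\n", object@bestEpoch,
              max(lg$epoch), min(lg$val)))
})

setMethod("show", "MineralCalibration", function(object) {
  cat(sprintf("MineralCalibration: density = %.4f * apparent + %.4f (g/cm^3)\n",
              object@slope, object@intercept))
  print(object@points)
})

setMethod("show", "PairedComparison", function(object) {
  if (object@degenerate) {
    cat("PairedComparison: degenerate (zero-variance differences), n =",
        length(object@a), "\n")
  } else {
    cat(sprintf("PairedComparison: n = %d, t = %.3f, p = %.3g, change = %+.1f%%\n",
                length(object@a), object@tStatistic, object@pValue,
                object@modeChangePct))
    cat(sprintf("  Shapiro-Wilk p = %.3g, Levene p = %.3g\n",
                object@shapiroP, object@leveneP))
  }
})

setMethod("show", "BeamlineParams", function(object) {
  cat(sprintf("BeamlineParams: %g keV, %g ph/s/um^2, %g s x %g projections\n",
              object@energyKeV, object@fluxDensity, object@exposureS,
              object@nProjections))
  cat(sprintf("  sample: %g cm^2/g, %g g/cm^3, %g mm path over %g mm^2\n",
              object@sampleMassAtten, object@sampleDensity,
              object@sampleThicknessMm, object@areaMm2))
})

setMethod("show", "ExperimentReport", function(object) {
  cat("ExperimentReport\n")
  print(object@perFraction)
  if (length(object@paired)) {
    cat("Paired comparisons:\n")
    for (nm in names(object@paired)) {
      cat(" ", nm, ": ")
      show(object@paired[[nm]])
    }
  }
})
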