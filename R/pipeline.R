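#' @include AllClasses.R
NULL

#' Configure a simulated dose experiment
#'
#' Bundles everything the two experiment drivers need: the phantom, the
#' acquisition (projection count and photon budget), the dose fractions,
#' the Noise2Inverse settings and a master seed from which every stage
#' seed is derived (so reports are regenerable bit-for-bit).
#'
#' @param phantomSpec a [PhantomSpec-class]; in-plane grid must be square.
#' @param nAngles full-dose projection count.
#' @param photons expected incident photons per detector bin (the default
#'   is a synthetic budget chosen so the one-sixth-dose FBP is visibly
#'   non-segmentable while the full dose remains workable).
#' @param fractions dose-fraction denominators of the sweep.
#' @param K sinogram splits.
#' @param hyperparams an [N2IHyperparams-class].
#' @param nSamples samples in the paired experiment (default 8).
#' @param pairedFractions the two dose levels of the paired experiment
#'   (default full vs one-third).
#' @param seed master seed.
#' @return a validated [ExperimentConfig-class].
#' @export
experimentConfig <- function(phantomSpec = defaultBoneSpec(),
                             nAngles = 420L, photons = 1e5,
                             fractions = c(1, 2, 3, 4, 6), K = 2L,
                             hyperparams = n2iHyperparams(),
                             nSamples = 8L, pairedFractions = c(1, 3),
                             seed = 1L) {
  if (phantomSpec@gridShape[2] != phantomSpec@gridShape[3])
    stop("pipeline reconstruction needs a square in-plane grid")
  new("ExperimentConfig", phantomSpec = phantomSpec,
      nAngles = as.integer(nAngles), photons = photons,
      fractions = fractions, K = as.integer(K), hyperparams = hyperparams,
      nSamples = as.integer(nSamples), pairedFractions = pairedFractions,
      seed = as.integer(seed))
}

# detector padding that avoids projection truncation of the square FOV
# (the bath continues beyond the reconstructed window, as at a beamline)
detectorPad <- function(nx) as.integer(ceiling(0.21 * nx)) + 2L

# acquire one phantom: embed in bath, project with a wide detector, add
# photon noise; seeds derived per slice
acquireSinograms <- function(phantom, nAngles, photons, seed, bathValue) {
  att <- phantom@attenuation
  d <- dim(att)
  pad <- detectorPad(d[3])
  wide <- array(bathValue, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad))
  wide[, pad + seq_len(d[2]), pad + seq_len(d[3])] <- att
  sinos <- projectVolume(wide, projectionAngles(nAngles),
                         voxelSizeUm = phantom@voxelSizeUm)
  lapply(seq_along(sinos), function(z)
    suppressMessages(simulateCounts(sinos[[z]], photons,
                                    seed = seed * 1009L + z)))
}

# crop a padded reconstruction back to the phantom window
cropPad <- function(vol, nx) {
  pad <- detectorPad(nx)
  vol[, pad + seq_len(nx), pad + seq_len(nx), drop = FALSE]
}

# full quantification of one denoised volume; returns the summary row pieces
quantifyVolume <- function(den, phantom, win) {
  h <- phantom@voxelSizeUm
  denWin <- cropVolume(den, win)
  thr <- autoThreshold(denWin, "yen")
  mask <- denWin < thr
  lt <- labelLacunae(mask, h)
  refs <- referenceMasks(phantom)
  cal <- calibrateMineralization(den, refs, c("water", "alumina"))
  minWin <- cropVolume(cal$volume, win)
  list(
    nLacunae = nrow(lt),
    modeVolume = if (nrow(lt) > 0) distributionMode(lt$volume_um3) else NA_real_,
    modeAspect = if (nrow(lt) > 0) distributionMode(lt$aspect_ratio) else NA_real_,
    modeMineral = distributionMode(as.numeric(minWin)),
    threshold = thr, table = lt, calibration = cal$calibration)
}

# one fraction of the sweep: subsample -> split -> FBP -> train -> denoise
runFraction <- function(noisy, frac, cfg, phantom, clean, win) {
  nx <- dim(clean)[3]
  subs <- lapply(noisy, subsampleAngles, denominator = frac)
  ndet <- ncol(subs[[1]]@data)
  fbpWide <- array(0, c(dim(clean)[1], ndet, ndet))
  for (z in seq_along(subs)) fbpWide[z, , ] <- fbp(subs[[z]])
  fbpVol <- cropPad(fbpWide, nx)
  srs <- makeSubrecons(subs, cfg@K)
  srs@subRecons <- lapply(srs@subRecons, cropPad, nx = nx)
  hp <- cfg@hyperparams
  hp@seed <- as.integer(hp@seed + 131L * frac)
  pairs <- makeTrainingPairs(srs, hp@slab)
  model <- trainDenoiser(pairs, hp)
  den <- denoiseVolume(model, srs)
  cleanWin <- cropVolume(clean, win)
  iqDen <- imageQuality(cropVolume(den, win), cleanWin)
  iqFbp <- imageQuality(cropVolume(fbpVol, win), cleanWin)
  q <- quantifyVolume(den, phantom, win)
  list(row = data.frame(
    fraction = frac,
    projections = nAngles(subs[[1]]),
    mse_fbp = iqFbp$mse, psnr_fbp = iqFbp$psnr, ssim_fbp = iqFbp$ssim,
    mse_denoised = iqDen$mse, psnr_denoised = iqDen$psnr,
    ssim_denoised = iqDen$ssim,
    n_lacunae = q$nLacunae, mode_volume_um3 = q$modeVolume,
    mode_aspect = q$modeAspect, mode_mineral_mgHAcm3 = q$modeMineral),
    model = model, denoised = den, quant = q)
}

#' Run the five-fraction dose sweep (experiment 1)
#'
#' For every dose fraction: angular subsampling, sinogram split into K
#' parts, FBP sub-reconstructions, Noise2Inverse training, averaged
#' inference, then quantification (lacunar volume and aspect-ratio modes,
#' mineralization mode) and image quality against the clean phantom.  All
#' fractions image the same phantom, so rows are directly comparable; a
#' failing fraction is logged and skipped, the others proceed.
#'
#' @param cfg an [ExperimentConfig-class].
#' @param keepVolumes keep the denoised volumes in the manifest
#'   (memory-hungry; default FALSE).
#' @return an [ExperimentReport-class]; `perFraction` carries per-fraction
#'   metrics, dose bookkeeping and percent changes vs the full-dose row.
#' @export
runDoseSweep <- function(cfg, keepVolumes = FALSE) {
  stopifnot(is(cfg, "ExperimentConfig"))
  validObject(cfg)
  phantom <- generatePhantom(cfg@phantomSpec)
  clean <- phantom@attenuation
  win <- analysisWindow(phantom)
  noisy <- acquireSinograms(phantom, cfg@nAngles, cfg@photons, cfg@seed,
                            cfg@phantomSpec@bathAttenuation)
  rows <- list(); volumes <- list(); logs <- list()
  for (frac in cfg@fractions) {
    res <- tryCatch(
      runFraction(noisy, frac, cfg, phantom, clean, win),
      error = function(e) {
        warning("fraction 1/", frac, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- res$row
    logs[[as.character(frac)]] <- trainingLog(res$model)
    if (keepVolumes) volumes[[as.character(frac)]] <- res$denoised
  }
  per <- do.call(rbind, rows)
  # dose bookkeeping consistent with the budget module
  full <- dosePerScan(paperGeometryPreset())
  per$dose_kGy <- full / per$fraction
  ref <- per[per$fraction == min(per$fraction), ]
  # NA-safe percent change: a fraction can legitimately yield no lacunae
  pct <- function(new, reference)
    ifelse(is.finite(new) & is.finite(reference) & reference != 0,
           100 * (new - reference) / reference, NA_real_)
  per$pct_volume <- pct(per$mode_volume_um3, ref$mode_volume_um3)
  per$pct_aspect <- pct(per$mode_aspect, ref$mode_aspect)
  per$pct_mineral <- pct(per$mode_mineral_mgHAcm3, ref$mode_mineral_mgHAcm3)
  truth <- truthTable(phantom)
  manifest <- list(seed = cfg@seed, nAngles = cfg@nAngles,
                   photons = cfg@photons, K = cfg@K,
                   fractions = cfg@fractions,
                   gridShape = cfg@phantomSpec@gridShape,
                   truthModeVolume = if (nrow(truth) > 0)
                     distributionMode(truth$volume_um3) else NA_real_,
                   truthModeAspect = if (nrow(truth) > 0)
                     distributionMode(truth$aspect_ratio) else NA_real_,
                   trainingLogs = logs)
  if (keepVolumes) manifest$volumes <- volumes
  new("ExperimentReport", perFraction = per, paired = list(),
      manifest = manifest)
}

#' Run the paired full-vs-reduced-dose experiment (experiment 2)
#'
#' Generates `nSamples` phantoms with distinct seeds, trains ONE network
#' per dose level jointly across all samples (pooled training pairs),
#' denoises and quantifies every sample under both levels, and compares
#' the per-sample modes (lacunar volume, aspect ratio, mineralization)
#' with a paired t-test plus Shapiro-Wilk and Levene diagnostics.
#'
#' @param cfg an [ExperimentConfig-class]; `pairedFractions` gives the two
#'   dose levels (default full vs one-third) and `nSamples` the cohort
#'   size (default 8).
#' @return an [ExperimentReport-class] with one [PairedComparison-class]
#'   per feature in `@paired` and per-sample modes in `perFraction`.
#' @export
runPairedExperiment <- function(cfg) {
  stopifnot(is(cfg, "ExperimentConfig"))
  validObject(cfg)
  if (cfg@nSamples < 3L) stop("paired experiment needs nSamples >= 3")
  specs <- lapply(seq_len(cfg@nSamples), function(i) {
    sp <- cfg@phantomSpec
    sp@seed <- as.integer(cfg@seed + 7919L * i)
    sp
  })
  phantoms <- lapply(specs, generatePhantom)
  noisyAll <- lapply(seq_len(cfg@nSamples), function(i)
    acquireSinograms(phantoms[[i]], cfg@nAngles, cfg@photons,
                     seed = cfg@seed + 104729L * i,
                     bathValue = cfg@phantomSpec@bathAttenuation))
  levels <- cfg@pairedFractions
  modes <- list()
  for (li in seq_along(levels)) {
    frac <- levels[li]
    nx <- cfg@phantomSpec@gridShape[3]
    srsList <- lapply(noisyAll, function(noisy) {
      srs <- makeSubrecons(lapply(noisy, subsampleAngles, denominator = frac),
                           cfg@K)
      srs@subRecons <- lapply(srs@subRecons, cropPad, nx = nx)
      srs
    })
    hp <- cfg@hyperparams
    hp@seed <- as.integer(hp@seed + 131L * frac)
    pooled <- mergeTrainingPairs(lapply(srsList, makeTrainingPairs,
                                        slab = hp@slab))
    model <- trainDenoiser(pooled, hp)
    rows <- lapply(seq_len(cfg@nSamples), function(i) {
      den <- denoiseVolume(model, srsList[[i]])
      q <- quantifyVolume(den, phantoms[[i]], analysisWindow(phantoms[[i]]))
      data.frame(sample = i, fraction = frac, n_lacunae = q$nLacunae,
                 mode_volume_um3 = q$modeVolume, mode_aspect = q$modeAspect,
                 mode_mineral_mgHAcm3 = q$modeMineral)
    })
    modes[[li]] <- do.call(rbind, rows)
  }
  per <- do.call(rbind, modes)
  a <- modes[[1]]; b <- modes[[2]]
  paired <- list(
    volume = comparePaired(a$mode_volume_um3, b$mode_volume_um3),
    aspect = comparePaired(a$mode_aspect, b$mode_aspect),
    mineralization = comparePaired(a$mode_mineral_mgHAcm3,
                                   b$mode_mineral_mgHAcm3))
  manifest <- list(seed = cfg@seed, nSamples = cfg@nSamples,
                   pairedFractions = levels, nAngles = cfg@nAngles,
                   photons = cfg@photons, K = cfg@K,
                   phantomSeeds = vapply(specs, function(s) s@seed, 1L))
  new("ExperimentReport", perFraction = per, paired = paired,
      manifest = manifest)
}
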