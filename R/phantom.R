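#' @include AllClasses.R
NULL

#' Construct a phantom specification
#'
#' Low-level constructor with full control over every field; most users
#' want [defaultBoneSpec()] and tweak from there.
#'
#' @param gridShape integer(3) voxels `(nz, ny, nx)`.
#' @param voxelSizeUm voxel edge, micrometres.
#' @param nLacunae number of ellipsoidal lacunae.
#' @param volumeRangeUm3 truncation range of true lacuna volumes, um^3.
#' @param volumeModeUm3 mode of the log-normal volume distribution.
#' @param volumeSigmaLog log-sd of the volume distribution.
#' @param aspectRatioRange truncation range of short/long axis ratios.
#' @param aspectMean,aspectSd centre/spread of the aspect distribution.
#' @param matrixAttenuation,lacunaAttenuation,bathAttenuation linear
#'   attenuation coefficients, 1/mm.
#' @param referenceInclusion list(material, attenuation, knownDensity).
#' @param boneCrossSectionMm2 cross-section for dose bookkeeping, mm^2.
#' @param seed integer seed making generation deterministic.
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape,
                        voxelSizeUm = 1.6,
                        nLacunae = 60L,
                        volumeRangeUm3 = c(100, 1600),
                        volumeModeUm3 = 393,
                        volumeSigmaLog = 0.45,
                        aspectRatioRange = c(0.25, 0.85),
                        aspectMean = 0.46,
                        aspectSd = 0.08,
                        matrixAttenuation = unname(massAttenuation("hydroxyapatite")) * 1.226 / 10,
                        lacunaAttenuation = unname(massAttenuation("water")) * 1.00 / 10,
                        bathAttenuation = unname(massAttenuation("water")) * 1.00 / 10,
                        referenceInclusion = list(
                          material = "alumina",
                          attenuation = unname(massAttenuation("alumina") *
                            referenceDensity("alumina")) / 10,
                          knownDensity = unname(referenceDensity("alumina"))),
                        boneCrossSectionMm2 = 3.28,
                        seed = 1L) {
  new("PhantomSpec",
      gridShape = as.integer(gridShape), voxelSizeUm = voxelSizeUm,
      nLacunae = as.integer(nLacunae), volumeRangeUm3 = volumeRangeUm3,
      volumeModeUm3 = volumeModeUm3, volumeSigmaLog = volumeSigmaLog,
      aspectRatioRange = aspectRatioRange, aspectMean = aspectMean,
      aspectSd = aspectSd, matrixAttenuation = matrixAttenuation,
      lacunaAttenuation = lacunaAttenuation, bathAttenuation = bathAttenuation,
      referenceInclusion = referenceInclusion,
      boneCrossSectionMm2 = boneCrossSectionMm2, seed = as.integer(seed))
}

#' The packaged default bovine-cortical-bone phantom
#'
#' A desk-scale phantom whose defaults encode the study conditions: 1.6 um
#' voxels, a lacunar volume distribution with mode 393 um^3, aspect ratios
#' centred on 0.46, and a matrix gray level that maps through the default
#' hydroxyapatite calibration to 1226 mgHA/cm^3.  The bone occupies a
#' centred rectangular prism (1:2 cross-section, mimicking the machined
#' sample), surrounded by a water bath carrying one alumina reference
#' inclusion.  The 64 x 192 x 192 grid keeps one full reconstruction +
#' training cycle desk-sized; pass a different `gridShape` for larger runs.
#'
#' @param gridShape voxel grid `(nz, ny, nx)`; in-plane dimensions should be
#'   equal (reconstruction is square).
#' @param nLacunae lacuna count (the source study does not report a number
#'   density; the default gives ~1% lacunar porosity, typical of cortical
#'   bone).
#' @param seed RNG seed.
#' @param ... further arguments forwarded to [phantomSpec()].
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- defaultBoneSpec(gridShape = c(8, 64, 64), nLacunae = 5)
#' spec
#' @export
defaultBoneSpec <- function(gridShape = c(64L, 192L, 192L), nLacunae = 60L,
                            seed = 1L, ...) {
  phantomSpec(gridShape = gridShape, nLacunae = nLacunae, seed = seed, ...)
}

# voxel index ranges of the bone prism, bath reference box and inclusion
phantomGeometry <- function(gridShape) {
  nz <- gridShape[1]; ny <- gridShape[2]; nx <- gridShape[3]
  boneY <- c(max(1L, round(0.32 * ny)), round(0.68 * ny))
  boneX <- c(max(1L, round(0.14 * nx)), round(0.86 * nx))
  inclR <- max(2, round(0.07 * ny))
  inclCy <- round((boneY[1] + 1) / 2)          # bath strip above the bone
  inclCx <- round(nx / 2)
  bathY <- c(max(1L, round(0.08 * ny)), max(2L, round(0.20 * ny)))
  bathX <- c(round(0.24 * nx), round(0.40 * nx))
  list(boneZ = c(1L, nz), boneY = as.integer(boneY), boneX = as.integer(boneX),
       inclusionCenter = c(y = inclCy, x = inclCx), inclusionRadius = inclR,
       bathRefY = as.integer(bathY), bathRefX = as.integer(bathX))
}

# sample from a truncated log-normal parameterized by its mode
sampleVolumes <- function(n, mode, sigma, range) {
  mu <- log(mode) + sigma^2
  out <- numeric(0)
  while (length(out) < n) {
    v <- stats::rlnorm(2 * n + 8, meanlog = mu, sdlog = sigma)
    out <- c(out, v[v >= range[1] & v <= range[2]])
  }
  out[seq_len(n)]
}

sampleTruncNorm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    v <- stats::rnorm(2 * n + 8, mean, sd)
    out <- c(out, v[v >= range[1] & v <= range[2]])
  }
  out[seq_len(n)]
}

# uniform random rotation matrix from a random unit quaternion
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a labeled synthetic bone volume
#'
#' Places `nLacunae` non-overlapping, randomly oriented ellipsoids inside
#' the bone prism by rejection sampling, voxelizes them on the grid
#' (voxel-centre membership test), assigns material attenuations and
#' records the analytic truth for every lacuna.  Deterministic for a fixed
#' `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param maxAttempts total rejection-sampling attempts before giving up.
#' @return a [LabeledVolume-class]; its truth table has columns `id`,
#'   `volume_um3` (analytic), `aspect_ratio`, `cx`, `cy`, `cz`
#'   (micrometres) and `voxel_count`.
#' @examples
#' vol <- generatePhantom(defaultBoneSpec(gridShape = c(6, 48, 48),
#'                                        nLacunae = 3))
#' truthTable(vol)
#' @export
generatePhantom <- function(spec, maxAttempts = 200L * max(1L, spec@nLacunae)) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@voxelSizeUm
  nz <- spec@gridShape[1]; ny <- spec@gridShape[2]; nx <- spec@gridShape[3]
  geo <- phantomGeometry(spec@gridShape)

  labels <- array(0L, dim = c(nz, ny, nx))
  att <- array(spec@bathAttenuation, dim = c(nz, ny, nx))
  att[, geo$boneY[1]:geo$boneY[2], geo$boneX[1]:geo$boneX[2]] <-
    spec@matrixAttenuation

  # reference inclusion: cylinder along z in the bath
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  inclDisk <- (yy - geo$inclusionCenter["y"])^2 +
    (xx - geo$inclusionCenter["x"])^2 <= geo$inclusionRadius^2
  for (z in seq_len(nz)) {
    sl <- att[z, , ]
    sl[inclDisk] <- spec@referenceInclusion$attenuation
    att[z, , ] <- sl
  }

  n <- spec@nLacunae
  truth <- data.frame(id = integer(0), volume_um3 = numeric(0),
                      aspect_ratio = numeric(0), cx = numeric(0),
                      cy = numeric(0), cz = numeric(0),
                      voxel_count = integer(0))
  if (n > 0) {
    placed <- withSeed(spec@seed, {
      vols <- sampleVolumes(n, spec@volumeModeUm3, spec@volumeSigmaLog,
                            spec@volumeRangeUm3)
      asps <- sampleTruncNorm(n, spec@aspectMean, spec@aspectSd,
                              spec@aspectRatioRange)
      out <- vector("list", n)
      centers <- matrix(NA_real_, n, 3)  # (x, y, z) um
      radii <- numeric(n)
      attempts <- 0L
      k <- 0L
      # bone extents in um (voxel-centre coordinates)
      lo <- c((geo$boneX[1] - 0.5) * h, (geo$boneY[1] - 0.5) * h, 0.5 * h)
      hi <- c((geo$boneX[2] - 0.5) * h, (geo$boneY[2] - 0.5) * h,
              (nz - 0.5) * h)
      while (k < n && attempts < maxAttempts) {
        attempts <- attempts + 1L
        i <- k + 1L
        rho <- asps[i]
        a <- (3 * vols[i] / (4 * pi * rho^1.5))^(1 / 3)
        b <- a * sqrt(rho)
        cc <- a * rho
        R <- randomRotation()
        # half-extent of the oriented ellipsoid along each grid axis
        ext <- sqrt(rowSums((R %*% diag(c(a, b, cc)))^2))
        m <- ext + h   # margin from bone faces, per axis
        if (2 * (cc + h) > min(hi - lo)) {
          stop(sprintf(
            "lacuna of volume %.0f um^3 cannot fit inside the bone region",
            vols[i]))
        }
        if (any(hi - lo < 2 * m)) next   # orientation does not fit; redraw
        ctr <- lo + m + stats::runif(3) * (hi - lo - 2 * m)
        ok <- TRUE
        if (k > 0) {
          d <- sqrt(colSums((t(centers[seq_len(k), , drop = FALSE]) - ctr)^2))
          ok <- all(d > radii[seq_len(k)] + a + h)
        }
        if (!ok) next
        k <- i
        centers[k, ] <- ctr
        radii[k] <- a
        out[[k]] <- list(center = ctr, axes = c(a, b, cc), R = R,
                         volume = vols[i], aspect = rho)
      }
      if (k < n)
        stop(sprintf("placed only %d of %d lacunae after %d attempts",
                     k, n, attempts))
      out
    })

    for (i in seq_len(n)) {
      L <- placed[[i]]
      a <- L$axes[1]
      # bounding box in voxel indices
      zr <- pmax(1L, pmin(nz, floor((L$center[3] - a) / h + 0.5):ceiling((L$center[3] + a) / h + 0.5)))
      yr <- pmax(1L, pmin(ny, floor((L$center[2] - a) / h + 0.5):ceiling((L$center[2] + a) / h + 0.5)))
      xr <- pmax(1L, pmin(nx, floor((L$center[1] - a) / h + 0.5):ceiling((L$center[1] + a) / h + 0.5)))
      zr <- unique(zr); yr <- unique(yr); xr <- unique(xr)
      g <- expand.grid(z = zr, y = yr, x = xr)
      P <- cbind((g$x - 0.5) * h - L$center[1],
                 (g$y - 0.5) * h - L$center[2],
                 (g$z - 0.5) * h - L$center[3])
      M <- L$R %*% diag(1 / L$axes^2) %*% t(L$R)
      inside <- rowSums((P %*% M) * P) <= 1
      sel <- g[inside, , drop = FALSE]
      idx <- cbind(sel$z, sel$y, sel$x)
      labels[idx] <- i
      att[idx] <- spec@lacunaAttenuation
      truth <- rbind(truth, data.frame(
        id = i, volume_um3 = L$volume, aspect_ratio = L$aspect,
        cx = L$center[1], cy = L$center[2], cz = L$center[3],
        voxel_count = nrow(sel)))
    }
  }

  new("LabeledVolume", attenuation = att, labels = labels, truth = truth,
      voxelSizeUm = h, geometry = geo)
}

#' Analysis window and calibration masks of a phantom
#'
#' `analysisWindow` returns the index ranges of the bone interior used for
#' quantification (the bone prism eroded by a small margin, mirroring the
#' fixed analysis window of the source protocol).  `referenceMasks` returns
#' logical masks over the full grid for the two calibration regions: a box
#' inside the water bath and the eroded core of the dense inclusion.
#'
#' @param vol a [LabeledVolume-class].
#' @param margin voxels eroded from the bone faces (in-plane) for the
#'   analysis window.
#' @return `analysisWindow`: list of integer index vectors `z`, `y`, `x`;
#'   `referenceMasks`: named list of two logical arrays.
#' @export
analysisWindow <- function(vol, margin = 3L) {
  geo <- vol@geometry
  d <- dim(vol@attenuation)
  zm <- if (d[1] > 4L) 2L else 0L
  list(z = (geo$boneZ[1] + zm):(geo$boneZ[2] - zm),
       y = (geo$boneY[1] + margin):(geo$boneY[2] - margin),
       x = (geo$boneX[1] + margin):(geo$boneX[2] - margin))
}

#' @rdname analysisWindow
#' @export
referenceMasks <- function(vol) {
  geo <- vol@geometry
  d <- dim(vol@attenuation)
  bath <- array(FALSE, d)
  bath[, geo$bathRefY[1]:geo$bathRefY[2], geo$bathRefX[1]:geo$bathRefX[2]] <- TRUE
  ny <- d[2]; nx <- d[3]
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  erode <- if (geo$inclusionRadius >= 5) 2 else 1
  disk <- (yy - geo$inclusionCenter["y"])^2 + (xx - geo$inclusionCenter["x"])^2 <=
    (geo$inclusionRadius - erode)^2
  incl <- array(FALSE, d)
  for (z in seq_len(d[1])) incl[z, , ] <- disk
  list(bath = bath, inclusion = incl)
}
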