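#' @include AllClasses.R
NULL

#' Construct a sinogram object
#'
#' @param data numeric matrix, `n_angles x n_detector`, line integrals
#'   (mu * mm).
#' @param angles strictly increasing radians in `[0, pi)`.
#' @param photonsPerPixel expected incident counts (`Inf` = noiseless).
#' @param sliceIndex axial slice index.
#' @param pixelSizeUm detector pitch, micrometres.
#' @return a validated [Sinogram-class].
#' @export
sinogram <- function(data, angles, photonsPerPixel = Inf, sliceIndex = 1L,
                     pixelSizeUm = 1.6) {
  new("Sinogram", data = data, angles = as.numeric(angles),
      photonsPerPixel = photonsPerPixel, sliceIndex = as.integer(sliceIndex),
      pixelSizeUm = pixelSizeUm)
}

#' Equally spaced parallel-beam view angles
#'
#' `n` angles over the half turn `[0, pi)`, the package-wide convention.
#'
#' @param n number of projections.
#' @return numeric vector of radians.
#' @export
projectionAngles <- function(n) seq(0, pi, length.out = n + 1)[seq_len(n)]

#' Project a volume to parallel-beam sinograms
#'
#' Discrete Radon transform of every axial slice: for each angle the slice
#' is integrated along rays at unit (one pixel) steps with bilinear
#' sampling, scaled by the pixel pitch so entries are line integrals in
#' mu * mm.  Linear in the input volume.
#'
#' @param vol a [LabeledVolume-class], a 3D array `(nz, ny, nx)` or a single
#'   slice matrix of attenuation values (1/mm).
#' @param angles radians in `[0, pi)` (see [projectionAngles()]).
#' @param voxelSizeUm voxel pitch; taken from `vol` when it is a
#'   [LabeledVolume-class].
#' @return list of [Sinogram-class], one per slice.
#' @examples
#' img <- matrix(0, 32, 32); img[10:20, 12:22] <- 0.3
#' s <- projectVolume(img, projectionAngles(24), voxelSizeUm = 1.6)[[1]]
#' dim(sinogramData(s))
#' @export
projectVolume <- function(vol, angles, voxelSizeUm = NULL) {
  if (is(vol, "LabeledVolume")) {
    voxelSizeUm <- vol@voxelSizeUm
    vol <- vol@attenuation
  }
  if (is.matrix(vol)) vol <- array(vol, dim = c(1L, dim(vol)))
  if (is.null(voxelSizeUm))
    stop("voxelSizeUm is required for plain arrays")
  if (any(angles < 0 | angles >= pi))
    stop("angles must lie in [0, pi) (half-turn parallel-beam convention)")
  if (!all(is.finite(vol))) stop("volume must be finite")
  pixelMm <- voxelSizeUm / 1000
  lapply(seq_len(dim(vol)[1]), function(z) {
    sinogram(cpp_radon(vol[z, , ], angles, pixelMm), angles,
             photonsPerPixel = Inf, sliceIndex = z,
             pixelSizeUm = voxelSizeUm)
  })
}

#' Apply a photon-counting noise model to a sinogram
#'
#' Draws transmitted counts `N ~ Poisson(I0 * exp(-p))` independently per
#' bin and returns the post-log sinogram `-log(max(N, 1) / I0)`.  Counts
#' are clamped at 1 before the log (standard transmission-CT practice); a
#' message reports how many bins were clamped.  With `photons = Inf` the
#' input is returned unchanged.
#'
#' @param sino a [Sinogram-class].
#' @param photons expected incident photons per bin (I0), or `Inf`.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return a [Sinogram-class] with `photonsPerPixel` recorded.
#' @export
simulateCounts <- function(sino, photons, seed) {
  stopifnot(is(sino, "Sinogram"))
  if (is.infinite(photons)) {
    sino@photonsPerPixel <- Inf
    return(sino)
  }
  if (!is.finite(photons) || photons <= 0)
    stop("photons must be positive (or Inf for the noiseless passthrough)")
  p <- sino@data
  counts <- withSeed(seed, stats::rpois(length(p), photons * exp(-p)))
  nClamped <- sum(counts < 1)
  if (nClamped > 0)
    message(nClamped, " zero-count bins clamped to 1 before the log")
  counts <- pmax(counts, 1)
  sino@data <- matrix(-log(counts / photons), nrow(p), ncol(p))
  sino@photonsPerPixel <- photons
  sino
}

#' Angular subsampling to a fractional dose
#'
#' Keeps every `denominator`-th projection starting at `offset` (0-based),
#' the dose-reduction mechanism of the simulated-dose datasets: the
#' retained projection count is `ceiling((n - offset) / denominator)`, and
#' per-projection noise is unchanged.
#'
#' @param sino a [Sinogram-class].
#' @param denominator integer n >= 1: keep a 1/n dose.
#' @param offset starting angle index, `0 <= offset < denominator`.
#' @return the subsampled [Sinogram-class].
#' @examples
#' s <- sinogram(matrix(0, 3937, 8), projectionAngles(3937))
#' nAngles(subsampleAngles(s, 3))   # 1313
#' nAngles(subsampleAngles(s, 6))   # 657
#' @export
subsampleAngles <- function(sino, denominator, offset = 0L) {
  stopifnot(is(sino, "Sinogram"))
  denominator <- as.integer(denominator)
  offset <- as.integer(offset)
  if (denominator < 1L) stop("denominator must be >= 1")
  if (offset < 0L || offset >= denominator)
    stop("offset must satisfy 0 <= offset < denominator")
  n <- nrow(sino@data)
  if (denominator > n)
    stop("denominator (", denominator, ") exceeds the number of angles (", n, ")")
  keep <- seq(offset + 1L, n, by = denominator)
  sinogram(sino@data[keep, , drop = FALSE], sino@angles[keep],
           photonsPerPixel = sino@photonsPerPixel,
           sliceIndex = sino@sliceIndex, pixelSizeUm = sino@pixelSizeUm)
}
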