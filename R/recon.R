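#' @include AllClasses.R
NULL

# band-limited Ram-Lak kernel of circular length m (detector pitch = 1)
ramLakKernel <- function(m) {
  h <- numeric(m)
  h[1] <- 0.25
  n <- seq_len(m %/% 2)
  odd <- n[n %% 2 == 1]
  h[odd + 1] <- -1 / (pi * odd)^2
  h[m - odd + 1] <- -1 / (pi * odd)^2
  h
}

#' Filtered back projection of one sinogram
#'
#' Standard parallel-beam FBP on the sinogram's own angle list: each
#' projection row is convolved with the band-limited ramp (Ram-Lak) kernel
#' via FFT, then backprojected with linear detector interpolation and
#' scaled by `pi / n_angles`.  Output gray values approximate the linear
#' attenuation coefficient (1/mm) of the imaged slice; the reconstruction
#' circle is not masked (the bath fills the field of view).
#'
#' @param sino a [Sinogram-class] with at least 2 angles.
#' @param filter `"ramlak"` (default, plain ramp) or `"shepp-logan"`.
#' @return square matrix `n_det x n_det` of attenuation values (1/mm).
#' @examples
#' img <- matrix(0, 48, 48)
#' img[(row(img) - 24)^2 + (col(img) - 24)^2 < 14^2] <- 0.3
#' s <- projectVolume(img, projectionAngles(90), voxelSizeUm = 1.6)[[1]]
#' rec <- fbp(s)
#' @export
fbp <- function(sino, filter = c("ramlak", "shepp-logan")) {
  stopifnot(is(sino, "Sinogram"))
  filter <- match.arg(filter)
  p <- sino@data
  na <- nrow(p)
  if (na < 2L) stop("FBP needs at least 2 angles")
  ndet <- ncol(p)
  pixelMm <- sino@pixelSizeUm / 1000
  pp <- p / pixelMm                      # per-pixel line sums
  m <- max(64L, nextPow2(2L * ndet))
  h <- ramLakKernel(m)
  H <- Re(stats::fft(h))                 # real, even kernel
  if (filter == "shepp-logan") {
    f <- fftfreq(m)
    H <- H * ifelse(f == 0, 1, sin(pi * f) / (pi * f))
  }
  pad <- matrix(0, na, m)
  pad[, seq_len(ndet)] <- pp
  Fp <- t(stats::mvfft(t(pad)))
  q <- Re(t(stats::mvfft(t(Fp * rep(H, each = na)), inverse = TRUE))) / m
  q <- q[, seq_len(ndet), drop = FALSE]
  cpp_backproject(q, sino@angles, ndet, ndet) * pi / na
}

#' Split a sinogram into K angle-interleaved sub-sinograms
#'
#' Sub-sinogram `j` keeps rows `j, j+K, j+2K, ...` (0-based), so the K
#' angle sets are disjoint, their union is the parent's angle set, and
#' sizes differ by at most one (the extra angle goes to split 0).
#'
#' @param sino a [Sinogram-class].
#' @param K number of splits, `1 <= K <= n_angles`.
#' @return list of K [Sinogram-class] objects (`K = 1` returns the input as
#'   a singleton list).
#' @examples
#' s <- sinogram(matrix(0, 657, 8), projectionAngles(657))
#' vapply(splitSinogram(s, 3), nAngles, 1L)   # 219 219 219
#' @export
splitSinogram <- function(sino, K) {
  stopifnot(is(sino, "Sinogram"))
  K <- as.integer(K)
  n <- nrow(sino@data)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of angles (", n, ")")
  lapply(seq_len(K) - 1L, function(j) {
    keep <- seq(j + 1L, n, by = K)
    sinogram(sino@data[keep, , drop = FALSE], sino@angles[keep],
             photonsPerPixel = sino@photonsPerPixel,
             sliceIndex = sino@sliceIndex, pixelSizeUm = sino@pixelSizeUm)
  })
}

#' Reconstruct the K sub-volumes used by Noise2Inverse
#'
#' Splits each slice sinogram into K interleaved parts and reconstructs
#' each part with [fbp()], recording the angle provenance.  The K volumes
#' share the underlying signal but have independent noise, which is the
#' premise of Noise2Inverse training.
#'
#' @param sinos a [Sinogram-class] or a list of them (one per slice).
#' @param K number of splits, >= 2.
#' @param filter passed to [fbp()].
#' @return a [SubReconSet-class] whose sub-volumes have shape
#'   `(n_slices, n_det, n_det)`.
#' @export
makeSubrecons <- function(sinos, K, filter = "ramlak") {
  if (is(sinos, "Sinogram")) sinos <- list(sinos)
  K <- as.integer(K)
  if (K < 2L) stop("Noise2Inverse needs K >= 2 splits")
  nz <- length(sinos)
  ndet <- ncol(sinos[[1]]@data)
  vols <- lapply(seq_len(K), function(k) array(0, dim = c(nz, ndet, ndet)))
  angleSets <- NULL
  for (z in seq_len(nz)) {
    parts <- splitSinogram(sinos[[z]], K)
    if (z == 1L) angleSets <- lapply(parts, function(s) s@angles)
    for (k in seq_len(K)) vols[[k]][z, , ] <- fbp(parts[[k]], filter = filter)
  }
  new("SubReconSet", K = K, subRecons = vols, angleSets = angleSets,
      pixelSizeUm = sinos[[1]]@pixelSizeUm)
}

#' Parameters for single-distance phase retrieval
#'
#' Defaults are the hydroxyapatite refractive decrement and absorption
#' index at 24 keV used for the comparison baseline.
#'
#' @param delta refractive index decrement.
#' @param beta absorption index.
#' @param energyKeV photon energy.
#' @param distanceMm propagation (sample-detector) distance; no packaged
#'   default exists, it must be supplied.
#' @param pixelUm detector pixel size.
#' @return list of validated parameters.
#' @export
paganinParams <- function(delta = 1.1378e-6, beta = 4.8945e-9,
                          energyKeV = 24, distanceMm, pixelUm = 1.6) {
  stopifnot(delta > 0, beta > 0, energyKeV > 0, distanceMm >= 0, pixelUm > 0)
  list(delta = delta, beta = beta, energyKeV = energyKeV,
       distanceMm = distanceMm, pixelUm = pixelUm)
}

#' Paganin single-distance phase retrieval
#'
#' Applies the low-pass kernel `1 / (1 + (lambda * z * delta / (4 pi beta))
#' |k|^2)` to each flat-corrected transmission projection in Fourier space,
#' followed by the negative log.  With `distanceMm = 0` the kernel is unity
#' and the result reduces to the plain `-log(transmission)` contact image.
#'
#' @param projections a transmission image (matrix) or stack
#'   (`n_proj, ny, nx` array); all values must be positive.
#' @param params from [paganinParams()].
#' @return retrieved projections, same shape as the input.
#' @examples
#' flat <- matrix(1, 16, 16)
#' range(paganinFilter(flat, paganinParams(distanceMm = 50)))   # all zero
#' @export
paganinFilter <- function(projections, params) {
  single <- is.matrix(projections)
  if (single) projections <- array(projections, c(1L, dim(projections)))
  if (any(projections <= 0))
    stop("transmission projections must be positive (flat-corrected)")
  d <- dim(projections)
  lambdaUm <- 1.23984193e-3 / params$energyKeV      # wavelength in um
  fac <- lambdaUm * (params$distanceMm * 1000) * params$delta /
    (4 * pi * params$beta)                           # um^2
  ky <- 2 * pi * fftfreq(d[2]) / params$pixelUm
  kx <- 2 * pi * fftfreq(d[3]) / params$pixelUm
  denom <- 1 + fac * (outer(ky^2, rep(1, d[3])) + outer(rep(1, d[2]), kx^2))
  out <- array(0, d)
  for (i in seq_len(d[1])) {
    f <- stats::fft(projections[i, , ]) / denom
    filt <- Re(stats::fft(f, inverse = TRUE)) / (d[2] * d[3])
    out[i, , ] <- -log(pmax(filt, 1e-12))
  }
  if (single) out[1, , ] else out
}

#' Sliding-window median baseline
#'
#' The conventional denoising baseline: a `(2r+1)^3` sliding-window median
#' with edge-reflected boundaries.  Idempotent on constant volumes.
#'
#' @param vol 3D array `(nz, ny, nx)` or a matrix (treated as one slice).
#' @param radius window radius in voxels, >= 1.
#' @return filtered volume, same shape.
#' @export
medianBaseline <- function(vol, radius = 1L) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  single <- is.matrix(vol)
  if (single) vol <- array(vol, c(1L, dim(vol)))
  out <- cpp_median3d(vol, radius)
  if (single) out[1, , ] else out
}
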