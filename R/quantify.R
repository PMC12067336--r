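#' @include AllClasses.R
NULL

#' Automatic histogram thresholding (Yen / Otsu)
#'
#' Computes a 256-bin histogram over the image range and scans every bin
#' boundary exhaustively: Yen maximizes the maximum-correlation criterion,
#' Otsu the between-class variance.  Mirrors the common ImageJ
#' implementations used for lacuna segmentation.
#'
#' @param img numeric array/matrix of finite values with at least two
#'   distinct values.
#' @param method `"yen"` or `"otsu"`.
#' @param nBins histogram bins (default 256).
#' @return the threshold gray value (a bin boundary inside the image range).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 10, 1), rnorm(500, 30, 2))
#' autoThreshold(x, "otsu")
#' @export
autoThreshold <- function(img, method = c("yen", "otsu"), nBins = 256L) {
  method <- match.arg(method)
  x <- as.numeric(img)
  if (!all(is.finite(x))) stop("image must be finite")
  mn <- min(x); mx <- max(x)
  if (mn == mx) stop("cannot threshold a constant image")
  bin <- pmin(floor((x - mn) / (mx - mn) * nBins) + 1L, nBins)
  p <- tabulate(bin, nBins) / length(x)
  t <- seq_len(nBins - 1L)
  P1 <- cumsum(p)[t]
  eps <- 1e-12
  if (method == "yen") {
    G <- cumsum(p^2)
    G1 <- G[t]
    G2 <- G[nBins] - G1
    crit <- 2 * log(pmax(P1 * (1 - P1), eps)) - log(pmax(G1 * G2, eps))
  } else {
    mu <- cumsum(p * seq_len(nBins))
    muT <- mu[nBins]
    w1 <- pmax(P1, eps)
    w2 <- pmax(1 - P1, eps)
    crit <- (muT * P1 - mu[t])^2 / (w1 * w2)
  }
  tBest <- t[which.max(crit)]
  mn + tBest * (mx - mn) / nBins
}

#' Label and measure lacunae in a binary mask
#'
#' 3D connected-component analysis with a 26-connected labeling scheme,
#' followed by per-component morphometry: volume (`voxel_count *
#' voxelSize^3`), centroid, and aspect ratio from the eigenvalues of the
#' voxel-coordinate covariance matrix.  Components outside the inclusive
#' volume filter `[vmin, vmax]` are dropped (default 50-2000 um^3, the
#' conventional lacuna range).
#'
#' The reported aspect ratio is the ratio of the shortest to the longest
#' principal axis length, `sqrt(lambda_min / lambda_max)` (1 = sphere,
#' -> 0 = rod/plate); `aspectMethod = "eigenvalue"` reports the raw
#' eigenvalue ratio instead.  Moments use the population covariance of the
#' voxel centres, which is an essentially unbiased estimate of the
#' continuous-shape covariance at these component sizes.
#'
#' @param mask logical (or strictly 0/1) 3D array.
#' @param voxelSizeUm voxel edge in micrometres.
#' @param vmin,vmax inclusive volume filter bounds, um^3.
#' @param aspectMethod `"axis"` (default) or `"eigenvalue"`.
#' @return data.frame (`id`, `voxel_count`, `volume_um3`, `aspect_ratio`,
#'   `cx`, `cy`, `cz`) of the kept components, with attributes
#'   `nComponents` (total labeled) and `nRejected` (filtered out).
#' @export
labelLacunae <- function(mask, voxelSizeUm, vmin = 50, vmax = 2000,
                         aspectMethod = c("axis", "eigenvalue")) {
  aspectMethod <- match.arg(aspectMethod)
  if (is.logical(mask)) {
    lg <- mask
  } else {
    u <- unique(as.vector(mask))
    if (!all(u %in% c(0, 1))) stop("mask must be binary (logical or 0/1)")
    lg <- mask == 1
    dim(lg) <- dim(mask)
  }
  h <- voxelSizeUm
  lab <- cpp_label26(lg)
  idx <- which(lab > 0L)
  nComp <- if (length(idx)) max(lab[idx]) else 0L
  rows <- vector("list", nComp)
  if (nComp > 0L) {
    co <- arrayInd(idx, dim(lab))        # (z, y, x) voxel indices
    comp <- lab[idx]
    ord <- order(comp)
    co <- co[ord, , drop = FALSE]
    comp <- comp[ord]
    bounds <- c(0L, cumsum(tabulate(comp, nComp)))
    for (i in seq_len(nComp)) {
      sel <- (bounds[i] + 1L):bounds[i + 1L]
      P <- co[sel, , drop = FALSE]
      nv <- nrow(P)
      vol <- nv * h^3
      ctr <- colMeans(P)                 # (z, y, x) in voxels
      if (nv >= 2L) {
        C <- stats::cov(P * h) * (nv - 1) / nv      # population covariance
        ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
        ar <- if (max(ev) <= 0) 1 else if (aspectMethod == "axis")
          sqrt(max(min(ev), 0) / max(ev)) else max(min(ev), 0) / max(ev)
      } else {
        ar <- 1
      }
      rows[[i]] <- data.frame(
        id = i, voxel_count = nv, volume_um3 = vol, aspect_ratio = ar,
        cx = (ctr[3] - 0.5) * h, cy = (ctr[2] - 0.5) * h,
        cz = (ctr[1] - 0.5) * h)
    }
  }
  out <- if (nComp > 0L) do.call(rbind, rows) else
    data.frame(id = integer(0), voxel_count = integer(0),
               volume_um3 = numeric(0), aspect_ratio = numeric(0),
               cx = numeric(0), cy = numeric(0), cz = numeric(0))
  keep <- out$volume_um3 >= vmin & out$volume_um3 <= vmax
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "nComponents") <- nComp
  attr(res, "nRejected") <- nComp - sum(keep)
  res
}

#' Mode of a distribution via kernel density estimation
#'
#' The location of the maximum of a Gaussian KDE evaluated on a fixed grid
#' over the data range; deterministic given the bandwidth (Silverman's
#' rule by default).  A single value, or a zero-variance sample, returns
#' that value directly.
#'
#' @param values numeric vector (at least one value).
#' @param bandwidth KDE bandwidth; `NULL` uses `stats::bw.nrd0`.
#' @param n grid points.
#' @return the mode estimate.
#' @examples
#' distributionMode(c(7, 7, 7))                  # 7
#' @export
distributionMode <- function(values, bandwidth = NULL, n = 2048L) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("need at least one value")
  if (length(values) == 1L || stats::sd(values) == 0) return(values[1])
  d <- stats::density(values, bw = bandwidth %||% "nrd0", n = n)
  d$x[which.max(d$y)]
}

#' Calibrate reconstructed gray values to mineral density
#'
#' For each reference region the apparent density is the mean gray value
#' (1/mm, converted to 1/cm) divided by the material's mass attenuation
#' coefficient; a linear least-squares fit of known vs apparent density
#' (exact through two points) is then applied to the bone gray values via
#' the mass attenuation of hydroxyapatite, yielding mgHA/cm^3.
#'
#' @param vol reconstructed attenuation volume (1/mm), array or matrix.
#' @param regions named list of logical masks (same shape as `vol`), one
#'   per reference material; each must cover at least 10 voxels.
#' @param materials character vector of material names matching `regions`.
#' @param knownDensities tabulated densities (g/cm^3); defaults from
#'   [referenceDensity()].
#' @param massAtten mass attenuation of the reference materials (cm^2/g);
#'   defaults from [massAttenuation()].
#' @param haMassAtten mass attenuation of hydroxyapatite (cm^2/g).
#' @return list with `volume` (mineral density, mgHA/cm^3, same shape as
#'   the input) and `calibration` (a [MineralCalibration-class]).
#' @export
calibrateMineralization <- function(vol, regions, materials,
                                    knownDensities = referenceDensity(materials),
                                    massAtten = massAttenuation(materials),
                                    haMassAtten = massAttenuation("hydroxyapatite")) {
  if (length(regions) < 2L) stop("need at least 2 reference regions")
  if (length(materials) != length(regions))
    stop("materials must match regions")
  nVox <- vapply(regions, sum, 1)
  if (any(nVox < 10))
    stop("every reference region needs at least 10 voxels")
  apparent <- vapply(seq_along(regions), function(i)
    mean(vol[regions[[i]]]) * 10 / massAtten[i], 1)
  if (max(apparent) - min(apparent) < 1e-12)
    stop("degenerate calibration: identical apparent densities")
  fit <- stats::lm(knownDensities ~ apparent)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  cal <- new("MineralCalibration",
             points = data.frame(material = materials, apparent = apparent,
                                 known = knownDensities),
             slope = slope, intercept = intercept)
  dens <- (slope * (vol * 10 / haMassAtten) + intercept) * 1000
  list(volume = dens, calibration = cal)
}

#' Apply a mineral calibration to gray values
#'
#' @param cal a [MineralCalibration-class].
#' @param gray attenuation values (1/mm).
#' @param haMassAtten hydroxyapatite mass attenuation (cm^2/g).
#' @return mineral density, mgHA/cm^3.
#' @export
applyCalibration <- function(cal, gray,
                             haMassAtten = massAttenuation("hydroxyapatite")) {
  (cal@slope * (gray * 10 / haMassAtten) + cal@intercept) * 1000
}

#' Paired comparison of two groups of per-sample statistics
#'
#' Reports Shapiro-Wilk normality of the paired differences and Levene
#' variance homogeneity across groups (informational, not gating), then a
#' two-sided paired t-test, plus the percent change of group means.  When
#' the paired differences have zero variance the t statistic is undefined;
#' the result is returned flagged degenerate instead of erroring.
#'
#' @param a,b numeric vectors of equal length >= 3 (paired by position).
#' @return a [PairedComparison-class].
#' @examples
#' comparePaired(c(10, 12, 14, 11), c(8, 9, 12, 9))
#' @export
comparePaired <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("groups must have equal length")
  if (length(a) < 3L) stop("need at least 3 pairs")
  ok <- is.finite(a) & is.finite(b)
  if (!all(ok)) {
    warning(sum(!ok), " pair(s) with missing values dropped")
    if (sum(ok) < 3L) {
      return(new("PairedComparison", a = a, b = b, shapiroP = NA_real_,
                 leveneP = NA_real_, tStatistic = NA_real_,
                 pValue = NA_real_, modeChangePct = NA_real_,
                 degenerate = TRUE))
    }
    full <- comparePaired(a[ok], b[ok])
    full@a <- a
    full@b <- b
    return(full)
  }
  d <- b - a
  if (stats::sd(d) == 0) {
    return(new("PairedComparison", a = a, b = b, shapiroP = NA_real_,
               leveneP = NA_real_, tStatistic = NA_real_, pValue = NA_real_,
               modeChangePct = if (mean(a) != 0)
                 100 * (mean(b) - mean(a)) / mean(a) else NA_real_,
               degenerate = TRUE))
  }
  sw <- stats::shapiro.test(d)$p.value
  lv <- car::leveneTest(c(a, b), factor(rep(c("a", "b"), each = length(a))))
  lvP <- lv[["Pr(>F)"]][1]
  tt <- stats::t.test(b, a, paired = TRUE)
  new("PairedComparison", a = a, b = b, shapiroP = sw, leveneP = lvP,
      tStatistic = unname(tt$statistic), pValue = tt$p.value,
      modeChangePct = 100 * (mean(b) - mean(a)) / mean(a),
      degenerate = FALSE)
}
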