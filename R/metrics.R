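#' @include AllClasses.R
NULL

# mean SSIM of two matrices over the valid region of a w x w uniform window
ssim2d <- function(x, y, L, w = 7L) {
  w <- min(w, dim(x))
  if (w %% 2L == 0L) w <- w - 1L
  if (w < 1L) return(NA_real_)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mx <- boxMeanValid(x, w)
  my <- boxMeanValid(y, w)
  vx <- boxMeanValid(x * x, w) - mx^2
  vy <- boxMeanValid(y * y, w) - my^2
  cxy <- boxMeanValid(x * y, w) - mx * my
  # unbiased sample estimates, as in the standard implementation
  f <- w * w / (w * w - 1)
  vx <- vx * f; vy <- vy * f; cxy <- cxy * f
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Image-quality metrics against a reference
#'
#' Mean squared error, peak signal-to-noise ratio and structural
#' similarity.  `PSNR = 10 log10(range^2 / MSE)`; the data range defaults
#' to the reference image's max - min and is recorded in the report, since
#' PSNR is meaningless without its range convention.  SSIM uses the
#' standard constants K1 = 0.01, K2 = 0.03 and a 7-pixel uniform window,
#' computed slice-wise on volumes and averaged.
#'
#' @param test,reference arrays of identical shape (matrix or 3D
#'   `(nz, ny, nx)` volume).
#' @param dataRange `"auto"` (reference max - min) or an explicit positive
#'   number.
#' @return list of class `QualityReport`: `mse`, `psnr` (dB, `Inf` for
#'   identical images), `ssim`, `dataRange`.
#' @examples
#' ref <- matrix(runif(64), 8, 8)
#' imageQuality(ref + 0.1, ref, dataRange = 1)$mse   # 0.01
#' @export
imageQuality <- function(test, reference, dataRange = "auto") {
  if (!identical(dim(test), dim(reference)))
    stop("test and reference must have identical shapes")
  if (!all(is.finite(reference))) stop("reference must be finite")
  if (identical(dataRange, "auto")) {
    dataRange <- max(reference) - min(reference)
    if (dataRange == 0) stop("reference has zero range; give dataRange explicitly")
  }
  if (!is.numeric(dataRange) || dataRange <= 0)
    stop("dataRange must be positive")
  mse <- mean((test - reference)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(dataRange^2 / mse)
  d <- dim(test)
  ssim <- if (length(d) == 2L) {
    ssim2d(test, reference, dataRange)
  } else {
    mean(vapply(seq_len(d[1]), function(z)
      ssim2d(test[z, , ], reference[z, , ], dataRange), 1))
  }
  structure(list(mse = mse, psnr = psnr, ssim = ssim, dataRange = dataRange),
            class = "QualityReport")
}

#' @export
print.QualityReport <- function(x, ...) {
  cat(sprintf("QualityReport: MSE %.4g | PSNR %.2f dB | SSIM %.3f (range %.4g)\n",
              x$mse, x$psnr, x$ssim, x$dataRange))
  invisible(x)
}

#' Percent change relative to a reference value
#'
#' `100 * (new - reference) / reference`; the convention behind every
#' percent figure in the dose-sweep reports (display rounding to one
#' decimal is left to the caller).
#'
#' @param new,reference numeric (vectorized); `reference` must be non-zero.
#' @return percent change.
#' @examples
#' percentChange(0.00186, 0.00225)   # -17.33
#' percentChange(0.47, 0.35)         # 34.29
#' @export
percentChange <- function(new, reference) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * (new - reference) / reference
}
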