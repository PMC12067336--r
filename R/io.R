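#' Read and write volumes as 32-bit TIFF stacks
#'
#' Volumes are stored slice-per-page as 32-bit grayscale, the interchange
#' format for reconstructed stacks.  The TIFF backend stores samples on a
#' [0, 1] scale, so gray values are affinely mapped into that range on
#' write and the original range is recorded in a small JSON sidecar
#' (`<path>.range.json`); `readVolumeTiff` restores the original units
#' automatically when the sidecar is present.
#'
#' @param vol 3D array `(nz, ny, nx)` or a matrix (single slice).
#' @param path file path.
#' @return `writeVolumeTiff` returns `path` invisibly; `readVolumeTiff`
#'   returns a 3D array `(nz, ny, nx)`.
#' @export
writeVolumeTiff <- function(vol, path) {
  if (is.matrix(vol)) vol <- array(vol, c(1L, dim(vol)))
  lo <- min(vol); hi <- max(vol)
  scaled <- if (hi > lo) (vol - lo) / (hi - lo) else vol * 0
  pages <- lapply(seq_len(dim(vol)[1]), function(z) scaled[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(sprintf('{"min": %.17g, "max": %.17g}', lo, hi),
             paste0(path, ".range.json"))
  invisible(path)
}

#' @rdname writeVolumeTiff
#' @export
readVolumeTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  sidecar <- paste0(path, ".range.json")
  if (file.exists(sidecar)) {
    txt <- paste(readLines(sidecar, warn = FALSE), collapse = "")
    lo <- as.numeric(sub('.*"min":\\s*([-0-9.eE+]+).*', "\\1", txt))
    hi <- as.numeric(sub('.*"max":\\s*([-0-9.eE+]+).*', "\\1", txt))
    if (is.finite(lo) && is.finite(hi) && hi > lo) out <- out * (hi - lo) + lo
  }
  out
}

#' Write / read a lacuna morphometry table as CSV
#'
#' Plain CSV with header `id, volume_um3, aspect_ratio, cx, cy, cz` (plus
#' any extra measurement columns present).
#'
#' @param table a lacuna table (data.frame).
#' @param path file path.
#' @return `writeLacunaTable` returns `path` invisibly; `readLacunaTable`
#'   the data.frame.
#' @export
writeLacunaTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLacunaTable
#' @export
readLacunaTable <- function(path) {
  utils::read.csv(path)
}
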