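# internal helpers

# run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# reflect a 1-based index into [1, n] without repeating the boundary slice:
# offsets around slice 1 give 3, 2, 1, 2, 3 (mirror convention)
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- i - 1L
  p <- 2L * (n - 1L)
  j <- ((j %% p) + p) %% p
  ifelse(j < n, j, p - j) + 1L
}

nextPow2 <- function(n) 2^ceiling(log2(n))

# DFT sample frequencies (cycles per sample), length n
fftfreq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

# valid-region (no padding) box mean of a matrix with a w x w window,
# via integral images; output is (nr - w + 1) x (nc - w + 1)
boxMeanValid <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1, nc + 1)
  cs <- apply(m, 2, cumsum)
  S[-1, -1] <- t(apply(cs, 1, cumsum))
  i <- seq_len(nr - w + 1)
  j <- seq_len(nc - w + 1)
  (S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
      S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]) / (w * w)
}

# crop a (nz, ny, nx) volume to index ranges given as a list(z=, y=, x=)
cropVolume <- function(vol, win) {
  vol[win$z, win$y, win$x, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
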