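# shared fixture builders (everything generated in code, nothing on disk)

# uniform disk image, value mu, radius r pixels
diskImage <- function(n, r, mu = 0.3) {
  ctr <- (n + 1) / 2
  img <- matrix(0, n, n)
  img[(row(img) - ctr)^2 + (col(img) - ctr)^2 <= r^2] <- mu
  img
}

# digital axis-aligned ellipsoid mask with semi-axes (in voxels) a >= b >= c
# along x, y, z; cubic grid just large enough
digitalEllipsoid <- function(a, b, c, R = diag(3)) {
  n <- 2L * ceiling(max(a, b, c)) + 5L
  ctr <- (n + 1) / 2
  g <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  P <- cbind(g$x - ctr, g$y - ctr, g$z - ctr) %*% R
  m <- (P[, 1] / a)^2 + (P[, 2] / b)^2 + (P[, 3] / c)^2 <= 1
  array(m, c(n, n, n))
}

# rotation matrix about the z axis
rotZ <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# small phantom spec used across tests (fast to generate and reconstruct)
tinySpec <- function(seed = 3, nz = 8L, n = 64L, nLacunae = 6L) {
  defaultBoneSpec(gridShape = c(nz, n, n), nLacunae = nLacunae, seed = seed,
                  volumeRangeUm3 = c(100, 700))
}

# independent brute-force threshold oracles (naive loops, coded separately
# from the package's vectorized implementations)
bruteForceYen <- function(x, nBins = 256L) {
  mn <- min(x); mx <- max(x)
  bin <- pmin(floor((x - mn) / (mx - mn) * nBins) + 1L, nBins)
  p <- tabulate(bin, nBins) / length(x)
  best <- -Inf; bestT <- 1L
  for (t in 1:(nBins - 1L)) {
    P1 <- 0; G1 <- 0; G2 <- 0
    for (i in 1:t) { P1 <- P1 + p[i]; G1 <- G1 + p[i]^2 }
    for (i in (t + 1L):nBins) G2 <- G2 + p[i]^2
    crit <- 2 * log(max(P1 * (1 - P1), 1e-12)) - log(max(G1 * G2, 1e-12))
    if (crit > best) { best <- crit; bestT <- t }
  }
  mn + bestT * (mx - mn) / nBins
}

bruteForceOtsu <- function(x, nBins = 256L) {
  mn <- min(x); mx <- max(x)
  bin <- pmin(floor((x - mn) / (mx - mn) * nBins) + 1L, nBins)
  p <- tabulate(bin, nBins) / length(x)
  best <- -Inf; bestT <- 1L
  for (t in 1:(nBins - 1L)) {
    w1 <- sum(p[1:t]); w2 <- 1 - w1
    if (w1 < 1e-12 || w2 < 1e-12) next
    m1 <- sum(p[1:t] * (1:t)) / w1
    m2 <- sum(p[(t + 1L):nBins] * ((t + 1L):nBins)) / w2
    crit <- w1 * w2 * (m1 - m2)^2
    if (crit > best) { best <- crit; bestT <- t }
  }
  mn + bestT * (mx - mn) / nBins
}
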