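# Brute-force oracles, written independently of the package internals:
# plain loops over pixels, eigen() for moments, counting-based ranks.

oracle_moments <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  mu <- colMeans(pts)
  M <- matrix(0, 2, 2)
  for (i in seq_len(n)) {
    d <- pts[i, ] - mu
    M <- M + d %*% t(d)
  }
  list(n = n, mu = mu, M = M / n)
}

oracle_eccentricity <- function(mask) {
  m <- oracle_moments(mask)
  ev <- eigen(m$M, symmetric = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(1 - max(ev[2], 0) / ev[1])
}

oracle_compactness <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  mu <- colMeans(pts)
  msd <- 0
  for (i in seq_len(nrow(pts))) {
    msd <- msd + sum((pts[i, ] - mu)^2)
  }
  msd <- msd / nrow(pts)
  2 * pi * msd / nrow(pts)
}

oracle_mass_displacement <- function(mask, intensity) {
  pts <- which(mask, arr.ind = TRUE)
  w <- intensity[mask]
  geo <- colMeans(pts)
  wgt <- c(sum(w * pts[, 1]), sum(w * pts[, 2])) / sum(w)
  sqrt(sum((wgt - geo)^2))
}

# midranks by counting (independent of base rank())
oracle_midrank <- function(x) {
  sapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2)
}

oracle_rwc <- function(p, s, thr_p, thr_s) {
  rp <- oracle_midrank(p)
  rs <- oracle_midrank(s)
  d <- abs(rp - rs)
  rmax <- max(d)
  w <- if (rmax == 0) rep(1, length(d)) else (rmax - d) / rmax
  sel <- p > thr_p & s > thr_s
  sum(p[sel] * w[sel]) / sum(p)
}

# 8-connected component count by breadth-first flood fill
oracle_n_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            mask[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE
          queue[[length(queue) + 1]] <- c(a, b)
        }
      }
    }
  }
  n
}
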