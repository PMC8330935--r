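# Independent reference implementations used as oracles. These are written
# as literal double loops against the mathematical definitions and stay
# independent of the package's compiled code paths.

# Phansalkar threshold map: brute-force per-pixel evaluation over the
# digital disk with mirror (edge-inclusive) padding. The accumulation
# order (dx outer, dy inner) matches the documented window contract.
bruteForcePhansalkar <- function(img, radius, k = 0.25, r = 0.5, p = 2.0,
                                 q = 10.0) {
  n <- nrow(img); m <- ncol(img)
  refl <- function(i, nn) {
    if (i < 0L) -1L - i else if (i >= nn) 2L * nn - 1L - i else i
  }
  out <- matrix(0, n, m)
  offs <- list()
  for (dx in -radius:radius) for (dy in -radius:radius)
    if (dx * dx + dy * dy <= radius * radius)
      offs[[length(offs) + 1L]] <- c(dx, dy)
  nw <- length(offs)
  for (j in 0:(m - 1L)) {
    for (i in 0:(n - 1L)) {
      s <- 0; sq <- 0
      for (w in seq_len(nw)) {
        ii <- refl(i + offs[[w]][2], n)
        jj <- refl(j + offs[[w]][1], m)
        v <- img[ii + 1L, jj + 1L]
        s <- s + v
        sq <- sq + v * v
      }
      mu <- s / nw
      ex2 <- sq / nw
      mumu <- mu * mu
      va <- ex2 - mumu
      if (va < 0) va <- 0
      sg <- sqrt(va)
      pe <- p * exp(-q * mu)
      kk <- k * (sg / r - 1.0)
      out[i + 1L, j + 1L] <- mu * (1.0 + pe + kk)
    }
  }
  out
}

# 8-connected components by recursive-style flood fill over an explicit
# queue, scanning in row-major order (label identity is not compared, only
# the partition).
floodFillComponents <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  nxt <- 0L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii < 1 || ii > n || jj < 1 || jj > m) next
        if (mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Component size multiset from a label matrix.
componentSizes <- function(lab) {
  if (max(lab) == 0L) return(integer())
  sort(as.integer(tabulate(lab[lab > 0L])))
}

# Brute-force Youden scan over explicit candidate thresholds.
bruteForceYouden <- function(ct, lcv) {
  s <- sort(unique(ct))
  cand <- (head(s, -1) + tail(s, -1)) / 2
  best <- NULL
  for (t in cand) {
    sens <- mean(ct[lcv] <= t)
    spec <- mean(ct[!lcv] > t)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12)
      best <- list(threshold = t, J = J, sens = sens, spec = spec)
  }
  best
}

# A small fast scene configuration shared across imaging tests.
smallConfig <- function(seed = 1, nIamd = 2, nControl = 2, ...) {
  SimulationConfig(seed = seed, nIamd = nIamd, nControl = nControl,
                   imageSizePx = 128, ...)
}
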