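## Independent brute-force oracles used to cross-check the implementation.
## These deliberately share no code with the package internals.

## Direct double-loop correlation with replicate borders.
brute_correlate <- function(m, w) {
  k <- (nrow(w) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (u in -k:k) for (v in -k:k) {
      ii <- min(max(i + u, 1L), H)
      jj <- min(max(j + v, 1L), W)
      s <- s + w[u + k + 1L, v + k + 1L] * m[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

## Unweighted three-parameter circular Hough: scans every (x0, y0, r)
## triple, counting edge points whose rounded distance matches a radius.
## Returns the argmax center (ties: smallest row, then col).
brute_hough_argmax <- function(edges, radii, H, W) {
  rset <- round(radii)
  acc <- matrix(0, H, W)
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    d <- round(sqrt((edges$row - r0)^2 + (edges$col - c0)^2))
    acc[r0, c0] <- sum(d %in% rset)
  }
  mx <- max(acc)
  idx <- which(acc == mx)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  o <- order(rows, cols)[1L]
  c(rows[o], cols[o])
}

## Scalar bilinear interpolation (0 outside the image).
brute_bilinear <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  if (r < 1 || r > H || c < 1 || c > W) return(0)
  r0 <- min(max(floor(r), 1), H - 1)
  c0 <- min(max(floor(c), 1), W - 1)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * m[r0, c0] + fr * (1 - fc) * m[r0 + 1, c0] +
    (1 - fr) * fc * m[r0, c0 + 1] + fr * fc * m[r0 + 1, c0 + 1]
}

## Naive exhaustive (a, b) scan: loops over every candidate pair and every
## boundary sample. Same scoring definition as the package, independent code.
brute_ellipse_scan <- function(mag, center, radii, K = NULL) {
  if (is.null(K)) K <- max(64L, ceiling(2 * pi * max(radii)))
  th <- seq(0, 2 * pi, length.out = K + 1L)[-(K + 1L)]
  best <- NULL
  for (a in radii) for (b in radii) {
    s <- mean(vapply(th, function(t)
      brute_bilinear(mag, center[1] + b * sin(t), center[2] + a * cos(t)), 0))
    better <- is.null(best) || s > best$score + 1e-9 ||
      (abs(s - best$score) <= 1e-9 &&
         (a + b < best$a + best$b - 1e-12 ||
          (abs(a + b - (best$a + best$b)) <= 1e-12 && a < best$a)))
    if (better) best <- list(a = a, b = b, score = s)
  }
  best
}

## Brute-force score of one (a, b) candidate at an arbitrary center.
brute_ellipse_score <- function(mag, center, a, b, K) {
  th <- seq(0, 2 * pi, length.out = K + 1L)[-(K + 1L)]
  mean(vapply(th, function(t)
    brute_bilinear(mag, center[1] + b * sin(t), center[2] + a * cos(t)), 0))
}
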