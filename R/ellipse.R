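## Bilinear sampling of matrix m at fractional (row, col) positions.
## Positions outside the image contribute 0.
.bilinear <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  out <- numeric(length(r))
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  if (any(ok)) {
    rr <- r[ok]; cc <- c[ok]
    r0 <- pmin(pmax(floor(rr), 1), H - 1L)
    c0 <- pmin(pmax(floor(cc), 1), W - 1L)
    fr <- rr - r0
    fc <- cc - c0
    i00 <- r0 + (c0 - 1) * H
    out[ok] <- (1 - fr) * (1 - fc) * m[i00] +
               fr       * (1 - fc) * m[i00 + 1] +
               (1 - fr) * fc       * m[i00 + H] +
               fr       * fc       * m[i00 + H + 1]
  }
  if (is.matrix(r)) dim(out) <- dim(r)
  out
}

#' Fit axis-aligned ellipse semi-axes around a known center
#'
#' Measures object size by scoring every semi-axis pair `(a, b)` on the
#' discretized `rr x rr` grid: the score of a candidate is the mean gradient
#' magnitude, sampled bilinearly, at `K` equally spaced points of the
#' boundary `x = x0 + a cos(theta)`, `y = y0 + b sin(theta)`, with
#' `K = max(64, ceiling(2*pi*r_max))` (at least one sample per boundary
#' pixel). Gradients are restricted to the square window of side `2*r_max`
#' centered on the center (every candidate boundary lies inside it). The
#' best-scoring pair is returned; ties are broken by smaller `a + b`, then
#' smaller `a`. The center is held fixed from the Hough stage; no rotation
#' term is searched.
#'
#' @param field a [compute_gradients()] result.
#' @param center a [find_center()] estimate, or a `c(row, col)` vector.
#' @param rr a [radius_range()] for both semi-axes.
#' @return An object of class `ellipse_fit` with fields `center`, `a`
#'   (semi-axis along columns), `b` (semi-axis along rows) and `score`
#'   (mean boundary gradient magnitude), or `NULL` (no-fit signal) when the
#'   window holds no gradient energy.
#' @export
fit_ellipse_axes <- function(field, center, rr) {
  stopifnot(inherits(field, "gradient_field"), inherits(rr, "radius_range"))
  if (inherits(center, "center_estimate")) center <- center$center
  r0 <- center[[1]]; c0 <- center[[2]]
  H <- field$dim[1]; W <- field$dim[2]
  if (r0 < 1 || r0 > H || c0 < 1 || c0 > W)
    stop("invalid configuration: center outside image", call. = FALSE)
  half <- rr$r_max
  wr <- max(1, ceiling(r0 - half)):min(H, floor(r0 + half))
  wc <- max(1, ceiling(c0 - half)):min(W, floor(c0 + half))
  if (max(field$magnitude[wr, wc]) <= 0) return(NULL)
  mag <- field$magnitude

  K <- max(64L, ceiling(2 * pi * rr$r_max))
  th <- seq(0, 2 * pi, length.out = K + 1L)[-(K + 1L)]
  ct <- cos(th); st <- sin(th)
  ab <- rr$radii
  n <- length(ab)
  scores <- matrix(0, n, n)              # rows: a, cols: b
  ymat <- r0 + outer(st, ab)             # K x n, reused for every a
  for (ai in seq_len(n)) {
    xs <- c0 + ab[ai] * ct
    scores[ai, ] <- colMeans(.bilinear(mag, ymat, matrix(xs, K, n)))
  }
  mx <- max(scores)
  if (mx <= 0) return(NULL)
  cand <- which(scores == mx)
  ai <- (cand - 1L) %% n + 1L
  bi <- (cand - 1L) %/% n + 1L
  pick <- order(ab[ai] + ab[bi], ab[ai])[1L]
  structure(list(center = c(row = r0, col = c0),
                 a = ab[ai[pick]], b = ab[bi[pick]], score = mx),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit center (%.6g, %.6g), a = %.6g px, b = %.6g px, score %.4g>\n",
              x$center[1], x$center[2], x$a, x$b, x$score))
  invisible(x)
}

#' Equivalent circular diameter of an ellipse
#'
#' The diameter of the circle with the same area as the ellipse:
#' `2 * sqrt(a * b)`. Used as the single "diameter" figure in reports.
#'
#' @param e an [fit_ellipse_axes()] result (or any list with `a` and `b`).
#' @return Diameter in pixels.
#' @export
equivalent_diameter <- function(e) {
  2 * sqrt(e$a * e$b)
}
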