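## ---- internal raster helpers ------------------------------------------------

## Replicate-pad a matrix by k pixels on every side. Border replication is the
## package-wide policy for smoothing and gradients: it avoids the spurious
## frame edges that zero-padding would feed into the Hough vote.
.pad_replicate <- function(m, k) {
  if (k == 0L) return(m)
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

## Direct spatial-domain correlation of a matrix with a small odd-sized mask,
## replicate borders. out(x,y) = sum_u sum_v w(u,v) * f(x+u, y+v).
.correlate <- function(m, w) {
  kh <- (nrow(w) - 1L) %/% 2L
  kw <- (ncol(w) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  p <- .pad_replicate(m, max(kh, kw))
  off <- max(kh, kw)
  out <- matrix(0, H, W)
  for (du in seq_len(nrow(w))) {
    for (dv in seq_len(ncol(w))) {
      wt <- w[du, dv]
      if (wt != 0) {
        r0 <- off - kh + du
        c0 <- off - kw + dv
        out <- out + wt * p[r0:(r0 + H - 1L), c0:(c0 + W - 1L), drop = FALSE]
      }
    }
  }
  out
}

.gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Separable Gaussian blur, replicate borders.
.blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- .gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  p <- .pad_replicate(m, r)
  tmp <- matrix(0, H, W + 2L * r)
  for (i in seq_along(k)) tmp <- tmp + k[i] * p[i:(i + H - 1L), , drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_along(k)) out <- out + k[j] * tmp[, j:(j + W - 1L), drop = FALSE]
  out
}

## Evaluate an expression with a temporary RNG seed, restoring the caller's
## RNG state afterwards so library code never perturbs user simulations.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- image containers -------------------------------------------------------

#' RGB image container
#'
#' Wraps an `H x W x 3` numeric array of channel intensities in
#' `[0, 2^bit_depth - 1]`. Pixels are addressed as `(row, col)`, 1-based,
#' with `(1, 1)` at the top-left; `x` means column and `y` means row
#' throughout the package.
#'
#' @param pixels numeric `H x W x 3` array (a plain `H x W` matrix is
#'   replicated across the three channels).
#' @param bit_depth integer number of bits per channel (default 8).
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, bit_depth = 8L) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("invalid image: pixels must be an H x W x 3 array", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 3L || d[2] < 3L)
    stop("invalid image: need at least 3 x 3 pixels", call. = FALSE)
  hi <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > hi)
    stop(sprintf("invalid image: channel values must lie in [0, %d]", hi),
         call. = FALSE)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth)),
            class = "rgb_image")
}

#' Grayscale image container
#'
#' Holds an `H x W` intensity matrix together with its bit depth and the
#' observed minimum/maximum intensity (`graymin`, `graymax`), which are
#' recomputed by every transform that changes the pixels.
#'
#' @param pixels numeric `H x W` matrix.
#' @param bit_depth integer number of bits (default 8).
#' @return An object of class `gray_image` with fields `pixels`,
#'   `bit_depth`, `graymin`, `graymax`.
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("invalid image: pixels must be a matrix of at least 3 x 3", call. = FALSE)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 graymin = min(pixels), graymax = max(pixels)),
            class = "gray_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %d x %d, %d-bit>\n", d[1], d[2], x$bit_depth))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit, range [%.6g, %.6g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$graymin, x$graymax))
  invisible(x)
}

#' Read a micrograph from disk
#'
#' Reads an 8-bit JPEG, PNG or TIFF image (1 or 3 channels; an alpha channel
#' is dropped) and returns an [rgb_image()]. Grayscale files are replicated
#' across the three channels.
#'
#' @param path file path; format is chosen by extension.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (length(dim(raw)) == 3L && dim(raw)[3] == 2L) raw <- raw[, , 1L]  # gray+alpha
  if (length(dim(raw)) == 3L && dim(raw)[3] == 1L) raw <- raw[, , 1L]
  rgb_image(round(raw * 255), bit_depth = 8L)
}

#' Write an image as PNG
#'
#' @param img an [rgb_image()], [gray_image()], or a numeric matrix/array of
#'   intensities in `[0, 2^bit_depth - 1]`.
#' @param path output path.
#' @param bit_depth bit depth used to scale raw matrices/arrays (default 8).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path, bit_depth = 8L) {
  if (inherits(img, "rgb_image")) { px <- img$pixels; bit_depth <- img$bit_depth }
  else if (inherits(img, "gray_image")) { px <- img$pixels; bit_depth <- img$bit_depth }
  else px <- img
  hi <- 2^bit_depth - 1
  px <- pmin(pmax(px / hi, 0), 1)
  png::writePNG(px, target = path)
  invisible(path)
}

## ---- preprocessing operations ----------------------------------------------

#' Convert an RGB image to grayscale
#'
#' Each output intensity is the mean of the three channels,
#' `(R + G + B) / 3`, rounded to the nearest integer (ties to even). The bit
#' depth is preserved and the observed intensity range is recorded.
#'
#' @param img an [rgb_image()].
#' @return A [gray_image()].
#' @export
to_grayscale <- function(img) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  g <- round((img$pixels[, , 1L] + img$pixels[, , 2L] + img$pixels[, , 3L]) / 3)
  gray_image(g, bit_depth = img$bit_depth)
}

#' Linear contrast enhancement
#'
#' Stretches the dynamic range to the full bit depth: the enhancement factor
#' is `E_f = (2^n - 1) / (graymax - graymin)` and each output pixel is
#' `round((g - graymin) * E_f)`, so the output spans exactly
#' `[0, 2^n - 1]`. A constant image cannot be stretched; it is returned
#' unchanged with a warning.
#'
#' @param img a [gray_image()].
#' @return A [gray_image()] spanning the full dynamic range.
#' @export
contrast_enhance <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  if (img$graymax == img$graymin) {
    warning("constant image: contrast enhancement is undefined; returning unchanged")
    return(img)
  }
  ef <- (2^img$bit_depth - 1) / (img$graymax - img$graymin)
  gray_image(round((img$pixels - img$graymin) * ef), bit_depth = img$bit_depth)
}

#' Weighted-average filter mask
#'
#' Builds a normalized weighted-average smoothing mask. Given a single
#' number 3 or 5, returns the binomial mask of that size: the 3x3 mask
#' `[1 2 1; 2 4 2; 1 2 1] / 16`, or its natural 5x5 extension, the outer
#' product of `[1 4 6 4 1]` normalized by 256. Given a matrix of
#' non-negative weights, normalizes it by its sum. The center coefficient
#' must be the (weakly) largest — the weighted-average property.
#'
#' @param x mask size (3 or 5) or an odd-sized square matrix of raw weights.
#' @return An object of class `filter_mask` with fields `coefficients`
#'   (summing to 1) and `normalizer` (the raw weight sum).
#' @export
filter_mask <- function(x = 5L) {
  if (length(x) == 1L && is.numeric(x)) {
    size <- as.integer(x)
    if (!size %in% c(3L, 5L))
      stop("invalid configuration: built-in binomial masks are 3x3 or 5x5", call. = FALSE)
    v <- choose(size - 1L, 0:(size - 1L))
    x <- outer(v, v)
  }
  if (!is.matrix(x) || nrow(x) != ncol(x) || nrow(x) %% 2L == 0L)
    stop("invalid configuration: mask must be an odd-sized square matrix", call. = FALSE)
  if (any(x < 0)) stop("invalid configuration: mask weights must be non-negative", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("invalid configuration: mask weights sum to zero", call. = FALSE)
  k <- (nrow(x) + 1L) %/% 2L
  if (x[k, k] < max(x))
    stop("invalid configuration: center coefficient must be the maximum", call. = FALSE)
  structure(list(coefficients = x / s, normalizer = s), class = "filter_mask")
}

#' Weighted-average spatial smoothing
#'
#' Two-dimensional correlation filtering of the image with a normalized
#' weighted-average mask: `g(x,y) = sum_u sum_v w(u,v) f(x+u, y+v)`.
#' Borders are handled by edge replication. The output is kept in floating
#' point (quantization happens only when an image is written out), and its
#' range cannot exceed the input range because the mask is a convex
#' combination.
#'
#' @param img a [gray_image()].
#' @param mask a [filter_mask()]; default the 5x5 binomial mask.
#' @return A smoothed [gray_image()].
#' @export
weighted_smooth <- function(img, mask = filter_mask(5L)) {
  stopifnot(inherits(img, "gray_image"), inherits(mask, "filter_mask"))
  if (nrow(mask$coefficients) > nrow(img$pixels) ||
      ncol(mask$coefficients) > ncol(img$pixels))
    stop("invalid configuration: mask larger than image", call. = FALSE)
  gray_image(.correlate(img$pixels, mask$coefficients), bit_depth = img$bit_depth)
}
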