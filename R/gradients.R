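## Sobel kernels. x is the column direction (rightward), y the row direction
## (downward); Gx(x,y) = sum_u,v wx(u,v) f(row+u, col+v).
.sobel_x <- matrix(c(-1, 0, 1,
                     -2, 0, 2,
                     -1, 0, 1), nrow = 3, byrow = TRUE)
.sobel_y <- t(.sobel_x)

#' Per-pixel image gradients
#'
#' Computes the gradient vector field of a (smoothed) grayscale image with
#' the 3x3 Sobel operator, replicate borders. The magnitude is
#' `sqrt(Gx^2 + Gy^2)` and the orientation is `atan2(Gy, Gx)` in radians, so
#' that `cos(theta) = Gx / |grad|` and `sin(theta) = Gy / |grad|` wherever
#' the magnitude is positive.
#'
#' @param img a [gray_image()] or numeric matrix, at least 3x3.
#' @return An object of class `gradient_field` with fields `gx`, `gy`,
#'   `magnitude`, `orientation` (all `H x W` matrices) and `dim`.
#' @export
compute_gradients <- function(img) {
  m <- if (inherits(img, "gray_image")) img$pixels else img
  if (!is.matrix(m) || nrow(m) < 3L || ncol(m) < 3L)
    stop("invalid image: gradients need at least 3 x 3 pixels", call. = FALSE)
  gx <- .correlate(m, .sobel_x)
  gy <- .correlate(m, .sobel_y)
  mag <- sqrt(gx^2 + gy^2)
  structure(list(gx = gx, gy = gy, magnitude = mag,
                 orientation = atan2(gy, gx), dim = dim(m)),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field %d x %d, max |grad| = %.4g>\n",
              x$dim[1], x$dim[2], max(x$magnitude)))
  invisible(x)
}

#' Extract edge points above a gradient-magnitude threshold
#'
#' Returns exactly the pixels whose gradient magnitude is at least
#' `gmag_threshold`. An empty result is legal.
#'
#' @param field a [compute_gradients()] result.
#' @param gmag_threshold non-negative magnitude threshold.
#' @return An object of class `edge_points`: a data frame with columns
#'   `row`, `col`, `magnitude`, `orientation`, plus attributes
#'   `threshold_used` and `dim` (the source image size).
#' @export
threshold_edges <- function(field, gmag_threshold) {
  stopifnot(inherits(field, "gradient_field"), gmag_threshold >= 0)
  idx <- which(field$magnitude >= gmag_threshold)
  H <- field$dim[1]
  pts <- data.frame(row = (idx - 1L) %% H + 1L,
                    col = (idx - 1L) %/% H + 1L,
                    magnitude = field$magnitude[idx],
                    orientation = field$orientation[idx])
  structure(pts, threshold_used = gmag_threshold, image_dim = field$dim,
            class = c("edge_points", "data.frame"))
}

#' Automatic gradient-magnitude threshold
#'
#' Chooses the magnitude threshold such that at most `keep_fraction` of the
#' pixels with nonzero magnitude survive [threshold_edges()]. This bounds the
#' number of edge points the Hough stage must process. With ties, the
#' threshold is raised to the next distinct magnitude so the "at most"
#' guarantee holds (unless the tied value is already the maximum, in which
#' case the tie is kept).
#'
#' @param field a [compute_gradients()] result.
#' @param keep_fraction fraction in (0, 1] of nonzero-magnitude pixels to
#'   keep (default 0.10).
#' @return The threshold (scalar); 0 with a warning for an all-zero field.
#' @export
auto_threshold <- function(field, keep_fraction = 0.10) {
  stopifnot(inherits(field, "gradient_field"),
            keep_fraction > 0, keep_fraction <= 1)
  nz <- field$magnitude[field$magnitude > 0]
  if (length(nz) == 0L) {
    warning("all-zero gradient field: threshold is 0")
    return(0)
  }
  k <- max(1L, floor(keep_fraction * length(nz)))
  s <- sort(nz, decreasing = TRUE)
  thr <- s[k]
  if (sum(nz >= thr) > k) {
    larger <- s[s > thr]
    thr <- if (length(larger)) min(larger) else thr
  }
  thr
}
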