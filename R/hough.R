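#' Radius search range
#'
#' Discretized radius interval searched by the Hough vote and the ellipse
#' fit. By default radii are stepped at 1 px:
#' `n_steps = floor(r_max - r_min) + 1`.
#'
#' @param r_min,r_max radius bounds in pixels, `0 < r_min <= r_max`.
#' @param n_steps number of radius steps (default 1-px spacing).
#' @return An object of class `radius_range` with fields `r_min`, `r_max`,
#'   `n_steps` and the discretized `radii`.
#' @export
radius_range <- function(r_min, r_max, n_steps = NULL) {
  if (!(r_min > 0 && r_min <= r_max))
    stop("invalid configuration: need 0 < r_min <= r_max", call. = FALSE)
  if (is.null(n_steps)) n_steps <- as.integer(floor(r_max - r_min)) + 1L
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("invalid configuration: n_steps must be >= 1", call. = FALSE)
  radii <- if (n_steps == 1L) (r_min + r_max) / 2 else
    seq(r_min, r_max, length.out = n_steps)
  structure(list(r_min = r_min, r_max = r_max, n_steps = n_steps, radii = radii),
            class = "radius_range")
}

#' @export
print.radius_range <- function(x, ...) {
  cat(sprintf("<radius_range [%.6g, %.6g] px, %d steps>\n",
              x$r_min, x$r_max, x$n_steps))
  invisible(x)
}

#' Gradient-weighted circular Hough vote
#'
#' Each edge point casts, for every discretized radius `r`, two votes along
#' its gradient line at `(x - r cos(theta), y - r sin(theta))` and
#' `(x + r cos(theta), y + r sin(theta))`, each weighted by the point's
#' gradient magnitude. Both polarities are used so detection does not depend
#' on whether the object is brighter or darker than the background. Votes
#' are cast to the nearest accumulator cell; votes falling outside the image
#' are discarded. The accumulator is 2-D over centers (radius marginalized);
#' sizing is done afterwards by [fit_ellipse_axes()].
#'
#' @param edges a [threshold_edges()] result.
#' @param rr a [radius_range()].
#' @param image_shape `c(H, W)`; defaults to the edge set's source size.
#' @return An object of class `hough_accumulator` with fields `votes`
#'   (`H x W`), `radius_range`, `total_weight`, and reference statistics
#'   `n_edges`, `max_edge_mag` used by [find_center()]'s confidence.
#' @export
vote_circular <- function(edges, rr, image_shape = attr(edges, "image_dim")) {
  stopifnot(inherits(edges, "edge_points"), inherits(rr, "radius_range"))
  H <- as.integer(image_shape[1]); W <- as.integer(image_shape[2])
  acc <- matrix(0, H, W)
  if (nrow(edges) == 0L) {
    warning("empty edge set: accumulator is empty")
    return(structure(list(votes = acc, radius_range = rr, total_weight = 0,
                          n_edges = 0L, max_edge_mag = 0),
                     class = "hough_accumulator"))
  }
  x <- edges$col; y <- edges$row
  ct <- cos(edges$orientation); st <- sin(edges$orientation)
  w <- edges$magnitude
  for (r in rr$radii) {
    for (s in c(1, -1)) {
      cc <- round(x - s * r * ct)
      rr0 <- round(y - s * r * st)
      keep <- cc >= 1 & cc <= W & rr0 >= 1 & rr0 <= H
      if (!any(keep)) next
      idx <- rr0[keep] + (cc[keep] - 1) * H
      agg <- rowsum(w[keep], idx)
      at <- as.numeric(rownames(agg))
      acc[at] <- acc[at] + agg[, 1L]
    }
  }
  structure(list(votes = acc, radius_range = rr, total_weight = sum(acc),
                 n_edges = nrow(edges), max_edge_mag = max(w)),
            class = "hough_accumulator")
}

#' @export
print.hough_accumulator <- function(x, ...) {
  cat(sprintf("<hough_accumulator %d x %d, total weight %.4g, %d edge points>\n",
              nrow(x$votes), ncol(x$votes), x$total_weight, x$n_edges))
  invisible(x)
}

## Shared peak search. exclusion: logical matrix, TRUE = cell may not win.
.peak_search <- function(acc, exclusion = NULL) {
  votes <- acc$votes
  H <- nrow(votes); W <- ncol(votes)
  if (acc$total_weight <= 0) return(NULL)
  sm <- .correlate(votes, filter_mask(3L)$coefficients)
  ok <- if (is.null(exclusion)) rep(TRUE, length(sm)) else !as.vector(exclusion)
  if (!any(ok)) return(NULL)
  vals <- as.vector(sm)
  mx <- max(vals[ok])
  if (mx <= 0) return(NULL)
  idx <- which(ok & vals == mx)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  o <- order(rows, cols)[1L]     # ties: smallest row, then smallest col
  pr <- rows[o]; pc <- cols[o]
  ## raw vote mass around the peak. An edge point whose orientation is off
  ## by a small angle e misses the center by ~ r*e, so the coherent cluster
  ## widens in proportion to the radius: the neighborhood half-width scales
  ## as r_min/32 (at least +-1 px for the discretization spread).
  h <- max(1L, as.integer(round(acc$radius_range$r_min / 32)))
  nb <- votes[max(1L, pr - h):min(H, pr + h),
              max(1L, pc - h):min(W, pc + h), drop = FALSE]
  peak_vote <- sum(nb)
  denom <- ceiling(2 * pi * acc$radius_range$r_min) * acc$max_edge_mag
  conf <- if (denom > 0) peak_vote / denom else 0
  structure(list(center = c(row = pr, col = pc), peak_vote = peak_vote,
                 confidence = conf),
            class = "center_estimate")
}

#' Locate the accumulator peak
#'
#' Smooths the accumulator with the 3x3 binomial mask (to gather the
#' "maximum region" split across neighboring cells by discretization) and
#' returns the argmax cell; ties are broken by smallest row, then smallest
#' column. The confidence is the raw vote mass around the peak (neighborhood
#' half-width `max(1, r_min/32)` pixels — orientation noise smears a
#' coherent circle's votes in proportion to its radius) divided by the
#' theoretical maximum vote of a full circle at `r_min`: `ceiling(2*pi*r_min)`
#' boundary pixels all voting with the strongest observed edge magnitude
#' into one cell. Confidence is invariant to rescaling the gradient
#' magnitudes; a coherent circle in the radius range scores several units,
#' while diffuse vote background stays near or below one.
#'
#' @param acc a [vote_circular()] accumulator.
#' @return An object of class `center_estimate` (fields `center`
#'   = `c(row, col)`, `peak_vote`, `confidence`), or `NULL` when the
#'   accumulator holds no votes (no-detection signal).
#' @export
find_center <- function(acc) {
  stopifnot(inherits(acc, "hough_accumulator"))
  .peak_search(acc, NULL)
}

#' Locate the accumulator peak outside an exclusion mask
#'
#' Same as [find_center()] but the argmax is taken over unmasked cells only.
#' Used to restrict the polar-body search to the perivitelline annulus.
#'
#' @param acc a [vote_circular()] accumulator.
#' @param exclusion_mask logical `H x W` matrix, `TRUE` for cells that may
#'   not be returned.
#' @return A `center_estimate`, or `NULL` when every cell is masked or the
#'   accumulator is empty.
#' @export
find_center_excluding <- function(acc, exclusion_mask) {
  stopifnot(inherits(acc, "hough_accumulator"))
  if (!is.null(exclusion_mask) &&
      !identical(dim(exclusion_mask), dim(acc$votes)))
    stop("invalid configuration: exclusion mask shape mismatch", call. = FALSE)
  .peak_search(acc, exclusion_mask)
}

#' @export
print.center_estimate <- function(x, ...) {
  cat(sprintf("<center_estimate (row %d, col %d), confidence %.3f>\n",
              x$center[1], x$center[2], x$confidence))
  invisible(x)
}
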