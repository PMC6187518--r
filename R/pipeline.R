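#' Detector configuration
#'
#' Tunable parameters of the detection pipeline.
#'
#' @param mask_size smoothing mask size, 3 or 5 (default 5; the binomial
#'   weighted-average mask of that size).
#' @param keep_fraction fraction of nonzero-magnitude pixels kept as edge
#'   points by the automatic gradient threshold (default 0.10).
#' @param gmag_threshold explicit gradient-magnitude threshold; overrides
#'   `keep_fraction` when non-`NULL`.
#' @param max_edge_points hard cap on the number of edge points fed to the
#'   Hough vote (strongest magnitudes kept; default 20000). Bounds the vote
#'   cost on large images.
#' @param min_confidence minimum [find_center()] confidence for declaring a
#'   detection (default 2: at least two ideal-circle vote masses). Coherent
#'   circles in the radius range score several units while the diffuse vote
#'   "echoes" cast by boundaries at other radii stay near or below one;
#'   this gate drives the "polar body not located" branch.
#' @param pb_annulus_inner inner radius of the polar-body search annulus as
#'   a fraction of the oocyte semi-axis (default 0.8).
#' @param pb_annulus_margin outer margin beyond the oocyte semi-axis in
#'   multiples of the polar-body `r_max` (default 3).
#' @param rim_shell_px half-width in pixels of the shell around the detected
#'   oocyte boundary whose edge points are withheld from the polar-body vote
#'   (default 12; covers the smoothed rim's gradient ridge plus the center
#'   localization uncertainty).
#' @return An object of class `oodetect_config`.
#' @export
oodetect_config <- function(mask_size = 5L, keep_fraction = 0.10,
                            gmag_threshold = NULL, max_edge_points = 20000L,
                            min_confidence = 2, pb_annulus_inner = 0.8,
                            pb_annulus_margin = 3, rim_shell_px = 12) {
  stopifnot(mask_size %in% c(3L, 5L), keep_fraction > 0, keep_fraction <= 1,
            max_edge_points >= 1, min_confidence >= 0,
            pb_annulus_inner > 0, pb_annulus_margin >= 0, rim_shell_px >= 0)
  structure(list(mask_size = as.integer(mask_size),
                 keep_fraction = keep_fraction,
                 gmag_threshold = gmag_threshold,
                 max_edge_points = as.integer(max_edge_points),
                 min_confidence = min_confidence,
                 pb_annulus_inner = pb_annulus_inner,
                 pb_annulus_margin = pb_annulus_margin,
                 rim_shell_px = rim_shell_px),
            class = "oodetect_config")
}

## Shared front half of the pipeline: grayscale -> contrast stretch ->
## weighted smoothing -> gradients -> thresholded edge points.
.preprocess <- function(img, cfg) {
  if (is.character(img)) img <- read_image(img)
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  g <- to_grayscale(img)
  g <- contrast_enhance(g)
  g <- weighted_smooth(g, filter_mask(cfg$mask_size))
  field <- compute_gradients(g)
  thr <- if (is.null(cfg$gmag_threshold)) {
    suppressWarnings(auto_threshold(field, cfg$keep_fraction))
  } else cfg$gmag_threshold
  edges <- threshold_edges(field, thr)
  if (nrow(edges) > cfg$max_edge_points) {
    keep <- order(edges$magnitude, decreasing = TRUE)[seq_len(cfg$max_edge_points)]
    edges <- edges[sort(keep), , drop = FALSE]
    attr(edges, "image_dim") <- field$dim
    class(edges) <- c("edge_points", "data.frame")
  }
  list(image = img, gray = g, field = field, edges = edges)
}

## Detect one circular-ish object. exclusion restricts the center search;
## boundary_shell = list(center, a, b, margin_px) drops edge points lying on
## an already-detected boundary (its votes would otherwise echo at smaller
## radii on both sides of the rim). Confidence is always referenced to the
## strongest edge in the full image so evidence filtering cannot inflate it.
.detect_object <- function(pre, rr, cfg, exclusion = NULL,
                           boundary_shell = NULL,
                           min_conf = cfg$min_confidence) {
  empty <- structure(list(found = FALSE, center_px = NULL, ellipse = NULL,
                          diameter_px = NA_real_, confidence = 0),
                     class = "oo_detection")
  if (nrow(pre$edges) == 0L) return(empty)
  edges <- pre$edges
  if (!is.null(boundary_shell)) {
    bs <- boundary_shell
    rho <- sqrt(((edges$col - bs$center[[2]]) / bs$a)^2 +
                ((edges$row - bs$center[[1]]) / bs$b)^2)
    keep <- abs(rho - 1) > bs$margin_px / min(bs$a, bs$b)
    edges <- edges[keep, , drop = FALSE]
    attr(edges, "image_dim") <- pre$field$dim
    class(edges) <- c("edge_points", "data.frame")
    if (nrow(edges) == 0L) return(empty)
  }
  acc <- vote_circular(edges, rr, pre$field$dim)
  acc$max_edge_mag <- max(pre$edges$magnitude)
  ce <- find_center_excluding(acc, exclusion)
  if (is.null(ce) || ce$confidence < min_conf) {
    if (!is.null(ce)) empty$confidence <- ce$confidence
    return(empty)
  }
  fit <- fit_ellipse_axes(pre$field, ce, rr)
  if (is.null(fit)) { empty$confidence <- ce$confidence; return(empty) }
  structure(list(found = TRUE, center_px = ce$center, ellipse = fit,
                 diameter_px = equivalent_diameter(fit),
                 confidence = ce$confidence),
            class = "oo_detection")
}

#' @export
print.oo_detection <- function(x, ...) {
  if (!x$found) cat(sprintf("<detection: not found (confidence %.3f)>\n", x$confidence))
  else cat(sprintf("<detection: center (%d, %d), a = %.6g, b = %.6g, diameter %.4g px, confidence %.3f>\n",
                   x$center_px[1], x$center_px[2], x$ellipse$a, x$ellipse$b,
                   x$diameter_px, x$confidence))
  invisible(x)
}

#' Detect the oocyte in a micrograph
#'
#' Runs the full stage chain — grayscale conversion, linear contrast
#' enhancement, weighted-average smoothing, Sobel gradients, edge
#' thresholding, gradient-weighted circular Hough voting, peak extraction
#' and elliptical sizing — for the oocyte radius range. The detection is
#' declared found when the Hough confidence reaches the configured gate.
#'
#' @param img an [rgb_image()], a raw array, or a file path.
#' @param rr_oocyte a [radius_range()] in pixels.
#' @param cfg an [oodetect_config()].
#' @return An `oo_detection`: `found`, `center_px`, `ellipse`,
#'   `diameter_px`, `confidence`.
#' @export
detect_oocyte <- function(img, rr_oocyte, cfg = oodetect_config()) {
  pre <- .preprocess(img, cfg)
  .detect_object(pre, rr_oocyte, cfg)
}

## Exclusion mask: TRUE outside the perivitelline annulus around the oocyte.
.annulus_exclusion <- function(dim, center, inner, outer) {
  d2 <- outer((seq_len(dim[1]) - center[[1]])^2,
              (seq_len(dim[2]) - center[[2]])^2, "+")
  d2 < inner^2 | d2 > outer^2
}

#' Detect the polar body in the perivitelline annulus
#'
#' Repeats the center search with the polar-body radius range, restricted
#' (via [find_center_excluding()]) to an annulus around the detected
#' oocyte spanning `[0.8 * min(a, b), max(a, b) + 3 * r_max_pb]` — the
#' perivitelline space plus a margin for elliptical oocytes. When the vote
#' confidence stays below the gate the polar body is declared not located.
#'
#' @param img image as in [detect_oocyte()].
#' @param rr_pb polar-body [radius_range()] in pixels.
#' @param oocyte a found `oo_detection` for the oocyte.
#' @param cfg an [oodetect_config()].
#' @param pre optional preprocessed stages (internal reuse).
#' @return An `oo_detection`; `found = FALSE` carries the
#'   `"polar body not located"` message attribute.
#' @export
detect_polar_body <- function(img, rr_pb, oocyte, cfg = oodetect_config(),
                              pre = NULL) {
  if (!isTRUE(oocyte$found))
    stop("precondition: oocyte must be detected before the polar body", call. = FALSE)
  if (is.null(pre)) pre <- .preprocess(img, cfg)
  a <- oocyte$ellipse$a; b <- oocyte$ellipse$b
  inner <- cfg$pb_annulus_inner * min(a, b)
  outer_r <- max(a, b) + cfg$pb_annulus_margin * rr_pb$r_max
  excl <- .annulus_exclusion(pre$field$dim, oocyte$center_px, inner, outer_r)
  shell <- list(center = oocyte$center_px, a = a, b = b,
                margin_px = cfg$rim_shell_px)
  det <- .detect_object(pre, rr_pb, cfg, exclusion = excl,
                        boundary_shell = shell)
  if (!det$found) attr(det, "message") <- "polar body not located"
  det
}

#' Bearing of the polar body from the oocyte center
#'
#' Angle of the center-to-center line with respect to the positive x-axis,
#' in degrees in `[0, 360)`. Image rows grow downward, so the row term is
#' negated: angles are counter-clockwise-positive in the usual mathematical
#' sense (a polar body directly above the oocyte is at 90 degrees, directly
#' below at 270).
#'
#' @param oocyte_center,pb_center `c(row, col)` centers in pixels.
#' @return Angle in degrees.
#' @export
orientation_angle <- function(oocyte_center, pb_center) {
  dr <- pb_center[[1]] - oocyte_center[[1]]
  dc <- pb_center[[2]] - oocyte_center[[2]]
  if (dr == 0 && dc == 0)
    stop("undefined angle: identical centers", call. = FALSE)
  (atan2(-dr, dc) * 180 / pi) %% 360
}

## Add calibrated quantities to one detection.
.calibrate_detection <- function(det, center_img, um_per_px) {
  if (det$found) {
    det$a_px <- det$ellipse$a
    det$b_px <- det$ellipse$b
    if (!is.null(um_per_px)) {
      det$diameter_um <- det$diameter_px * um_per_px
      det$center_um_rel <- c(x = (det$center_px[[2]] - center_img[[2]]) * um_per_px,
                             y = -(det$center_px[[1]] - center_img[[1]]) * um_per_px)
    }
  }
  det
}

#' Assemble the positional report
#'
#' Combines the oocyte and polar-body detections into the final report used
#' by downstream manipulation: absolute pixel centers, centers relative to
#' the image center (the microscope's vision-field center, at
#' `((H+1)/2, (W+1)/2)` in 1-based coordinates) in micrometers when
#' calibrated, equivalent diameters, and the polar-body bearing angle. The
#' relative coordinates are `(absolute - image_center) * um_per_px` with the
#' row (y) component negated, matching [orientation_angle()]'s convention.
#'
#' @param oocyte,polar_body `oo_detection` objects ([detect_oocyte()],
#'   [detect_polar_body()]); `polar_body` may be `NULL`.
#' @param image_shape `c(H, W)` in pixels.
#' @param um_per_px optional calibration (micrometers per pixel); when
#'   absent the report is emitted in pixels only.
#' @return An object of class `oodetect_report`.
#' @export
build_report <- function(oocyte, polar_body = NULL, image_shape,
                         um_per_px = NULL) {
  if (!is.null(um_per_px) && um_per_px <= 0)
    stop("invalid configuration: um_per_px must be > 0", call. = FALSE)
  H <- image_shape[[1]]; W <- image_shape[[2]]
  center_img <- c(row = (H + 1) / 2, col = (W + 1) / 2)
  messages <- character()
  oo <- .calibrate_detection(oocyte, center_img, um_per_px)
  if (!oo$found) messages <- c(messages, "oocyte not located")
  pb <- if (is.null(polar_body)) {
    structure(list(found = FALSE, center_px = NULL, ellipse = NULL,
                   diameter_px = NA_real_, confidence = 0),
              class = "oo_detection")
  } else .calibrate_detection(polar_body, center_img, um_per_px)
  if (oo$found && !pb$found) messages <- c(messages, "polar body not located")
  angle <- if (oo$found && pb$found)
    orientation_angle(oo$center_px, pb$center_px) else NULL
  structure(list(oocyte = oo, polar_body = pb, angle_deg = angle,
                 image_center_px = center_img, image_shape = c(H = H, W = W),
                 um_per_px = um_per_px, messages = messages),
            class = "oodetect_report")
}

#' Locate an oocyte and its polar body in one micrograph
#'
#' The main entry point: runs the full detection pipeline and returns the
#' positional report. Radius ranges may be given in micrometers (requiring
#' `um_per_px`) or in pixels.
#'
#' @param image file path (JPEG/PNG/TIFF), [rgb_image()], or raw array.
#' @param oocyte_radius,pb_radius two-element `c(min, max)` radius ranges,
#'   in the units of `units`. Defaults (55–85 µm and 5–15 µm) cover typical
#'   metaphase-II oocytes (~140 µm diameter) and polar bodies (~20 µm).
#' @param units `"um"` (default; requires `um_per_px`) or `"px"`.
#' @param um_per_px micrometers per pixel; optional when `units = "px"`, in
#'   which case the report is in pixels only.
#' @param config an [oodetect_config()].
#' @return An `oodetect_report` with components `oocyte`, `polar_body`,
#'   `angle_deg`, `image_center_px`, `messages` and `runtime_s`. Methods:
#'   `print`, `summary`, `coef`, `plot`, [report_json()],
#'   [write_overlay()].
#' @examples
#' spec <- scene_spec(seed = 7)
#' sc <- render_scene(spec)
#' rep <- oodetect(sc$image, um_per_px = spec$um_per_px)
#' rep
#' coef(rep)
#' @export
oodetect <- function(image, oocyte_radius = c(55, 85), pb_radius = c(5, 15),
                     units = c("um", "px"), um_per_px = NULL,
                     config = oodetect_config()) {
  units <- match.arg(units)
  t0 <- proc.time()[["elapsed"]]
  if (units == "um") {
    if (is.null(um_per_px))
      stop("invalid configuration: radius ranges in um require um_per_px", call. = FALSE)
    oocyte_radius <- oocyte_radius / um_per_px
    pb_radius <- pb_radius / um_per_px
  }
  rr_oo <- radius_range(oocyte_radius[1], oocyte_radius[2])
  rr_pb <- radius_range(pb_radius[1], pb_radius[2])
  pre <- .preprocess(image, config)
  oo <- .detect_object(pre, rr_oo, config)
  pb <- if (oo$found) detect_polar_body(NULL, rr_pb, oo, config, pre = pre) else NULL
  rep <- build_report(oo, pb, pre$field$dim, um_per_px)
  rep$runtime_s <- proc.time()[["elapsed"]] - t0
  rep
}

#' @export
print.oodetect_report <- function(x, ...) {
  cat("Oocyte / polar-body detection report\n")
  fmt_det <- function(lbl, d) {
    if (!d$found) {
      cat(sprintf("  %s: not found (confidence %.3f)\n", lbl, d$confidence))
      return(invisible())
    }
    cat(sprintf("  %s: center (row %s, col %s) px, a = %.5g px, b = %.5g px, diameter %.5g px",
                lbl, format(d$center_px[[1]]), format(d$center_px[[2]]),
                d$ellipse$a, d$ellipse$b, d$diameter_px))
    if (!is.null(d$diameter_um))
      cat(sprintf(" (%.5g um, rel. center x = %.5g, y = %.5g um)",
                  d$diameter_um, d$center_um_rel[["x"]], d$center_um_rel[["y"]]))
    cat(sprintf(", confidence %.3f\n", d$confidence))
  }
  fmt_det("oocyte    ", x$oocyte)
  fmt_det("polar body", x$polar_body)
  if (!is.null(x$angle_deg))
    cat(sprintf("  polar-body bearing: %.2f deg from +x axis (CCW)\n", x$angle_deg))
  for (m in x$messages) cat("  note: ", m, "\n", sep = "")
  invisible(x)
}

#' @export
summary.oodetect_report <- function(object, ...) {
  print(object)
  cat(sprintf("  image: %d x %d px, center (%.1f, %.1f)\n",
              object$image_shape[["H"]], object$image_shape[["W"]],
              object$image_center_px[[1]], object$image_center_px[[2]]))
  if (!is.null(object$um_per_px))
    cat(sprintf("  calibration: %.4g um/px\n", object$um_per_px))
  if (!is.null(object$runtime_s))
    cat(sprintf("  runtime: %.2f s\n", object$runtime_s))
  invisible(object)
}

#' @export
coef.oodetect_report <- function(object, ...) {
  row_of <- function(d) {
    if (!d$found) return(c(row = NA, col = NA, a_px = NA, b_px = NA,
                           diameter_px = NA, confidence = d$confidence))
    c(row = d$center_px[[1]], col = d$center_px[[2]],
      a_px = d$ellipse$a, b_px = d$ellipse$b,
      diameter_px = d$diameter_px, confidence = d$confidence)
  }
  rbind(oocyte = row_of(object$oocyte), polar_body = row_of(object$polar_body))
}

#' Serialize a detection report as JSON
#'
#' @param report an `oodetect_report`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  det_list <- function(d) {
    out <- list(found = d$found)
    if (d$found) {
      out$center_px <- as.numeric(d$center_px)
      out$a_px <- d$ellipse$a
      out$b_px <- d$ellipse$b
      out$diameter_px <- d$diameter_px
      if (!is.null(d$diameter_um)) out$diameter_um <- d$diameter_um
      if (!is.null(d$center_um_rel)) out$center_um_rel <- as.numeric(d$center_um_rel)
    }
    out$confidence <- d$confidence
    out
  }
  x <- list(oocyte = det_list(report$oocyte),
            polar_body = det_list(report$polar_body),
            angle_deg = report$angle_deg,
            image_center_px = as.numeric(report$image_center_px),
            calibration_um_per_px = report$um_per_px,
            runtime_s = report$runtime_s,
            messages = as.list(report$messages))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

## Draw a 1-px polyline into an RGB pixel array (used by the overlay writer).
.draw_points <- function(px, rows, cols, color) {
  H <- dim(px)[1]; W <- dim(px)[2]
  rows <- round(rows); cols <- round(cols)
  ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  idx <- rows[ok] + (cols[ok] - 1) * H
  for (ch in 1:3) px[idx + (ch - 1) * H * W] <- color[ch]
  px
}

.draw_segment <- function(px, p0, p1, color) {
  n <- max(2L, ceiling(max(abs(p1 - p0))) + 1L)
  .draw_points(px, seq(p0[[1]], p1[[1]], length.out = n),
               seq(p0[[2]], p1[[2]], length.out = n), color)
}

.draw_ellipse <- function(px, center, a, b, color) {
  th <- seq(0, 2 * pi, length.out = max(64L, ceiling(4 * pi * max(a, b))))
  .draw_points(px, center[[1]] + b * sin(th), center[[2]] + a * cos(th), color)
}

#' Write an annotated overlay PNG
#'
#' Draws the detected boundaries (blue), the image coordinate axes through
#' the vision-field center (red) and the oocyte-to-polar-body bearing line
#' (green) onto the input image.
#'
#' @param report an `oodetect_report`.
#' @param image the image the report was computed from (path,
#'   [rgb_image()], or array).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(report, image, path) {
  if (is.character(image)) image <- read_image(image)
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  px <- image$pixels
  hi <- 2^image$bit_depth - 1
  H <- dim(px)[1]; W <- dim(px)[2]
  cc <- report$image_center_px
  px <- .draw_segment(px, c(cc[[1]], 1), c(cc[[1]], W), c(hi, 0, 0))
  px <- .draw_segment(px, c(1, cc[[2]]), c(H, cc[[2]]), c(hi, 0, 0))
  for (d in list(report$oocyte, report$polar_body)) {
    if (isTRUE(d$found))
      px <- .draw_ellipse(px, d$center_px, d$ellipse$a, d$ellipse$b, c(0, 0, hi))
  }
  if (isTRUE(report$oocyte$found) && isTRUE(report$polar_body$found))
    px <- .draw_segment(px, report$oocyte$center_px, report$polar_body$center_px,
                        c(0, hi, 0))
  write_image_png(rgb_image(px, image$bit_depth), path)
}

#' Plot a detection report
#'
#' Displays the micrograph with the detected ellipses, vision-field axes
#' and bearing line.
#'
#' @param x an `oodetect_report`.
#' @param image the source image (path, [rgb_image()], or array).
#' @param ... passed to [graphics::plot()].
#' @export
plot.oodetect_report <- function(x, image, ...) {
  if (is.character(image)) image <- read_image(image)
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  px <- image$pixels / (2^image$bit_depth - 1)
  H <- dim(px)[1]; W <- dim(px)[2]
  graphics::plot(NA, xlim = c(1, W), ylim = c(H, 1), asp = 1,
                 xlab = "col", ylab = "row", ...)
  graphics::rasterImage(px, 1, H, W, 1)
  cc <- x$image_center_px
  graphics::abline(h = cc[[1]], v = cc[[2]], col = "red")
  th <- seq(0, 2 * pi, length.out = 361)
  for (d in list(x$oocyte, x$polar_body)) {
    if (isTRUE(d$found))
      graphics::lines(d$center_px[[2]] + d$ellipse$a * cos(th),
                      d$center_px[[1]] + d$ellipse$b * sin(th),
                      col = "blue", lwd = 2)
  }
  if (isTRUE(x$oocyte$found) && isTRUE(x$polar_body$found))
    graphics::segments(x$oocyte$center_px[[2]], x$oocyte$center_px[[1]],
                       x$polar_body$center_px[[2]], x$polar_body$center_px[[1]],
                       col = "green", lwd = 2)
  invisible(x)
}
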