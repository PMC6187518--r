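## Polar radius of an axis-aligned ellipse at math-convention bearing beta
## (degrees, CCW from +x, y up): distance from center to boundary.
.ellipse_radius_at <- function(a, b, bearing_deg) {
  th <- bearing_deg * pi / 180
  1 / sqrt((cos(th) / a)^2 + (sin(th) / b)^2)
}

#' Synthetic ICSI scene specification
#'
#' Describes one ground-truthed micrograph look-alike: a denudated
#' metaphase-II oocyte (ooplasm disc with multiplicative granular texture
#' and a dark rim), its perivitelline gap, the zona pellucida ring, an
#' optional polar body inside the gap, optional cumulus-like clutter blobs
#' near the zona, plus Gaussian blur and additive Gaussian noise. Defaults
#' emulate the nominal geometry: 140-µm oocyte diameter, 20-µm polar body,
#' 0.5 µm/px. The perivitelline gap (24 µm) is wider than in real oocytes
#' so the polar body lies wholly inside it, which the detector's annulus
#' search assumes.
#'
#' @param um_per_px scale, micrometers per pixel (default 0.5).
#' @param background_rgb background color triple in `[0, 255]`.
#' @param oocyte list: `center_um` (x, y offset of the oocyte center from
#'   the image center, µm, y up), semi-axes `a_um`, `b_um`,
#'   `rim_contrast` (intensity drop of the ooplasm below background),
#'   `granularity` (fractional multiplicative texture amplitude).
#' @param polar_body list: `present`, `bearing_deg`, `placement` in
#'   `[0, 1]` (radial position within the free gap), semi-axes `a_um`,
#'   `b_um`.
#' @param blur_sigma Gaussian blur in px (default 1.5).
#' @param noise_sigma additive Gaussian noise, intensity units (default 3).
#' @param clutter list: `n` blobs and `size_um` radius range, placed near
#'   the zona.
#' @param gap_um,zona_um perivitelline gap width and zona thickness, µm.
#' @param zona_contrast,clutter_contrast intensity offsets of the zona ring
#'   (above background) and clutter blobs (below background).
#' @param image_size optional `c(H, W)`; computed from the geometry (with a
#'   12-px margin) when `NULL`.
#' @param seed integer; identical `(spec, seed)` render identical images.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(um_per_px = 0.5,
                       background_rgb = c(185, 180, 172),
                       oocyte = list(),
                       polar_body = list(),
                       blur_sigma = 1.5, noise_sigma = 3,
                       clutter = list(),
                       gap_um = 24, zona_um = 8,
                       zona_contrast = 25, clutter_contrast = 70,
                       image_size = NULL, seed = 1L) {
  oo <- utils::modifyList(list(center_um = c(0, 0), a_um = 70, b_um = 70,
                               rim_contrast = 60, granularity = 0.08), oocyte)
  pb <- utils::modifyList(list(present = TRUE, bearing_deg = 40,
                               placement = 0.5, a_um = 10, b_um = 10),
                          polar_body)
  cl <- utils::modifyList(list(n = 0L, size_um = c(4, 10)), clutter)
  stopifnot(um_per_px > 0, length(background_rgb) == 3,
            all(background_rgb >= 0 & background_rgb <= 255),
            oo$a_um > 0, oo$b_um > 0, gap_um > 0, zona_um >= 0,
            pb$placement >= 0, pb$placement <= 1, cl$n >= 0)
  if (isTRUE(pb$present) && 2 * max(pb$a_um, pb$b_um) > gap_um)
    stop("invalid spec: polar body does not fit inside the perivitelline gap",
         call. = FALSE)
  outer_um <- max(oo$a_um, oo$b_um) + gap_um + zona_um
  margin_px <- 12L
  if (is.null(image_size)) {
    half <- ceiling((outer_um + max(abs(oo$center_um))) / um_per_px) + margin_px
    image_size <- c(2L * half + 1L, 2L * half + 1L)
  }
  spec <- structure(list(image_size = as.integer(image_size),
                         background_rgb = background_rgb, um_per_px = um_per_px,
                         oocyte = oo, polar_body = pb, blur_sigma = blur_sigma,
                         noise_sigma = noise_sigma, clutter = cl,
                         gap_um = gap_um, zona_um = zona_um,
                         zona_contrast = zona_contrast,
                         clutter_contrast = clutter_contrast,
                         seed = as.integer(seed)),
                    class = "scene_spec")
  ## oocyte (including zona) must fit with >= 10 px margin
  ctr <- .scene_centers(spec)$oocyte_px
  half_px <- outer_um / um_per_px
  if (ctr[1] - half_px < 10 || ctr[1] + half_px > image_size[1] - 9 ||
      ctr[2] - half_px < 10 || ctr[2] + half_px > image_size[2] - 9)
    stop("invalid spec: oocyte does not fit in the image with a 10-px margin",
         call. = FALSE)
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec %d x %d px, %.3g um/px, oocyte %g x %g um, pb %s, seed %d>\n",
              x$image_size[1], x$image_size[2], x$um_per_px,
              2 * x$oocyte$a_um, 2 * x$oocyte$b_um,
              if (x$polar_body$present) sprintf("at %g deg", x$polar_body$bearing_deg)
              else "absent", x$seed))
  invisible(x)
}

## Ground-truth centers in pixel coordinates (row, col), 1-based.
.scene_centers <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  upp <- spec$um_per_px
  cimg <- c((H + 1) / 2, (W + 1) / 2)
  oo <- spec$oocyte
  oo_px <- c(cimg[1] - oo$center_um[2] / upp, cimg[2] + oo$center_um[1] / upp)
  pb_px <- NULL
  if (isTRUE(spec$polar_body$present)) {
    pb <- spec$polar_body
    beta <- pb$bearing_deg
    r_inner <- .ellipse_radius_at(oo$a_um, oo$b_um, beta)
    pb_r <- max(pb$a_um, pb$b_um)
    d_um <- r_inner + pb_r + pb$placement * (spec$gap_um - 2 * pb_r)
    pb_px <- c(oo_px[1] - d_um * sin(beta * pi / 180) / upp,
               oo_px[2] + d_um * cos(beta * pi / 180) / upp)
  }
  list(image_center_px = cimg, oocyte_px = oo_px, pb_px = pb_px)
}

## Logical mask of an axis-aligned ellipse (semi-axes in px).
.ellipse_mask <- function(H, W, r0, c0, a, b) {
  dx2 <- ((seq_len(W) - c0) / a)^2
  dy2 <- ((seq_len(H) - r0) / b)^2
  outer(dy2, dx2, "+") <= 1
}

#' Render a synthetic scene
#'
#' Renders the scene described by a [scene_spec()] and returns both the
#' 8-bit RGB image and the exact ground truth. Structures are drawn as flat
#' regions (zona ring above background, ooplasm and polar body below it by
#' the rim contrast, band-limited multiplicative granularity inside the
#' ooplasm), then Gaussian-blurred and corrupted with additive Gaussian
#' noise. All randomness is driven by `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return A list with `image` (an [rgb_image()]) and `truth` (image size,
#'   scale, per-object centers in px, semi-axes in px and µm, equivalent
#'   diameters in µm, polar-body presence and bearing).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  upp <- spec$um_per_px
  ctr <- .scene_centers(spec)
  oo <- spec$oocyte
  a_px <- oo$a_um / upp; b_px <- oo$b_um / upp
  gap_px <- spec$gap_um / upp; zona_px <- spec$zona_um / upp
  r0 <- ctr$oocyte_px[1]; c0 <- ctr$oocyte_px[2]

  .with_seed(spec$seed, {
    delta <- matrix(0, H, W)                       # offset from background
    zona_out <- .ellipse_mask(H, W, r0, c0, a_px + gap_px + zona_px,
                              b_px + gap_px + zona_px)
    zona_in <- .ellipse_mask(H, W, r0, c0, a_px + gap_px, b_px + gap_px)
    delta[zona_out & !zona_in] <- spec$zona_contrast
    oomask <- .ellipse_mask(H, W, r0, c0, a_px, b_px)
    delta[oomask] <- -oo$rim_contrast
    if (isTRUE(spec$polar_body$present)) {
      pbm <- .ellipse_mask(H, W, ctr$pb_px[1], ctr$pb_px[2],
                           spec$polar_body$a_um / upp, spec$polar_body$b_um / upp)
      delta[pbm] <- -oo$rim_contrast
    }
    if (spec$clutter$n > 0) {
      zr <- (max(a_px, b_px) + gap_px + zona_px)
      for (i in seq_len(spec$clutter$n)) {
        beta <- stats::runif(1, 0, 360)
        rad <- zr + stats::runif(1, -2, 12) / upp
        sz <- stats::runif(1, spec$clutter$size_um[1], spec$clutter$size_um[2]) / upp
        blob <- .ellipse_mask(H, W, r0 - rad * sin(beta * pi / 180),
                              c0 + rad * cos(beta * pi / 180), sz, sz)
        delta[blob] <- -spec$clutter_contrast
      }
    }
    texture <- matrix(1, H, W)
    if (oo$granularity > 0) {
      wn <- .blur_gaussian(matrix(stats::rnorm(H * W), H, W), 2)
      texture[oomask] <- 1 + oo$granularity * (wn[oomask] / stats::sd(wn))
    }
    px <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) {
      m <- (spec$background_rgb[ch] + delta) * texture
      m <- .blur_gaussian(m, spec$blur_sigma)
      if (spec$noise_sigma > 0)
        m <- m + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
      px[, , ch] <- pmin(pmax(round(m), 0), 255)
    }
    truth <- list(
      image_size = c(H, W), um_per_px = upp,
      image_center_px = ctr$image_center_px,
      oocyte = list(center_px = ctr$oocyte_px, a_px = a_px, b_px = b_px,
                    a_um = oo$a_um, b_um = oo$b_um,
                    diameter_um = 2 * sqrt(oo$a_um * oo$b_um)),
      polar_body = list(present = isTRUE(spec$polar_body$present),
                        center_px = ctr$pb_px,
                        a_um = spec$polar_body$a_um, b_um = spec$polar_body$b_um,
                        diameter_um = 2 * sqrt(spec$polar_body$a_um *
                                               spec$polar_body$b_um),
                        bearing_deg = if (isTRUE(spec$polar_body$present))
                          spec$polar_body$bearing_deg else NULL))
    list(image = rgb_image(px, 8L), truth = truth)
  })
}

#' Generate a benchmark suite of scene specifications
#'
#' Builds `n` seeded [scene_spec()]s for one of the four benchmark
#' categories:
#' \describe{
#'   \item{background}{`n` distinct background colors, fixed clean
#'     geometry.}
#'   \item{orientation}{polar-body bearings evenly spanning `[0, 360)`
#'     with small seeded oocyte center offsets.}
#'   \item{magnification}{`um_per_px` varied geometrically over 0.5x–2x of
#'     the default 0.5 µm/px, constant µm geometry.}
#'   \item{disturbance}{5–20 cumulus-like clutter blobs near the zona.}
#' }
#' Everything is derived deterministically from `base_seed`.
#'
#' @param category one of `"background"`, `"orientation"`,
#'   `"magnification"`, `"disturbance"`.
#' @param n number of scenes (>= 1).
#' @param base_seed integer seed for the whole suite.
#' @return A list of [scene_spec()] (class `scene_suite`) with the category
#'   and seed as attributes.
#' @export
generate_suite <- function(category = c("background", "orientation",
                                        "magnification", "disturbance"),
                           n, base_seed = 1L) {
  if (length(category) != 1L || !category %in% c("background", "orientation",
                                                 "magnification", "disturbance"))
    stop("invalid configuration: unknown suite category", call. = FALSE)
  stopifnot(n >= 1)
  n <- as.integer(n)
  specs <- .with_seed(base_seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    switch(category,
      background = {
        cols <- unique(matrix(sample(90:225, 3L * 4L * n, replace = TRUE),
                              ncol = 3L))[seq_len(n), , drop = FALSE]
        lapply(seq_len(n), function(i)
          scene_spec(background_rgb = cols[i, ], seed = seeds[i]))
      },
      orientation = {
        bearings <- (seq_len(n) - 1L) * 360 / n
        offs <- matrix(stats::runif(2L * n, -10, 10), ncol = 2L)
        lapply(seq_len(n), function(i)
          scene_spec(oocyte = list(center_um = offs[i, ]),
                     polar_body = list(bearing_deg = bearings[i]),
                     seed = seeds[i]))
      },
      magnification = {
        fac <- if (n == 1L) 1 else exp(seq(log(0.5), log(2), length.out = n))
        lapply(seq_len(n), function(i)
          scene_spec(um_per_px = 0.5 * fac[i], seed = seeds[i]))
      },
      disturbance = {
        counts <- sample(5:20, n, replace = TRUE)
        lapply(seq_len(n), function(i)
          scene_spec(clutter = list(n = counts[i]), seed = seeds[i]))
      })
  })
  structure(specs, category = category, base_seed = base_seed,
            class = c("scene_suite", "list"))
}

#' @export
print.scene_suite <- function(x, ...) {
  cat(sprintf("<scene_suite '%s', %d scenes, base seed %d>\n",
              attr(x, "category"), length(x), attr(x, "base_seed")))
  invisible(x)
}

#' Score the detector against ground truth over a suite
#'
#' Renders every scene, runs the detection pipeline (radius ranges supplied
#' in micrometers and converted per scene scale), and scores each report
#' against the scene's truth. A detection is counted as *correct* when the
#' object is found and its center error does not exceed 25% of the object's
#' true diameter; diameter and position errors are aggregated over detected
#' scenes only. These definitions are the single source of truth reused by
#' all accuracy checks.
#'
#' @param suite a [generate_suite()] result (or list of [scene_spec()]).
#' @param config an [oodetect_config()].
#' @param oocyte_radius_um,pb_radius_um radius ranges in micrometers.
#' @param detector detection function
#'   `function(image, um_per_px, truth)` returning an `oodetect_report`;
#'   the default runs [oodetect()] and ignores `truth`. Substituting an
#'   oracle detector that echoes the truth is the harness self-test.
#' @param progress print a line per scene.
#' @return An object of class `oo_benchmark`: `per_scene` data frame
#'   (per-object errors, flags) and `aggregate` list (detection rates in
#'   percent; max and mean diameter error percent and position error µm per
#'   object).
#' @export
run_benchmark <- function(suite, config = oodetect_config(),
                          oocyte_radius_um = c(55, 85),
                          pb_radius_um = c(5, 15),
                          detector = NULL, progress = FALSE) {
  stopifnot(length(suite) >= 1L)
  if (is.null(detector))
    detector <- function(image, um_per_px, truth)
      oodetect(image, oocyte_radius = oocyte_radius_um,
               pb_radius = pb_radius_um, units = "um",
               um_per_px = um_per_px, config = config)
  rows <- vector("list", length(suite))
  for (i in seq_along(suite)) {
    spec <- suite[[i]]
    sc <- render_scene(spec)
    tr <- sc$truth
    rep <- tryCatch(detector(sc$image, spec$um_per_px, tr),
                    error = function(e) e)
    failed <- inherits(rep, "error")
    upp <- spec$um_per_px
    score_obj <- function(det, tobj) {
      if (failed || !isTRUE(det$found))
        return(list(found = FALSE, diam_err_pct = NA_real_,
                    pos_err_um = NA_real_, correct = FALSE))
      d_est <- det$diameter_px * upp
      pos <- sqrt(sum((det$center_px - tobj$center_px)^2)) * upp
      list(found = TRUE,
           diam_err_pct = abs(d_est - tobj$diameter_um) / tobj$diameter_um * 100,
           pos_err_um = pos,
           correct = pos <= 0.25 * tobj$diameter_um)
    }
    oo <- score_obj(if (failed) NULL else rep$oocyte, tr$oocyte)
    pb <- if (tr$polar_body$present)
      score_obj(if (failed) NULL else rep$polar_body, tr$polar_body)
    else list(found = NA, diam_err_pct = NA_real_, pos_err_um = NA_real_,
              correct = NA)
    rows[[i]] <- data.frame(
      scene = i, seed = spec$seed, um_per_px = upp,
      error = failed,
      runtime_s = if (failed || is.null(rep$runtime_s)) NA_real_ else rep$runtime_s,
      oo_found = isTRUE(oo$found), oo_diam_err_pct = oo$diam_err_pct,
      oo_pos_err_um = oo$pos_err_um, oo_correct = isTRUE(oo$correct),
      pb_present = tr$polar_body$present,
      pb_found = isTRUE(pb$found), pb_diam_err_pct = pb$diam_err_pct,
      pb_pos_err_um = pb$pos_err_um,
      pb_correct = if (tr$polar_body$present) isTRUE(pb$correct) else NA,
      both_correct = isTRUE(oo$correct) &&
        (!tr$polar_body$present || isTRUE(pb$correct)))
    if (progress)
      message(sprintf("scene %d/%d: oocyte %s, polar body %s", i, length(suite),
                      if (isTRUE(oo$correct)) "ok" else "MISS",
                      if (!tr$polar_body$present) "absent"
                      else if (isTRUE(pb$correct)) "ok" else "MISS"))
  }
  per_scene <- do.call(rbind, rows)
  n <- nrow(per_scene)
  agg_err <- function(v) if (all(is.na(v))) c(max = NA_real_, mean = NA_real_)
    else c(max = max(v, na.rm = TRUE), mean = mean(v, na.rm = TRUE))
  with_pb <- per_scene$pb_present
  aggregate <- list(
    n = n,
    detection_rate_pct = 100 * sum(per_scene$both_correct) / n,
    oocyte = list(rate_pct = 100 * sum(per_scene$oo_correct) / n,
                  diam_err_pct = agg_err(per_scene$oo_diam_err_pct),
                  pos_err_um = agg_err(per_scene$oo_pos_err_um)),
    polar_body = list(
      rate_pct = if (any(with_pb))
        100 * sum(per_scene$pb_correct[with_pb]) / sum(with_pb) else NA_real_,
      diam_err_pct = agg_err(per_scene$pb_diam_err_pct),
      pos_err_um = agg_err(per_scene$pb_pos_err_um)))
  structure(list(per_scene = per_scene, aggregate = aggregate,
                 category = attr(suite, "category")),
            class = "oo_benchmark")
}

#' @export
print.oo_benchmark <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Benchmark%s: %d scenes\n",
              if (!is.null(x$category)) paste0(" [", x$category, "]") else "",
              a$n))
  cat(sprintf("  detection rate (both objects): %.1f%%\n", a$detection_rate_pct))
  cat(sprintf("  oocyte:     rate %.1f%%, diameter err max %.2f%% / mean %.2f%%, position err max %.2f um / mean %.2f um\n",
              a$oocyte$rate_pct, a$oocyte$diam_err_pct[["max"]],
              a$oocyte$diam_err_pct[["mean"]], a$oocyte$pos_err_um[["max"]],
              a$oocyte$pos_err_um[["mean"]]))
  if (!is.na(a$polar_body$rate_pct))
    cat(sprintf("  polar body: rate %.1f%%, diameter err max %.2f%% / mean %.2f%%, position err max %.2f um / mean %.2f um\n",
                a$polar_body$rate_pct, a$polar_body$diam_err_pct[["max"]],
                a$polar_body$diam_err_pct[["mean"]],
                a$polar_body$pos_err_um[["max"]],
                a$polar_body$pos_err_um[["mean"]]))
  invisible(x)
}

#' Mixed clean-scene benchmark suite
#'
#' Convenience constructor for the headline accuracy suite: an even mix of
#' the three clean categories (background colors, polar-body bearings,
#' magnifications), seeded from one base seed.
#'
#' @param n total number of scenes (default 80).
#' @param base_seed integer seed.
#' @return A `scene_suite` of length `n`.
#' @export
clean_mix_suite <- function(n = 80L, base_seed = 1L) {
  n <- as.integer(n)
  n1 <- n %/% 3L; n2 <- n %/% 3L; n3 <- n - n1 - n2
  specs <- c(generate_suite("background", n1, base_seed),
             generate_suite("orientation", n2, base_seed + 1L),
             generate_suite("magnification", n3, base_seed + 2L))
  structure(specs, category = "clean_mix", base_seed = base_seed,
            class = c("scene_suite", "list"))
}
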