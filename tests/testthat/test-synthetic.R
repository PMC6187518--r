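test_that("a noise-free render places the stated contrasts at the boundaries", {
  spec <- scene_spec(oocyte = list(granularity = 0), blur_sigma = 0,
                     noise_sigma = 0, seed = 1L)
  sc <- render_scene(spec)
  ctr <- sc$truth$oocyte$center_px
  px <- sc$image$pixels
  center_val <- px[ctr[1], ctr[2], ]
  expect_false(any(center_val == spec$background_rgb))
  ## stepping across the rim along +x: inside vs the perivitelline gap
  a_px <- sc$truth$oocyte$a_px
  inside <- px[ctr[1], floor(ctr[2] + a_px - 3), 1]
  outside <- px[ctr[1], ceiling(ctr[2] + a_px + 3), 1]
  expect_equal(outside - inside, spec$oocyte$rim_contrast)
})

test_that("the polar body lies wholly inside the perivitelline gap", {
  for (bearing in c(0, 115, 250)) {
    spec <- scene_spec(polar_body = list(bearing_deg = bearing), seed = 3L)
    tr <- render_scene(spec)$truth
    d <- sqrt(sum((tr$polar_body$center_px - tr$oocyte$center_px)^2)) *
      spec$um_per_px
    expect_gte(d - spec$polar_body$a_um, spec$oocyte$a_um)
    expect_lte(d + spec$polar_body$a_um, spec$oocyte$a_um + spec$gap_um)
  }
  expect_error(scene_spec(polar_body = list(a_um = 15, b_um = 15)),
               "does not fit")
})

test_that("rendering is reproducible from (spec, seed) and varies with the seed", {
  s1 <- scene_spec(seed = 5L)
  s2 <- scene_spec(seed = 6L)
  r1a <- render_scene(s1); r1b <- render_scene(s1); r2 <- render_scene(s2)
  expect_identical(r1a$image$pixels, r1b$image$pixels)
  expect_identical(r1a$truth, r1b$truth)
  expect_false(identical(r1a$image$pixels, r2$image$pixels))
  expect_identical(r1a$truth$oocyte, r2$truth$oocyte)   # same geometry truth
})

test_that("scenes that violate the geometry invariants are rejected", {
  expect_error(scene_spec(image_size = c(100L, 100L)), "10-px margin")
  expect_error(scene_spec(um_per_px = -1), "um_per_px")
})

test_that("the orientation suite spaces bearings evenly over the circle", {
  suite <- generate_suite("orientation", 8, base_seed = 2L)
  bearings <- vapply(suite, function(s) s$polar_body$bearing_deg, 0)
  expect_equal(bearings, seq(0, 315, by = 45))
})

test_that("suites are deterministic in their base seed", {
  for (cat in c("background", "orientation", "magnification", "disturbance")) {
    a <- generate_suite(cat, 5, base_seed = 7L)
    b <- generate_suite(cat, 5, base_seed = 7L)
    expect_identical(a, b)
  }
  expect_error(generate_suite("sparkle", 5, 1L), "unknown suite category")
})

test_that("the background suite varies only the background color", {
  suite <- generate_suite("background", 6, base_seed = 9L)
  cols <- t(vapply(suite, function(s) s$background_rgb, numeric(3)))
  expect_equal(nrow(unique(cols)), 6)
  expect_equal(length(unique(vapply(suite, function(s) s$um_per_px, 0))), 1L)
})

test_that("magnification changes pixels but not micrometer truth", {
  suite <- generate_suite("magnification", 3, base_seed = 4L)
  upps <- vapply(suite, function(s) s$um_per_px, 0)
  expect_equal(length(unique(upps)), 3L)
  expect_equal(range(upps), c(0.25, 1.0))
  diams <- vapply(suite, function(s) render_scene(s)$truth$oocyte$diameter_um, 0)
  expect_equal(diams, rep(140, 3))
  a_px <- vapply(suite, function(s) render_scene(s)$truth$oocyte$a_px, 0)
  expect_equal(length(unique(a_px)), 3L)
})

test_that("the disturbance suite adds 5-20 clutter blobs", {
  suite <- generate_suite("disturbance", 6, base_seed = 11L)
  counts <- vapply(suite, function(s) s$clutter$n, 0)
  expect_true(all(counts >= 5 & counts <= 20))
})

test_that("an oracle detector scores a perfect benchmark", {
  oracle <- function(image, um_per_px, truth) {
    mk <- function(t) structure(list(
      found = TRUE, center_px = t$center_px,
      ellipse = structure(list(center = t$center_px,
                               a = t$a_um / um_per_px, b = t$b_um / um_per_px,
                               score = 1), class = "ellipse_fit"),
      diameter_px = 2 * sqrt(t$a_um * t$b_um) / um_per_px,
      confidence = 1), class = "oo_detection")
    oo <- mk(truth$oocyte)
    pb <- if (truth$polar_body$present) mk(truth$polar_body) else NULL
    build_report(oo, pb, truth$image_size, um_per_px)
  }
  b <- run_benchmark(generate_suite("orientation", 4, base_seed = 13L),
                     detector = oracle)
  expect_equal(b$aggregate$detection_rate_pct, 100)
  expect_equal(b$aggregate$oocyte$diam_err_pct[["max"]], 0)
  expect_equal(b$aggregate$oocyte$pos_err_um[["max"]], 0)
  expect_equal(b$aggregate$polar_body$pos_err_um[["max"]], 0)
})

test_that("benchmark runs are deterministic and errors are counted over detections only", {
  suite <- generate_suite("background", 2, base_seed = 21L)
  b1 <- run_benchmark(suite)
  b2 <- run_benchmark(suite)
  b1$per_scene$runtime_s <- b2$per_scene$runtime_s <- NULL
  expect_identical(b1$per_scene, b2$per_scene)
  expect_identical(b1$aggregate, b2$aggregate)
  expect_equal(b1$aggregate$detection_rate_pct,
               100 * sum(b1$per_scene$both_correct) / nrow(b1$per_scene))
  miss <- function(image, um_per_px, truth) {
    empty <- structure(list(found = FALSE, center_px = NULL, ellipse = NULL,
                            diameter_px = NA_real_, confidence = 0),
                       class = "oo_detection")
    build_report(empty, NULL, truth$image_size, um_per_px)
  }
  b0 <- run_benchmark(suite, detector = miss)
  expect_equal(b0$aggregate$detection_rate_pct, 0)
  expect_true(is.na(b0$aggregate$oocyte$diam_err_pct[["max"]]))
})
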