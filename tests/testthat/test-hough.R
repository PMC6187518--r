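## Build an edge_points object directly (analytic edge sets).
make_edges <- function(row, col, magnitude, orientation, dim) {
  structure(data.frame(row = row, col = col, magnitude = magnitude,
                       orientation = orientation),
            threshold_used = 0, image_dim = dim,
            class = c("edge_points", "data.frame"))
}

## Analytic edge set of a circle: points on the boundary with radial
## orientations (gradient pointing outward) and unit magnitude.
circle_edges <- function(r0, c0, radius, dim, n = ceiling(2 * pi * radius),
                         magnitude = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  make_edges(row = round(r0 + radius * sin(th)),
             col = round(c0 + radius * cos(th)),
             magnitude = rep(magnitude, n), orientation = th, dim = dim)
}

test_that("a single edge point votes at both polarities along its gradient", {
  e <- make_edges(20, 30, magnitude = 2.5, orientation = 0, dim = c(40L, 60L))
  acc <- vote_circular(e, radius_range(7, 7, n_steps = 1), c(40L, 60L))
  hits <- which(acc$votes != 0, arr.ind = TRUE)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits[, "col"], c(23, 37))   # +- r horizontally
  expect_equal(hits[, "row"], c(20, 20), ignore_attr = TRUE)
  expect_equal(unique(acc$votes[acc$votes != 0]), 2.5)
  expect_equal(acc$total_weight, 5)
})

test_that("votes outside the image are discarded and empty edge sets warn", {
  e <- make_edges(2, 2, 1, orientation = pi, dim = c(10L, 10L))
  acc <- vote_circular(e, radius_range(5, 5, n_steps = 1), c(10L, 10L))
  expect_equal(sum(acc$votes != 0), 1)        # the outward vote falls off-image
  empty <- make_edges(integer(), integer(), numeric(), numeric(), c(10L, 10L))
  expect_warning(acc0 <- vote_circular(empty, radius_range(3, 5), c(10L, 10L)),
                 "empty edge set")
  expect_equal(acc0$total_weight, 0)
  expect_null(find_center(acc0))
})

test_that("the accumulator peak recovers a rendered circle center within 1 px", {
  m <- disc_image(200, 200, 100, 100, 40)
  e <- edges_of(m)
  acc <- vote_circular(e, radius_range(35, 45))
  ce <- find_center(acc)
  expect_lte(max(abs(ce$center - c(100, 100))), 1)
  expect_gt(ce$confidence, 0.25)
})

test_that("the weighted vote agrees with an unweighted brute-force Hough on small images", {
  m <- disc_image(64, 64, 33, 30, 18)
  e <- edges_of(m, keep_fraction = 0.5)    # full boundary ring
  rr <- radius_range(15, 21)
  ce <- find_center(vote_circular(e, rr))
  oracle <- brute_hough_argmax(e, rr$radii, 64L, 64L)
  expect_lte(max(abs(ce$center - oracle)), 1)
})

test_that("gradient weighting favors sharp boundaries over blurred copies", {
  ## one image, two identical discs; the right one Gaussian-blurred (sigma 3)
  m <- disc_image(140, 280, 70, 70, 30)
  right <- oodetect:::.blur_gaussian(disc_image(140, 280, 70, 210, 30), 3)
  m[, 141:280] <- right[, 141:280]
  g <- weighted_smooth(gray_image(m), filter_mask(5L))
  field <- compute_gradients(g)
  ## the sharp boundary's votes carry strictly higher weights ...
  d_sharp <- sqrt((row(m) - 70)^2 + (col(m) - 70)^2)
  d_blur <- sqrt((row(m) - 70)^2 + (col(m) - 210)^2)
  expect_gt(max(field$magnitude[abs(d_sharp - 30) < 3]),
            2 * max(field$magnitude[abs(d_blur - 30) < 3]))
  ## ... so under a tight edge budget only the sharp circle keeps voting
  e <- threshold_edges(field, auto_threshold(field, 0.02))
  acc <- vote_circular(e, radius_range(28, 32))
  mass_at <- function(r0, c0) sum(acc$votes[(r0 - 1):(r0 + 1),
                                            (c0 - 1):(c0 + 1)])
  expect_gt(mass_at(70, 70), mass_at(70, 210))
})

test_that("peak picking breaks ties toward the smallest row then column", {
  votes <- matrix(0, 30, 30)
  votes[10, 10] <- 5; votes[10, 20] <- 5
  acc <- structure(list(votes = votes, radius_range = radius_range(3, 3),
                        total_weight = 10, n_edges = 2L, max_edge_mag = 1),
                   class = "hough_accumulator")
  expect_equal(find_center(acc)$center, c(row = 10, col = 10))
  votes2 <- matrix(0, 30, 30); votes2[17, 4] <- 3
  acc2 <- structure(list(votes = votes2, radius_range = radius_range(3, 3),
                         total_weight = 3, n_edges = 1L, max_edge_mag = 1),
                    class = "hough_accumulator")
  expect_equal(find_center(acc2)$center, c(row = 17, col = 4))
})

test_that("exclusion masks restrict the peak search", {
  m <- disc_image(200, 200, 100, 100, 40)
  e <- edges_of(m)
  acc <- vote_circular(e, radius_range(35, 45))
  no_mask <- find_center_excluding(acc, matrix(FALSE, 200, 200))
  expect_equal(no_mask, find_center(acc))
  ## masking the winning region forces the next-best cell
  excl <- matrix(FALSE, 200, 200)
  excl[(no_mask$center[1] - 3):(no_mask$center[1] + 3),
       (no_mask$center[2] - 3):(no_mask$center[2] + 3)] <- TRUE
  second <- find_center_excluding(acc, excl)
  expect_false(excl[second$center[1], second$center[2]])
  expect_lte(second$peak_vote, no_mask$peak_vote + 1e-9)
  expect_null(find_center_excluding(acc, matrix(TRUE, 200, 200)))
  expect_error(find_center_excluding(acc, matrix(TRUE, 5, 5)), "shape mismatch")
})

test_that("translation moves the recovered center exactly with it", {
  base <- circle_edges(40, 45, 20, dim = c(120L, 120L))
  rrg <- radius_range(18, 22)
  c1 <- find_center(vote_circular(base, rrg))$center
  shifted <- make_edges(base$row + 13, base$col + 22, base$magnitude,
                        base$orientation, c(120L, 120L))
  c2 <- find_center(vote_circular(shifted, rrg))$center
  expect_equal(c2 - c1, c(row = 13, col = 22))
})

test_that("scaling gradient magnitudes scales votes but not the result", {
  e <- circle_edges(50, 50, 20, dim = c(100L, 100L))
  rrg <- radius_range(18, 22)
  a1 <- vote_circular(e, rrg)
  e2 <- make_edges(e$row, e$col, e$magnitude * 7, e$orientation, c(100L, 100L))
  a2 <- vote_circular(e2, rrg)
  expect_equal(a2$votes, 7 * a1$votes)
  ce1 <- find_center(a1); ce2 <- find_center(a2)
  expect_equal(ce1$center, ce2$center)
  expect_equal(ce2$confidence, ce1$confidence)   # confidence is scale-free
})

test_that("center recovery is unaffected by background polarity", {
  bright <- disc_image(100, 100, 50, 50, 20, inside = 220, outside = 40)
  dark <- disc_image(100, 100, 50, 50, 20, inside = 40, outside = 220)
  rrg <- radius_range(17, 23)
  cb <- find_center(vote_circular(edges_of(bright), rrg))$center
  cd <- find_center(vote_circular(edges_of(dark), rrg))$center
  expect_lte(max(abs(cb - c(50, 50))), 1)
  expect_lte(max(abs(cd - c(50, 50))), 1)
})

test_that("radius ranges validate their bounds", {
  expect_error(radius_range(0, 5), "r_min")
  expect_error(radius_range(8, 5), "r_min")
  rr <- radius_range(10, 20)
  expect_equal(rr$n_steps, 11L)
  expect_equal(rr$radii, 10:20)
})
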