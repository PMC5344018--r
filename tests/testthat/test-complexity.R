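test_that("box counts match trivial geometry and the brute-force oracle", {
  # single pixel: one box at every size
  img <- matrix(FALSE, 64, 64); img[20, 33] <- TRUE
  bc <- box_count(as_outline_image(img), c(1, 2, 4, 8, 16, 32))
  expect_equal(bc$count, rep(1L, 6))
  # fully foreground 512^2 at size 64: (512/64)^2 = 64 boxes
  full <- as_outline_image(matrix(TRUE, 512, 512))
  expect_equal(box_count(full, 64)$count, 64L)
  # random images against a double-loop count
  for (seed in 1:5) {
    set.seed(seed)
    rnd <- matrix(runif(64 * 64) < 0.1, 64, 64)
    if (!any(rnd)) rnd[1, 1] <- TRUE
    im <- as_outline_image(rnd)
    for (s in c(3, 7, 16)) {
      expect_equal(box_count(im, s)$count, brute_force_box_count(rnd, s))
    }
  }
})

test_that("box counts are non-increasing in box size", {
  img <- generate_phantom("koch", canvas = 512, iterations = 4)
  bc <- box_count(img, c(1, 2, 3, 5, 8, 13, 21, 34))
  expect_true(all(diff(bc$count) <= 0))
  expect_error(box_count(img, c(8, 4)), "increasing")
  expect_error(box_count(img, 0), "sizes")
})

test_that("fractal dimension recovers analytic phantom dimensions", {
  fd_line <- fractal_dimension(generate_phantom("line", 512))
  expect_gte(fd_line$dimension, 0.95)
  expect_lte(fd_line$dimension, 1.05)
  fd_sq <- fractal_dimension(generate_phantom("filled_square", 512))
  expect_gte(fd_sq$dimension, 1.90)
  expect_lte(fd_sq$dimension, 2.05)
  fd_circ <- fractal_dimension(generate_phantom("circle_outline", 512))
  expect_gte(fd_circ$dimension, 0.95)
  expect_lte(fd_circ$dimension, 1.1)
  # any planar raster: dimension in [0, 2] + fit tolerance
  set.seed(8)
  rnd <- matrix(runif(256^2) < 0.05, 256, 256)
  fd_rnd <- fractal_dimension(as_outline_image(rnd))
  expect_gte(fd_rnd$dimension, 0)
  expect_lte(fd_rnd$dimension, 2.05)
})

test_that("dimension estimates are stable under small translations", {
  base <- generate_phantom("koch", canvas = 1024, iterations = 5)
  dims <- vapply(0:9, function(k) {
    set.seed(k + 1)
    dr <- sample(-6:6, 1); dc <- sample(-6:6, 1)
    shifted <- matrix(FALSE, 1072, 1072)
    shifted[24 + dr + seq_len(1024), 24 + dc + seq_len(1024)] <- base
    fractal_dimension(as_outline_image(shifted),
                      box_sizes = 2^(1:7))$dimension
  }, numeric(1))
  expect_lt(diff(range(dims)), 0.05)
})

test_that("standardization scales the span and keeps images binary", {
  # a 100-px-tall blob on a 300 canvas, standardized to span 200/canvas 260
  img <- matrix(FALSE, 300, 300)
  img[101:200, 140:160] <- TRUE
  std <- standardize_image(as_outline_image(img), target_canvas = 260,
                           target_span = 200)
  expect_equal(dim(std), c(260L, 260L))
  idx <- which(std, arr.ind = TRUE)
  expect_equal(diff(range(idx[, 1])) + 1L, 200L)
  # aspect ratio preserved: width scaled by the same factor (x2)
  expect_lt(abs((diff(range(idx[, 2])) + 1L) - 42L), 3L)
  expect_type(std[1, 1], "logical")
  # standardizing an already-standard image changes (almost) nothing
  again <- standardize_image(std, target_canvas = 260, target_span = 200)
  expect_gte(mean(again == std), 0.99)
  expect_error(standardize_image(matrix(FALSE, 10, 10)), "foreground")
})

test_that("scaling leaves the dimension of a Koch phantom stable", {
  # transpose so the curve's long axis is the base-to-apex span
  small <- as_outline_image(t(generate_phantom("koch", canvas = 512,
                                               iterations = 4)))
  big <- standardize_image(small, target_canvas = 1024, target_span = 980)
  d1 <- fractal_dimension(small)$dimension
  d2 <- fractal_dimension(big)$dimension
  expect_lt(abs(d1 - d2), 0.05)
})

test_that("PNG and TIFF outlines round-trip through the reader", {
  img <- generate_phantom("circle_outline", canvas = 256)
  fp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(1 - unclass(img) * 1, fp)   # dark foreground on white
  back <- read_outline_image(fp)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE)
  ft <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(1 - unclass(img) * 1, ft)
  back2 <- read_outline_image(ft)
  expect_equal(sum(back2), sum(img))
})

test_that("perimeter complexity is a unit-free ratio", {
  expect_equal(perimeter_complexity(2.4, 0.8), 3.0)
  d <- 0.37
  expect_equal(perimeter_complexity(pi * d, d), pi)
  expect_equal(perimeter_complexity(2400, 800),
               perimeter_complexity(2.4, 0.8))
  expect_error(perimeter_complexity(0, 1), "positive")
  expect_error(perimeter_complexity(1, -2), "positive")
})
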