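# Row-major entry of the 2x2 toy matrices used throughout: R's matrix()
# is column-major, so byrow = TRUE keeps the rows as written.
toy_img <- matrix(c(0.3, 0.6, 0.5, 0.8), 2, 2, byrow = TRUE)
toy_mask <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)

test_that("mask normalization flips 0 and 1 and is an involution", {
  expect_equal(normalize_hair_mask(toy_mask),
               matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(normalize_hair_mask(matrix(0, 3, 3)), matrix(1, 3, 3))
  m <- matrix(sample(c(0, 1), 25, replace = TRUE), 5, 5)
  expect_equal(normalize_hair_mask(normalize_hair_mask(m)), m)
  expect_error(normalize_hair_mask(matrix(0.5, 2, 2)), "binary")
})

test_that("merge and post-process reproduce the overlay arithmetic", {
  nm <- normalize_hair_mask(toy_mask)
  merged <- merge_images(toy_img, nm)
  expect_equal(merged, matrix(c(0.3, 1.6, 1.5, 0.8), 2, 2, byrow = TRUE))
  expect_equal(postprocess_merged(merged),
               matrix(c(-0.7, 0.6, 0.5, -0.2), 2, 2, byrow = TRUE))
  # additive identity and inverse pair
  expect_equal(merge_images(toy_img, matrix(0, 2, 2)), toy_img)
  expect_equal(postprocess_merged(merge_images(toy_img, matrix(1, 2, 2))),
               toy_img)
  expect_error(merge_images(toy_img, matrix(0, 3, 3)), "dimensions")
  # elementwise loop oracle on a random pair
  set.seed(2)
  a <- matrix(runif(25), 5, 5); b <- matrix(runif(25), 5, 5)
  expected <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) expected[i, j] <- a[i, j] + b[i, j]
  expect_equal(merge_images(a, b), expected)
})

test_that("mask overlay closed form is img - mask with untouched background", {
  r <- add_mask_hair(toy_img, toy_mask)
  expect_equal(r$final_unclipped,
               matrix(c(-0.7, 0.6, 0.5, -0.2), 2, 2, byrow = TRUE))
  expect_equal(r$final_clipped, clip_image(toy_img - toy_mask))

  # independent per-element subtraction oracle on random input
  set.seed(3)
  img <- matrix(runif(64), 8, 8)
  mask <- matrix(rbinom(64, 1, 0.2), 8, 8)
  r2 <- add_mask_hair(img, mask)
  expected <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) expected[i, j] <- img[i, j] - mask[i, j]
  expect_equal(r2$final_unclipped, expected)
  # background bit-identical, all-zero mask is the identity
  expect_identical(r2$final_unclipped[mask == 0], img[mask == 0])
  expect_equal(add_mask_hair(img, matrix(0, 8, 8))$final_unclipped, img)

  # RGB broadcast: the same mask is subtracted from every channel
  rgb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  r3 <- add_mask_hair(rgb, mask)
  for (k in 1:3)
    expect_equal(r3$final_unclipped[, , k], rgb[, , k] - mask)
  expect_error(add_mask_hair(img, matrix(0, 4, 4)), "height and width")
})

test_that("sampled lines obey the endpoint formulas and length bounds", {
  set.seed(11)
  W <- 256L; H <- 256L
  n <- 10000L
  d_pos <- 0L
  for (i in seq_len(n)) {
    ln <- sample_line(W, H)
    expect_true(ln$length >= 10 && ln$length <= 30)
    expect_true(ln$x_start >= 0 && ln$x_start <= W)
    expect_true(ln$y_start >= 0 && ln$y_start <= H)
    expect_identical(ln$x_end, ln$x_start + ln$d * ln$length)
    expect_identical(ln$y_end, ln$y_start + ln$length)
    # 45-degree diagonals only
    expect_equal(abs(ln$x_end - ln$x_start), ln$y_end - ln$y_start)
    if (ln$d == 1L) d_pos <- d_pos + 1L
  }
  # direction is a fair coin (binomial bound, ~3.3 sigma at n = 10^4)
  expect_gt(d_pos / n, 0.47)
  expect_lt(d_pos / n, 0.53)
  # degenerate length range
  set.seed(1)
  lens <- replicate(50, sample_line(64, 64, length_range = c(10, 10))$length)
  expect_true(all(lens == 10))
})

test_that("line rasterization touches exactly the Bresenham path", {
  img <- matrix(1, 32, 32)
  # length-0 line: a single pixel
  one <- rasterize_line(img, list(x_start = 5L, y_start = 7L,
                                  x_end = 5L, y_end = 7L), color = 0)
  expect_equal(sum(one == 0), 1L)
  expect_equal(one[8, 6], 0)           # (row, col) = (y, x) + 1
  # fully off-canvas line leaves the image unchanged
  off <- rasterize_line(img, list(x_start = 100L, y_start = 100L,
                                  x_end = 120L, y_end = 120L), color = 0)
  expect_identical(off, img)
  # a 45-degree diagonal of length L changes exactly L + 1 pixels
  for (d in c(-1L, 1L)) {
    L <- 9L
    ln <- list(x_start = 15L, y_start = 3L, x_end = 15L + d * L, y_end = 3L + L)
    out <- rasterize_line(img, ln, color = 0)
    expect_equal(sum(out == 0), L + 1L)
  }
})

test_that("line-hair synthesis is seeded, pure, and draws n_lines segments", {
  img <- make_lesion_texture(1, c(64, 64))
  expect_identical(synth_line_hair(img, n_lines = 0, seed = 1), img)
  a <- synth_line_hair(img, n_lines = 40, seed = 5, length_range = c(5, 10))
  b <- synth_line_hair(img, n_lines = 40, seed = 5, length_range = c(5, 10))
  expect_identical(a, b)
  r <- synth_line_hair(img, n_lines = 40, seed = 5, length_range = c(5, 10),
                       return_lines = TRUE)
  expect_length(r$lines, 40L)
  # pixels untouched by any segment are bit-identical to the input
  touched <- matrix(FALSE, 64, 64)
  probe <- synth_line_hair(matrix(1, 64, 64), n_lines = 40, seed = 5,
                           length_range = c(5, 10), color = 0)
  touched[probe == 0] <- TRUE
  expect_identical(a[!touched], img[!touched])
})
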