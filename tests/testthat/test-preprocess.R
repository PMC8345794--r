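test_that("grayscale loading normalises bit depth and collapses channels", {
  tmp <- withr::local_tempdir()
  # 8-bit PNG, all pixels at full scale -> constant 1.0
  p1 <- file.path(tmp, "white.png")
  png::writePNG(matrix(1, 16, 16), p1)
  expect_equal(read_gray(p1), matrix(1, 16, 16))
  # RGB with equal channels -> that gray value
  p2 <- file.path(tmp, "gray_rgb.png")
  png::writePNG(array(0.3, c(16, 16, 3)), p2)
  g <- read_gray(p2)
  expect_equal(length(unique(as.vector(g))), 1)
  expect_lte(abs(g[1, 1] - 0.3), 1 / 255)  # 8-bit write quantization
  # 16-bit TIFF: matches direct scaling by 65535, max exactly 1
  vals <- matrix(c(0, 1000, 30000, 65535, seq(100, 60000, length.out = 12)),
                 4, 4)
  vals <- round(vals)
  p3 <- file.path(tmp, "deep.tif")
  tiff::writeTIFF(vals / 65535, p3, bits.per.sample = 16)
  got <- read_gray(p3)
  expect_equal(max(got), 1)
  expect_equal(sort(as.vector(got)), sort(as.vector(vals / 65535)),
               tolerance = 1e-9)
  expect_error(read_gray(file.path(tmp, "missing.png")), "not found")
})

test_that("resizing preserves constants, means, and is idempotent", {
  expect_equal(resize_square(matrix(0.5, 400, 400), 200),
               matrix(0.5, 200, 200))
  img <- matrix(runif(200 * 200), 200, 200)
  expect_identical(resize_square(img, 200), img)
  ramp <- matrix(seq(0, 1, length.out = 256 * 192), 256, 192)
  out <- resize_square(ramp, 200)
  expect_equal(dim(out), c(200, 200))
  expect_lt(abs(mean(out) - mean(ramp)) / mean(ramp), 0.01)
  # idempotence at fixed size
  once <- resize_square(ramp, 100)
  expect_equal(resize_square(once, 100), once)
  expect_error(resize_square(ramp, 4), "at least 8")
})

test_that("CLAHE preserves shape and range and boosts contrast", {
  # constant image stays constant (within one 8-bit gray level of spread)
  out <- clahe_enhance(matrix(0.5, 64, 64))
  expect_equal(dim(out), c(64, 64))
  expect_lte(diff(range(out)), 1 / 255)
  # two-valued image (half 0.2, half 0.8): global std does not decrease
  withr::with_seed(5, tv <- matrix(sample(rep(c(0.2, 0.8), 32 * 64)), 64, 64))
  expect_gte(sd(clahe_enhance(tv)), sd(tv) - 1e-9)
  # low-contrast noise: std strictly increases
  withr::with_seed(7, {
    noisy <- matrix(0.5 + rnorm(64 * 64, 0, 0.02), 64, 64)
  })
  enhanced <- clahe_enhance(noisy)
  expect_gt(sd(enhanced), sd(noisy))
  expect_true(all(enhanced >= 0 & enhanced <= 1))
  expect_error(clahe_enhance(matrix(0.5, 16, 16), tile = 32), "larger")
})

test_that("quantization bins [0,1] uniformly", {
  q <- quantize_gray(matrix(0.5, 10, 10), 8)
  expect_equal(unique(as.vector(q)), 4L)
  q2 <- quantize_gray(matrix(c(0, 1), 4, 4), 2)
  expect_setequal(unique(as.vector(q2)), c(0L, 1L))
  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  q3 <- quantize_gray(ramp, 8)
  expect_equal(as.vector(table(q3)), rep(8, 8))
  expect_error(quantize_gray(ramp, 1), "at least 2")
})

test_that("manifest preprocessing attaches processed images", {
  tmp <- withr::local_tempdir()
  man <- phantom_dataset(c(LACS = 2, PACS = 2, TACS = 2), seed = 4,
                         dir = tmp, size = 64)
  pre <- preprocess_images(man, size = 48)
  expect_equal(nrow(pre), 6)
  expect_true(all(vapply(pre$image, function(m) all(dim(m) == 48), TRUE)))
  expect_true(all(vapply(pre$image, function(m) all(m >= 0 & m <= 1), TRUE)))
})
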