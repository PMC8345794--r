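test_that("a balanced dataset passes through unchanged", {
  withr::with_seed(1, x <- matrix(rnorm(20), 10, 2))
  lab <- rep(c("a", "b"), each = 5)
  res <- stroketex:::adasyn_core(x, lab, seed = 3)
  expect_equal(res$x, x)
  expect_false(any(res$synthetic))
})

test_that("synthetics lie on segments between minority seeds and neighbours", {
  withr::with_seed(2, {
    maj <- matrix(rnorm(12), 6, 2)
    mnr <- matrix(rnorm(6, mean = 4), 3, 2)
  })
  x <- rbind(maj, mnr)
  lab <- rep(c("maj", "min"), c(6, 3))
  res <- suppressWarnings(stroketex:::adasyn_core(x, lab, k = 5, beta = 1,
                                                  seed = 17))
  syn <- res$x[res$synthetic, , drop = FALSE]
  expect_equal(nrow(syn) + 3, sum(res$labels == "min"))
  expect_true(all(res$labels[res$synthetic] == "min"))
  # every synthetic is a convex combination of two minority originals
  on_segment <- function(s) {
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      d <- mnr[j, ] - mnr[i, ]
      lam <- sum((s - mnr[i, ]) * d) / sum(d * d)
      proj <- mnr[i, ] + lam * d
      if (lam >= 0 && lam < 1 && sqrt(sum((s - proj)^2)) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))
  # originals are retained unchanged, in order
  expect_equal(res$x[1:9, ], x)
})

test_that("the study's 222/18/27 imbalance balances to the majority count", {
  withr::with_seed(5, {
    x <- rbind(matrix(rnorm(222 * 4), 222, 4),
               matrix(rnorm(18 * 4, 2), 18, 4),
               matrix(rnorm(27 * 4, -2), 27, 4))
  })
  lab <- rep(c("PACS", "LACS", "TACS"), c(222, 18, 27))
  res <- stroketex:::adasyn_core(x, lab, k = 5, beta = 1, seed = 101)
  counts <- table(res$labels)
  expect_equal(unname(counts["PACS"]), 222)
  # each minority reaches the majority count up to per-seed rounding
  expect_lte(abs(counts[["LACS"]] - 222), 9)    # 18 seeds, half a unit each
  expect_lte(abs(counts[["TACS"]] - 222), 14)   # 27 seeds
  expect_gte(sum(counts), 640)
})

test_that("resampling is seed-deterministic with stable class counts", {
  withr::with_seed(3, x <- rbind(matrix(rnorm(16), 8, 2),
                                 matrix(rnorm(8, 3), 4, 2)))
  lab <- rep(c("a", "b"), c(8, 4))
  expect_warning(r1 <- stroketex:::adasyn_core(x, lab, seed = 7), "truncated")
  r2 <- suppressWarnings(stroketex:::adasyn_core(x, lab, seed = 7))
  r3 <- suppressWarnings(stroketex:::adasyn_core(x, lab, seed = 8))
  expect_identical(r1, r2)
  expect_equal(table(r1$labels), table(r3$labels))
  expect_false(identical(r1$x, r3$x))
})

test_that("interface validation and the tidy wrapper behave", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(stroketex:::adasyn_core(x, rep("a", 5)), "at least 2 classes")
  expect_error(stroketex:::adasyn_core(x, c("a", "a", "a", "a", "b")),
               "fewer than 2")
  withr::with_seed(4, df <- tibble::tibble(
    f1 = rnorm(12), f2 = rnorm(12),
    label = rep(c("a", "b"), c(9, 3))))
  out <- suppressWarnings(adasyn(df, seed = 5))
  expect_s3_class(out, "tbl_df")
  expect_named(out, c("f1", "f2", "label", ".synthetic"))
  expect_equal(sum(!out$.synthetic), 12)
  expect_equal(unname(table(out$label)["b"]), 9, tolerance = 2)
})

test_that("image-space balancing returns images of the original geometry", {
  withr::with_seed(9, imgs <- c(
    lapply(1:6, function(i) matrix(runif(64), 8, 8)),
    lapply(1:2, function(i) matrix(runif(64) + 1, 8, 8) / 2)))
  lab <- rep(c("maj", "min"), c(6, 2))
  res <- suppressWarnings(adasyn_images(imgs, lab, seed = 2))
  expect_true(all(vapply(res$images, function(m) all(dim(m) == c(8, 8)), TRUE)))
  expect_equal(res$images[1:8], imgs)
  expect_equal(length(res$images), length(res$labels))
})
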