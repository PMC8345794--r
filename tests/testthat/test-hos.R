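test_that("projections remove DC, localise point sources and see bar orientation", {
  expect_true(all(radon_projection(matrix(0.4, 32, 32), 45) == 0))
  # single bright centre pixel: peak at the centre bin for every angle
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  for (ang in c(1, 30, 90, 135, 180)) {
    p <- radon_projection(img, ang)
    expect_equal(which.max(p), (length(p) + 1) / 2)
  }
  # a vertical bar projects to a much taller peak at 90 degrees than at 1
  bar <- matrix(0, 64, 64); bar[, 30:34] <- 1
  p90 <- radon_projection(bar, 90)
  p1 <- radon_projection(bar, 1)
  expect_gt(max(abs(p90)), 10 * max(abs(p1)))
})

test_that("the direct bispectrum matches a full-plane oracle and its symmetry", {
  withr::with_seed(8, sig <- rnorm(24))
  B <- bispectrum_direct(sig, 32)
  BO <- oracle_bispectrum(sig, 32)
  # oracle full plane is symmetric in (f1, f2) by construction of X products
  expect_equal(BO[1:9, 1:9], t(BO[1:9, 1:9]), tolerance = 1e-9)
  # region restriction matches the oracle pointwise
  expect_equal(B$B, BO[cbind(B$f1 + 1, B$f2 + 1)], tolerance = 1e-9)
  expect_true(all(B$f2 <= B$f1 & B$f1 + B$f2 <= 16))
  expect_error(bispectrum_direct(rnorm(300), 256), "exceeds")
})

test_that("quadratic phase coupling produces the bispectral peak", {
  n <- 256; t <- 0:(n - 1)
  fa <- 0.1; fb <- 0.15
  withr::with_seed(21, {pa <- runif(1, 0, 2 * pi); pb <- runif(1, 0, 2 * pi)})
  coupled <- cos(2 * pi * fa * t + pa) + cos(2 * pi * fb * t + pb) +
    cos(2 * pi * (fa + fb) * t + pa + pb)
  B <- bispectrum_direct(coupled, 256)
  peak <- which.max(Mod(B$B))
  # argmax over the region at the (f_b, f_a) bin pair (f1 >= f2)
  expect_equal(c(B$f1[peak], B$f2[peak]), c(round(fb * 256), round(fa * 256)))
  # ensemble-averaged bispectrum: random third-component phase destroys the
  # coherent peak that the coupled triple retains (seeds 0..49)
  at_peak <- function(sig) {
    b <- bispectrum_direct(sig, 256)
    b$B[b$f1 == round(fb * 256) & b$f2 == round(fa * 256)]
  }
  uncoupled_mean <- mean(sapply(0:49, function(s) {
    withr::with_seed(s, p3 <- runif(1, 0, 2 * pi))
    at_peak(cos(2 * pi * fa * t + pa) + cos(2 * pi * fb * t + pb) +
              cos(2 * pi * (fa + fb) * t + p3))
  }))
  expect_lt(Mod(uncoupled_mean), Mod(at_peak(coupled)))
})

test_that("bispectral entropies follow point-mass and uniform conventions", {
  zero <- bispectrum_direct(rep(0, 32), 64)
  expect_equal(hos_features(zero),
               c(ent1 = 0, ent2 = 0, ent3 = 0, phase_entropy = 0, mean_mag = 0))
  # constant magnitude, phases spread uniformly over the 64 bins
  om <- stroketex:::bispec_region(64)
  npt <- length(om$f1)
  phases <- (seq_len(npt) %% 64) / 64 * 2 * pi - pi + 1e-9
  Bu <- structure(list(B = 2 * exp(1i * phases), f1 = om$f1, f2 = om$f2,
                       nfft = 64), class = "bispectrum")
  fu <- hos_features(Bu)
  expect_equal(unname(fu["ent1"]), log(npt), tolerance = 1e-9)
  expect_equal(unname(fu["mean_mag"]), 2)
  # point mass: all entropies zero
  Bp <- structure(list(B = c(3 + 0i, rep(0i, npt - 1)), f1 = om$f1,
                       f2 = om$f2, nfft = 64), class = "bispectrum")
  fp <- hos_features(Bp)
  expect_equal(unname(fp[c("ent1", "ent2", "ent3", "phase_entropy")]),
               rep(0, 4))
  # entropy never exceeds the uniform bound
  withr::with_seed(4, s <- rnorm(40))
  f <- hos_features(bispectrum_direct(s, 64))
  expect_lte(f["ent1"], log(npt))
})

test_that("the per-image HOS block has 5 features per angle and is sane", {
  cst <- hos_block(matrix(0.3, 32, 32), angles = 1:180, nfft = 64)
  expect_length(cst, 900)
  expect_true(all(cst == 0))
  withr::with_seed(13, img <- matrix(runif(48 * 48), 48, 48))
  blk <- hos_block(img, angles = seq(5, 180, by = 5), nfft = 128)
  expect_length(blk, 5 * 36)
  expect_true(all(is.finite(blk)))
  # isotropic noise: entropy-1 varies little across angles
  e1 <- blk[grepl("^hos_ent1_", names(blk))]
  expect_lt(sd(e1) / mean(e1), 0.5)
  # projections longer than nfft are handled by the centred window
  big <- hos_block(img, angles = c(45, 90), nfft = 64)
  expect_true(all(is.finite(big)))
})
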