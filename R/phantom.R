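# class-specific defaults encoding the stroke-syndrome semantics:
# LACS  - small deep/central high-contrast lacunar lesion, fine background
# PACS  - medium off-centre cortical lesion, intermediate texture scale
# TACS  - large lesion covering much of the anterior territory, coarse texture
phantom_defaults <- function(cls) {
  switch(cls,
    LACS = list(bg_corr = 3, lesion_radius = 8, lesion_contrast = 0.50,
                lesion_ecc = 0.85, offset = 0.06),
    PACS = list(bg_corr = 5, lesion_radius = 20, lesion_contrast = 0.35,
                lesion_ecc = 0.70, offset = 0.22),
    TACS = list(bg_corr = 8, lesion_radius = 55, lesion_contrast = 0.30,
                lesion_ecc = 0.80, offset = 0.12),
    abort(sprintf("Unknown phantom class '%s' (use LACS, PACS, TACS).", cls))
  )
}

# smooth Gaussian random field via FFT filtering of white noise
gaussian_field <- function(size, corr) {
  noise <- matrix(rnorm(size * size), size, size)
  f <- (seq_len(size) - 1)
  f <- pmin(f, size - f) / size           # circular frequency magnitude
  w <- exp(-2 * (pi * corr)^2 * outer(f^2, f^2, "+"))
  sm <- Re(fft(fft(noise) * w, inverse = TRUE)) / size^2
  sm / max(sd(sm), 1e-12)
}

#' Generate one synthetic stroke-phantom image
#'
#' Produces a 2D grayscale "brain slice" phantom: a smoothed Gaussian
#' random-field background inside an elliptical brain mask plus one
#' elliptical lesion whose size, contrast and location default to
#' class-specific values (LACS: small, central, high contrast; PACS:
#' medium, off-centre; TACS: large, covering over a quarter of the mask).
#' Class identity is encoded in texture statistics (background correlation
#' length, lesion geometry), not in global intensity, so the texture
#' extractors are genuinely exercised. Deterministic for a fixed seed.
#'
#' @param class `"LACS"`, `"PACS"` or `"TACS"`.
#' @param size Image side in pixels (default 200).
#' @param seed Integer seed.
#' @param bg_corr Background correlation length in pixels.
#' @param lesion_radius Lesion semi-major axis in pixels (0 = no lesion).
#' @param lesion_contrast Added lesion intensity.
#' @param lesion_ecc Minor/major axis ratio of the lesion ellipse.
#' @param offset Lesion centre offset from the brain centre, as a fraction
#'   of `size`.
#' @param noise_sd Pixel noise standard deviation (default 0.02).
#' @return `size` x `size` numeric matrix in \[0, 1\].
#' @export
phantom_image <- function(class = c("LACS", "PACS", "TACS"), size = 200,
                          seed = NULL, bg_corr = NULL, lesion_radius = NULL,
                          lesion_contrast = NULL, lesion_ecc = NULL,
                          offset = NULL, noise_sd = 0.02) {
  class <- match.arg(class)
  def <- phantom_defaults(class)
  bg_corr <- bg_corr %||% def$bg_corr
  lesion_radius <- lesion_radius %||% def$lesion_radius
  lesion_contrast <- lesion_contrast %||% def$lesion_contrast
  lesion_ecc <- lesion_ecc %||% def$lesion_ecc
  offset <- offset %||% def$offset
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  scale <- size / 200                      # defaults are given at 200 px
  if (lesion_radius * scale >= size / 2) {
    abort("`lesion_radius` must be below half the image size.")
  }
  with_seed_opt(seed, {
    y <- matrix(seq_len(size) - (size + 1) / 2, size, size)
    x <- t(y)
    mask <- (x / (0.45 * size))^2 + (y / (0.38 * size))^2 <= 1
    bg <- gaussian_field(size, bg_corr * scale)
    img <- matrix(0.05, size, size)
    img[mask] <- 0.45 + 0.10 * bg[mask]
    if (lesion_radius > 0 && lesion_contrast != 0) {
      ang <- runif(1, 0, pi)
      dir <- runif(1, 0, 2 * pi)
      cx <- offset * size * cos(dir)
      cy <- offset * size * sin(dir)
      xr <- (x - cx) * cos(ang) + (y - cy) * sin(ang)
      yr <- -(x - cx) * sin(ang) + (y - cy) * cos(ang)
      a <- lesion_radius * scale
      b <- a * lesion_ecc
      dist2 <- (xr / a)^2 + (yr / b)^2
      edge <- 1 / (1 + exp((dist2 - 1) * 12))   # soft lesion boundary
      img <- img + lesion_contrast * edge * mask
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(size^2, 0, noise_sd), size, size)
    clamp01(img)
  })
}

#' Generate a labelled phantom dataset
#'
#' Generates `n_per_class` phantoms per class with per-image seeds derived
#' from `seed`, optionally writing them to disk as 8-bit PNG files with a
#' `path,label` manifest CSV.
#'
#' @param n_per_class Named integer vector, e.g.
#'   `c(LACS = 18, PACS = 222, TACS = 27)`; unnamed vectors are taken in
#'   LACS, PACS, TACS order.
#' @param seed Base seed; per-image seeds are drawn from it.
#' @param dir Output directory (created if needed). `NULL` (default) keeps
#'   images in memory as a list-column.
#' @param size Image side in pixels (default 200).
#' @param ... Passed to [phantom_image()] (class-specific defaults apply).
#' @return Tibble manifest with columns `label`, `class_seed`, and `path`
#'   (when written) or `image` (in-memory).
#' @export
phantom_dataset <- function(n_per_class, seed = 1, dir = NULL, size = 200,
                            ...) {
  classes <- c("LACS", "PACS", "TACS")
  if (is.null(names(n_per_class))) names(n_per_class) <- classes[seq_along(n_per_class)]
  if (any(n_per_class < 1)) abort("All class counts must be at least 1.")
  label <- rep(names(n_per_class), n_per_class)
  n <- length(label)
  img_seeds <- with_seed_opt(seed, sample.int(.Machine$integer.max - 1, n))
  images <- map2(label, img_seeds,
                 function(cls, s) phantom_image(cls, size = size, seed = s, ...))
  out <- tibble(label = label, class_seed = img_seeds)
  if (is.null(dir)) {
    out$image <- images
  } else {
    if (!dir.exists(dir)) {
      ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) abort(sprintf("Cannot create output directory '%s'.", dir))
    }
    paths <- file.path(dir, sprintf("phantom_%s_%04d.png", label, seq_len(n)))
    for (i in seq_len(n)) {
      EBImage::writeImage(EBImage::Image(t(images[[i]])), paths[i], type = "png")
    }
    out$path <- paths
    readr::write_csv(out[c("path", "label")], file.path(dir, "manifest.csv"))
  }
  out
}
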