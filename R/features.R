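#' Expected feature-catalog size for a configuration
#'
#' The fused catalog holds, per sub-image (1 original + `levels` approx +
#' `levels` detail), 14 GLCM + 11 GLRLM texture features plus 5 HOS features
#' per projection angle. With the defaults (3 levels, 180 angles) that is
#' `25 * 7 + 5 * 180 * 7 = 175 + 6300 = 6475` features.
#'
#' @param config A [stroke_config()] list.
#' @return Named list: `texture`, `hos`, `total`.
#' @export
catalog_size <- function(config = stroke_config()) {
  n_sub <- 1 + 2 * config$wavelets$levels
  n_glcm <- length(config$glcm$feature_set)
  n_tex <- (n_glcm + 11) * n_sub
  n_hos <- 5 * length(config$hos$angles) * n_sub
  list(texture = n_tex, hos = n_hos, total = n_tex + n_hos)
}

#' Extract the fused feature vector of one preprocessed image
#'
#' Decomposes the image into its wavelet sub-images (original, A1..A3,
#' D1..D3), rescales each sub-image to \[0, 1\], and extracts the GLCM,
#' GLRLM and HOS feature blocks from every sub-image. Column order is
#' fixed: the GLCM block over all sub-images, then the GLRLM block, then
#' the HOS block; within a block, sub-images in the order orig, A1..A3,
#' D1..D3. Names follow `<extractor>_<feature>[_theta<angle>]_<subimage>`.
#'
#' @param img Preprocessed numeric matrix in \[0, 1\].
#' @param config A [stroke_config()] list.
#' @return Named numeric vector (length `catalog_size(config)$total`).
#' @export
extract_features_image <- function(img, config = stroke_config()) {
  ws <- dwt_stack(img, family = config$wavelets$family,
                  levels = config$wavelets$levels,
                  fusion = config$wavelets$fusion)
  subs <- subimages(ws, renormalize = TRUE)
  glcm_block <- unlist(imap(subs, function(s, nm) {
    q <- quantize_gray(s, config$glcm$levels)
    v <- glcm_features(glcm_matrix(q, distance = config$glcm$distance,
                                   angles = config$glcm$angles),
                       features = config$glcm$feature_set)
    setNames(v, paste0("glcm_", names(v), "_", nm))
  }))
  glrlm_block <- unlist(imap(subs, function(s, nm) {
    q <- quantize_gray(s, config$glrlm$levels)
    v <- glrlm_features(q, directions = config$glrlm$directions)
    setNames(v, paste0("glrlm_", names(v), "_", nm))
  }))
  hos_blk <- unlist(imap(subs, function(s, nm) {
    v <- hos_block(s, angles = config$hos$angles, nfft = config$hos$nfft,
                   phase_bins = config$hos$phase_bins)
    setNames(v, paste0(names(v), "_", nm))
  }))
  out <- c(glcm_block, glrlm_block, hos_blk)
  names(out) <- sub("^(orig|A[0-9]+|D[0-9]+)\\.", "", names(out))
  expected <- catalog_size(config)$total
  if (length(out) != expected) {
    abort(sprintf("Feature assembly produced %d columns, expected %d.",
                  length(out), expected))
  }
  if (!all(is.finite(out))) {
    abort("Feature assembly produced non-finite values.")
  }
  out
}

#' Extract the feature table of a labelled image set
#'
#' Applies [extract_features_image()] to every image and returns a tidy
#' feature table (one row per image, one column per catalog feature).
#'
#' @param data Either a manifest tibble with an `image` list-column and
#'   `label` (e.g. from [preprocess_images()] or [phantom_dataset()]), or a
#'   list of matrices with `labels` supplied.
#' @param labels Label vector when `data` is a list of matrices.
#' @param config A [stroke_config()] list.
#' @param progress Print a dot every 25 images (default FALSE).
#' @return Tibble: `id`, `label`, then the feature columns.
#' @export
extract_features <- function(data, labels = NULL, config = stroke_config(),
                             progress = FALSE) {
  if (is.data.frame(data)) {
    if (!"image" %in% names(data)) {
      abort("Manifest has no `image` column; run preprocess_images() first.")
    }
    images <- data$image
    labels <- data$label
  } else {
    images <- data
    if (is.null(labels)) abort("Supply `labels` with a list of images.")
  }
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    rows[[i]] <- extract_features_image(images[[i]], config)
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  feat <- as_tibble(do.call(rbind, rows))
  bind_cols(tibble(id = seq_along(images), label = as.character(labels)), feat)
}
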