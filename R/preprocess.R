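#' Read a grayscale image from disk
#'
#' Loads a PNG/TIFF/JPEG raster and returns it as a numeric matrix of
#' intensities in \[0, 1\] with rows indexing the vertical (y) axis and
#' columns the horizontal (x) axis. Multi-channel images are collapsed to a
#' single channel by averaging the channels, so an RGB image with equal
#' channels (0.3, 0.3, 0.3) loads as constant 0.3. Bit depth is handled by
#' the decoder: an 8-bit value of 255 and a 16-bit value of 65535 both map
#' to exactly 1.0.
#'
#' @param path Path to the image file.
#' @return Numeric matrix in \[0, 1\].
#' @seealso [resize_square()], [clahe_enhance()]
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) abort(sprintf("Image file not found: '%s'", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) abort(sprintf(
                    "Could not decode image '%s': %s", path, conditionMessage(e))))
  px <- EBImage::imageData(img)
  if (length(px) == 0) abort(sprintf("Image '%s' has zero size.", path))
  if (length(dim(px)) == 3) px <- rowMeans(px, dims = 2)
  # EBImage stores x (width) in the first dimension; transpose to row = y
  clamp01(t(px))
}

#' Resize an image to a square working resolution
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param size Output side length in pixels (default 200, the working
#'   resolution of the pipeline).
#' @param method Interpolation: `"bilinear"` (default; preserves constants
#'   and, closely, the mean) or `"nearest"`.
#' @return `size` x `size` numeric matrix in \[0, 1\].
#' @export
resize_square <- function(img, size = 200, method = c("bilinear", "nearest")) {
  assert_gray(img)
  method <- match.arg(method)
  if (size < 8) abort("`size` must be at least 8 pixels.")
  if (nrow(img) == size && ncol(img) == size) return(img)
  out <- EBImage::resize(EBImage::Image(t(img)), w = size, h = size,
                         filter = if (method == "bilinear") "bilinear" else "none")
  clamp01(t(EBImage::imageData(out)))
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Partitions the image into non-overlapping tiles, equalises each tile's
#' histogram towards uniform subject to a clip limit that prevents
#' over-amplification in flat regions, and blends the per-tile mappings with
#' bilinear interpolation to avoid tile-boundary artefacts.
#'
#' The tile geometry is given in pixels (`tile = 8` on a 200x200 image gives
#' a 25x25 tile grid); alternatively a fixed tile *grid* can be requested via
#' `grid`, matching implementations that parameterise the number of
#' contextual regions. `clip` is the normalised clip limit: the fraction of
#' the tile's pixel count at which any histogram bin is clipped (0.01 by
#' default), converted internally to the per-bin relative limit used by the
#' underlying routine (`clip * bins`).
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param tile Tile side length in pixels (default 8).
#' @param clip Normalised clip limit as a fraction of tile pixel count
#'   (default 0.01).
#' @param bins Number of histogram bins (default 256, 8-bit convention).
#' @param grid Optional integer vector `c(nx, ny)`: number of tiles across
#'   and down. When supplied it overrides `tile`.
#' @return Numeric matrix of the same shape, intensities in \[0, 1\].
#' @export
clahe_enhance <- function(img, tile = 8, clip = 0.01, bins = 256, grid = NULL) {
  assert_gray(img)
  if (is.null(grid)) {
    if (tile > min(dim(img))) {
      abort(sprintf("CLAHE tile (%d px) larger than image (%dx%d).",
                    tile, nrow(img), ncol(img)))
    }
    nx <- max(2L, round(ncol(img) / tile))
    ny <- max(2L, round(nrow(img) / tile))
  } else {
    nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  }
  nx <- min(nx, 256L); ny <- min(ny, 256L)
  out <- EBImage::clahe(EBImage::Image(t(img)), nx = nx, ny = ny,
                        bins = bins, limit = clip * bins)
  clamp01(t(EBImage::imageData(out)))
}

#' Load and preprocess a manifest of labelled images
#'
#' Applies the standard preprocessing chain (grayscale load, resize to the
#' working resolution, CLAHE) to every image listed in a manifest and returns
#' the manifest with the processed images attached as a list-column.
#'
#' @param manifest Data frame with columns `path` and `label` (labels in
#'   LACS/PACS/TACS for the stroke application, but any class set works).
#'   A list-column `image` of matrices may be supplied instead of `path`
#'   for in-memory datasets.
#' @param size Working resolution (default 200).
#' @param tile,clip CLAHE parameters, see [clahe_enhance()].
#' @return The manifest as a tibble with a list-column `image` of
#'   preprocessed `size` x `size` matrices.
#' @export
preprocess_images <- function(manifest, size = 200, tile = 8, clip = 0.01) {
  manifest <- as_tibble(manifest)
  if (!"label" %in% names(manifest)) abort("`manifest` must have a `label` column.")
  imgs <- if ("image" %in% names(manifest)) {
    manifest$image
  } else if ("path" %in% names(manifest)) {
    map(manifest$path, read_gray)
  } else {
    abort("`manifest` must have a `path` or `image` column.")
  }
  manifest$image <- map(imgs, function(im) {
    clahe_enhance(resize_square(im, size = size), tile = tile, clip = clip)
  })
  manifest
}

#' Quantize a grayscale image to discrete levels
#'
#' Uniformly bins intensities in \[0, 1\] into `levels` gray levels
#' `0 .. levels - 1`, the representation consumed by the GLCM and GLRLM
#' extractors.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param levels Number of gray levels (default 8).
#' @return Integer matrix with values in `0 .. levels - 1` and attribute
#'   `levels`.
#' @export
quantize_gray <- function(img, levels = 8) {
  if (levels < 2) abort("`levels` must be at least 2.")
  q <- pmin(floor(img * levels), levels - 1)
  storage.mode(q) <- "integer"
  attr(q, "levels") <- as.integer(levels)
  q
}

gray_levels <- function(imgq) {
  lv <- attr(imgq, "levels")
  if (is.null(lv)) abort("Image is not quantized; call quantize_gray() first.")
  lv
}

#' Plot a grayscale image
#'
#' Convenience ggplot2 raster display with the row/column orientation used
#' throughout the package.
#'
#' @param img Numeric matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_gray <- function(img, title = NULL) {
  df <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}
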