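# Orthonormal analysis filter banks. db2/db4 are the standard Daubechies
# minimum-phase coefficients; highpass is the quadrature mirror of lowpass.
wavelet_filters <- function(family) {
  lo <- switch(family,
    haar = c(1, 1) / sqrt(2),
    db2  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4  = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
             -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
             0.032883011666982945, -0.010597401784997278),
    abort(sprintf("Unsupported wavelet family '%s' (use haar, db2, db4).", family))
  )
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  list(lo = lo, hi = hi)
}

# one periodized decimated filtering step along a vector (odd lengths extend
# by replicating the last sample, so output length is ceiling(n / 2))
dwt_step_1d <- function(x, f) {
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
  L <- length(f)
  idx <- outer(seq(1, n, by = 2), seq_len(L) - 1, "+")
  idx <- (idx - 1) %% n + 1
  drop(matrix(x[idx], ncol = L) %*% f)
}

# apply a decimated filter to every column of a matrix
dwt_step_cols <- function(m, f) {
  out <- apply(m, 2, dwt_step_1d, f = f)
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)  # 1-row result
  out
}

dwt2_level <- function(img, flt) {
  # columns first (vertical), then rows (horizontal)
  lo_c <- dwt_step_cols(img, flt$lo)
  hi_c <- dwt_step_cols(img, flt$hi)
  list(
    a = t(dwt_step_cols(t(lo_c), flt$lo)),  # approximation  (LL)
    h = t(dwt_step_cols(t(hi_c), flt$lo)),  # horizontal detail (rows low, cols high)
    v = t(dwt_step_cols(t(lo_c), flt$hi)),  # vertical detail
    g = t(dwt_step_cols(t(hi_c), flt$hi))   # diagonal detail
  )
}

fuse_details <- function(h, v, g, fusion) {
  switch(fusion,
    mean_abs = (abs(h) + abs(v) + abs(g)) / 3,
    diagonal = g,
    max_abs  = pmax(abs(h), abs(v), abs(g)),
    abort(sprintf("Unknown detail fusion rule '%s'.", fusion))
  )
}

#' Multi-level 2D discrete wavelet decomposition
#'
#' Decomposes an image into `levels` dyadic levels. Each level yields one
#' approximation image `A_k` and one detail image `D_k`; because a separable
#' 2D DWT produces three detail subbands per level (horizontal, vertical,
#' diagonal), `D_k` is obtained by a configurable fusion rule:
#' `"mean_abs"` (default) averages the absolute subbands, `"diagonal"` keeps
#' the diagonal subband, `"max_abs"` takes the elementwise absolute maximum.
#' Boundaries are handled by periodization, so subband shapes halve
#' (ceiling) exactly at each level and orthonormal families conserve energy
#' across the level-1 subbands.
#'
#' @param img Numeric matrix; both dimensions must be at least `2^levels`.
#' @param family Wavelet family: `"haar"` (default), `"db2"`, `"db4"`.
#' @param levels Number of decomposition levels (default 3).
#' @param fusion Detail-fusion rule, see above.
#' @return An object of class `wavelet_stack`: list with `original`,
#'   `approx` (list `A1..A<levels>`), `detail` (list `D1..D<levels>`),
#'   `family`, `fusion`.
#' @export
dwt_stack <- function(img, family = "haar", levels = 3, fusion = "mean_abs") {
  assert_gray(img)
  if (min(dim(img)) < 2^levels) {
    abort(sprintf("Image %dx%d too small for %d decomposition levels.",
                  nrow(img), ncol(img), levels))
  }
  flt <- wavelet_filters(family)
  approx <- vector("list", levels)
  detail <- vector("list", levels)
  cur <- img
  for (k in seq_len(levels)) {
    sub <- dwt2_level(cur, flt)
    approx[[k]] <- sub$a
    detail[[k]] <- fuse_details(sub$h, sub$v, sub$g, fusion)
    cur <- sub$a
  }
  names(approx) <- paste0("A", seq_len(levels))
  names(detail) <- paste0("D", seq_len(levels))
  structure(list(original = img, approx = approx, detail = detail,
                 family = family, fusion = fusion, levels = levels),
            class = "wavelet_stack")
}

#' @export
print.wavelet_stack <- function(x, ...) {
  cat(sprintf("<wavelet_stack> family=%s fusion=%s levels=%d\n",
              x$family, x$fusion, x$levels))
  for (k in seq_len(x$levels)) {
    cat(sprintf("  A%d/D%d: %dx%d\n", k, k,
                nrow(x$approx[[k]]), ncol(x$approx[[k]])))
  }
  invisible(x)
}

#' Sub-images of a wavelet stack
#'
#' Returns the 7 images (for 3 levels) that the feature extractors consume:
#' the original plus A1..A3 and D1..D3, in that fixed order. Each sub-image
#' is optionally rescaled to \[0, 1\] so gray-level quantization is
#' well-defined per sub-image; a constant sub-image rescales to all zeros.
#'
#' @param ws A `wavelet_stack`.
#' @param renormalize Rescale each sub-image to \[0, 1\] (default TRUE).
#' @return Named list of matrices: `orig`, `A1..`, `D1..`.
#' @export
subimages <- function(ws, renormalize = TRUE) {
  stopifnot(inherits(ws, "wavelet_stack"))
  out <- c(list(orig = ws$original), ws$approx, ws$detail)
  if (renormalize) out <- lapply(out, renorm01)
  out
}
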