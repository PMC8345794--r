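#' Round half away from zero
#'
#' Decimal rounding in which a digit of exactly 5 rounds up (97.375 -> 97.38),
#' the convention used by the study tables this package reproduces. Base R's
#' `round()` rounds to even and is affected by binary representation
#' (`round(0.925, 2)` gives 0.92), which cannot reproduce those tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector; `NA` values pass through.
#' @examples
#' round_half_up(c(0.925, 97.375), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(img) < 8 || ncol(img) < 8) {
    abort(sprintf("`%s` must be at least 8x8 pixels, got %dx%d.",
                  arg, nrow(img), ncol(img)))
  }
  if (!all(is.finite(img))) abort(sprintf("`%s` contains non-finite values.", arg))
  invisible(img)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# rescale a matrix to [0, 1]; a constant matrix maps to all zeros
renorm01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= .Machine$double.eps * max(1, abs(r[2]))) {
    return(matrix(0, nrow(x), ncol(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

# run `expr` under a temporary RNG state seeded with `seed` (NULL = use
# current RNG stream untouched)
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# derive a named substream seed from a run seed, kept inside 32-bit range
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + offs) %% .Machine$integer.max)
}
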