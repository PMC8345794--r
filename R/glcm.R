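# offsets (row shift, col shift) for the standard GLCM angles
glcm_offset <- function(angle, distance) {
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    abort(sprintf("Unsupported GLCM angle %s (use 0, 45, 90, 135).", angle))
  )
}

glcm_count_matrix <- function(imgq, dr, dc, L) {
  nr <- nrow(imgq); nc <- ncol(imgq)
  if (abs(dr) >= nr || abs(dc) >= nc) {
    abort(sprintf("GLCM offset (%d,%d) does not fit a %dx%d image.",
                  dr, dc, nr, nc))
  }
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- imgq[r1, c1, drop = FALSE]
  b <- imgq[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate(a * L + b + 1L, nbins = L * L)
  matrix(counts, nrow = L, ncol = L, byrow = TRUE)
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs at the given pixel distance and
#' angles, symmetrises each directional matrix (so p(i, j) = p(j, i)),
#' averages over the angles, and normalises to a joint probability matrix.
#'
#' @param imgq Quantized image from [quantize_gray()].
#' @param distance Pixel offset distance (default 1).
#' @param angles Angles in degrees, subset of `c(0, 45, 90, 135)`.
#' @param symmetric Symmetrise pair counts (default TRUE).
#' @param average Average matrices over angles before normalisation
#'   (default TRUE); if FALSE a list of per-angle matrices is returned.
#' @return An object of class `glcm_matrix`: list with probability matrix
#'   `P` (L x L, summing to 1), `levels`, `angles`, `distance`,
#'   `symmetric` — or a list of such objects when `average = FALSE`.
#' @export
glcm_matrix <- function(imgq, distance = 1, angles = c(0, 45, 90, 135),
                        symmetric = TRUE, average = TRUE) {
  L <- gray_levels(imgq)
  mats <- lapply(angles, function(a) {
    off <- glcm_offset(a, distance)
    m <- glcm_count_matrix(imgq, off[1], off[2], L)
    if (symmetric) m <- m + t(m)
    m
  })
  wrap <- function(P, angs) {
    structure(list(P = P / sum(P), levels = L, angles = angs,
                   distance = distance, symmetric = symmetric),
              class = "glcm_matrix")
  }
  if (average) {
    wrap(Reduce(`+`, mats) / length(mats), angles)
  } else {
    lapply(seq_along(mats), function(i) wrap(mats[[i]], angles[i]))
  }
}

# entropy helper with the 0 * log 0 = 0 convention (natural log)
shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' GLCM feature registry
#'
#' Returns the named list of implemented GLCM feature functions. The default
#' feature set used by [glcm_features()] holds 14 features: the twelve named
#' in the source feature list (autocorrelation, maximum probability,
#' dissimilarity, entropy, cluster shade, sum average, sum entropy,
#' sum variance, difference variance, difference entropy, and the two
#' information measures of correlation) completed with contrast and
#' homogeneity. Cluster prominence is also implemented and can be swapped in
#' via the `features` argument of [glcm_features()].
#'
#' Conventions: gray-level indices are 0-based; logarithms are natural;
#' sum variance follows Haralick's original definition (second moment of
#' the level-sum distribution about the sum entropy value).
#'
#' @return Named list of functions taking a `glcm_matrix`.
#' @export
glcm_feature_registry <- function() {
  list(
    autocorrelation    = function(s) sum(s$I * s$J * s$P),
    max_probability    = function(s) max(s$P),
    dissimilarity      = function(s) sum(abs(s$I - s$J) * s$P),
    entropy            = function(s) shannon(s$P),
    cluster_shade      = function(s) sum((s$I + s$J - s$mux - s$muy)^3 * s$P),
    cluster_prominence = function(s) sum((s$I + s$J - s$mux - s$muy)^4 * s$P),
    homogeneity        = function(s) sum(s$P / (1 + (s$I - s$J)^2)),
    contrast           = function(s) sum((s$I - s$J)^2 * s$P),
    sum_average        = function(s) sum(s$ksum * s$psum),
    sum_entropy        = function(s) shannon(s$psum),
    sum_variance       = function(s) sum((s$ksum - shannon(s$psum))^2 * s$psum),
    difference_variance = function(s) {
      mu <- sum(s$kdiff * s$pdiff)
      sum((s$kdiff - mu)^2 * s$pdiff)
    },
    difference_entropy = function(s) shannon(s$pdiff),
    imc1 = function(s) {
      denom <- max(s$HX, s$HY)
      if (denom == 0) {
        inform("IMC1: zero marginal entropy; returning 0.")
        return(0)
      }
      (s$HXY - s$HXY1) / denom
    },
    imc2 = function(s) sqrt(max(0, 1 - exp(-2 * (s$HXY2 - s$HXY))))
  )
}

glcm_default_features <- function() {
  setdiff(names(glcm_feature_registry()), "cluster_prominence")
}

# precompute the shared terms the feature functions use
glcm_state <- function(M) {
  P <- M$P
  L <- M$levels
  lev <- 0:(L - 1)
  I <- matrix(lev, L, L)          # row index = first level
  J <- matrix(lev, L, L, byrow = TRUE)
  px <- rowSums(P); py <- colSums(P)
  # level-sum / level-difference distributions
  ksum <- 0:(2 * L - 2)
  psum <- vapply(ksum, function(k) sum(P[I + J == k]), numeric(1))
  kdiff <- 0:(L - 1)
  pdiff <- vapply(kdiff, function(k) sum(P[abs(I - J) == k]), numeric(1))
  pxpy <- outer(px, py)
  pos <- P > 0 & pxpy > 0
  HXY1 <- -sum(P[pos] * log(pxpy[pos]))
  HXY2 <- shannon(pxpy)
  list(P = P, I = I, J = J, mux = sum(lev * px), muy = sum(lev * py),
       ksum = ksum, psum = psum, kdiff = kdiff, pdiff = pdiff,
       HX = shannon(px), HY = shannon(py), HXY = shannon(P),
       HXY1 = HXY1, HXY2 = HXY2)
}

#' GLCM texture features
#'
#' Computes the 14 default co-occurrence features (see
#' [glcm_feature_registry()]) from a GLCM, or from a quantized image (the
#' matrix is then built with [glcm_matrix()] defaults).
#'
#' @param x A `glcm_matrix` or a quantized image.
#' @param features Character vector of registry names (default: the 14
#'   standard features).
#' @param ... Passed to [glcm_matrix()] when `x` is an image.
#' @return Named numeric vector of features.
#' @export
glcm_features <- function(x, features = glcm_default_features(), ...) {
  M <- if (inherits(x, "glcm_matrix")) x else glcm_matrix(x, ...)
  reg <- glcm_feature_registry()
  bad <- setdiff(features, names(reg))
  if (length(bad)) abort(sprintf("Unknown GLCM features: %s",
                                 paste(bad, collapse = ", ")))
  s <- glcm_state(M)
  vapply(reg[features], function(f) f(s), numeric(1))
}
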