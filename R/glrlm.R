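# pixel scan order for run extraction along a direction: returns the vector
# of pixel indices ordered line-by-line plus the line id of each pixel
glrlm_scan_plan <- function(nr, nc, direction) {
  key <- sprintf("glrlm_%d_%d_%s", nr, nc, direction)
  cache_get_or(key, function() {
    row <- matrix(seq_len(nr), nr, nc)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    sw <- switch(as.character(direction),
      "0"   = list(line = row, pos = col),            # left -> right
      "90"  = list(line = col, pos = row),            # top -> bottom
      "45"  = list(line = row + col, pos = col),      # anti-diagonals, up-right
      "135" = list(line = col - row, pos = col),      # diagonals, down-right
      abort(sprintf("Unsupported GLRLM direction %s.", direction))
    )
    ord <- order(as.vector(sw$line), as.vector(sw$pos))
    list(ord = ord, line = as.vector(sw$line)[ord])
  })
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along one scan direction. Row `i`
#' of the count matrix corresponds to gray level `i - 1`, column `l` to run
#' length `l`. Every pixel belongs to exactly one run, so
#' `sum(R * run_length)` equals the pixel count.
#'
#' @param imgq Quantized image from [quantize_gray()].
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @return Object of class `glrlm_matrix`: list with counts `R`
#'   (levels x max run length), `levels`, `direction`, `pixel_total`.
#' @export
glrlm_matrix <- function(imgq, direction = 0) {
  L <- gray_levels(imgq)
  plan <- glrlm_scan_plan(nrow(imgq), ncol(imgq), direction)
  v <- as.vector(imgq)[plan$ord]
  n <- length(v)
  new_run <- c(TRUE, v[-1] != v[-n] | plan$line[-1] != plan$line[-n])
  run_id <- cumsum(new_run)
  lengths <- tabulate(run_id)
  levels_of_run <- v[new_run]
  rmax <- max(nrow(imgq), ncol(imgq))
  counts <- tabulate((lengths - 1L) * L + levels_of_run + 1L, nbins = L * rmax)
  R <- matrix(counts, nrow = L, ncol = rmax)
  structure(list(R = R, levels = L, direction = direction,
                 pixel_total = n),
            class = "glrlm_matrix")
}

#' GLRLM texture features from a run-length matrix
#'
#' The 11 classical run-length features (Galloway; Chu; Dasarathy & Holder):
#' short/long run emphasis, gray-level and run-length non-uniformity, run
#' percentage, low/high gray-level run emphasis and the four joint
#' short/long x low/high emphases. Gray-level indices are 1-based in the
#' emphasis weights so level 0 does not divide by zero.
#'
#' @param R A `glrlm_matrix`.
#' @return Named numeric vector of 11 features.
#' @export
glrlm_features_from_matrix <- function(R) {
  stopifnot(inherits(R, "glrlm_matrix"))
  m <- R$R
  N <- sum(m)
  if (N == 0) abort("Empty run-length matrix (no runs).")
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))        # 1-based gray level
  l <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  c(
    sre   = sum(m / l^2) / N,
    lre   = sum(m * l^2) / N,
    gln   = sum(rowSums(m)^2) / N,
    rln   = sum(colSums(m)^2) / N,
    rp    = N / R$pixel_total,
    lgre  = sum(m / i^2) / N,
    hgre  = sum(m * i^2) / N,
    srlge = sum(m / (i^2 * l^2)) / N,
    srhge = sum(m * i^2 / l^2) / N,
    lrlge = sum(m * l^2 / i^2) / N,
    lrhge = sum(m * i^2 * l^2) / N
  )
}

#' Direction-averaged GLRLM features
#'
#' Computes the 11 run-length features per scan direction and averages the
#' feature values across directions (the rotation-robust protocol).
#'
#' @param imgq Quantized image.
#' @param directions Degrees, default `c(0, 45, 90, 135)`.
#' @return Named numeric vector of 11 features.
#' @export
glrlm_features <- function(imgq, directions = c(0, 45, 90, 135)) {
  per_dir <- vapply(directions,
                    function(d) glrlm_features_from_matrix(glrlm_matrix(imgq, d)),
                    numeric(11))
  rowMeans(per_dir)
}
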