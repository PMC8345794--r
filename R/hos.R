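# unit-spaced detector bin of every pixel for a projection angle; memoized
# per image shape. Beams travel along the direction at `angle` degrees from
# the horizontal axis; the detector axis is perpendicular, so at 90 degrees
# the image is integrated along vertical lines (columns).
radon_plan <- function(nr, nc, angle) {
  key <- sprintf("radon_%d_%d_%s", nr, nc, format(angle))
  cache_get_or(key, function() {
    th <- angle * pi / 180
    y <- matrix(seq_len(nr) - (nr + 1) / 2, nr, nc)
    x <- matrix(seq_len(nc) - (nc + 1) / 2, nr, nc, byrow = TRUE)
    t_pos <- x * sin(th) - y * cos(th)
    half <- ceiling(sqrt(((nr - 1) / 2)^2 + ((nc - 1) / 2)^2))
    bin <- round(t_pos) + half + 1
    list(bin = as.vector(bin), nbins = 2L * half + 1L)
  })
}

#' Radon-style line projection of an image
#'
#' Projects the mean-subtracted image onto the detector axis perpendicular
#' to the beam direction at `angle` degrees, sampled at unit pixel spacing.
#' A vertical bar therefore produces its sharpest peak at 90 degrees.
#'
#' @param img Numeric matrix.
#' @param angle Angle in degrees (the pipeline uses 1..180).
#' @return Numeric vector: the projection signal.
#' @export
radon_projection <- function(img, angle) {
  plan <- radon_plan(nrow(img), ncol(img), angle)
  v <- as.vector(img - mean(img))
  sums <- rep(0, plan$nbins)
  agg <- rowsum(v, plan$bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  sums
}

# Omega: the non-redundant bispectral frequency region
# {(f1, f2): 0 <= f2 <= f1, f1 + f2 <= nfft/2}, as 1-based FFT indices
bispec_region <- function(nfft) {
  key <- sprintf("omega_%d", nfft)
  cache_get_or(key, function() {
    half <- nfft %/% 2
    f1 <- rep.int(0:half, pmin(0:half, half - (0:half)) + 1)
    f2 <- unlist(lapply(0:half, function(a) 0:min(a, half - a)))
    list(f1 = f1, f2 = f2, i1 = f1 + 1L, i2 = f2 + 1L, i12 = f1 + f2 + 1L)
  })
}

#' Direct (single-segment) bispectrum estimate
#'
#' Computes `B(f1, f2) = X(f1) X(f2) conj(X(f1 + f2))` from the zero-padded
#' discrete Fourier transform `X` of the signal, restricted to the
#' non-redundant triangular region `0 <= f2 <= f1`, `f1 + f2 <= nfft / 2`.
#' The bispectrum detects quadratic phase coupling: a triple of sinusoids at
#' `f_a`, `f_b`, `f_a + f_b` with phases that add coherently produces a peak
#' at `(f_a, f_b)`.
#'
#' @param sig Numeric signal of length at most `nfft`.
#' @param nfft Transform length (default 256).
#' @return Object of class `bispectrum`: list with complex values `B` over
#'   the region, frequency index vectors `f1`, `f2`, and `nfft`.
#' @export
bispectrum_direct <- function(sig, nfft = 256) {
  if (length(sig) > nfft) {
    abort(sprintf("Signal length %d exceeds nfft = %d.", length(sig), nfft))
  }
  X <- fft(c(sig, rep(0, nfft - length(sig))))
  om <- bispec_region(nfft)
  structure(list(B = X[om$i1] * X[om$i2] * Conj(X[om$i12]),
                 f1 = om$f1, f2 = om$f2, nfft = nfft),
            class = "bispectrum")
}

# normalized-magnitude entropy of order q over the region
bispec_entropy <- function(mag, q) {
  w <- mag^q
  s <- sum(w)
  if (s == 0) return(0)
  shannon(w / s)
}

#' Bispectral (HOS) features
#'
#' Five features over the non-redundant region: the normalised bispectral
#' entropies of order 1, 2 and 3 (Shannon entropy of `|B|^q / sum |B|^q`),
#' the phase entropy (Shannon entropy of the histogram of `arg B` over
#' `phase_bins` uniform bins spanning (-pi, pi\]), and the mean bispectral
#' magnitude. An identically zero bispectrum yields all five features 0 by
#' convention.
#'
#' @param B A `bispectrum`.
#' @param phase_bins Number of phase histogram bins (default 64).
#' @return Named numeric vector: `ent1`, `ent2`, `ent3`, `phase_entropy`,
#'   `mean_mag`.
#' @export
hos_features <- function(B, phase_bins = 64) {
  stopifnot(inherits(B, "bispectrum"))
  mag <- Mod(B$B)
  if (sum(mag) == 0) {
    return(c(ent1 = 0, ent2 = 0, ent3 = 0, phase_entropy = 0, mean_mag = 0))
  }
  ph <- Arg(B$B)
  # bins over (-pi, pi]: index in 1..phase_bins
  bin <- ceiling((ph + pi) / (2 * pi) * phase_bins)
  bin[bin < 1] <- 1L
  p_ph <- tabulate(bin, nbins = phase_bins) / length(ph)
  c(ent1 = bispec_entropy(mag, 1),
    ent2 = bispec_entropy(mag, 2),
    ent3 = bispec_entropy(mag, 3),
    phase_entropy = shannon(p_ph),
    mean_mag = mean(mag))
}

# fit a projection into the nfft window: drop all-zero tails, then center-crop
# (cropped samples are image-corner contributions beyond the window)
fit_to_nfft <- function(sig, nfft) {
  nz <- which(sig != 0)
  if (length(nz) == 0) return(numeric(0))
  sig <- sig[nz[1]:nz[length(nz)]]
  n <- length(sig)
  if (n > nfft) {
    start <- (n - nfft) %/% 2 + 1
    sig <- sig[start:(start + nfft - 1)]
  }
  sig
}

#' Full HOS feature block of an image
#'
#' Computes the five bispectral features of the radon projection at each
#' angle, yielding `5 * length(angles)` features (900 for the default
#' 1..180 degree grid). Feature names follow
#' `hos_<feature>_theta<angle>` ordering feature-major.
#'
#' @param img Numeric matrix.
#' @param angles Projection angles in degrees (default `1:180`).
#' @param nfft Bispectrum transform length (default 256).
#' @param phase_bins Phase histogram bins (default 64).
#' @return Named numeric vector of `5 * length(angles)` features.
#' @export
hos_block <- function(img, angles = 1:180, nfft = 256, phase_bins = 64) {
  per_angle <- vapply(angles, function(a) {
    sig <- fit_to_nfft(radon_projection(img, a), nfft)
    if (length(sig) == 0) {
      c(ent1 = 0, ent2 = 0, ent3 = 0, phase_entropy = 0, mean_mag = 0)
    } else {
      hos_features(bispectrum_direct(sig, nfft), phase_bins = phase_bins)
    }
  }, numeric(5))
  fnames <- rownames(per_angle)
  out <- as.vector(t(per_angle))   # feature-major: all angles of ent1, ...
  names(out) <- as.vector(outer(paste0("theta", angles), fnames,
                                function(a, f) paste0("hos_", f, "_", a)))
  out
}
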