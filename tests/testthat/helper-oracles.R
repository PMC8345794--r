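# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use naive double loops and walk-based
# enumeration so they share no code with the package internals.

# quantized random image fixture
random_quantized <- function(nr, nc, levels, seed) {
  withr::with_seed(seed, {
    q <- matrix(sample(0:(levels - 1), nr * nc, replace = TRUE), nr, nc)
  })
  storage.mode(q) <- "integer"
  attr(q, "levels") <- as.integer(levels)
  q
}

# GLCM features by explicit double loops over the probability matrix
oracle_glcm_features <- function(P) {
  L <- nrow(P)
  lev <- 0:(L - 1)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  acc_ <- maxp <- dis <- ent <- shade <- hom <- con <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    p <- P[i, j]; a <- lev[i]; b <- lev[j]
    acc_ <- acc_ + a * b * p
    maxp <- max(maxp, p)
    dis <- dis + abs(a - b) * p
    if (p > 0) ent <- ent - p * log(p)
    shade <- shade + (a + b - mux - muy)^3 * p
    hom <- hom + p / (1 + (a - b)^2)
    con <- con + (a - b)^2 * p
  }
  psum <- numeric(2 * L - 1)
  pdif <- numeric(L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    psum[lev[i] + lev[j] + 1] <- psum[lev[i] + lev[j] + 1] + P[i, j]
    pdif[abs(lev[i] - lev[j]) + 1] <- pdif[abs(lev[i] - lev[j]) + 1] + P[i, j]
  }
  ks <- 0:(2 * L - 2); kd <- 0:(L - 1)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  se <- H(psum)
  sa <- sum(ks * psum)
  sv <- sum((ks - se)^2 * psum)
  mud <- sum(kd * pdif)
  dv <- sum((kd - mud)^2 * pdif)
  de <- H(pdif)
  hx <- H(px); hy <- H(py)
  hxy1 <- hxy2 <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    pp <- px[i] * py[j]
    if (pp > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log(pp)
      hxy2 <- hxy2 - pp * log(pp)
    }
  }
  imc1 <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(autocorrelation = acc_, max_probability = maxp, dissimilarity = dis,
    entropy = ent, cluster_shade = shade, homogeneity = hom, contrast = con,
    sum_average = sa, sum_entropy = se, sum_variance = sv,
    difference_variance = dv, difference_entropy = de, imc1 = imc1,
    imc2 = imc2)
}

# run-length matrix by walking every line pixel by pixel
oracle_glrlm_matrix <- function(imgq, direction) {
  L <- attr(imgq, "levels")
  nr <- nrow(imgq); nc <- ncol(imgq)
  step <- switch(as.character(direction),
                 "0" = c(0, 1), "90" = c(1, 0), "45" = c(-1, 1), "135" = c(1, 1))
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]; pc <- c - step[2]
    if (pr < 1 || pr > nr || pc < 1 || pc > nc) {
      starts[[length(starts) + 1]] <- c(r, c)
    }
  }
  R <- matrix(0, L, max(nr, nc))
  for (s in starts) {
    r <- s[1]; c <- s[2]
    run_val <- imgq[r, c]; run_len <- 1
    repeat {
      r2 <- r + step[1]; c2 <- c + step[2]
      inside <- r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc
      if (inside && imgq[r2, c2] == run_val) {
        run_len <- run_len + 1
      } else {
        R[run_val + 1, run_len] <- R[run_val + 1, run_len] + 1
        if (!inside) break
        run_val <- imgq[r2, c2]; run_len <- 1
      }
      r <- r2; c <- c2
    }
  }
  R
}

# one-way ANOVA by two-pass sums of squares
oracle_anova_f <- function(values, labels) {
  groups <- split(values, labels)
  n <- length(values); g <- length(groups)
  gm <- mean(values)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  (ssb / (g - 1)) / (ssw / (n - g))
}

# full-plane direct bispectrum by double loop (small nfft only)
oracle_bispectrum <- function(sig, nfft) {
  X <- stats::fft(c(sig, rep(0, nfft - length(sig))))
  half <- nfft %/% 2
  B <- matrix(complex(real = 0), half + 1, half + 1)
  for (f1 in 0:half) for (f2 in 0:half) {
    if (f1 + f2 <= half) {
      B[f1 + 1, f2 + 1] <- X[f1 + 1] * X[f2 + 1] * Conj(X[f1 + f2 + 1])
    }
  }
  B
}
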