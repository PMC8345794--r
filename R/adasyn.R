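#' ADASYN adaptive synthetic oversampling
#'
#' Balances a multi-class dataset by generating synthetic minority-class
#' vectors, following the adaptive synthetic sampling scheme: each minority
#' class (taken in ascending order of size, one-vs-rest against the largest
#' class) receives `G = (m_majority - m_class) * beta` synthetic vectors,
#' allocated to minority seeds in proportion to their learning difficulty
#' `r_i` = fraction of the seed's `k` nearest neighbours (in the full
#' original set, Euclidean distance) that belong to other classes. A
#' synthetic vector is a convex combination `x_i + lambda (x_z - x_i)` of
#' the seed and a random one of its `k` nearest same-class neighbours, with
#' `lambda` uniform in \[0, 1). All original rows are retained unchanged.
#' When every `r_i` is 0 (no foreign neighbours anywhere), allocation falls
#' back to uniform so the class is still balanced.
#'
#' @param data Data frame (or matrix) of numeric columns plus the label
#'   column, or a plain numeric matrix if `labels` is given.
#' @param label Name of the label column when `data` is a data frame
#'   (default `"label"`).
#' @param labels Vector of class labels when `data` is a matrix.
#' @param k Neighbour count (default 5); truncated with a warning when a
#'   class is too small.
#' @param beta Balancing degree in \[0, 1\] (default 1: full balance).
#' @param seed Integer seed for reproducibility (optional).
#' @return A tibble with the original columns plus a logical `.synthetic`
#'   column; original rows first, in their input order.
#' @examples
#' set.seed(1)
#' df <- tibble::tibble(x = rnorm(12), y = rnorm(12),
#'                      label = rep(c("a", "b"), c(9, 3)))
#' adasyn(df, seed = 7)
#' @export
adasyn <- function(data, label = "label", labels = NULL, k = 5, beta = 1,
                   seed = NULL) {
  if (is.matrix(data)) {
    if (is.null(labels)) abort("Supply `labels` when `data` is a matrix.")
    x <- data
    lab <- as.character(labels)
    df_cols <- NULL
  } else {
    data <- as_tibble(data)
    if (!label %in% names(data)) {
      abort(sprintf("Label column '%s' not found.", label))
    }
    lab <- as.character(data[[label]])
    x <- as.matrix(data[setdiff(names(data), label)])
    df_cols <- setdiff(names(data), label)
  }
  if (!is.numeric(x)) abort("Feature columns must all be numeric.")
  res <- adasyn_core(x, lab, k = k, beta = beta, seed = seed)
  out <- as_tibble(as.data.frame(res$x))
  if (!is.null(df_cols)) names(out) <- df_cols
  out[[if (is.null(df_cols)) "label" else label]] <- res$labels
  out$.synthetic <- res$synthetic
  out
}

adasyn_core <- function(x, labels, k = 5, beta = 1, seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (k < 1) abort("`k` must be at least 1.")
  counts <- table(labels)
  if (length(counts) < 2) abort("ADASYN needs at least 2 classes.")
  m_maj <- max(counts)
  minorities <- names(counts)[counts < m_maj]
  small <- minorities[counts[minorities] < 2]
  if (length(small)) {
    abort(sprintf("Minority class with fewer than 2 members: %s",
                  paste(small, collapse = ", ")))
  }
  # full-set pairwise distances once (original rows only)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  syn_list <- list()
  syn_lab <- character(0)
  with_seed_opt(seed, {
    for (cls in minorities[order(counts[minorities])]) {
      idx <- which(labels == cls)
      m_min <- length(idx)
      G <- round((m_maj - m_min) * beta)
      if (G <= 0) next
      kk <- min(k, nrow(x) - 1)
      if (kk > m_min - 1) {
        warn(sprintf(
          "ADASYN: k = %d exceeds class '%s' size; truncated to %d.",
          k, cls, m_min - 1))
        kk_min <- m_min - 1
      } else {
        kk_min <- kk
      }
      # difficulty: foreign fraction among k nearest neighbours in full set
      r <- vapply(idx, function(i) {
        nn <- order(d[i, ])[seq_len(kk)]
        mean(labels[nn] != cls)
      }, numeric(1))
      rhat <- if (sum(r) == 0) rep(1 / m_min, m_min) else r / sum(r)
      g <- round_half_up(rhat * G, 0)
      # same-class neighbour lists
      for (j in seq_along(idx)) {
        if (g[j] == 0) next
        i <- idx[j]
        others <- idx[idx != i]
        nn_min <- others[order(d[i, others])][seq_len(kk_min)]
        z <- nn_min[sample.int(length(nn_min), g[j], replace = TRUE)]
        lam <- runif(g[j])
        syn <- x[rep(i, g[j]), , drop = FALSE] +
          lam * (x[z, , drop = FALSE] - x[rep(i, g[j]), , drop = FALSE])
        syn_list[[length(syn_list) + 1]] <- syn
        syn_lab <- c(syn_lab, rep(cls, g[j]))
      }
    }
  })
  syn <- if (length(syn_list)) do.call(rbind, syn_list) else
    matrix(numeric(0), 0, ncol(x))
  list(x = rbind(x, syn),
       labels = c(labels, syn_lab),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(syn))))
}

#' Balance a set of images in flattened-pixel space
#'
#' Applies [adasyn()] to flattened preprocessed images, the image-space
#' balancing used ahead of feature extraction in this pipeline, and returns
#' the augmented image list. The leakage-safer alternative of balancing in
#' feature space is available by calling [adasyn()] on the feature table
#' instead.
#'
#' @param images List of equally-sized numeric matrices.
#' @param labels Class label per image.
#' @param k,beta,seed See [adasyn()].
#' @return List with `images` (originals then synthetics), `labels`,
#'   `synthetic` (logical).
#' @export
adasyn_images <- function(images, labels, k = 5, beta = 1, seed = NULL) {
  stopifnot(length(images) == length(labels))
  dims <- dim(images[[1]])
  flat <- do.call(rbind, lapply(images, as.vector))
  res <- adasyn_core(flat, as.character(labels), k = k, beta = beta, seed = seed)
  list(images = lapply(seq_len(nrow(res$x)),
                       function(i) matrix(res$x[i, ], dims[1], dims[2])),
       labels = res$labels,
       synthetic = res$synthetic)
}
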