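#' One-way ANOVA F statistic for a single feature
#'
#' `F = MS_between / MS_within` across the label groups, with the p-value
#' from the F distribution on `(g - 1, n - g)` degrees of freedom.
#' Degenerate conventions: zero within-group variance with non-zero
#' between-group variance gives `F = Inf, p = 0`; an entirely constant
#' feature gives `F = 0, p = 1`.
#'
#' @param values Numeric vector of per-sample feature values.
#' @param labels Group labels (at least 2 groups of at least 2 members).
#' @return Named list with `f` and `p`.
#' @export
anova_f <- function(values, labels) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2) abort("ANOVA needs at least 2 groups.")
  if (any(counts < 2)) {
    abort(sprintf("Group(s) with fewer than 2 members: %s",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  res <- anova_f_matrix(matrix(values, ncol = 1), labels)
  list(f = res$f[1], p = res$p[1])
}

# vectorized one-way ANOVA across the columns of a matrix
anova_f_matrix <- function(x, labels) {
  labels <- as.character(labels)
  n <- nrow(x)
  g <- length(unique(labels))
  grp_sum <- rowsum(x, labels)
  grp_n <- as.vector(table(labels)[rownames(grp_sum)])
  tot_mean <- colMeans(x)
  grp_mean <- grp_sum / grp_n
  ssb <- colSums(grp_n * (sweep(grp_mean, 2, tot_mean))^2)
  sst <- colSums(sweep(x, 2, tot_mean)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  eps <- .Machine$double.eps * pmax(sst, 1)
  f <- ifelse(ssw <= eps,
              ifelse(ssb <= eps, 0, Inf),
              msb / msw)
  p <- ifelse(is.infinite(f), 0,
              ifelse(f == 0 & ssb <= eps, 1,
                     pf(f, g - 1, n - g, lower.tail = FALSE)))
  list(f = as.numeric(f), p = as.numeric(p))
}

#' Rank features by ANOVA F-value
#'
#' Computes the one-way ANOVA F statistic of every feature column across the
#' label groups and orders the features from the largest F down to the
#' smallest (equivalently smallest p to largest, since the F tail is
#' monotone). Ties are broken by original column position, so ranking is
#' deterministic.
#'
#' @param data Data frame of numeric feature columns plus a label column, or
#'   a numeric matrix with `labels` given.
#' @param label Label column name (default `"label"`); ignored for matrices.
#' @param labels Label vector for matrix input.
#' @return Tibble with columns `feature`, `column` (original position),
#'   `f_value`, `p_value`, `rank`, ordered by rank.
#' @export
rank_features <- function(data, label = "label", labels = NULL) {
  if (is.matrix(data)) {
    if (is.null(labels)) abort("Supply `labels` when `data` is a matrix.")
    x <- data
    lab <- labels
  } else {
    data <- as.data.frame(data)
    if (!label %in% names(data)) abort(sprintf("Label column '%s' not found.", label))
    lab <- data[[label]]
    keep <- setdiff(names(data), label)
    num <- vapply(data[keep], is.numeric, logical(1))
    x <- as.matrix(data[keep[num]])
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  res <- anova_f_matrix(x, lab)
  ord <- order(-res$f, seq_len(ncol(x)))
  tibble(feature = colnames(x)[ord],
         column = ord,
         f_value = res$f[ord],
         p_value = res$p[ord],
         rank = seq_len(ncol(x)))
}

#' Plot the top-ranked features
#'
#' @param ranking Output of [rank_features()].
#' @param top Number of features to show (default 30).
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranking, top = 30) {
  df <- head(ranking, top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_value, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "ANOVA F-value", y = NULL,
                  title = sprintf("Top %d features by F-value", nrow(df))) +
    ggplot2::theme_minimal()
}
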