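#' SVM kernel specification
#'
#' The four kernels evaluated by the pipeline: linear (first-order
#' polynomial), second- and third-order polynomial, and the radial basis
#' function kernel. Hyperparameters default to `C = 1`, polynomial
#' `coef0 = 1`, and RBF `gamma = 1 / (n_features * var(X))` computed on the
#' standardized training matrix at fit time.
#'
#' @param kind One of `"linear"`, `"poly2"`, `"poly3"`, `"rbf"`.
#' @param cost Regularisation weight C (> 0).
#' @param gamma RBF kernel width (> 0); `NULL` = computed at fit time.
#' @param coef0 Polynomial kernel offset.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "poly2", "poly3", "rbf"),
                        cost = 1, gamma = NULL, coef0 = 1) {
  kind <- match.arg(kind)
  if (cost <= 0) abort("`cost` must be positive.")
  if (!is.null(gamma) && gamma <= 0) abort("`gamma` must be positive.")
  structure(list(kind = kind,
                 degree = switch(kind, linear = 1, poly2 = 2, poly3 = 3, rbf = NA),
                 cost = cost, gamma = gamma, coef0 = coef0),
            class = "kernel_spec")
}

as_kernel_spec <- function(kernel) {
  if (inherits(kernel, "kernel_spec")) kernel else kernel_spec(kernel)
}

# standardize columns with train statistics (constant columns left centred)
fit_scaler <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mu = mu, s = s)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$s, "/")

#' Fit an SVM and predict test labels
#'
#' Standardizes features with training-split statistics, fits a C-SVM with
#' the requested kernel (multiclass by one-vs-one voting), and predicts the
#' test rows. Deterministic for fixed inputs.
#'
#' @param train_x,test_x Numeric matrices with matching columns.
#' @param train_y Training labels (at least 2 classes).
#' @param kernel A [kernel_spec()] or kernel name.
#' @return Factor of predicted test labels.
#' @export
svm_fit_predict <- function(train_x, train_y, test_x, kernel = "rbf") {
  spec <- as_kernel_spec(kernel)
  train_y <- factor(train_y)
  if (nlevels(droplevels(train_y)) < 2) {
    abort("Training data contains a single class; cannot fit an SVM.")
  }
  sc <- fit_scaler(train_x)
  xs <- apply_scaler(train_x, sc)
  ts <- apply_scaler(test_x, sc)
  gamma <- spec$gamma %||% {
    v <- var(as.vector(xs))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(xs) * v)
  }
  fit <- e1071::svm(
    x = xs, y = droplevels(train_y),
    kernel = switch(spec$kind, linear = "linear", rbf = "radial",
                    poly2 = "polynomial", poly3 = "polynomial"),
    degree = if (spec$kind %in% c("poly2", "poly3")) spec$degree else 3,
    coef0 = spec$coef0, gamma = gamma, cost = spec$cost, scale = FALSE)
  predict(fit, ts)
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, folds, seed = NULL) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < folds)) {
    abort(sprintf(
      "Class(es) with fewer than %d members (%s); use fewer folds.",
      folds, paste(names(counts)[counts < folds], collapse = ", ")))
  }
  assign <- integer(length(labels))
  start <- 0L
  with_seed_opt(seed, {
    for (cls in names(counts)) {
      idx <- sample(which(labels == cls))
      # stagger the round-robin start per class so remainders spread over
      # different folds and total test sizes differ by at most one
      assign[idx] <- (start + seq_along(idx) - 1L) %% folds + 1L
      start <- (start + length(idx)) %% folds
    }
  })
  assign
}

#' Sequential forward selection over a ranked feature list
#'
#' Greedy single pass over the features in rank order: a candidate feature
#' is added to the selection if it strictly improves the internal validation
#' accuracy (mean accuracy over a stratified `inner_folds`-fold split of the
#' training data). The pass stops after `patience` consecutive
#' non-improvements (`patience = 0`: stop at the first), after
#' `max_features` features have been kept, or when the ranked list is
#' exhausted.
#'
#' @param x Training feature matrix.
#' @param y Training labels.
#' @param ranked Integer vector: feature column indices in rank order
#'   (e.g. the `column` column of [rank_features()]).
#' @param kernel A [kernel_spec()] or kernel name.
#' @param max_features Selection budget (default 50).
#' @param patience Consecutive non-improvements tolerated (default 5).
#' @param inner_folds Internal CV folds (default 5).
#' @param seed Seed for the internal fold split.
#' @return List with `selected` (column indices, in selection order) and
#'   `score` (the internal validation accuracy achieved).
#' @export
sfs_select <- function(x, y, ranked, kernel = "rbf", max_features = 50,
                       patience = 5, inner_folds = 5, seed = NULL) {
  if (nrow(x) == 0) abort("Empty training split.")
  y <- factor(y)
  fold_of <- stratified_folds(y, inner_folds, seed = seed)
  score_set <- function(cols) {
    acc <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold_of != f
      pred <- svm_fit_predict(x[tr, cols, drop = FALSE], y[tr],
                              x[!tr, cols, drop = FALSE], kernel)
      mean(pred == y[!tr])
    }, numeric(1))
    mean(acc)
  }
  selected <- integer(0)
  best <- 0
  fails <- 0
  max_fails <- max(patience, 1)
  for (cand in ranked) {
    sc <- score_set(c(selected, cand))
    if (sc > best) {
      best <- sc
      selected <- c(selected, cand)
      fails <- 0
      if (length(selected) >= max_features) break
    } else {
      fails <- fails + 1
      if (fails >= max_fails) break
    }
  }
  list(selected = selected, score = best)
}

# collapse a multiclass test outcome to binary confusion counts.
# "reference": the reference class plays the negative role; every test
#   sample contributes one count (TP/FN for non-reference samples classified
#   correctly/incorrectly, TN/FP likewise for reference samples), so
#   ACC equals plain multiclass accuracy.
# "micro": micro-averaged one-vs-rest sums over classes.
collapse_confusion <- function(true, pred, collapse = c("reference", "micro"),
                               reference = NULL) {
  collapse <- match.arg(collapse)
  true <- as.character(true); pred <- as.character(pred)
  if (collapse == "reference") {
    if (is.null(reference)) abort("Reference class required for this collapse.")
    correct <- true == pred
    neg <- true == reference
    c(tp = sum(correct & !neg), tn = sum(correct & neg),
      fp = sum(!correct & neg), fn = sum(!correct & !neg))
  } else {
    classes <- sort(unique(c(true, pred)))
    tp <- sum(true == pred)
    fp <- fn <- 0
    for (cls in classes) {
      fp <- fp + sum(pred == cls & true != cls)
      fn <- fn + sum(true == cls & pred != cls)
    }
    tn <- length(true) * length(classes) - tp - fp - fn
    c(tp = tp, tn = tn, fp = fp, fn = fn)
  }
}

#' Stratified k-fold cross-validation of the SVM pipeline
#'
#' Splits the samples into stratified folds; on each fold's training part
#' ranks the features ([rank_features()], unless a fixed global ranking is
#' supplied), runs sequential forward selection, fits the SVM, and predicts
#' the held-out part. The fold's multiclass confusion is collapsed to binary
#' TP/TN/FP/FN counts (see Details) from which the five reported metrics are
#' computed; the summary row averages the unrounded per-fold metrics.
#'
#' Collapse rule: by default (`collapse = "reference"`) the reference class
#' (the most frequent class unless given) acts as the negative class and
#' each test sample contributes exactly one count, so the reported ACC
#' equals plain multiclass accuracy. `collapse = "micro"` gives
#' micro-averaged one-vs-rest counts instead.
#'
#' @param data Feature data frame with a label column, or numeric matrix
#'   with `labels`.
#' @param label Label column name (default `"label"`).
#' @param labels Label vector for matrix input.
#' @param kernel A [kernel_spec()] or kernel name (default `"rbf"`).
#' @param folds Number of folds (default 10).
#' @param seed Seed controlling fold assignment and SFS inner splits.
#' @param ranking Optional fixed ranking (output of [rank_features()]) used
#'   for every fold ("global" mode); default `NULL` re-ranks on each fold's
#'   training part, which avoids selection leakage.
#' @param max_features,patience SFS controls, see [sfs_select()].
#' @param inner_folds Internal SFS validation folds (default 5, reduced
#'   automatically when a training class is smaller).
#' @param collapse `"reference"` (default) or `"micro"`.
#' @param reference Reference class for the collapse; default the most
#'   frequent label (ties: alphabetically first).
#' @return Object of class `cv_report`: list with `folds` (per-fold tibble
#'   of counts, metrics, selected features), `summary` (one-row tibble),
#'   `kernel`, `collapse`, `reference`, `selected` (per-fold index lists).
#' @export
cross_validate <- function(data, label = "label", labels = NULL,
                           kernel = "rbf", folds = 10, seed = NULL,
                           ranking = NULL, max_features = 50, patience = 5,
                           inner_folds = 5,
                           collapse = c("reference", "micro"),
                           reference = NULL) {
  collapse <- match.arg(collapse)
  if (is.matrix(data)) {
    if (is.null(labels)) abort("Supply `labels` when `data` is a matrix.")
    x <- data; lab <- as.character(labels)
  } else {
    data <- as.data.frame(data)
    lab <- as.character(data[[label]])
    keep <- setdiff(names(data), c(label, ".synthetic"))
    x <- as.matrix(data[keep])
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  spec <- as_kernel_spec(kernel)
  if (is.null(reference)) {
    counts <- table(lab)
    reference <- names(counts)[order(-counts, names(counts))][1]
  }
  fold_of <- stratified_folds(lab, folds, seed = derive_seed(seed, "cv"))
  ranked_global <- if (!is.null(ranking)) ranking$column else NULL
  fold_rows <- vector("list", folds)
  selected_list <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    ranked <- ranked_global %||%
      rank_features(x[tr, , drop = FALSE], labels = lab[tr])$column
    inner <- max(2, min(inner_folds, min(table(lab[tr]))))
    sel <- sfs_select(x[tr, , drop = FALSE], lab[tr], ranked, spec,
                      max_features = max_features, patience = patience,
                      inner_folds = inner,
                      seed = derive_seed(seed, paste0("sfs", f)))
    pred <- svm_fit_predict(x[tr, sel$selected, drop = FALSE], lab[tr],
                            x[!tr, sel$selected, drop = FALSE], spec)
    cc <- unname(collapse_confusion(lab[!tr], pred, collapse, reference))
    met <- metrics_from_counts(cc[1], cc[2], cc[3], cc[4])
    met$fold <- f
    met$n_test <- sum(!tr)
    met$n_selected <- length(sel$selected)
    fold_rows[[f]] <- met
    selected_list[[f]] <- colnames(x)[sel$selected]
  }
  fold_tbl <- bind_rows(fold_rows)
  fold_tbl <- fold_tbl[c("fold", "n_test", "n_selected",
                         "tp", "tn", "fp", "fn",
                         "acc", "ppv", "sen", "spe", "dice")]
  structure(list(folds = fold_tbl,
                 summary = aggregate_folds(fold_tbl),
                 kernel = spec, collapse = collapse, reference = reference,
                 selected = selected_list),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> kernel=%s, %d folds, collapse=%s (reference: %s)\n",
              x$kernel$kind, nrow(x$folds), x$collapse, x$reference))
  s <- x$summary
  cat(sprintf("  ACC %.2f%%  PPV %.2f%%  SEN %.2f%%  SPE %.2f%%  Dice %.2f\n",
              s$acc, s$ppv, s$sen, s$spe, s$dice))
  invisible(x)
}

#' Compare SVM kernels under cross-validation
#'
#' Runs [cross_validate()] once per kernel and assembles the fold-averaged
#' metrics into a comparison table.
#'
#' @inheritParams cross_validate
#' @param kernels Character vector of kernel names (default all four).
#' @return List with `table` (tibble: kernel + averaged metrics, rounded to
#'   the 2-decimal presentation convention) and `reports` (named list of
#'   `cv_report`s).
#' @export
compare_kernels <- function(data, label = "label", labels = NULL,
                            kernels = c("linear", "poly2", "poly3", "rbf"),
                            ...) {
  reports <- lapply(kernels, function(k) {
    cross_validate(data, label = label, labels = labels, kernel = k, ...)
  })
  names(reports) <- kernels
  tab <- bind_rows(lapply(kernels, function(k) {
    s <- reports[[k]]$summary
    tibble(kernel = k,
           sen = round_half_up(s$sen), spe = round_half_up(s$spe),
           ppv = round_half_up(s$ppv), acc = round_half_up(s$acc),
           dice = round_half_up(s$dice))
  }))
  list(table = tab, reports = reports)
}
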