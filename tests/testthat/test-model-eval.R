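test_that("metric arithmetic handles spot rows, perfection and degeneracy", {
  m <- metrics_from_counts(37, 21, 1, 6)
  expect_equal(round_half_up(c(m$acc, m$ppv, m$sen, m$spe, m$dice)),
               c(89.23, 97.37, 86.05, 95.45, 0.91))
  m2 <- metrics_from_counts(43, 21, 1, 1)
  expect_equal(round_half_up(c(m2$acc, m2$ppv, m2$sen, m2$spe, m2$dice)),
               c(96.97, 97.73, 97.73, 95.45, 0.98))
  perf <- metrics_from_counts(10, 10, 0, 0)
  expect_equal(c(perf$acc, perf$ppv, perf$sen, perf$spe, perf$dice),
               c(100, 100, 100, 100, 1))
  # zero denominators are NA, never silently 0
  nd <- metrics_from_counts(0, 5, 0, 0)
  expect_true(is.na(nd$ppv) && is.na(nd$sen) && is.na(nd$dice))
  expect_equal(nd$acc, 100)
  expect_error(metrics_from_counts(0, 0, 0, 0), "zero")
  # Dice is the harmonic mean of PPV and SEN
  withr::with_seed(1, cc <- matrix(sample(0:40, 40, TRUE), 10, 4))
  mm <- metrics_from_counts(cc[, 1], cc[, 2], cc[, 3], cc[, 4] + 1)
  ok <- !is.na(mm$ppv) & !is.na(mm$sen) & (mm$ppv + mm$sen) > 0
  expect_equal(mm$dice[ok],
               (2 * mm$ppv[ok] * mm$sen[ok] / (mm$ppv[ok] + mm$sen[ok])) / 100,
               tolerance = 1e-12)
})

test_that("fold aggregation sums counts and means metrics", {
  one <- metrics_from_counts(37, 21, 1, 6)
  expect_equal(aggregate_folds(one), one)
  two <- metrics_from_counts(c(10, 20), c(10, 20), c(0, 2), c(0, 2))
  agg <- aggregate_folds(two)
  expect_equal(agg$tp, 30)
  expect_equal(agg$acc, mean(two$acc))
})

test_that("forward selection finds a separating feature and honours budgets", {
  withr::with_seed(11, {
    n <- 60
    lab <- rep(c("A", "B", "C"), each = n / 3)
    sepf <- rep(c(0, 10, 20), each = n / 3) + rnorm(n, 0, 0.1)
    x <- cbind(sepf, matrix(rnorm(n * 9), n, 9))
  })
  colnames(x) <- paste0("f", 1:10)
  rk <- rank_features(x, labels = lab)
  sel <- sfs_select(x, lab, rk$column, kernel = "linear", seed = 11)
  expect_true(1 %in% sel$selected)
  expect_equal(sel$score, 1)
  sel1 <- sfs_select(x, lab, rk$column, kernel = "linear",
                     max_features = 1, seed = 11)
  expect_length(sel1$selected, 1)
  # patience 0: the selection is the strictly-improving prefix of the list
  sel0 <- sfs_select(x, lab, rk$column, kernel = "linear", patience = 0,
                     seed = 11)
  expect_equal(sel0$selected, rk$column[seq_along(sel0$selected)])
  expect_error(sfs_select(x[0, ], character(0), 1:10), "Empty")
})

test_that("SVM kernels separate what they should separate", {
  withr::with_seed(3, {
    tr <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 4), 20, 2))
    te <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 4), 10, 2))
    ylab <- rep(c("a", "b"), each = 20)
    yte <- rep(c("a", "b"), each = 10)
    # XOR pattern
    xor_x <- cbind(runif(200, -1, 1), runif(200, -1, 1))
    xor_y <- ifelse(xor_x[, 1] * xor_x[, 2] > 0, "p", "n")
  })
  pred <- svm_fit_predict(tr, ylab, te, "linear")
  expect_equal(as.character(pred), yte)
  idx <- 1:150
  rbf_acc <- mean(svm_fit_predict(xor_x[idx, ], xor_y[idx], xor_x[-idx, ],
                                  "rbf") == xor_y[-idx])
  lin_acc <- mean(svm_fit_predict(xor_x[idx, ], xor_y[idx], xor_x[-idx, ],
                                  "linear") == xor_y[-idx])
  expect_gt(rbf_acc, lin_acc)
  expect_error(svm_fit_predict(tr, rep("a", 40), te), "single class")
  expect_error(kernel_spec("rbf", cost = -1), "positive")
})

test_that("stratified folds partition 666 samples into 66/67-sized test sets", {
  lab <- rep(c("L", "P", "T"), each = 222)
  fold_of <- stroketex:::stratified_folds(lab, 10, seed = 4)
  sizes <- as.vector(table(fold_of))
  expect_true(all(sizes %in% c(66, 67)))
  expect_equal(sum(sizes), 666)
  # every index lands in exactly one test fold
  expect_equal(sort(unlist(lapply(1:10, function(f) which(fold_of == f)))),
               1:666)
  expect_error(stroketex:::stratified_folds(rep(c("a", "b"), c(5, 40)), 10),
               "fewer than 10")
})

test_that("confusion collapse rules are internally consistent", {
  true <- c("L", "L", "P", "P", "P", "T")
  pred <- c("L", "P", "P", "P", "T", "T")
  cc <- stroketex:::collapse_confusion(true, pred, "reference", reference = "P")
  # reference class P is the negative: 4 correct of 6, one P misclassified
  expect_equal(unname(cc), c(2, 2, 1, 1))   # tp tn fp fn
  m <- metrics_from_counts(cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]])
  expect_equal(m$acc, 100 * mean(true == pred))
  mic <- stroketex:::collapse_confusion(true, pred, "micro")
  expect_equal(unname(mic["tp"]), 4)
  expect_equal(sum(mic), 3 * length(true))
})

test_that("cross-validation produces a coherent report on separable data", {
  withr::with_seed(19, {
    n <- 90
    lab <- rep(c("A", "B", "C"), each = 30)
    x <- cbind(rep(c(0, 6, 12), each = 30) + rnorm(n),
               rep(c(5, 0, 5), each = 30) + rnorm(n),
               matrix(rnorm(n * 3), n, 3))
  })
  colnames(x) <- paste0("f", 1:5)
  rep_ <- cross_validate(x, labels = lab, kernel = "rbf", folds = 5,
                         seed = 2, max_features = 3, patience = 1)
  expect_s3_class(rep_, "cv_report")
  expect_equal(nrow(rep_$folds), 5)
  expect_equal(sum(rep_$folds$n_test), 90)
  expect_gt(rep_$summary$acc, 90)
  # tidiers
  td <- tidy(rep_)
  expect_equal(nrow(td), 5)
  expect_equal(td$kernel[1], "rbf")
  gl <- glance(rep_)
  expect_equal(gl$acc, rep_$summary$acc)
  expect_s3_class(autoplot(rep_), "ggplot")
  # per-fold metrics reproduce from their own counts
  re <- metrics_from_counts(rep_$folds)
  expect_equal(re$acc, rep_$folds$acc)
})
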