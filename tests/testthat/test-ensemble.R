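sep_data <- function(n_per = 30, d = 6, gap = 3, seed = 1, classes = 2) {
  with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(classes), function(k)
      matrix(rnorm(n_per * d, mean = gap * k), n_per, d)))
  })
  colnames(X) <- paste0("x", seq_len(d))
  list(X = X, y = factor(rep(letters[seq_len(classes)], each = n_per)))
}

as_fm <- function(X, y) {
  meta <- data.frame(transform = "tqwt", subband = 1, channel = 1,
                     feature = colnames(X))
  wavestate:::new_feature_matrix(X, y, meta)
}

test_that("bagging with L = 1 behaves as a single bootstrap learner", {
  dd <- sep_data()
  m <- bagging_fit(dd$X, dd$y, L = 1, seed = 4)
  expect_length(m$members, 1)
  expect_identical(predict(m, dd$X),
                   wavestate:::predict_tree(m$members[[1]], dd$X))
})

test_that("bagged trees separate linearly separable classes perfectly", {
  dd <- sep_data(gap = 4)
  m <- bagging_fit(dd$X, dd$y, L = 50, seed = 1)
  expect_equal(mean(predict(m, dd$X) == dd$y), 1.0)
})

test_that("fits are reproducible and invariant to duplicated columns", {
  dd <- sep_data(gap = 1.5)
  p1 <- predict(bagging_fit(dd$X, dd$y, L = 20, seed = 7), dd$X)
  p2 <- predict(bagging_fit(dd$X, dd$y, L = 20, seed = 7), dd$X)
  expect_identical(p1, p2)
  Xdup <- cbind(dd$X, dd$X)
  colnames(Xdup) <- paste0("x", seq_len(ncol(Xdup)))
  p3 <- predict(bagging_fit(Xdup, dd$y, L = 20, seed = 7), Xdup)
  expect_identical(p1, p3)
})

test_that("every ensemble method fits and predicts on 3-class data", {
  dd <- sep_data(n_per = 20, gap = 3, classes = 3)
  for (meth in wavestate:::ENSEMBLE_METHODS) {
    m <- fit_ensemble(learner_spec(meth, L = 15), dd$X, dd$y, seed = 2)
    acc <- mean(predict(m, dd$X) == dd$y)
    expect_gte(acc, 0.9)
    votes <- predict(m, dd$X, type = "vote")
    expect_equal(dim(votes), c(nrow(dd$X), 3))
    expect_equal(unname(rowSums(votes)), rep(1, nrow(dd$X)),
                 tolerance = 1e-12)
  }
})

test_that("metrics match hand-computed confusion arithmetic", {
  # one-vs-rest for class "pos": Tp = 9, Fn = 1, Fp = 2, Tn = 8
  truth <- factor(c(rep("pos", 10), rep("neg", 10)), levels = c("neg", "pos"))
  pred <- factor(c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos"),
                 levels = c("neg", "pos"))
  rep <- metrics_report(truth, pred)
  pos <- rep$per_class[rep$per_class$class == "pos", ]
  expect_equal(pos$recall, 0.90)
  expect_equal(pos$specificity, 0.80)
  expect_equal(pos$precision, 9 / 11)
  expect_equal(pos$f1, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))
  expect_equal(rep$accuracy, 0.85)
  # the printed-variant flag swaps the roles of Tp and Tn
  rep2 <- metrics_report(truth, pred, paper_eq11 = TRUE)
  pos2 <- rep2$per_class[rep2$per_class$class == "pos", ]
  expect_equal(pos2$recall, 0.80)
  expect_equal(pos2$specificity, 0.90)
})

test_that("a perfect predictor scores 1 everywhere", {
  truth <- factor(rep(c("a", "b", "c"), each = 5))
  rep <- metrics_report(truth, truth)
  expect_equal(rep$accuracy, 1)
  expect_true(all(rep$per_class[, c("recall", "specificity", "precision",
                                    "f1")] == 1))
})

test_that("random guessing on balanced 3-class data stays near 1/3", {
  y <- factor(rep(c("a", "b", "c"), each = 680))
  accs <- vapply(1:20, function(s) {
    pred <- with_seed(s, factor(sample(levels(y), length(y), TRUE),
                                levels = levels(y)))
    metrics_report(y, pred)$accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.28 & accs <= 0.39))
})

test_that("stratified folds preserve class balance within one segment", {
  y <- factor(rep(c("a", "b", "c"), each = 50))
  folds <- wavestate:::make_folds(y, cv_scheme("kfold_10"), seed = 3)
  expect_length(folds, 10)
  expect_setequal(unlist(folds), seq_along(y))
  for (f in folds) {
    tab <- table(y[f])
    expect_lte(max(tab) - min(tab), 1)
  }
  hold <- wavestate:::make_folds(y, cv_scheme("holdout_80_20"), seed = 3)
  expect_equal(length(hold[[1]]), 30)
  expect_equal(as.integer(table(y[hold[[1]]])), rep(10L, 3))
})

test_that("pooled accuracy equals the segment-weighted fold mean", {
  dd <- sep_data(n_per = 25, gap = 1, classes = 3)
  rep <- evaluate_cv(learner_spec("bagged_tree", L = 10), as_fm(dd$X, dd$y),
                     cv_scheme("kfold_5"), seed = 2)
  expect_equal(rep$accuracy,
               sum(rep$fold_accuracy * rep$fold_sizes) / sum(rep$fold_sizes),
               tolerance = 1e-12)
})

test_that("evaluation is bit-reproducible under a fixed seed", {
  dd <- sep_data(n_per = 20, gap = 1.2, classes = 3)
  fm <- as_fm(dd$X, dd$y)
  r1 <- evaluate_cv(learner_spec("bagged_tree", L = 15), fm,
                    cv_scheme("kfold_5"), seed = 11)
  r2 <- evaluate_cv(learner_spec("bagged_tree", L = 15), fm,
                    cv_scheme("kfold_5"), seed = 11)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$per_class, r2$per_class)
})

test_that("random search returns the budgeted history and best candidate", {
  dd <- sep_data(n_per = 15, gap = 3, classes = 3)
  fm <- as_fm(dd$X, dd$y)
  opt1 <- optimize_ensemble(fm, budget = 1, cv_scheme("kfold_5"), seed = 5)
  expect_equal(nrow(opt1$history), 1)
  expect_equal(opt1$best_accuracy, opt1$history$accuracy[1])
  opt <- optimize_ensemble(fm, budget = 4, cv_scheme("kfold_5"), seed = 5)
  expect_equal(nrow(opt$history), 4)
  expect_equal(opt$best_accuracy, max(opt$history$accuracy, na.rm = TRUE))
  expect_s3_class(opt$best_model, "wv_ensemble")
})

test_that("iterative majority voting tracks round and fold maxima", {
  dd <- sep_data(n_per = 20, gap = 2, classes = 3)
  fm <- as_fm(dd$X, dd$y)
  spec <- learner_spec("bagged_tree", L = 10)
  one <- imv_tfcv(spec, fm, rounds = 1, base_seed = 3)
  expect_length(one$round_accuracy, 1)
  expect_equal(one$best_overall_accuracy, one$round_accuracy[1])
  imv <- imv_tfcv(spec, fm, rounds = 3, base_seed = 3)
  expect_gte(imv$best_overall_accuracy, mean(imv$round_accuracy))
  expect_gte(imv$best_foldwise_accuracy, imv$best_overall_accuracy)
  expect_equal(dim(imv$fold_accuracy), c(3, 10))
})

test_that("vote-fraction ROC separates classes with informative features", {
  dd <- sep_data(n_per = 25, gap = 2, classes = 3)
  m <- fit_ensemble(learner_spec("bagged_tree", L = 25), dd$X, dd$y,
                    seed = 1)
  rocs <- ensemble_roc(m, as_fm(dd$X, dd$y))
  aucs <- vapply(rocs, function(r) as.numeric(pROC::auc(r)), numeric(1))
  expect_named(aucs, c("a", "b", "c"))
  expect_true(all(aucs > 0.9))
})

test_that("non-stratified folds that lose a class advise stratification", {
  y <- factor(c(rep("a", 20), rep("b", 20), "c"))
  X <- matrix(rnorm(41 * 3), 41, 3, dimnames = list(NULL, paste0("x", 1:3)))
  fm <- as_fm(X, y)
  expect_error(
    evaluate_cv(learner_spec("bagged_tree", L = 5), fm,
                cv_scheme("kfold_10", stratified = FALSE), seed = 1),
    "stratified")
})

test_that("CV accuracy rises with class separation", {
  accs <- vapply(c(0, 1, 2.5), function(gap) {
    mean(vapply(1:3, function(s) {
      dd <- sep_data(n_per = 20, d = 4, gap = gap, seed = s, classes = 3)
      evaluate_cv(learner_spec("bagged_tree", L = 15), as_fm(dd$X, dd$y),
                  cv_scheme("kfold_5"), seed = s)$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(accs[2] > accs[1] - 0.05 && accs[3] > accs[2] - 0.05)
  expect_gt(accs[3], accs[1])
})
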