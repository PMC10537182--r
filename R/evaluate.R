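# Model evaluation: holdout (80:20), five-fold and ten-fold
# cross-validation, with one-vs-rest confusion metrics per class and
# iterative majority voting (repeated ten-fold rounds keeping the best
# overall and best fold-wise accuracy).

#' Cross-validation scheme
#' @param kind `"holdout_80_20"`, `"kfold_5"` or `"kfold_10"`.
#' @param stratified preserve class proportions per fold (default TRUE).
#' @return A list of class `"CVScheme"`.
#' @export
cv_scheme <- function(kind = c("kfold_10", "kfold_5", "holdout_80_20"),
                      stratified = TRUE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, stratified = stratified,
                 n_folds = switch(kind, holdout_80_20 = 1L, kfold_5 = 5L,
                                  kfold_10 = 10L)),
            class = "CVScheme")
}

# list of test-index vectors, one per fold
make_folds <- function(y, scheme, seed) {
  n <- length(y)
  with_seed(seed, {
    if (scheme$kind == "holdout_80_20") {
      test <- if (scheme$stratified) {
        unlist(lapply(levels(y), function(cl) {
          ix <- which(y == cl)
          sample(ix, max(1L, round(0.2 * length(ix))))
        }), use.names = FALSE)
      } else sample.int(n, max(1L, round(0.2 * n)))
      return(list(sort(test)))
    }
    k <- scheme$n_folds
    fold_of <- integer(n)
    if (scheme$stratified) {
      # cycle fold ids across class strata so fold sizes stay within +-1
      # overall even when a class has fewer members than folds
      offset <- 0L
      for (cl in levels(y)) {
        ix <- sample(which(y == cl))
        fold_of[ix] <- (offset + seq_along(ix) - 1L) %% k + 1L
        offset <- offset + length(ix)
      }
    } else {
      fold_of <- sample(rep_len(seq_len(k), n))
    }
    lapply(seq_len(k), function(f) which(fold_of == f))
  })
}

#' Classification metrics report
#'
#' One-vs-rest confusion counts per class plus overall accuracy. The
#' conventional definitions are used: recall = Tp/(Tp+Fn) on the positive
#' class, specificity = Tn/(Tn+Fp), precision = Tp/(Tp+Fp), F1 the
#' harmonic mean of recall and precision. `paper_eq11 = TRUE` computes the
#' variant with the roles of Tp and Tn exchanged in recall/specificity.
#'
#' @param truth,pred factors over the same levels.
#' @param paper_eq11 use the swapped recall/specificity variant.
#' @return A `MetricsReport`: list with `accuracy`, `per_class` (data frame
#'   with Tp, Tn, Fp, Fn, recall, specificity, precision, f1) and
#'   `confusion` (full cross-table).
#' @export
metrics_report <- function(truth, pred, paper_eq11 = FALSE) {
  lv <- levels(truth)
  pred <- factor(pred, levels = lv)
  per <- do.call(rbind, lapply(lv, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    if (paper_eq11) {
      rec <- tn / (fp + tn); spe <- tp / (fn + tp)
    } else {
      rec <- tp / (tp + fn); spe <- tn / (tn + fp)
    }
    ppv <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1 <- if (rec + ppv == 0) 0 else 2 * rec * ppv / (rec + ppv)
    data.frame(class = cl, Tp = tp, Tn = tn, Fp = fp, Fn = fn,
               recall = rec, specificity = spe, precision = ppv, f1 = f1)
  }))
  structure(list(accuracy = mean(pred == truth), per_class = per,
                 confusion = table(truth = truth, predicted = pred)),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("<MetricsReport> accuracy %.4f\n", x$accuracy))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cross-validated evaluation of a learner specification
#'
#' Refits the learner on each training fold, predicts the held-out fold,
#' pools the out-of-fold predictions and reports metrics.
#'
#' @param spec a [learner_spec()] (or a fitted search result's `best_spec`).
#' @param fm a `FeatureMatrix`.
#' @param scheme a [cv_scheme()].
#' @param seed RNG seed (folds and member resamples).
#' @param paper_eq11 passed to [metrics_report()].
#' @return A `MetricsReport` with extra fields `fold_accuracy` and
#'   `fold_sizes`.
#' @export
evaluate_cv <- function(spec, fm, scheme = cv_scheme("kfold_10"), seed = 1,
                        paper_eq11 = FALSE) {
  y <- droplevels(fm$labels)
  X <- fm$values
  folds <- make_folds(y, scheme, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    if (length(test) == 0) { fold_acc[f] <- NA_real_; next }
    ytr <- droplevels(y[-test])
    if (nlevels(ytr) < nlevels(y))
      stop("a fold is missing a class; use a stratified scheme")
    model <- fit_ensemble(spec, X[-test, , drop = FALSE], y[-test],
                          seed = seed * 1000L + f)
    pf <- predict(model, X[test, , drop = FALSE])
    pred[test] <- factor(as.character(pf), levels = levels(y))
    fold_acc[f] <- mean(pf == y[test])
  }
  if (scheme$kind == "holdout_80_20") {
    keep <- folds[[1]]
    rep <- metrics_report(y[keep], pred[keep], paper_eq11)
  } else {
    rep <- metrics_report(y, pred, paper_eq11)
  }
  rep$fold_accuracy <- fold_acc
  rep$fold_sizes <- vapply(folds, length, integer(1))
  rep
}

#' One-vs-rest ROC curves and AUC from ensemble vote fractions
#'
#' Uses the ensemble's vote fractions as continuous scores: for each class
#' the positive score is that class's vote share, evaluated against the
#' one-vs-rest truth.
#'
#' @param model a fitted `"wv_ensemble"`.
#' @param fm a `FeatureMatrix` (typically held-out data).
#' @return Named list, one `pROC::roc` object per class; AUCs are in
#'   `vapply(result, pROC::auc, numeric(1))`.
#' @export
ensemble_roc <- function(model, fm) {
  scores <- predict(model, fm$values, type = "vote")
  y <- droplevels(fm$labels)
  out <- lapply(levels(y), function(cl)
    pROC::roc(response = factor(y == cl, levels = c(FALSE, TRUE)),
              predictor = scores[, cl], quiet = TRUE,
              direction = "<", levels = c(FALSE, TRUE)))
  names(out) <- levels(y)
  out
}

#' Iterative majority voting over repeated ten-fold rounds
#'
#' Runs ten-fold cross-validation `rounds` times with seeds
#' `base_seed .. base_seed + rounds - 1`, records each round's overall and
#' per-fold accuracies, and reports the best round and the best single
#' fold across all rounds.
#'
#' @param spec a [learner_spec()].
#' @param fm a `FeatureMatrix`.
#' @param rounds number of ten-fold rounds (default 10).
#' @param base_seed first round's seed.
#' @param paper_eq11 passed through to the metric computation.
#' @return An `IMVResult`: list with `round_accuracy`, `fold_accuracy`
#'   (rounds x folds matrix), `best_round`, `best_overall_accuracy`,
#'   `best_foldwise_accuracy`, and the best round's `MetricsReport`.
#' @export
imv_tfcv <- function(spec, fm, rounds = 10, base_seed = 1,
                     paper_eq11 = FALSE) {
  stopifnot(rounds >= 1)
  scheme <- cv_scheme("kfold_10")
  reports <- lapply(seq_len(rounds) - 1L, function(r)
    evaluate_cv(spec, fm, scheme, seed = base_seed + r, paper_eq11))
  overall <- vapply(reports, `[[`, numeric(1), "accuracy")
  folds <- do.call(rbind, lapply(reports, `[[`, "fold_accuracy"))
  best <- which.max(overall)
  structure(list(round_accuracy = overall,
                 fold_accuracy = folds,
                 best_round = best,
                 best_overall_accuracy = overall[best],
                 best_foldwise_accuracy = max(folds, na.rm = TRUE),
                 best_report = reports[[best]]),
            class = "IMVResult")
}

#' @export
print.IMVResult <- function(x, ...) {
  cat(sprintf(
    "<IMVResult> %d rounds: best overall %.4f (round %d), best fold %.4f\n",
    length(x$round_accuracy), x$best_overall_accuracy, x$best_round,
    x$best_foldwise_accuracy))
  invisible(x)
}
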