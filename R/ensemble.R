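# Optimizable ensemble classifiers. Five methods are available, all
# aggregated by (weighted) majority vote: bagged trees, boosted trees
# (SAMME with shrinkage), random under-sampling boosted trees, random
# subspace k-NN and random subspace linear discriminant. Hyper-parameters
# are searched by seeded random search with cross-validated accuracy as
# the objective. All fits are deterministic given a seed.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

ENSEMBLE_METHODS <- c("bagged_tree", "boosted_tree", "rus_boosted_tree",
                      "subspace_knn", "subspace_discriminant")

#' Ensemble learner specification
#'
#' @param method one of `"bagged_tree"`, `"boosted_tree"`,
#'   `"rus_boosted_tree"`, `"subspace_knn"`, `"subspace_discriminant"`.
#' @param L number of base learners (default 50).
#' @param max_splits split budget per tree (mapped to an equivalent tree
#'   depth; default 31).
#' @param learning_rate boosting shrinkage in (0, 1] (default 0.1).
#' @param subspace_dim predictors per subspace member (default: half).
#' @param k neighbours for subspace k-NN (default 5).
#' @return A list of class `"LearnerSpec"`.
#' @export
learner_spec <- function(method, L = 50, max_splits = 31,
                         learning_rate = 0.1, subspace_dim = NULL, k = 5) {
  method <- match.arg(method, ENSEMBLE_METHODS)
  stopifnot(L >= 1, max_splits >= 1, learning_rate > 0, learning_rate <= 1,
            k >= 1)
  structure(list(method = method, L = as.integer(L),
                 max_splits = as.integer(max_splits),
                 learning_rate = learning_rate,
                 subspace_dim = subspace_dim, k = as.integer(k)),
            class = "LearnerSpec")
}

tree_control <- function(max_splits) {
  rpart::rpart.control(cp = 0, minsplit = 4, minbucket = 2, xval = 0,
                       maxdepth = min(30L, ceiling(log2(max_splits + 1))))
}

fit_tree <- function(X, y, max_splits, weights = NULL) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  rpart::rpart(.y ~ ., data = df, method = "class", weights = weights,
               control = tree_control(max_splits))
}

predict_tree <- function(tr, newX) {
  p <- predict(tr, data.frame(newX, check.names = FALSE), type = "class")
  factor(as.character(p), levels = tr$ylevels %||% levels(p))
}

# weighted vote tally: rows = cases, cols = classes
vote_tally <- function(votes, levels, w = NULL) {
  n <- length(votes[[1]])
  if (is.null(w)) w <- rep(1, length(votes))
  tally <- matrix(0, n, length(levels), dimnames = list(NULL, levels))
  for (l in seq_along(votes)) {
    ij <- cbind(seq_len(n), as.integer(factor(votes[[l]], levels = levels)))
    tally[ij] <- tally[ij] + w[l]
  }
  tally
}

# ties break to the first (alphabetically earlier) class level
majority_vote <- function(votes, levels, w = NULL) {
  tally <- vote_tally(votes, levels, w)
  factor(levels[max.col(tally, ties.method = "first")], levels = levels)
}

#' Fit a bagged ensemble
#'
#' Draws `L` bootstrap resamples of the full training-set size (with
#' replacement), fits one base tree on each, and predicts by majority vote
#' over the `L` members. A resample that collapses to a single class is
#' redrawn (bounded retries).
#'
#' @param X numeric predictor matrix (rows = segments).
#' @param y class factor.
#' @param L ensemble size.
#' @param max_splits per-tree split budget.
#' @param seed RNG seed for the resamples.
#' @return A fitted model of class `"wv_ensemble"`.
#' @export
bagging_fit <- function(X, y, L = 50, max_splits = 31, seed = 1) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need at least two classes")
  with_seed(seed, {
    members <- lapply(seq_len(L), function(l) {
      for (try in 1:10) {
        idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
        if (nlevels(droplevels(y[idx])) >= 2) break
        if (try == 10) stop("degenerate bootstrap resamples (single class)")
      }
      fit_tree(X[idx, , drop = FALSE], y[idx], max_splits)
    })
    structure(list(kind = "bag", members = members, levels = levels(y)),
              class = "wv_ensemble")
  })
}

boost_fit <- function(X, y, L, max_splits, learning_rate, seed,
                      undersample = FALSE) {
  y <- droplevels(factor(y))
  K <- nlevels(y)
  n <- nrow(X)
  with_seed(seed, {
    w <- rep(1 / n, n)
    members <- list(); alphas <- numeric(0)
    for (l in seq_len(L)) {
      if (undersample) {
        nmin <- min(table(y))
        idx <- unlist(lapply(levels(y), function(cl) {
          cls <- which(y == cl)
          if (length(cls) <= nmin) cls
          else sample(cls, nmin, prob = w[cls] / sum(w[cls]))
        }), use.names = FALSE)
        tr <- fit_tree(X[idx, , drop = FALSE], y[idx], max_splits)
      } else {
        tr <- fit_tree(X, y, max_splits, weights = w * n)
      }
      pred <- predict_tree(tr, X)
      miss <- pred != y
      err <- sum(w[miss])
      if (err >= 1 - 1 / K) { if (length(members) == 0) {
        members <- list(tr); alphas <- 1 }; break }
      err <- max(err, 1e-10)
      alpha <- learning_rate * (log((1 - err) / err) + log(K - 1))
      members[[length(members) + 1L]] <- tr
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
      if (err < 1e-10) break
    }
    structure(list(kind = "boost", members = members, alphas = alphas,
                   levels = levels(y)), class = "wv_ensemble")
  })
}

subspace_fit <- function(X, y, L, dim, seed, base = c("knn", "lda"), k = 5) {
  base <- match.arg(base)
  y <- droplevels(factor(y))
  d <- ncol(X)
  dim <- max(1L, min(as.integer(dim), d))
  with_seed(seed, {
    members <- list()
    for (l in seq_len(L)) {
      vars <- sort(sample.int(d, dim))
      if (base == "lda") {
        ok <- vars[apply(X[, vars, drop = FALSE], 2, var) >
                     .Machine$double.eps]
        if (length(ok) == 0) next
        fit <- tryCatch(suppressWarnings(
          MASS::lda(X[, ok, drop = FALSE], grouping = y)),
          error = function(e) NULL)
        if (is.null(fit)) next
        members[[length(members) + 1L]] <- list(vars = ok, fit = fit)
      } else {
        members[[length(members) + 1L]] <- list(vars = vars)
      }
    }
    if (length(members) == 0) stop("no valid subspace members")
    structure(list(kind = paste0("subspace_", base), members = members,
                   levels = levels(y), X = X, y = y, k = k),
              class = "wv_ensemble")
  })
}

#' Fit an ensemble from a LearnerSpec
#' @param spec a [learner_spec()].
#' @param X predictor matrix; `y` class factor; `seed` RNG seed.
#' @param y class labels.
#' @param seed RNG seed.
#' @return A `"wv_ensemble"` model.
#' @export
fit_ensemble <- function(spec, X, y, seed = 1) {
  d <- ncol(X)
  dim <- spec$subspace_dim %||% max(1L, floor(d / 2))
  switch(spec$method,
    bagged_tree = bagging_fit(X, y, spec$L, spec$max_splits, seed),
    boosted_tree = boost_fit(X, y, spec$L, spec$max_splits,
                             spec$learning_rate, seed),
    rus_boosted_tree = boost_fit(X, y, spec$L, spec$max_splits,
                                 spec$learning_rate, seed,
                                 undersample = TRUE),
    subspace_knn = subspace_fit(X, y, spec$L, dim, seed, "knn", spec$k),
    subspace_discriminant = subspace_fit(X, y, spec$L, dim, seed, "lda"))
}

#' @export
predict.wv_ensemble <- function(object, newdata, type = c("class", "vote"),
                                ...) {
  type <- match.arg(type)
  X <- newdata
  lv <- object$levels
  if (object$kind == "bag") {
    votes <- lapply(object$members, predict_tree, newX = X)
    w <- NULL
  } else if (object$kind == "boost") {
    votes <- lapply(object$members, predict_tree, newX = X)
    w <- object$alphas
  } else if (object$kind == "subspace_knn") {
    k_eff <- max(1L, min(object$k, nrow(object$X)))
    votes <- lapply(object$members, function(mb)
      factor(as.character(class::knn(
        object$X[, mb$vars, drop = FALSE],
        X[, mb$vars, drop = FALSE], object$y, k = k_eff)), levels = lv))
    w <- NULL
  } else {
    votes <- lapply(object$members, function(mb)
      factor(as.character(predict(mb$fit,
                                  X[, mb$vars, drop = FALSE])$class),
             levels = lv))
    w <- NULL
  }
  if (type == "class") return(majority_vote(votes, lv, w))
  if (is.null(w)) w <- rep(1, length(votes))
  vote_tally(votes, lv, w) / sum(w)
}

sample_spec <- function(d, n) {
  # random-search draw over the five methods and their ranges
  method <- sample(ENSEMBLE_METHODS, 1)
  loguni <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  learner_spec(
    method,
    L = round(loguni(10, 500)),
    max_splits = max(1L, round(loguni(1, max(2, n - 1)))),
    learning_rate = loguni(1e-3, 1),
    subspace_dim = sample.int(max(1L, floor(d / 2)), 1),
    k = sample.int(20, 1))
}

#' Random-search optimization of the ensemble classifier
#'
#' Draws `budget` candidate learner specifications across the five ensemble
#' methods (ensemble size log-uniform in [10, 500], learning rate
#' log-uniform in [1e-3, 1], split budget log-uniform in [1, n-1], subspace
#' dimension uniform in [1, d/2], k uniform in [1, 20]), scores each by
#' cross-validated accuracy, and returns the best spec with the full
#' search history.
#'
#' @param fm a `FeatureMatrix`.
#' @param budget number of candidates (>= 1).
#' @param scheme a [cv_scheme()].
#' @param seed RNG seed.
#' @return List with `best_spec`, `best_model` (fit on all data),
#'   `best_accuracy` and `history` (one row per candidate).
#' @export
optimize_ensemble <- function(fm, budget = 30, scheme = cv_scheme("kfold_10"),
                              seed = 1) {
  stopifnot(budget >= 1)
  d <- ncol(fm$values); n <- nrow(fm$values)
  specs <- with_seed(seed, lapply(seq_len(budget), function(i)
    sample_spec(d, n)))
  hist <- data.frame(candidate = seq_len(budget),
                     method = vapply(specs, `[[`, character(1), "method"),
                     L = vapply(specs, `[[`, integer(1), "L"),
                     accuracy = NA_real_)
  best <- -Inf; best_spec <- NULL
  for (i in seq_len(budget)) {
    rep <- tryCatch(evaluate_cv(specs[[i]], fm, scheme, seed = seed + i),
                    error = function(e) NULL)
    if (is.null(rep)) next
    hist$accuracy[i] <- rep$accuracy
    if (rep$accuracy > best) { best <- rep$accuracy; best_spec <- specs[[i]] }
  }
  if (is.null(best_spec)) stop("all candidate fits failed")
  model <- fit_ensemble(best_spec, fm$values, fm$labels, seed = seed)
  list(best_spec = best_spec, best_model = model,
       best_accuracy = best, history = hist)
}
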