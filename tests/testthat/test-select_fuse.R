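test_that("informative features outrank noise features", {
  fm <- planted_feature_matrix(n_per_class = 80, informative = c(2),
                               n_features = 6, seed = 1)
  rk <- rank_features(fm)
  expect_equal(rk$feature[1], "f2")
  expect_gt(rk$relevance[rk$feature == "f2"],
            max(rk$relevance[rk$feature != "f2"]))
})

test_that("exact duplicates are penalized by the redundancy term", {
  with_seed(42, {
    n <- 240
    y <- factor(rep(c("a", "b", "c"), each = n / 3))
    A <- as.integer(y) + rnorm(n, 0, 0.15)     # strong
    C <- A                                     # exact copy of A
    D <- as.integer(y) + rnorm(n, 0, 0.9)      # moderate, independent
    E <- rnorm(n)                              # noise
  })
  values <- cbind(A = A, C = C, D = D, E = E)
  meta <- data.frame(transform = "tqwt", subband = 1, channel = 1,
                     feature = c("fA", "fC", "fD", "fE"))
  colnames(values) <- paste("tqwt.1.1", meta$feature, sep = ".")
  fm <- wavestate:::new_feature_matrix(values, y, meta)
  rk <- rank_features(fm)
  expect_equal(rk$feature[1], "fA")
  # the duplicate has the highest possible relevance yet ranks below the
  # independent feature because of the redundancy term
  expect_gt(rk$relevance[rk$feature == "fC"],
            rk$relevance[rk$feature == "fD"])
  expect_gt(rk$rank[rk$feature == "fC"], rk$rank[rk$feature == "fD"])
  # brute-force MI oracle: the greedy criterion right after picking A is
  # lower for the duplicate than for the independent feature
  dA <- wavestate:::discretize_ef(A, 10)
  dC <- wavestate:::discretize_ef(C, 10)
  dD <- wavestate:::discretize_ef(D, 10)
  expect_lt(bf_mi(dC, y) - bf_mi(dC, dA), bf_mi(dD, y) - bf_mi(dD, dA))
  # and the internal MI estimate matches the oracle exactly
  expect_equal(wavestate:::mi_discrete(dA, y), bf_mi(dA, y),
               tolerance = 1e-12)
  expect_equal(rk$relevance[rk$feature == "fA"] * log(2),
               bf_mi(dA, y), tolerance = 1e-12)
})

test_that("a planted perfect feature beats pure-noise features", {
  fm <- planted_feature_matrix(n_per_class = 67, informative = 3,
                               n_features = 10, noise = 1e-3, seed = 5)
  rk <- rank_features(fm)
  expect_equal(rk$feature[1], "f3")
  expect_gt(rk$score[1], max(rk$score[-1]))
})

test_that("selection keeps whole feature types across channels", {
  ds <- tiny_segment_set(per_class = 3, channels = 14, seconds = 8,
                         shift = 0.5)
  fm <- extract_subband_features(ds, "mdwt", mdwt_params(), 1)
  rk <- rank_features(fm)
  top4 <- select_top(fm, rk, 4)
  expect_equal(ncol(top4$values), 4 * 14)
  top1 <- select_top(fm, rk, 1)
  expect_equal(unique(top1$column_meta$feature), rk$feature[1])
  top27 <- select_top(fm, rk, 27)
  expect_setequal(colnames(top27$values), colnames(fm$values))
  # greedy nesting: top-k columns are a subset of top-(k+1)
  for (k in c(2, 5, 10)) {
    expect_true(all(colnames(select_top(fm, rk, k)$values) %in%
                      colnames(select_top(fm, rk, k + 1)$values)))
  }
  expect_error(select_top(fm, rk, 0), "k must be")
  expect_error(select_top(fm, rk, 28), "k must be")
})

test_that("ranking is deterministic", {
  fm <- planted_feature_matrix(seed = 9)
  expect_identical(rank_features(fm)$feature, rank_features(fm)$feature)
})

test_that("fusion concatenates top-k columns per transform", {
  mk <- function(seed, tr) {
    fm <- planted_feature_matrix(n_per_class = 20, informative = 1:2,
                                 n_features = 6, channels = 14, seed = seed)
    fm$column_meta$transform <- tr
    list(fm = fm, ranking = rank_features(fm))
  }
  m1 <- mk(1, "mdwt"); m2 <- mk(2, "tqwt"); m3 <- mk(3, "fawt")
  fused <- fuse_features(list(m1, m2, m3), 4)
  expect_equal(ncol(fused$values), 3 * 4 * 14)
  expect_setequal(unique(fused$column_meta$transform),
                  c("mdwt", "tqwt", "fawt"))
  two <- fuse_features(list(m1, m2), 1)
  expect_equal(ncol(two$values), 2 * 14)
  self <- fuse_features(list(m1, m1), 2)
  expect_equal(ncol(self$values), 2 * 2 * 14)
  expect_equal(nrow(self$values), nrow(m1$fm$values))
  short <- mk(4, "tqwt")
  short$fm <- wavestate:::new_feature_matrix(
    short$fm$values[1:30, ], short$fm$labels[1:30], short$fm$column_meta)
  expect_error(fuse_features(list(m1, short), 2), "segment order")
})

test_that("planted features are recovered across seeds", {
  hits <- vapply(1:20, function(s) {
    fm <- planted_feature_matrix(n_per_class = 40, informative = c(4, 7),
                                 n_features = 12, noise = 0.3, seed = s)
    rk <- rank_features(fm)
    all(c("f4", "f7") %in% rk$feature[1:2])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
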