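test_that("degenerate signals produce defined fallbacks, never NaN", {
  x <- rep(3, 64)
  expect_equal(compute_feature(x, "standard_deviation"), 0)
  expect_equal(compute_feature(x, "wavelength"), 0)
  expect_equal(compute_feature(x, "slope_sign_changes"), 0)
  expect_equal(compute_feature(x, "zero_crossing_rate"), 0)
  expect_equal(compute_feature(x, "lyapunov_exponent"), 0)
  v <- suppressWarnings(compute_feature_vector(x))
  expect_true(all(is.finite(v)))
  expect_warning(compute_feature(x, "norm_first_diff"), "constant")
})

test_that("alternating signs cross zero at every step", {
  x <- rep(c(1, -1), 32)
  expect_equal(compute_feature(x, "zero_crossing_rate"), 1)
})

test_that("white noise has Hurst near 1/2, a line has dimension near 1", {
  hs <- vapply(1:5, function(s) hurst_rs(with_seed(s, rnorm(3840))),
               numeric(1))
  expect_true(all(hs > 0.4 & hs < 0.6))
  expect_lt(abs(higuchi_fd(as.numeric(1:500), kmax = 10) - 1), 0.05)
})

test_that("quartile features follow the linear-interpolation rule", {
  x <- as.numeric(1:8)
  # h = (n-1)p + 1: Q1 at 2.75, Q2 at 4.5, Q3 at 6.25
  expect_equal(compute_feature(x, "iqr"), 6.25 - 2.75)
  expect_equal(compute_feature(x, "trimean"), (2.75 + 2 * 4.5 + 6.25) / 4)
})

test_that("the default vector has 27 ordered features, deterministically", {
  x <- with_seed(1, rnorm(256))
  v <- compute_feature_vector(x)
  expect_length(v, 27)
  expect_identical(names(v), feature_names())
  expect_identical(v, compute_feature_vector(x))
  z <- suppressWarnings(compute_feature_vector(numeric(64)))
  expect_equal(unname(z[c("average_energy", "absolute_energy",
                          "simple_square_integral")]), c(0, 0, 0))
  expect_equal(unname(z["log_energy"]), 64 * log(1e-12))
})

test_that("features scale and shift as their formulas dictate", {
  x <- with_seed(2, rnorm(400))
  v1 <- compute_feature_vector(x)
  vc <- compute_feature_vector(3 * x)
  deg1 <- c("standard_deviation", "wavelength", "dasdv")
  deg2 <- c("average_energy", "absolute_energy", "simple_square_integral")
  inv <- c("skewness", "kurtosis", "hjorth_mobility", "zero_crossing_rate")
  expect_equal(unname(vc[deg1]), unname(3 * v1[deg1]), tolerance = 1e-10)
  expect_equal(unname(vc[deg2]), unname(9 * v1[deg2]), tolerance = 1e-10)
  expect_equal(unname(vc[inv]), unname(v1[inv]), tolerance = 1e-10)
  vs <- compute_feature_vector(x + 5)
  shift_inv <- c("skewness", "kurtosis", "standard_deviation", "iqr")
  expect_equal(unname(vs[shift_inv]), unname(v1[shift_inv]),
               tolerance = 1e-8)
  expect_gt(vs[["absolute_energy"]], v1[["absolute_energy"]])
})

test_that("estimator parameters are overridable through specs", {
  x <- with_seed(3, rnorm(300))
  v4 <- compute_feature(x, list(name = "v_order", parameters = list(v = 4)))
  expect_equal(v4, (mean(abs(x)^4))^(1 / 4))
  expect_false(isTRUE(all.equal(v4, compute_feature(x, "v_order"))))
  h5 <- compute_feature(x, list(name = "higuchi_fd",
                                parameters = list(kmax = 5)))
  expect_equal(h5, higuchi_fd(x, 5))
})

test_that("unknown features and short signals are rejected", {
  expect_error(compute_feature(rnorm(64), "petrosian_fd"), "unknown feature")
  expect_error(compute_feature(rnorm(8), "hurst_exponent"), "too short")
  expect_error(compute_feature(rnorm(2), "standard_deviation"), "too short")
  expect_error(compute_feature(c(rnorm(63), NA), "standard_deviation"),
               "non-finite")
})

test_that("subband feature matrices have channels x 27 columns", {
  ds <- tiny_segment_set(per_class = 2, channels = 2, seconds = 8)
  fm <- extract_subband_features(ds, "mdwt", mdwt_params(), 1)
  expect_equal(dim(fm$values), c(6, 2 * 27))
  expect_identical(as.character(fm$labels),
                   as.character(ds$labels))
  expect_equal(nrow(fm$column_meta), 54)
  expect_setequal(unique(fm$column_meta$feature), feature_names())
  ds1 <- tiny_segment_set(per_class = 2, channels = 1, seconds = 8)
  expect_equal(ncol(extract_subband_features(ds1, "mdwt", mdwt_params(),
                                             1)$values), 27)
  expect_error(extract_subband_features(ds1, "mdwt", mdwt_params(), 9),
               "out of range")
})

test_that("feature matrices round-trip through CSV", {
  ds <- tiny_segment_set(per_class = 2, channels = 2, seconds = 8)
  fm <- extract_subband_features(ds, "tqwt", tqwt_params(), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(unname(back$values), unname(fm$values), tolerance = 1e-12)
  expect_identical(as.character(back$labels), as.character(fm$labels))
  expect_identical(back$column_meta$feature, fm$column_meta$feature)
})
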