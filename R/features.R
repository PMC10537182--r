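# The 27 statistical and nonlinear subband features. Notation: N = length,
# d_i = x[i+1] - x[i] (first difference), g_i = x[i+2] - x[i] (second
# difference), sigma = sample SD (N-1 divisor), quartiles by linear
# interpolation (type 7). Fractional powers act on |x|. Degenerate inputs
# (constant signals) return 0 for the features whose formula divides by
# sigma or needs oscillation, so feature matrices never contain NaN.

central_moment <- function(x, k) mean((x - mean(x))^k)

# least-squares slope of y on x (both centred)
slope_fit <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Hurst exponent by rescaled-range analysis
#'
#' R/S analysis: for logarithmically spaced window sizes in `[min_w, N/2]`
#' the signal is cut into non-overlapping blocks and each block's rescaled
#' range R/S is averaged per size. With `corrected = TRUE` (default) the
#' Anis-Lloyd-Peters expected value under an i.i.d. null is subtracted and
#' `H = 0.5 + slope of (log(R/S) - log E[R/S])` on `log(w)`, which removes
#' the well-known upward small-sample bias of the raw statistic; with
#' `corrected = FALSE` the raw slope of `log(R/S)` is returned.
#'
#' @param x numeric signal.
#' @param min_w smallest window (default 10).
#' @param n_sizes number of window sizes (default 10).
#' @param corrected apply the Anis-Lloyd-Peters correction (default TRUE).
#' @return Estimated H (0.5 for white noise, 0 for a constant signal).
#' @export
hurst_rs <- function(x, min_w = 10, n_sizes = 10, corrected = TRUE) {
  N <- length(x)
  sizes <- unique(round(exp(seq(log(min_w), log(N / 2), length.out = n_sizes))))
  rs <- rs_means(as.numeric(x), as.integer(sizes))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) return(0)
  lw <- log(sizes[ok]); ly <- log(rs[ok])
  if (corrected) {
    ly <- ly - log(vapply(sizes[ok], rs_expected_iid, numeric(1)))
    return(0.5 + slope_fit(lw, ly))
  }
  slope_fit(lw, ly)
}

# Anis-Lloyd expected R/S of an i.i.d. series of length w, with the Peters
# front factor (w - 0.5)/w; lgamma keeps the small-w branch stable.
rs_expected_iid <- function(w) {
  i <- seq_len(w - 1)
  s <- sum(sqrt((w - i) / i))
  front <- (w - 0.5) / w
  if (w <= 340) {
    front * exp(lgamma((w - 1) / 2) - lgamma(w / 2) - 0.5 * log(pi)) * s
  } else {
    front * s / sqrt(w * pi / 2)
  }
}

#' Higuchi fractal dimension
#'
#' Curve-length estimate: FD is the slope of `log L(k)` versus `log(1/k)`
#' over scales `k = 1..kmax` (close to 1 for a smooth curve, up to 2 for
#' noise-like signals).
#'
#' @param x numeric signal.
#' @param kmax maximum scale (default 10).
#' @return Estimated fractal dimension.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  L <- higuchi_lengths(as.numeric(x), as.integer(kmax))
  k <- seq_len(kmax)
  ok <- L > 0
  if (sum(ok) < 2) return(0)
  slope_fit(log(1 / k[ok]), log(L[ok]))
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Delay embedding with dimension `emb_dim` and unit delay; each reference
#' vector is paired with its nearest neighbour outside a Theiler window of
#' one mean period (estimated from zero crossings), and the exponent is
#' the slope of the mean log-divergence over the first `fit_steps` steps,
#' in nats per sample. Reference points are strided down to at most
#' `max_ref` for long signals.
#'
#' @param x numeric signal.
#' @param emb_dim embedding dimension (default 10).
#' @param tau embedding delay in samples (default 1).
#' @param fit_steps divergence steps fitted (default 20).
#' @param max_ref reference-point budget (default 512).
#' @return Estimated exponent (0 for a constant or too-short signal).
#' @export
lyapunov_rosenstein <- function(x, emb_dim = 10, tau = 1, fit_steps = 20,
                                max_ref = 512) {
  x <- as.numeric(x)
  N <- length(x)
  xc <- x - mean(x)
  crossings <- sum(xc[-N] * xc[-1] < 0)
  if (crossings == 0) return(0)
  theiler <- max(1L, round(2 * (N - 1) / crossings))
  y <- lyap_divergence(x, as.integer(emb_dim), as.integer(tau),
                       as.integer(theiler), as.integer(fit_steps),
                       as.integer(max_ref))
  k <- 0:fit_steps
  ok <- is.finite(y)
  if (sum(ok) < 2) return(0)
  slope_fit(k[ok], y[ok])
}

guard_sigma <- function(val, sigma) {
  if (sigma < .Machine$double.eps) {
    warning("constant signal: sigma-normalized feature set to 0",
            call. = FALSE)
    return(0)
  }
  val
}

FEATURE_DEFS <- list(
  standard_deviation  = function(x, p) sd(x),
  hurst_exponent      = function(x, p) hurst_rs(x, p$min_w %||% 10,
                                                p$n_sizes %||% 10),
  average_energy      = function(x, p) mean(x^2),
  wavelength          = function(x, p) sum(abs(diff(x))),
  v_order             = function(x, p) { v <- p$v %||% 2
                                         (mean(abs(x)^v))^(1 / v) },
  skewness            = function(x, p) { m2 <- central_moment(x, 2)
    if (m2 < .Machine$double.eps) 0 else central_moment(x, 3) / m2^1.5 },
  kurtosis            = function(x, p) { m2 <- central_moment(x, 2)
    if (m2 < .Machine$double.eps) 0 else central_moment(x, 4) / m2^2 },
  hjorth_mobility     = function(x, p) { v <- var(x)
    if (v < .Machine$double.eps) 0 else sqrt(var(diff(x)) / v) },
  higuchi_fd          = function(x, p) higuchi_fd(x, p$kmax %||% 10),
  lyapunov_exponent   = function(x, p)
    lyapunov_rosenstein(x, p$emb_dim %||% 10, p$tau %||% 1,
                        p$fit_steps %||% 20, p$max_ref %||% 512),
  dasdv               = function(x, p) sqrt(sum(diff(x)^2) / (length(x) - 1)),
  abs_sum_exp_root    = function(x, p) abs(sum(abs(x)^(p$power %||% 0.75))),
  abs_sum_sqrt        = function(x, p) abs(sum(abs(x)^0.5)),
  norm_first_diff     = function(x, p)
    guard_sigma(sum(abs(diff(x))) / (length(x) - 1) / sd(x), sd(x)),
  norm_second_diff    = function(x, p)
    guard_sigma(sum(abs(diff(x, lag = 2))) / (length(x) - 2) / sd(x), sd(x)),
  mean_sqrt           = function(x, p) mean(abs(x)^0.5),
  diff_variance       = function(x, p) var(diff(x)),
  log_energy          = function(x, p) sum(log(x^2 + 1e-12)),
  absolute_energy     = function(x, p) sum(x^2),
  simple_square_integral = function(x, p) sum(abs(x)^2),
  slope_sign_changes  = function(x, p) { d <- diff(x)
                                         sum(d[-length(d)] * d[-1] < 0) },
  peak_amplitude      = function(x, p) max(x),
  minima              = function(x, p) min(x),
  peak_to_peak        = function(x, p) max(x) - min(x),
  zero_crossing_rate  = function(x, p)
    sum(x[-length(x)] * x[-1] < 0) / (length(x) - 1),
  iqr                 = function(x, p)
    unname(quantile(x, 0.75) - quantile(x, 0.25)),
  trimean             = function(x, p)
    unname((quantile(x, 0.25) + 2 * quantile(x, 0.5) + quantile(x, 0.75)) / 4)
)

#' Names of the 27 subband features, in canonical order
#' @return Character vector of length 27.
#' @export
feature_names <- function() names(FEATURE_DEFS)

#' Default feature specification list
#'
#' One spec per feature: a list with `name` and a `parameters` map of
#' estimator settings (e.g. `kmax` for the Higuchi dimension, `v` for the
#' V-order, `emb_dim`/`fit_steps` for the Lyapunov exponent).
#'
#' @param overrides named list mapping feature name to a parameter list,
#'   merged over the defaults.
#' @return List of 27 `FeatureSpec`s.
#' @export
feature_specs <- function(overrides = list()) {
  lapply(feature_names(), function(nm) {
    list(name = nm, parameters = overrides[[nm]] %||% list())
  })
}

#' Compute a single feature of a signal
#' @param x numeric signal (length >= 16, finite values).
#' @param spec a `FeatureSpec` (list with `name`, `parameters`) or a bare
#'   feature name.
#' @return A single numeric value.
#' @export
compute_feature <- function(x, spec) {
  if (is.character(spec)) spec <- list(name = spec, parameters = list())
  fn <- FEATURE_DEFS[[spec$name]]
  if (is.null(fn)) stop("unknown feature '", spec$name, "'")
  needs_history <- spec$name %in% c("hurst_exponent", "higuchi_fd",
                                    "lyapunov_exponent")
  if (length(x) < if (needs_history) 16 else 4)
    stop("signal too short for feature '", spec$name, "'")
  if (!all(is.finite(x))) stop("non-finite values in signal")
  as.numeric(fn(as.numeric(x), spec$parameters %||% list()))
}

#' Compute an ordered feature vector
#' @param x numeric signal.
#' @param specs list of `FeatureSpec`s (default: all 27).
#' @return Named numeric vector, one value per spec, in spec order.
#' @export
compute_feature_vector <- function(x, specs = feature_specs()) {
  vals <- vapply(specs, function(sp) compute_feature(x, sp), numeric(1))
  names(vals) <- vapply(specs, `[[`, character(1), "name")
  vals
}

decompose_channel <- function(x, transform, params) {
  switch(transform,
         mdwt = mdwt_decompose(x, params),
         tqwt = tqwt_decompose(x, params),
         fawt = fawt_decompose(x, params),
         stop("unknown transform '", transform, "'"))
}

#' Extract one subband's feature matrix from a SegmentSet
#'
#' For every segment and channel, the channel signal is decomposed with the
#' requested transform, the chosen subband is taken (real form), and the
#' feature vector is computed. Columns are ordered channel-major
#' (channel 1 features, channel 2 features, ...), giving
#' `channels x length(specs)` columns (378 for 14 channels and 27 features).
#'
#' @param segs a `SegmentSet`.
#' @param transform `"mdwt"`, `"tqwt"` or `"fawt"`.
#' @param params matching parameter bundle.
#' @param subband_index 1-based subband (SB-1 = highest frequency).
#' @param specs feature specs (default all 27).
#' @return A `FeatureMatrix`: list with `values` (segments x columns),
#'   `labels`, and `column_meta` (transform, subband, channel, feature).
#' @export
extract_subband_features <- function(segs, transform, params, subband_index,
                                     specs = feature_specs()) {
  stopifnot(inherits(segs, "SegmentSet"))
  nch <- nrow(segs$segments[[1]]$signal)
  nf <- length(specs)
  rows <- lapply(segs$segments, function(seg) {
    unlist(lapply(seq_len(nch), function(ch) {
      sbs <- decompose_channel(seg$signal[ch, ], transform, params)
      if (subband_index < 1 || subband_index > n_subbands(sbs))
        stop("subband_index out of range: transform '", transform,
             "' has ", n_subbands(sbs), " subbands")
      compute_feature_vector(Re(sbs$subbands[[subband_index]]), specs)
    }), use.names = FALSE)
  })
  values <- do.call(rbind, rows)
  meta <- data.frame(
    transform = transform,
    subband = subband_index,
    channel = rep(seq_len(nch), each = nf),
    feature = rep(vapply(specs, `[[`, character(1), "name"), nch),
    stringsAsFactors = FALSE)
  colnames(values) <- with(meta, paste(transform, subband, channel, feature,
                                       sep = "."))
  new_feature_matrix(values, segs$labels, meta)
}

new_feature_matrix <- function(values, labels, column_meta) {
  stopifnot(nrow(values) == length(labels),
            ncol(values) == nrow(column_meta))
  if (any(!is.finite(values))) stop("feature matrix contains non-finite values")
  structure(list(values = values, labels = labels,
                 column_meta = column_meta), class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("<FeatureMatrix> %d segments x %d columns (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$column_meta$transform), collapse = "+")))
  invisible(x)
}

#' Write / read a FeatureMatrix as CSV
#'
#' Columns are headed `transform.subband.channel.feature`; the class label
#' travels in a final `label` column.
#'
#' @param fm a `FeatureMatrix`.
#' @param path CSV path.
#' @return `path` / the re-read `FeatureMatrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$values)
  df$label <- as.character(fm$labels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  labels <- factor(df$label)
  df$label <- NULL
  parts <- strsplit(colnames(df), ".", fixed = TRUE)
  meta <- data.frame(
    transform = vapply(parts, `[[`, character(1), 1),
    subband = as.integer(vapply(parts, `[[`, character(1), 2)),
    channel = as.integer(vapply(parts, `[[`, character(1), 3)),
    feature = vapply(parts, function(pp) paste(pp[-(1:3)], collapse = "."),
                     character(1)),
    stringsAsFactors = FALSE)
  new_feature_matrix(as.matrix(df), labels, meta)
}
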