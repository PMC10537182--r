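# Independent brute-force implementations of the 27 features, written as
# direct formula evaluations (explicit loops and first-principles
# quantile/moment arithmetic), used to cross-check the package versions.

bf_quantile <- function(x, p) {
  # linear-interpolation quantile (type 7): h = (n-1)p + 1
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(s[lo])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

bf_hurst <- function(x, min_w = 10, n_sizes = 10) {
  N <- length(x)
  sizes <- unique(round(exp(seq(log(min_w), log(N / 2),
                                length.out = n_sizes))))
  rs <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    w <- sizes[si]
    nb <- floor(N / w)
    vals <- c()
    for (b in seq_len(nb)) {
      z <- x[((b - 1) * w + 1):(b * w)]
      mu <- 0; for (v in z) mu <- mu + v
      mu <- mu / w
      ss <- 0; cum <- 0; mx <- -Inf; mn <- Inf
      for (v in z) {
        d <- v - mu
        ss <- ss + d * d
        cum <- cum + d
        if (cum > mx) mx <- cum
        if (cum < mn) mn <- cum
      }
      s <- sqrt(ss / (w - 1))
      if (s > 0) vals <- c(vals, (mx - mn) / s)
    }
    rs[si] <- mean(vals)
  }
  expct <- vapply(sizes, function(w) {
    i <- seq_len(w - 1)
    sm <- sum(sqrt((w - i) / i))
    f <- (w - 0.5) / w
    if (w <= 340) f * exp(lgamma((w - 1) / 2) - lgamma(w / 2) -
                            0.5 * log(pi)) * sm
    else f * sm / sqrt(w * pi / 2)
  }, numeric(1))
  lw <- log(sizes); ly <- log(rs) - log(expct)
  0.5 + sum((lw - mean(lw)) * (ly - mean(ly))) / sum((lw - mean(lw))^2)
}

bf_higuchi <- function(x, kmax = 10) {
  N <- length(x)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- c()
    for (m in seq_len(k)) {
      nseg <- floor((N - m) / k)
      if (nseg < 1) next
      s <- 0
      for (i in seq_len(nseg))
        s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lm <- c(Lm, s * (N - 1) / (nseg * k * k))
    }
    L[k] <- mean(Lm)
  }
  lk <- log(1 / seq_len(kmax)); ll <- log(L)
  sum((lk - mean(lk)) * (ll - mean(ll))) / sum((lk - mean(lk))^2)
}

bf_lyapunov <- function(x, m = 10, tau = 1, fit_steps = 20, max_ref = 512) {
  N <- length(x)
  xc <- x - mean(x)
  crossings <- sum(xc[-N] * xc[-1] < 0)
  if (crossings == 0) return(0)
  theiler <- max(1, round(2 * (N - 1) / crossings))
  M <- N - (m - 1) * tau
  Mf <- M - fit_steps
  if (Mf < 2) return(0)
  stride <- ceiling(Mf / max_ref)
  emb <- sapply(0:(m - 1), function(e) x[(1:Mf) + e * tau])
  acc <- numeric(fit_steps + 1); cnt <- integer(fit_steps + 1)
  for (i in seq(1, Mf, by = stride)) {
    best <- Inf; bj <- -1
    for (j in seq_len(Mf)) {
      if (abs(i - j) <= theiler) next
      d <- sum((emb[i, ] - emb[j, ])^2)
      if (d < best && d > 0) { best <- d; bj <- j }
    }
    if (bj < 0) next
    for (k in 0:fit_steps) {
      d <- sum((x[(i + k):(i + k + (m - 1) * tau)] -
                  x[(bj + k):(bj + k + (m - 1) * tau)])^2)
      if (d > 0) { acc[k + 1] <- acc[k + 1] + 0.5 * log(d)
                   cnt[k + 1] <- cnt[k + 1] + 1 }
    }
  }
  y <- acc / cnt; k <- 0:fit_steps
  ok <- is.finite(y)
  kc <- k[ok] - mean(k[ok])
  sum(kc * (y[ok] - mean(y[ok]))) / sum(kc^2)
}

brute_force_feature <- function(x, name) {
  N <- length(x)
  d <- x[-1] - x[-N]
  g <- x[-c(1, 2)] - x[-c(N - 1, N)]
  mu <- sum(x) / N
  m2 <- sum((x - mu)^2) / N
  sigma <- sqrt(sum((x - mu)^2) / (N - 1))
  switch(name,
    standard_deviation = sigma,
    hurst_exponent = bf_hurst(x),
    average_energy = sum(x^2) / N,
    wavelength = sum(abs(d)),
    v_order = sqrt(sum(abs(x)^2) / N),
    skewness = (sum((x - mu)^3) / N) / m2^1.5,
    kurtosis = (sum((x - mu)^4) / N) / m2^2,
    hjorth_mobility = {
      vd <- sum((d - mean(d))^2) / (N - 2)
      vx <- sum((x - mu)^2) / (N - 1)
      sqrt(vd / vx)
    },
    higuchi_fd = bf_higuchi(x),
    lyapunov_exponent = bf_lyapunov(x),
    dasdv = sqrt(sum(d^2) / (N - 1)),
    abs_sum_exp_root = abs(sum(abs(x)^0.75)),
    abs_sum_sqrt = abs(sum(abs(x)^0.5)),
    norm_first_diff = (sum(abs(d)) / (N - 1)) / sigma,
    norm_second_diff = (sum(abs(g)) / (N - 2)) / sigma,
    mean_sqrt = sum(abs(x)^0.5) / N,
    diff_variance = sum((d - mean(d))^2) / (N - 2),
    log_energy = sum(log(x^2 + 1e-12)),
    absolute_energy = sum(x^2),
    simple_square_integral = sum(abs(x)^2),
    slope_sign_changes = sum(d[-(N - 1)] * d[-1] < 0),
    peak_amplitude = max(x),
    minima = min(x),
    peak_to_peak = max(x) - min(x),
    zero_crossing_rate = sum(x[-N] * x[-1] < 0) / (N - 1),
    iqr = bf_quantile(x, 0.75) - bf_quantile(x, 0.25),
    trimean = (bf_quantile(x, 0.25) + 2 * bf_quantile(x, 0.5) +
                 bf_quantile(x, 0.75)) / 4,
    stop("no oracle for ", name))
}

# plain contingency-table mutual information in nats
bf_mi <- function(a, b) {
  ta <- table(a); tb <- table(b); tj <- table(a, b)
  n <- length(a)
  s <- 0
  for (i in rownames(tj)) for (j in colnames(tj)) {
    pij <- tj[i, j] / n
    if (pij > 0) s <- s + pij * log(pij / ((ta[[i]] / n) * (tb[[j]] / n)))
  }
  s
}
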