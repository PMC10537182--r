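# Tunable Q-factor wavelet transform: an oversampled two-channel filter
# bank applied recursively to the low-pass branch, implemented directly in
# the DFT domain. The low-pass band shrinks by the scaling factor
# a = 1 - beta/R per level and the high-pass band has relative width
# beta = 2/(q + 1). Inside the transition band the filters follow the
# 2-vanishing-moment Daubechies frequency response
#   theta(w) = (1 + cos w) * sqrt(2 - cos w) / 2,   w in [0, pi],
# which satisfies theta(w)^2 + theta(pi - w)^2 = 1 and therefore makes the
# analysis/synthesis pair a perfect-reconstruction tight frame.

#' TQWT scaling factors from quality factor and oversampling rate
#'
#' `beta = 2/(q+1)` (high-pass scaling) and `a = 1 - beta/R` (low-pass
#' scaling). The inverse identities `q = (2 - beta)/beta` and
#' `R = beta/(1 - a)` hold to machine precision.
#'
#' @param q quality factor, `>= 1` (1 for non-oscillatory signals).
#' @param R oversampling rate, `>= 3` for good time-domain localization.
#' @return Named list with `beta` and `a`.
#' @export
tqwt_design <- function(q = 2, R = 5) {
  if (q < 1) stop("quality factor q must be >= 1")
  if (R < 3) stop("oversampling rate R must be >= 3")
  beta <- 2 / (q + 1)
  list(beta = beta, a = 1 - beta / R)
}

#' TQWT parameter bundle
#' @param q quality factor (default 2).
#' @param R oversampling rate (default 5).
#' @param B number of decomposition levels (default 7, giving 8 subbands).
#' @return A list of class `"TQWTParams"` including the derived `beta`, `a`.
#' @export
tqwt_params <- function(q = 2, R = 5, B = 7) {
  stopifnot(B >= 1)
  d <- tqwt_design(q, R)
  structure(list(q = q, R = R, B = as.integer(B),
                 beta = d$beta, a = d$a), class = "TQWTParams")
}

theta_daub <- function(v) (1 + cos(v)) * sqrt(2 - cos(v)) / 2

# analysis filter bank for one level: spectrum X of even length N ->
# low-pass spectrum of length N0 and high-pass spectrum of length N1.
tqwt_afb <- function(X, N0, N1) {
  N <- length(X)
  P <- (N - N1) / 2L
  T <- (N0 + N1 - N) / 2L - 1L
  trans <- theta_daub(seq_len(T) / (T + 1) * pi)
  V0 <- complex(N0); V1 <- complex(N1)
  V0[1] <- X[1]
  if (P >= 1) V0[2:(P + 1)] <- X[2:(P + 1)]
  if (T >= 1) V0[(P + 2):(P + T + 1)] <- X[(P + 2):(P + T + 1)] * trans
  if (N0 / 2 >= 2) V0[N0:(N0 / 2 + 2)] <- Conj(V0[2:(N0 / 2)])
  if (T >= 1) V1[2:(T + 1)] <- X[(P + 2):(P + T + 1)] * rev(trans)
  if (N1 / 2 >= T + 2) V1[(T + 2):(N1 / 2)] <- X[(P + T + 2):(N / 2)]
  V1[N1 / 2 + 1] <- X[N / 2 + 1]
  if (N1 / 2 >= 2) V1[N1:(N1 / 2 + 2)] <- Conj(V1[2:(N1 / 2)])
  list(V0 = V0, V1 = V1)
}

# synthesis: exact inverse of tqwt_afb (windows sum in squares to one).
tqwt_sfb <- function(V0, V1, N) {
  N0 <- length(V0); N1 <- length(V1)
  P <- (N - N1) / 2L
  T <- (N0 + N1 - N) / 2L - 1L
  trans <- theta_daub(seq_len(T) / (T + 1) * pi)
  Y <- complex(N)
  Y[1] <- V0[1]
  if (P >= 1) Y[2:(P + 1)] <- V0[2:(P + 1)]
  if (T >= 1) Y[(P + 2):(P + T + 1)] <-
      V0[(P + 2):(P + T + 1)] * trans + V1[2:(T + 1)] * rev(trans)
  if (N / 2 >= P + T + 2) Y[(P + T + 2):(N / 2)] <- V1[(T + 2):(N1 / 2)]
  Y[N / 2 + 1] <- V1[N1 / 2 + 1]
  Y[N:(N / 2 + 2)] <- Conj(Y[2:(N / 2)])
  Y
}

tqwt_level_lengths <- function(N, params) {
  a <- params$a; beta <- params$beta
  Ns <- integer(params$B + 1L); N0s <- integer(params$B)
  N1s <- integer(params$B)
  cur <- N
  for (b in seq_len(params$B)) {
    Ns[b] <- cur
    N0s[b] <- 2L * round(a * cur / 2)
    N1s[b] <- 2L * round(beta * cur / 2)
    if (N0s[b] < 8L)
      stop("signal too short: level ", b, " low-pass band has < 8 samples")
    cur <- N0s[b]
  }
  Ns[params$B + 1L] <- cur
  list(N = Ns, N0 = N0s, N1 = N1s)
}

#' Decompose a signal with the TQWT
#'
#' Yields `B` high-pass subbands (SB-1 = level-1, highest frequency) plus
#' one final low-pass subband (SB-`B+1`). Odd-length inputs are zero-padded
#' by one sample (recorded in the result and undone on reconstruction).
#'
#' @param x numeric signal.
#' @param params a [tqwt_params()] bundle.
#' @return A `SubbandSet`.
#' @export
tqwt_decompose <- function(x, params = tqwt_params()) {
  x <- as.numeric(x)
  padded <- length(x) %% 2L
  if (padded) x <- c(x, 0)
  N <- length(x)
  ll <- tqwt_level_lengths(N, params)
  sb <- vector("list", params$B + 1L)
  X <- fft(x)
  for (b in seq_len(params$B)) {
    v <- tqwt_afb(X, ll$N0[b], ll$N1[b])
    sb[[b]] <- Re(fft(v$V1, inverse = TRUE)) / ll$N1[b]
    X <- v$V0
  }
  sb[[params$B + 1L]] <- Re(fft(X, inverse = TRUE)) / length(X)
  new_subband_set("tqwt", sb, N - padded, params,
                  extras = list(padded = padded))
}

#' Invert a TQWT decomposition
#' @param sbs a `SubbandSet` from [tqwt_decompose()].
#' @return Numeric signal of the original length.
#' @export
tqwt_reconstruct <- function(sbs) {
  stopifnot(sbs$transform_id == "tqwt")
  params <- sbs$params
  N <- sbs$original_length + (sbs$padded %||% 0L)
  ll <- tqwt_level_lengths(N, params)
  for (b in seq_len(params$B + 1L)) {
    want <- if (b <= params$B) ll$N1[b] else tail(ll$N, 1)
    if (length(sbs$subbands[[b]]) != want)
      stop("tampered subband lengths at SB-", b)
  }
  V0 <- fft(sbs$subbands[[params$B + 1L]])
  for (b in rev(seq_len(params$B))) {
    V1 <- fft(sbs$subbands[[b]])
    V0 <- tqwt_sfb(V0, V1, ll$N[b])
  }
  y <- Re(fft(V0, inverse = TRUE)) / N
  y[seq_len(sbs$original_length)]
}
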