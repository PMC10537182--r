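# Flexible analytic wavelet transform: an iterated filter bank with
# rational sampling-rate changes (p/q on the low-pass channel, r/s on the
# high-pass channel) and one-sided (analytic) high-pass atoms, so each
# high-pass subband is intrinsically complex. Implemented in the DFT
# domain: per level the input spectrum is split by a pair of windows whose
# squares sum to one on every bin (Daubechies transition response on the
# low/high crossover; a mirrored taper across the Nyquist bin for the
# analytic band), so analysis followed by the matched synthesis is exact.
# Band edges follow the design equations
#   wp = ((1-beta)pi + eps)/p,  ws = pi/q,
#   w0 = ((1-beta)pi + eps)/r,  w1 = p pi/(q r),
#   w2 = (pi - eps)/r,          w3 = (pi + eps)/r,
# snapped to the DFT grid of each level.

#' FAWT parameter bundle
#'
#' @param B decomposition levels (default 6, giving 7 subbands).
#' @param p,q low-pass channel up/down-sampling integers (`p < q`;
#'   defaults 3, 5 so the low band keeps 3/5 of the spectrum per level).
#' @param r,s high-pass channel up/down-sampling integers (defaults 2, 3).
#' @param beta perfect-reconstruction factor in `(0, 1]`; default `r/s`.
#' @param eps transition-width factor (radians); default
#'   `((q - p)/(q + p)) * pi`.
#' @return A list of class `"FAWTParams"` (edge ordering validated).
#' @export
fawt_params <- function(B = 6, p = 3, q = 5, r = 2, s = 3,
                        beta = r / s, eps = ((q - p) / (q + p)) * pi) {
  stopifnot(B >= 1, p >= 1, q >= 1, r >= 1, s >= 1)
  if (p >= q) stop("FAWT requires p < q")
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  pr <- structure(list(B = as.integer(B), p = as.integer(p),
                       q = as.integer(q), r = as.integer(r),
                       s = as.integer(s), beta = beta, eps = eps),
                  class = "FAWTParams")
  fawt_design(pr)                       # errors on an ordering violation
  pr
}

#' FAWT frequency edges
#'
#' Computes the six band-edge frequencies of the low-pass (`wp`, `ws`) and
#' analytic high-pass (`w0`..`w3`) filters from the sampling factors, `beta`
#' and `eps`, and validates the ordering `wp < ws` and
#' `w0 <= w1 <= w2 < w3`.
#'
#' @param params a [fawt_params()] bundle (or a bare list with fields
#'   `p, q, r, s, beta, eps`).
#' @param validate if `FALSE`, return edges without the ordering check
#'   (useful for inspecting degenerate settings such as `eps = 0`).
#' @return Named numeric vector `c(wp, ws, w0, w1, w2, w3)` (radians).
#' @export
fawt_design <- function(params, validate = TRUE) {
  p <- params$p; q <- params$q; r <- params$r; s <- params$s
  beta <- params$beta; eps <- params$eps
  ed <- c(wp = ((1 - beta) * pi + eps) / p,
          ws = pi / q,
          w0 = ((1 - beta) * pi + eps) / r,
          w1 = p * pi / (q * r),
          w2 = (pi - eps) / r,
          w3 = (pi + eps) / r)
  if (validate) {
    checks <- c("wp < ws" = ed["wp"] < ed["ws"],
                "w0 <= w1" = ed["w0"] <= ed["w1"],
                "w1 <= w2" = ed["w1"] <= ed["w2"],
                "w2 < w3" = ed["w2"] < ed["w3"])
    if (any(!checks))
      stop("FAWT frequency-edge ordering violated: ",
           paste(names(checks)[!checks], collapse = ", "))
  }
  ed
}

# per-level window layout on the DFT grid of a length-N (even) signal.
# P flat low-pass bins after DC, T crossover bins (shared by both
# channels), then high-pass-only bins up to the Nyquist taper of half-width
# M bins centred on the (self-mirrored, full-weight) Nyquist bin.
fawt_layout <- function(N, params) {
  ed <- fawt_design(params)
  N0 <- 2L * round(N * params$p / (2 * params$q))
  N1 <- 2L * round(N * params$r / (2 * params$s))
  e1 <- params$p * ed[["wp"]]           # input-frequency flat edge
  P <- min(floor(e1 * N / (2 * pi)), N0 / 2 - 2L)
  T <- N0 / 2 - 1L - P
  M <- max(1L, min(floor(params$eps * N / (2 * pi)), N / 2 - N0 / 2 - 1L))
  if (P < 1L || T < 1L || N / 2 - M <= N0 / 2 + 1L || N1 < N / 2 + M - P + 1L)
    stop("signal too short for the requested FAWT level structure")
  list(N = N, N0 = N0, N1 = N1, P = as.integer(P), T = as.integer(T),
       M = as.integer(M))
}

# shared analytic-band window over input bins kb = P+2 .. N/2+1+M:
# rising Daubechies crossover (T bins), flat passband, then the Nyquist
# taper (theta decreasing over 2M+1 bins; the self-mirrored Nyquist bin
# itself keeps full weight).
fawt_gwin <- function(lay) {
  P <- lay$P; T <- lay$T; M <- lay$M; N <- lay$N
  kb <- (P + 2L):(N / 2 + 1L + M)
  g <- numeric(length(kb))
  g[1:T] <- rev(theta_daub(seq_len(T) / (T + 1) * pi))
  flat_hi <- length(kb) - 2L * M - 1L
  if (flat_hi >= T + 1L) g[(T + 1L):flat_hi] <- 1
  g[(flat_hi + 1L):length(kb)] <- theta_daub(pi * seq_len(2 * M + 1) /
                                               (2 * M + 2))
  g[flat_hi + M + 1L] <- 1
  list(kb = kb, g = g)
}

fawt_afb <- function(X, lay) {
  N <- lay$N; N0 <- lay$N0; N1 <- lay$N1
  P <- lay$P; T <- lay$T
  trans <- theta_daub(seq_len(T) / (T + 1) * pi)
  V0 <- complex(N0)
  V0[1:(P + 1)] <- X[1:(P + 1)]
  V0[(P + 2):(P + T + 1)] <- X[(P + 2):(P + T + 1)] * trans
  if (N0 / 2 >= 2) V0[N0:(N0 / 2 + 2)] <- Conj(V0[2:(N0 / 2)])
  gw <- fawt_gwin(lay)
  V1 <- complex(N1)
  V1[2:(length(gw$kb) + 1L)] <- X[gw$kb] * gw$g
  list(V0 = V0, V1 = V1)
}

fawt_sfb <- function(V0, V1, lay) {
  N <- lay$N
  P <- lay$P; T <- lay$T; M <- lay$M
  trans <- theta_daub(seq_len(T) / (T + 1) * pi)
  gw <- fawt_gwin(lay)
  kb <- gw$kb; g <- gw$g
  Y <- complex(N)
  Y[1:(P + 1)] <- V0[1:(P + 1)]
  Y[(P + 2):(P + T + 1)] <- V0[(P + 2):(P + T + 1)] * trans
  w <- g * V1[2:(length(kb) + 1L)]
  # positive-frequency part (up to Nyquist) directly ...
  pos <- kb <= N / 2 + 1L
  Y[kb[pos]] <- Y[kb[pos]] + w[pos]
  # ... and the past-Nyquist tail folded back onto its mirror bins
  if (M >= 1L) {
    for (m in seq_len(M)) {
      j <- which(kb == N / 2 + 1L + m)
      Y[N / 2 + 1L - m] <- Y[N / 2 + 1L - m] + Conj(w[j])
    }
  }
  Y[N:(N / 2 + 2)] <- Conj(Y[2:(N / 2)])
  Y
}

fawt_layouts <- function(N, params) {
  lays <- vector("list", params$B)
  cur <- N
  for (b in seq_len(params$B)) {
    lays[[b]] <- fawt_layout(cur, params)
    cur <- lays[[b]]$N0
  }
  lays
}

#' Decompose a signal with the FAWT
#'
#' `B` analytic high-pass subbands (SB-1 = highest frequency) plus one
#' final low-pass subband. Each high-pass subband is delivered as a real
#' signal, twice the real part of the analytic (complex) subband; the
#' complex form is retained in `$analytic` and used for reconstruction.
#' Odd-length inputs are zero-padded by one sample (recorded and undone).
#'
#' @param x numeric signal.
#' @param params a [fawt_params()] bundle.
#' @return A `SubbandSet` with fields `analytic` (complex subbands) and
#'   `padded`.
#' @export
fawt_decompose <- function(x, params = fawt_params()) {
  x <- as.numeric(x)
  padded <- length(x) %% 2L
  if (padded) x <- c(x, 0)
  N <- length(x)
  lays <- fawt_layouts(N, params)
  ana <- vector("list", params$B + 1L)
  X <- fft(x)
  for (b in seq_len(params$B)) {
    v <- fawt_afb(X, lays[[b]])
    ana[[b]] <- fft(v$V1, inverse = TRUE) / lays[[b]]$N1
    X <- v$V0
  }
  ana[[params$B + 1L]] <- Re(fft(X, inverse = TRUE)) / length(X)
  sb <- lapply(seq_len(params$B), function(b) 2 * Re(ana[[b]]))
  sb[[params$B + 1L]] <- ana[[params$B + 1L]]
  new_subband_set("fawt", sb, N - padded, params,
                  extras = list(analytic = ana, padded = padded))
}

#' Invert a FAWT decomposition
#' @param sbs a `SubbandSet` from [fawt_decompose()] (uses the stored
#'   analytic subbands).
#' @return Numeric signal of the original length.
#' @export
fawt_reconstruct <- function(sbs) {
  stopifnot(sbs$transform_id == "fawt")
  params <- sbs$params
  N <- sbs$original_length + (sbs$padded %||% 0L)
  lays <- fawt_layouts(N, params)
  ana <- sbs$analytic
  for (b in seq_len(params$B)) {
    if (length(ana[[b]]) != lays[[b]]$N1)
      stop("tampered subband lengths at SB-", b)
  }
  V0 <- fft(as.complex(ana[[params$B + 1L]]))
  for (b in rev(seq_len(params$B))) {
    V1 <- fft(ana[[b]])
    V0 <- fawt_sfb(V0, V1, lays[[b]])
  }
  y <- Re(fft(V0, inverse = TRUE)) / N
  y[seq_len(sbs$original_length)]
}
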