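# Multilevel discrete wavelet transform: a dyadic cascade of orthogonal
# low/high-pass filters. Boundary handling is half-sample symmetric
# extension with full-length coefficient retention, which keeps the cascade
# exactly invertible. Daubechies scaling filters db1-db10 are built in;
# higher orders can be supplied as explicit coefficient vectors.

DB_SCALING <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db3 = c(0.0352262918821007, -0.08544127388224149, -0.13501102001039084,
          0.4598775021193313, 0.8068915093133388, 0.3326705529509569),
  db4 = c(-0.010597401785069032, 0.032883011666885206, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
          0.07757149384004571, -0.03224486958463837, -0.24229488706638203,
          0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
          -0.031582039317486616, 0.02752286553030572, 0.09750160558732304,
          -0.12976686756726194, -0.22626469396543983, 0.3152503517091982,
          0.7511339080210959, 0.4946238903984533, 0.11154074335008017),
  db7 = c(0.0003537137999745171, -0.0018016407040474908,
          0.00042957797292136652, 0.012550998556098717, -0.01657454163066688,
          -0.03802993693501441, 0.08061260915108308, 0.07130921926683026,
          -0.22403618499387498, -0.14390600392856498, 0.4697822874051931,
          0.7291320908462351, 0.39653931948191725, 0.07785205408500918),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282, -0.04408825393079475,
          -0.017369301001807547, 0.12874742662047847, 0.00047248457391328234,
          -0.2840155429615469, -0.015829105256349306, 0.5853546836542067,
          0.6756307362972898, 0.3128715909143166, 0.05441584224310401),
  db9 = c(3.9347319995026124e-05, -0.0002519631889427101,
          0.00023038576399541288, 0.0018476468829611268,
          -0.004281503681904723, -0.004723204757894831, 0.022361662123515244,
          0.00025094711499193845, -0.06763282905952399, 0.030725681478322865,
          0.14854074933476008, -0.09684078322087904, -0.29327378327258685,
          0.13319738582208895, 0.6572880780366389, 0.6048231236767786,
          0.24383467463766728, 0.03807794736316728),
  db10 = c(-1.326420300235487e-05, 9.358867000108985e-05,
           -0.0001164668549943862, -0.0006858566950046825,
           0.00199240529499085, 0.0013953517469940798, -0.010733175482979604,
           0.0036065535669883944, 0.0332126740593703, -0.02945753682194567,
           -0.07139414716586077, 0.09305736460380659, 0.12736934033574265,
           -0.19594627437659665, -0.24984642432648865, 0.2811723436604265,
           0.6884590394525921, 0.7498471006181029, 0.4716906672891158,
           0.154041093273377))

wavelet_filters <- function(wavelet) {
  if (is.numeric(wavelet)) {
    h <- wavelet
  } else {
    h <- DB_SCALING[[wavelet]]
    if (is.null(h)) stop("unknown wavelet '", wavelet,
                         "'; built-ins are db1..db10")
  }
  L <- length(h)
  dec_lo <- h
  dec_hi <- rev(h) * (-1)^(seq_len(L))    # quadrature mirror
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), L = L)
}

#' MDWT parameter bundle
#' @param wavelet_name orthogonal wavelet name (`"db1"`..`"db10"`) or a
#'   numeric scaling-filter vector. Default `"db2"`.
#' @param levels decomposition depth (default 4, giving the five classical
#'   EEG rhythm bands at 128 Hz).
#' @return A list of class `"MDWTParams"`.
#' @export
mdwt_params <- function(wavelet_name = "db2", levels = 4) {
  stopifnot(levels >= 1)
  structure(list(wavelet_name = wavelet_name, levels = as.integer(levels)),
            class = "MDWTParams")
}

# one analysis step, half-sample symmetric extension (pywt "symmetric"):
# output length floor((n + L - 1)/2) per band.
dwt_step <- function(x, f) {
  n <- length(x); L <- f$L
  ext <- c(x[seq(L - 1L, 1L)], x, x[seq(n, n - L + 2L)])
  cA <- stats::filter(ext, f$dec_lo, sides = 1)
  cD <- stats::filter(ext, f$dec_hi, sides = 1)
  idx <- seq(L + 1L, length(ext), by = 2L)
  list(cA = as.numeric(cA[idx]), cD = as.numeric(cD[idx]))
}

# inverse step: upsample, synthesis filters, keep the central 2c - L + 2
# samples of the full convolution, then crop to the stored level length.
idwt_step <- function(cA, cD, f, out_len) {
  L <- f$L; c2 <- 2L * length(cA)
  up <- function(co) { u <- numeric(c2); u[seq(1, c2, 2)] <- co; u }
  pad <- c(0, up(cA), numeric(L)); padD <- c(0, up(cD), numeric(L))
  y <- stats::filter(pad, f$rec_lo, sides = 1) +
       stats::filter(padD, f$rec_hi, sides = 1)
  y <- as.numeric(y)[L:(c2 + 1L)]
  y[seq_len(out_len)]
}

#' Decompose a signal with the multilevel DWT
#'
#' `levels` detail subbands plus one approximation. SB-1 is the level-1
#' detail (highest frequency), SB-`levels` the deepest detail, and
#' SB-`levels+1` the approximation.
#'
#' @param x numeric signal.
#' @param params an [mdwt_params()] bundle.
#' @return A `SubbandSet` (coefficient domain; see [mdwt_reconstruct()]).
#' @export
mdwt_decompose <- function(x, params = mdwt_params()) {
  f <- wavelet_filters(params$wavelet_name)
  if (length(x) < f$L * 2^params$levels)
    stop(sprintf("signal too short: need >= %d samples for %d levels of %s",
                 f$L * 2^params$levels, params$levels, params$wavelet_name))
  details <- vector("list", params$levels)
  lens <- integer(params$levels + 1L)
  cur <- as.numeric(x)
  for (j in seq_len(params$levels)) {
    lens[j] <- length(cur)
    st <- dwt_step(cur, f)
    details[[j]] <- st$cD
    cur <- st$cA
  }
  sb <- c(details, list(cur))   # SB-1..SB-L details, then the LP residue
  new_subband_set("mdwt", sb, length(x), params,
                  extras = list(level_lengths = lens))
}

#' Invert an MDWT decomposition
#' @param sbs a `SubbandSet` from [mdwt_decompose()] (subbands may have been
#'   modified, e.g. zeroed, but lengths must be untouched).
#' @return Numeric signal of the original length.
#' @export
mdwt_reconstruct <- function(sbs) {
  stopifnot(sbs$transform_id == "mdwt")
  params <- sbs$params
  f <- wavelet_filters(params$wavelet_name)
  k <- n_subbands(sbs)
  cur <- sbs$subbands[[k]]
  for (j in rev(seq_len(params$levels))) {
    cD <- sbs$subbands[[j]]
    if (length(cD) != length(cur))
      stop("tampered subband lengths at level ", j)
    cur <- idwt_step(cur, cD, f, sbs$level_lengths[j])
  }
  cur
}
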