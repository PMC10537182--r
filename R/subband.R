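# Uniform container for the outputs of the three filter banks. Subbands are
# indexed SB-1 = highest-frequency band, descending to the final low-pass
# band (SB-(levels+1)); the ordering is configurable downstream but this is
# the package-wide default.

new_subband_set <- function(transform_id, subbands, original_length, params,
                            extras = list()) {
  stopifnot(transform_id %in% c("mdwt", "tqwt", "fawt"), is.list(subbands))
  structure(c(list(transform_id = transform_id,
                   subbands = subbands,
                   original_length = as.integer(original_length),
                   params = params), extras),
            class = "SubbandSet")
}

#' Number of subbands in a SubbandSet
#' @param sbs a `SubbandSet`.
#' @return Integer count (`levels + 1` for all three transforms).
#' @export
n_subbands <- function(sbs) length(sbs$subbands)

#' @export
print.SubbandSet <- function(x, ...) {
  cat(sprintf("<SubbandSet:%s> %d subbands from %d samples\n",
              x$transform_id, n_subbands(x), x$original_length))
  lens <- vapply(x$subbands, length, integer(1))
  cat("  lengths:", paste(lens, collapse = " "), "\n")
  invisible(x)
}

#' Nominal frequency span of each subband
#'
#' Maps subband indices to approximate Hz spans given a sampling rate. For
#' the MDWT the spans are the dyadic halves (at 128 Hz, 4 levels:
#' 32-64, 16-32, 8-16, 4-8, 0-4 Hz, i.e. the five classical EEG rhythms).
#' For the TQWT the level-b high-pass band covers
#' `[(1-beta) a^(b-1), a^(b-1)] * fs/2`; for the FAWT the level-b band is the
#' level-1 analytic band scaled by `(p/q)^(b-1)` and clipped to Nyquist.
#'
#' @param sbs a `SubbandSet`.
#' @param fs sampling rate in Hz of the signal that was decomposed.
#' @return Data frame with `subband`, `low_hz`, `high_hz`.
#' @export
subband_rhythm_map <- function(sbs, fs) {
  nyq <- fs / 2
  p <- sbs$params
  k <- n_subbands(sbs)
  if (sbs$transform_id == "mdwt") {
    lev <- seq_len(k - 1L)
    low <- nyq / 2^lev
    high <- nyq / 2^(lev - 1L)
    low <- c(low, 0); high <- c(high, nyq / 2^(k - 1L))
  } else if (sbs$transform_id == "tqwt") {
    beta <- 2 / (p$q + 1); a <- 1 - beta / p$R
    lev <- seq_len(k - 1L)
    low <- (1 - beta) * a^(lev - 1L) * nyq
    high <- a^(lev - 1L) * nyq
    low <- c(low, 0); high <- c(high, a^(k - 1L) * nyq)
  } else {
    ed <- fawt_design(p)
    lev <- seq_len(k - 1L)
    sc <- (p$p / p$q)^(lev - 1L)
    low <- (p$r * ed["w0"] / pi) * nyq * sc
    high <- pmin(p$r * ed["w3"] / pi, 1) * nyq * sc
    low <- c(low, 0)
    high <- c(high, (p$r * ed["w0"] / pi) * nyq * (p$p / p$q)^(k - 2L))
  }
  data.frame(subband = paste0("SB-", seq_len(k)),
             low_hz = unname(low), high_hz = unname(high))
}

#' Serialize a SubbandSet to a directory of CSV arrays plus YAML metadata
#'
#' Each subband is written as `SB-<i>.csv` (complex bands as two columns
#' re/im); `meta.yml` captures the transform, parameters, lengths and any
#' padding, enough to rebuild the set with [read_subband_set()].
#'
#' @param sbs a `SubbandSet`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subband_set <- function(sbs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(sbs$subbands)) {
    s <- sbs$subbands[[i]]
    df <- if (is.complex(s)) data.frame(re = Re(s), im = Im(s))
          else data.frame(re = s)
    write.csv(df, file.path(dir, sprintf("SB-%d.csv", i)), row.names = FALSE)
  }
  meta <- list(transform_id = sbs$transform_id,
               original_length = sbs$original_length,
               params = sbs$params,
               padded = sbs$padded %||% 0L,
               lengths = vapply(sbs$subbands, length, integer(1)))
  yaml::write_yaml(meta, file.path(dir, "meta.yml"))
  invisible(dir)
}

#' Read back a SubbandSet written by [write_subband_set()]
#' @param dir directory containing `SB-*.csv` and `meta.yml`.
#' @return A `SubbandSet`.
#' @export
read_subband_set <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yml"))
  k <- length(meta$lengths)
  sb <- lapply(seq_len(k), function(i) {
    df <- read.csv(file.path(dir, sprintf("SB-%d.csv", i)))
    if ("im" %in% names(df)) complex(real = df$re, imaginary = df$im)
    else df$re
  })
  new_subband_set(meta$transform_id, sb, meta$original_length, meta$params,
                  extras = list(padded = meta$padded))
}
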