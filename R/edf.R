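# Minimal European Data Format (EDF) support: the plain-EDF subset used by
# consumer EEG exports (16-bit samples, no annotation signals). Physical
# calibration follows the EDF spec: phys = pmin + (dig - dmin)*(pmax-pmin)/
# (dmax-dmin), applied per signal.

edf_field <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read an EDF file into a Recording
#'
#' All signals must share a common sampling rate (samples-per-record equal
#' across signals); EDF annotation channels are not supported.
#'
#' @param path EDF file path.
#' @param ... metadata overrides (`subject_id`, `session_id`, `state`)
#'   forwarded to [new_recording()].
#' @return A `Recording` whose `channel_names` are the EDF signal labels.
#' @export
read_edf <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  edf_field(con, 8)                       # version
  patient <- edf_field(con, 80)
  edf_field(con, 80)                      # recording id
  edf_field(con, 8); edf_field(con, 8)    # date, time
  edf_field(con, 8)                       # header bytes
  edf_field(con, 44)                      # reserved
  n_rec <- as.integer(edf_field(con, 8))
  rec_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16), character(1))
  for (i in seq_len(ns)) edf_field(con, 80)   # transducer
  for (i in seq_len(ns)) edf_field(con, 8)    # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 1)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 1)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 1)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 1)
  for (i in seq_len(ns)) edf_field(con, 80)   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(edf_field(con, 8)),
                integer(1))
  for (i in seq_len(ns)) edf_field(con, 32)   # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF signals differ in samples-per-record; mixed-rate files are ",
         "not supported")
  if (rec_dur <= 0) stop("EDF file with non-positive record duration")
  fs <- spr[1L] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw16 <- readBin(con, "integer", n = spr[i], size = 2L,
                       endian = "little", signed = TRUE)
      if (length(raw16) < spr[i]) stop("truncated EDF data record")
      sig[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        pmin[i] + (raw16 - dmin[i]) * scale[i]
    }
  }
  args <- list(signal = sig, fs = fs, channel_names = labels,
               subject_id = if (nzchar(patient)) patient else "s1")
  over <- list(...)
  args[names(over)] <- over
  do.call(new_recording, args)
}

edf_pad <- function(x, n) {
  x <- substr(format(x), 1, n)
  formatC(x, width = n, flag = "-")
}

#' Write a Recording to an EDF file
#'
#' Samples are quantized to 16 bits over each channel's observed range.
#' Record duration is chosen so that samples-per-record is an integer; any
#' trailing part-record is zero-padded digitally at the channel midpoint.
#'
#' @param rec a `Recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "Recording"))
  fs <- rec$fs
  rec_dur <- if (abs(fs - round(fs)) < 1e-9) 1 else 10
  spr <- as.integer(round(fs * rec_dur))
  n <- ncol(rec$signal)
  n_rec <- as.integer(ceiling(n / spr))
  ns <- nrow(rec$signal)
  pmin <- apply(rec$signal, 1, min); pmax <- apply(rec$signal, 1, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, w) writeChar(paste0(edf_pad(x, w), collapse = ""), con,
                                 eos = NULL)
  wf("0", 8); wf(rec$subject_id, 80); wf(rec$session_id, 80)
  wf("01.01.00", 8); wf("00.00.00", 8)
  wf(256L * (1L + ns), 8); wf("", 44)
  wf(n_rec, 8); wf(format(rec_dur), 8); wf(ns, 4)
  for (lab in rec$channel_names) wf(lab, 16)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf("uV", 8)
  for (i in seq_len(ns)) wf(formatC(pmin[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wf(formatC(pmax[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wf(dmin, 8)
  for (i in seq_len(ns)) wf(dmax, 8)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf(spr, 8)
  for (i in seq_len(ns)) wf("", 32)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      chunk <- rep((pmin[i] + pmax[i]) / 2, spr)
      keep <- idx <= n
      chunk[keep] <- rec$signal[i, idx[keep]]
      dig <- round(dmin + (chunk - pmin[i]) * scale[i])
      dig <- as.integer(pmin.int(pmax.int(dig, dmin), dmax))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
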