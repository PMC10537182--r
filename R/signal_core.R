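#' @useDynLib wavestate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd quantile median fft rnorm runif predict cor
#' @importFrom utils read.csv write.csv write.table head tail
"_PACKAGE"

MENTAL_STATES <- c("focused", "unfocused", "drowsy")

#' Construct a labeled multichannel EEG recording
#'
#' A `Recording` is the basic container of the pipeline: a channels x samples
#' numeric matrix (microvolts), its sampling rate, ordered channel names and
#' subject/session/state metadata. The reference configuration is a 14-channel
#' headset sampled at 128 Hz, but any channel count and rate are accepted.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one per row of `signal`. Defaults to
#'   `"ch1"..."chN"`.
#' @param subject_id,session_id identifier strings.
#' @param state one of `"focused"`, `"unfocused"`, `"drowsy"`, or `NA` for an
#'   unlabeled recording.
#' @return An object of class `"Recording"`.
#' @export
new_recording <- function(signal, fs, channel_names = NULL,
                          subject_id = "s1", session_id = "r1",
                          state = NA_character_) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a numeric matrix (channels x samples)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stop("channel_names must have one entry per channel")
  bad <- which(!is.finite(signal), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-finite value in channel '%s' (row %d, sample %d)",
      channel_names[bad[1L, 1L]], bad[1L, 1L], bad[1L, 2L]))
  }
  if (!is.na(state)) state <- match.arg(state, MENTAL_STATES)
  structure(list(
    signal = signal, fs = as.numeric(fs),
    channel_names = as.character(channel_names),
    subject_id = as.character(subject_id),
    session_id = as.character(session_id),
    state = state), class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat(sprintf("  subject=%s session=%s state=%s\n",
              x$subject_id, x$session_id, x$state))
  invisible(x)
}

#' Load a recording from disk
#'
#' Supported formats: `"edf"` (European Data Format, 16-bit), and
#' `"matrix_csv"` (plain numeric CSV, rows = channels, no header unless a
#' sidecar says otherwise). Headerless matrix files carry no sampling rate, so
#' `fs` must be supplied explicitly (or through a YAML sidecar `<path>.meta.yml`
#' with fields `fs`, `channel_names`, `subject_id`, `session_id`, `state`).
#'
#' @param path file path.
#' @param format `"edf"` or `"matrix_csv"`. Default guesses from the extension.
#' @param fs sampling rate in Hz, required for matrix files without a sidecar.
#' @param ... metadata overrides passed to [new_recording()].
#' @return A [new_recording()] object with validated invariants.
#' @export
load_recording <- function(path, format = c("auto", "edf", "matrix_csv"),
                           fs = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix_csv"
  }
  if (format == "edf") return(read_edf(path, ...))
  meta <- list()
  sidecar <- paste0(path, ".meta.yml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs))
    stop("matrix files have no header: supply fs explicitly or via a ",
         "'", basename(sidecar), "' sidecar")
  # rows = channels, so files are wide; parse line-wise (read.csv's
  # per-column handling is pathological at thousands of columns)
  lines <- readLines(path)
  m <- do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE),
                             as.numeric))
  dimnames(m) <- NULL
  args <- list(signal = m, fs = fs,
               channel_names = meta$channel_names,
               subject_id = meta$subject_id %||% "s1",
               session_id = meta$session_id %||% "r1",
               state = meta$state %||% NA_character_)
  over <- list(...)
  args[names(over)] <- over
  do.call(new_recording, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording as a matrix CSV plus YAML sidecar
#'
#' Inverse of [load_recording()] for the `matrix_csv` format. Rows are
#' channels; the sidecar `<path>.meta.yml` stores fs, channel names and
#' subject/session/state metadata.
#'
#' @param rec a `Recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "Recording"))
  writeLines(vapply(seq_len(nrow(rec$signal)), function(i)
    paste(sprintf("%.17g", rec$signal[i, ]), collapse = ","),
    character(1)), path)
  yaml::write_yaml(list(fs = rec$fs, channel_names = rec$channel_names,
                        subject_id = rec$subject_id,
                        session_id = rec$session_id,
                        state = if (is.na(rec$state)) NULL else rec$state),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' Cut a recording into fixed-length non-overlapping windows
#'
#' Windows are contiguous from the start of the recording; a trailing
#' remainder shorter than one window is dropped, so every segment has exactly
#' `round(window_seconds * fs)` samples (3840 for the default 30 s at 128 Hz).
#'
#' @param rec a `Recording`.
#' @param window_seconds window length in seconds (default 30).
#' @param overlap_fraction fraction of window overlap in `[0, 1)` (default 0,
#'   the non-overlapping design).
#' @return List of `Segment` objects, each carrying the parent metadata and a
#'   `window_index`.
#' @export
segment_recording <- function(rec, window_seconds = 30, overlap_fraction = 0) {
  stopifnot(inherits(rec, "Recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  w <- round(window_seconds * rec$fs)
  n <- ncol(rec$signal)
  if (n < w) stop("recording shorter than one window")
  step <- max(1L, round(w * (1 - overlap_fraction)))
  starts <- seq(1L, n - w + 1L, by = step)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    structure(list(
      signal = rec$signal[, s:(s + w - 1L), drop = FALSE],
      fs = rec$fs, subject_id = rec$subject_id,
      session_id = rec$session_id, state = rec$state,
      window_index = i), class = "Segment")
  })
}

#' Bundle segments with aligned class labels
#'
#' @param segments list of `Segment`s sharing channel count and fs.
#' @param labels optional factor/character of states; defaults to each
#'   segment's own `state`.
#' @return A `SegmentSet`: list with `segments`, `labels` (factor) and a
#'   provenance data frame (subject, session, state, window).
#' @export
new_segment_set <- function(segments, labels = NULL) {
  stopifnot(length(segments) > 0L)
  nch <- vapply(segments, function(s) nrow(s$signal), integer(1))
  if (length(unique(nch)) != 1L) stop("segments differ in channel count")
  if (is.null(labels))
    labels <- vapply(segments, function(s) s$state, character(1))
  if (length(labels) != length(segments))
    stop("labels must align 1:1 with segments")
  prov <- data.frame(
    subject_id = vapply(segments, `[[`, character(1), "subject_id"),
    session_id = vapply(segments, `[[`, character(1), "session_id"),
    state = vapply(segments, `[[`, character(1), "state"),
    window_index = vapply(segments, `[[`, integer(1), "window_index"),
    stringsAsFactors = FALSE)
  structure(list(segments = segments,
                 labels = factor(labels),
                 provenance = prov),
            class = "SegmentSet")
}

#' @export
print.SegmentSet <- function(x, ...) {
  cat(sprintf("<SegmentSet> %d segments, %d channels, labels: %s\n",
              length(x$segments), nrow(x$segments[[1]]$signal),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Zero-phase band-pass filter a recording
#'
#' Forward-backward (zero-phase) Butterworth filtering of every channel.
#' The reference headset band-limits on the device (0.2-43 Hz), so this step
#' is optional pre-processing for recordings from other sources.
#'
#' @param rec a `Recording`.
#' @param low_hz,high_hz band edges, `0 <= low < high < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return A band-limited copy of `rec`, same length.
#' @export
bandpass <- function(rec, low_hz = 0.2, high_hz = 43, order = 4) {
  stopifnot(inherits(rec, "Recording"))
  nyq <- rec$fs / 2
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 <= low < high < fs/2")
  if (low_hz == 0) {
    flt <- signal::butter(order, high_hz / nyq, type = "low")
  } else {
    flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  out <- rec
  for (i in seq_len(nrow(rec$signal)))
    out$signal[i, ] <- signal::filtfilt(flt, rec$signal[i, ])
  out
}
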