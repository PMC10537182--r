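test_that("matrix CSV recordings load with validated invariants", {
  rec <- tiny_recording(channels = 14, seconds = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- load_recording(path, format = "matrix_csv")
  expect_s3_class(back, "Recording")
  expect_equal(nrow(back$signal), 14)
  expect_equal(ncol(back$signal) / back$fs, 30)
  expect_equal(back$signal, rec$signal, tolerance = 1e-12)

  # headerless matrices refuse to guess the sampling rate
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.table(rec$signal, path2, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_error(load_recording(path2, format = "matrix_csv"), "fs")
  expect_equal(load_recording(path2, format = "matrix_csv", fs = 128)$fs,
               128)
})

test_that("non-finite samples are rejected naming the channel", {
  sig <- matrix(rnorm(40), nrow = 2)
  sig[2, 7] <- NaN
  expect_error(new_recording(sig, 128, channel_names = c("F3", "F4")),
               "F4.*row 2.*sample 7")
})

test_that("EDF files round-trip with their signal labels", {
  labels <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2", "P8",
              "T8", "FC6", "F4", "F8", "AF4")
  rec <- tiny_recording(channels = 14, seconds = 4, seed = 3)
  rec$channel_names <- labels
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- load_recording(path, format = "edf")
  expect_equal(back$channel_names, labels)
  expect_equal(back$fs, 128)
  expect_equal(dim(back$signal), dim(rec$signal))
  # 16-bit quantization: errors bounded by one digital step
  step <- (max(rec$signal) - min(rec$signal)) / 65535
  expect_lt(max(abs(back$signal - rec$signal)), 2 * step)
})

test_that("segmentation follows the floor rule with exact window sizes", {
  rec <- tiny_recording(channels = 3, seconds = 600)   # 10 min
  segs <- segment_recording(rec, 30)
  expect_length(segs, 20)
  expect_true(all(vapply(segs, function(s) ncol(s$signal), integer(1)) ==
                    3840))
  expect_length(segment_recording(tiny_recording(seconds = 30), 30), 1)
  expect_length(segment_recording(tiny_recording(seconds = 45), 30), 1)
  expect_error(segment_recording(tiny_recording(seconds = 20), 30),
               "shorter")
})

test_that("segment concatenation reproduces the leading samples exactly", {
  rec <- tiny_recording(channels = 2, seconds = 95, seed = 5)
  segs <- segment_recording(rec, 30)
  expect_length(segs, 3)
  recon <- do.call(cbind, lapply(segs, `[[`, "signal"))
  expect_identical(recon, rec$signal[, seq_len(3 * 3840)])
  # count independent of channel count
  for (nch in c(1, 5)) {
    expect_length(segment_recording(tiny_recording(channels = nch,
                                                   seconds = 95), 30), 3)
  }
})

test_that("overlapping segmentation uses the configured stride", {
  rec <- tiny_recording(seconds = 60)
  segs <- segment_recording(rec, 30, overlap_fraction = 0.5)
  expect_length(segs, 3)   # starts at 0, 15, 30 s
})

test_that("zero-phase bandpass keeps the passband and kills the stopband", {
  fs <- 128
  t <- (0:(60 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  rec50 <- new_recording(matrix(sin(2 * pi * 50 * t), 1), fs)
  out50 <- bandpass(rec50, 0.2, 43)
  expect_lt(rms(out50$signal) / rms(rec50$signal), 0.05)
  rec10 <- new_recording(matrix(sin(2 * pi * 10 * t), 1), fs)
  out10 <- bandpass(rec10, 0.2, 43)
  expect_lt(abs(rms(out10$signal) / rms(rec10$signal) - 1), 0.05)
  z <- bandpass(new_recording(matrix(0, 1, fs * 10), fs), 0.2, 43)
  expect_equal(max(abs(z$signal)), 0)
  expect_equal(ncol(out10$signal), length(t))
  expect_error(bandpass(rec10, 43, 0.2), "band edges")
  expect_error(bandpass(rec10, 1, 70), "band edges")
})
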