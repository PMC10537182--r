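# Small fixtures built in code.

with_seed <- wavestate:::with_seed

tiny_recording <- function(channels = 2, seconds = 60, fs = 128, seed = 1,
                           state = "focused") {
  n <- round(seconds * fs)
  sig <- with_seed(seed, matrix(rnorm(channels * n), nrow = channels))
  new_recording(sig, fs, state = state)
}

# SegmentSet with class-dependent mean shift in the raw signal (fast to
# classify without the wavelet stages)
tiny_segment_set <- function(per_class = 6, channels = 2, seconds = 30,
                             fs = 128, seed = 1, shift = 0) {
  states <- c("focused", "unfocused", "drowsy")
  segs <- list()
  with_seed(seed, {
    for (s in seq_along(states)) {
      for (i in seq_len(per_class)) {
        sig <- matrix(rnorm(channels * seconds * fs), nrow = channels) *
          (1 + shift * (s - 1))
        rec <- new_recording(sig, fs, state = states[s],
                             subject_id = paste0("s", i))
        segs <- c(segs, segment_recording(rec, seconds))
      }
    }
  })
  new_segment_set(segs)
}

# feature matrix with planted structure: `informative` columns carry the
# class signal, the rest are pure noise
planted_feature_matrix <- function(n_per_class = 60, informative = c(1, 2),
                                   n_features = 8, channels = 1,
                                   noise = 0.2, seed = 1) {
  states <- c("a", "b", "c")
  y <- factor(rep(states, each = n_per_class))
  ncls <- as.integer(y)
  with_seed(seed, {
    cols <- lapply(seq_len(n_features * channels), function(j) {
      f <- (j - 1) %/% channels + 1
      if (f %in% informative) ncls + rnorm(length(y), 0, noise)
      else rnorm(length(y))
    })
  })
  values <- do.call(cbind, cols)
  meta <- data.frame(
    transform = "mdwt", subband = 1,
    channel = rep(seq_len(channels), times = n_features),
    feature = paste0("f", rep(seq_len(n_features), each = channels)))
  colnames(values) <- paste(meta$transform, meta$subband, meta$channel,
                            meta$feature, sep = ".")
  wavestate:::new_feature_matrix(values, y, meta)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
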