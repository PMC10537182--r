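# Synthetic multichannel EEG with state-dependent rhythm power. Each
# channel is a sum of band-limited Gaussian noise components (one per
# classical EEG rhythm, synthesized in the frequency domain with random
# phases and exactly shaped magnitude) plus a 1/f pink-noise floor, scaled
# by a per-subject multiplicative gain. The default state profiles encode
# the physiological expectations the pipeline relies on: drowsiness is
# slow-wave (theta/alpha) dominant, focus is beta dominant, the unfocused
# state is spectrally flat.

EEG_BANDS <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 43))

#' State profile: relative rhythm-band power of one mental state
#'
#' @param delta,theta,alpha,beta,gamma non-negative band variances
#'   (arbitrary power units; only ratios matter to the classifier).
#' @param pink variance of the 1/f noise floor (default 0.8).
#' @param jitter_sd SD of the per-subject log-normal gain (default 0.1).
#' @return A list of class `"StateProfile"`.
#' @export
state_profile <- function(delta, theta, alpha, beta, gamma, pink = 0.8,
                          jitter_sd = 0.1) {
  bp <- c(delta = delta, theta = theta, alpha = alpha, beta = beta,
          gamma = gamma)
  if (any(bp < 0) || all(bp == 0))
    stop("band powers must be >= 0 with at least one > 0")
  structure(list(band_power = bp, pink = pink, jitter_sd = jitter_sd),
            class = "StateProfile")
}

#' Default (well-separated) state profiles
#'
#' Drowsy: theta/alpha dominant with a 4:1 alpha-to-beta ratio; focused:
#' beta dominant; unfocused: flat across rhythms.
#'
#' @return Named list of three `StateProfile`s.
#' @export
default_profiles <- function() {
  list(focused = state_profile(0.6, 0.7, 1.0, 2.5, 0.8),
       unfocused = state_profile(1, 1, 1, 1, 0.6),
       drowsy = state_profile(1.6, 2.3, 2.0, 0.5, 0.2))
}

#' Null profiles: the same flat spectrum for every state
#'
#' Used for negative controls: with identical profiles no classifier can
#' beat chance except by overfitting noise.
#'
#' @return Named list of three identical `StateProfile`s.
#' @export
null_profiles <- function() {
  p <- state_profile(1, 1, 1, 1, 1)
  list(focused = p, unfocused = p, drowsy = p)
}

#' Simulation configuration
#'
#' @param n_subjects,sessions_per_subject cohort structure (defaults 1, 1).
#' @param minutes_per_state continuous minutes recorded per state per
#'   session (default 10, i.e. 20 thirty-second segments).
#' @param fs sampling rate (default 128 Hz).
#' @param channels channel count (default 14).
#' @param profiles named list of `StateProfile`s, one per state.
#' @param master_seed master RNG seed; every recording derives its own
#'   stream from it.
#' @return A list of class `"SimConfig"`.
#' @export
sim_config <- function(n_subjects = 1, sessions_per_subject = 1,
                       minutes_per_state = 10, fs = 128, channels = 14,
                       profiles = default_profiles(), master_seed = 1) {
  stopifnot(n_subjects >= 1, sessions_per_subject >= 1,
            minutes_per_state > 0, fs > 0, channels >= 1)
  n <- fs * 60 * minutes_per_state
  if (abs(n - round(n)) > 1e-9)
    stop("fs * 60 * minutes_per_state must be an integer sample count")
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 minutes_per_state = minutes_per_state, fs = fs,
                 channels = as.integer(channels), profiles = profiles,
                 master_seed = as.integer(master_seed)),
            class = "SimConfig")
}

# deterministic sub-stream seed from the master seed and a string tag
derive_seed <- function(master, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(master) * 7919 + h) %% 2147483629)
}

# band-limited Gaussian noise via frequency-domain synthesis: random
# phases, flat magnitude inside [f1, f2), rescaled to the target variance.
band_noise <- function(n, fs, f1, f2, variance) {
  if (variance <= 0) return(numeric(n))
  freq <- (seq_len(n) - 1) * fs / n
  half <- 2:(floor(n / 2))                     # positive non-DC, non-Nyquist
  inband <- half[freq[half] >= f1 & freq[half] < f2]
  if (length(inband) == 0) return(numeric(n))
  X <- complex(n)
  X[inband] <- complex(real = rnorm(length(inband)),
                       imaginary = rnorm(length(inband)))
  X[n + 2 - inband] <- Conj(X[inband])
  x <- Re(fft(X, inverse = TRUE)) / n
  x * sqrt(variance) / sd(x)
}

pink_noise <- function(n, fs, variance, f_lo = 0.5) {
  if (variance <= 0) return(numeric(n))
  freq <- (seq_len(n) - 1) * fs / n
  half <- 2:(floor(n / 2))
  keep <- half[freq[half] >= f_lo]
  X <- complex(n)
  X[keep] <- complex(real = rnorm(length(keep)),
                     imaginary = rnorm(length(keep))) / sqrt(freq[keep])
  X[n + 2 - keep] <- Conj(X[keep])
  x <- Re(fft(X, inverse = TRUE)) / n
  x * sqrt(variance) / sd(x)
}

#' Generate one synthetic recording
#'
#' Deterministic given `(cfg$master_seed, subject, session, state)`; the
#' per-subject gain is drawn once per subject (log-normal with the
#' profile's `jitter_sd`), so all of a subject's recordings share it.
#'
#' @param profile a `StateProfile`.
#' @param cfg a [sim_config()].
#' @param subject,session 1-based indices.
#' @param state state label attached to the recording.
#' @return A `Recording` of `cfg$channels` x `fs * 60 * minutes_per_state`.
#' @export
generate_recording <- function(profile, cfg, subject = 1, session = 1,
                               state = "focused") {
  n <- as.integer(round(cfg$fs * 60 * cfg$minutes_per_state))
  gain <- with_seed(derive_seed(cfg$master_seed, paste0("subj", subject)),
                    exp(rnorm(1, 0, profile$jitter_sd)))
  sig <- with_seed(
    derive_seed(cfg$master_seed,
                paste("rec", subject, session, state, sep = "/")), {
    t(vapply(seq_len(cfg$channels), function(ch) {
      x <- pink_noise(n, cfg$fs, profile$pink)
      for (b in names(EEG_BANDS)) {
        bd <- EEG_BANDS[[b]]
        x <- x + band_noise(n, cfg$fs, bd[1], bd[2], profile$band_power[[b]])
      }
      gain * x
    }, numeric(n)))
  })
  new_recording(sig, cfg$fs,
                subject_id = paste0("subj", subject),
                session_id = paste0("sess", session),
                state = state)
}

#' Generate a full labeled synthetic dataset
#'
#' One recording per (subject, session, state), segmented into 30 s
#' non-overlapping windows; equal minutes per state give exactly balanced
#' classes.
#'
#' @param cfg a [sim_config()].
#' @param window_seconds segmentation window (default 30).
#' @return A `SegmentSet`.
#' @export
generate_dataset <- function(cfg, window_seconds = 30) {
  segs <- list()
  for (su in seq_len(cfg$n_subjects)) {
    for (se in seq_len(cfg$sessions_per_subject)) {
      for (st in names(cfg$profiles)) {
        rec <- generate_recording(cfg$profiles[[st]], cfg, su, se, st)
        segs <- c(segs, segment_recording(rec, window_seconds))
      }
    }
  }
  new_segment_set(segs)
}

#' Periodogram band power of a signal
#'
#' Average power (variance contribution) of `x` in the band `[f1, f2)` Hz,
#' from the raw FFT periodogram. Used to audit the generator.
#'
#' @param x numeric signal; `fs` sampling rate; `f1`,`f2` band edges (Hz).
#' @param fs sampling rate (Hz).
#' @param f1,f2 band edges (Hz).
#' @return Power in the band (same units as `var(x)`).
#' @export
band_power <- function(x, fs, f1, f2) {
  n <- length(x)
  X <- fft(x - mean(x))
  p <- Mod(X)^2 / n^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- 2:(floor(n / 2) + 1)
  2 * sum(p[half][freq[half] >= f1 & freq[half] < f2])
}
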