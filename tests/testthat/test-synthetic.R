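test_that("generation is deterministic given the seed structure", {
  cfg <- sim_config(minutes_per_state = 0.5, channels = 3, master_seed = 5)
  r1 <- generate_recording(default_profiles()$drowsy, cfg, 1, 1, "drowsy")
  r2 <- generate_recording(default_profiles()$drowsy, cfg, 1, 1, "drowsy")
  expect_identical(r1$signal, r2$signal)
  r3 <- generate_recording(default_profiles()$drowsy, cfg, 1, 2, "drowsy")
  expect_false(identical(r1$signal, r3$signal))
})

test_that("dataset structure matches the configured segmentation", {
  cfg <- sim_config(n_subjects = 1, minutes_per_state = 10, channels = 2,
                    master_seed = 2)
  ds <- generate_dataset(cfg)
  expect_length(ds$segments, 60)
  expect_equal(as.integer(table(ds$labels)), rep(20L, 3))
  expect_true(all(vapply(ds$segments, function(s) ncol(s$signal),
                         integer(1)) == 3840))
  expect_equal(ds$segments[[1]]$fs, 128)
})

test_that("generated band powers track the requested profiles", {
  # single-band profiles with no pink floor: power concentrates in band
  cfg <- sim_config(minutes_per_state = 0.5, channels = 1, master_seed = 1)
  p_alpha <- state_profile(0, 0, 1, 0, 0, pink = 0)
  x <- generate_recording(p_alpha, cfg, 1, 1, "drowsy")$signal[1, ]
  expect_gte(band_power(x, 128, 8, 13) / var(x), 0.95)
  # multi-band profile: each band's power within 10 % averaged over seeds
  prof <- state_profile(1, 2, 3, 1.5, 0.5, pink = 0, jitter_sd = 0)
  ratios <- sapply(1:10, function(s) {
    cfg2 <- sim_config(minutes_per_state = 0.5, channels = 1,
                       master_seed = 100 + s)
    x <- generate_recording(prof, cfg2, 1, 1, "focused")$signal[1, ]
    vapply(names(wavestate:::EEG_BANDS), function(b) {
      bd <- wavestate:::EEG_BANDS[[b]]
      band_power(x, 128, bd[1], bd[2]) / prof$band_power[[b]]
    }, numeric(1))
  })
  expect_true(all(abs(rowMeans(ratios) - 1) < 0.1))
})

test_that("the drowsy default is alpha-dominant over beta", {
  cfg <- sim_config(minutes_per_state = 0.5, channels = 1, master_seed = 3)
  x <- generate_recording(default_profiles()$drowsy, cfg, 1, 1,
                          "drowsy")$signal[1, ]
  expect_gte(band_power(x, 128, 8, 13) / band_power(x, 128, 13, 30), 2)
})

test_that("the FAWT branch alone recovers well-separated states", {
  # 1 subject x 10 min/state, 4 channels to keep the screen affordable:
  # screen the 7 FAWT subbands, take the best, mRMR top-4, optimize, TFCV
  ds <- generate_dataset(sim_config(n_subjects = 1, channels = 4,
                                    master_seed = 11))
  tab <- subband_accuracy_table(ds, "fawt", fawt_params(),
                                cv_scheme("kfold_5"), seed = 1, L = 25)
  best_sb <- which.max(tab$accuracy)
  fm <- extract_subband_features(ds, "fawt", fawt_params(), best_sb)
  top <- select_top(fm, rank_features(fm), 4)
  opt <- optimize_ensemble(top, budget = 6, cv_scheme("kfold_5"), seed = 2)
  rep <- evaluate_cv(opt$best_spec, top, cv_scheme("kfold_10"), seed = 1)
  expect_gte(rep$accuracy, 0.90)
})

test_that("invalid profiles and configs are rejected", {
  expect_error(state_profile(-1, 0, 1, 0, 0), "band powers")
  expect_error(state_profile(0, 0, 0, 0, 0), "band powers")
  expect_error(sim_config(n_subjects = 0), "n_subjects")
})

test_that("synthetic recordings survive the real I/O path", {
  cfg <- sim_config(minutes_per_state = 0.5, channels = 3, master_seed = 9)
  rec <- generate_recording(default_profiles()$focused, cfg, 1, 1, "focused")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, csv)
  back <- load_recording(csv)
  expect_equal(back$signal, rec$signal, tolerance = 1e-10)
  expect_equal(back$state, "focused")
  edf <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, edf)
  backe <- read_edf(edf)
  expect_equal(dim(backe$signal), dim(rec$signal))
})
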