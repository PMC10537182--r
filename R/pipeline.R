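# Config-driven pipeline stages behind the command-line front end:
# simulate -> decompose -> features -> rank -> fuse -> train-eval, plus a
# `reproduce` command that runs the whole chain in memory and emits a
# summary table (per-subband accuracies per transform, fusion and IMV
# rows). One declarative YAML config holds every parameter; each stage
# logs its parameters and writes a sidecar with the config hash so reruns
# are auditable.

#' Default pipeline configuration
#'
#' @return Nested list understood by the `cmd_*` stage functions: simulate
#'   settings, the three transform parameter sets, subband choices,
#'   ranking/fusion settings, classifier search settings, seed, out_dir.
#' @export
default_pipeline_config <- function() {
  list(
    simulate = list(n_subjects = 3, sessions_per_subject = 1,
                    minutes_per_state = 10, fs = 128, channels = 14,
                    profiles = "default", master_seed = 11),
    window_seconds = 30,
    transforms = list(
      mdwt = list(wavelet_name = "db2", levels = 4),
      tqwt = list(q = 2, R = 5, B = 7),
      fawt = list(B = 6, p = 3, q = 5, r = 2, s = 3)),
    subbands = list(mode = "fixed", mdwt = 1, tqwt = 1, fawt = 7),
    ranking = list(bins = 10, k = 4),
    classifier = list(budget = 10, cv = "kfold_10", imv_rounds = 10,
                      paper_eq11 = FALSE),
    decompose_limit = 5,
    seed = 1,
    out_dir = "wavestate_out")
}

#' Load a pipeline config file (YAML), merged over the defaults
#' @param path YAML file; missing fields fall back to
#'   [default_pipeline_config()].
#' @return Config list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  cfg
}

config_hash <- function(cfg) {
  s <- yaml::as.yaml(cfg)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 0xFFFFFFFB
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stage_log <- function(stage, cfg, t0, extra = list()) {
  info <- c(list(stage = stage, config_hash = config_hash(cfg),
                 seed = cfg$seed,
                 elapsed_s = round((proc.time() - t0)[[3]], 2),
                 when = format(Sys.time(), "%Y-%m-%d %H:%M:%S")), extra)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(info, file.path(cfg$out_dir,
                                   paste0(stage, ".meta.yml")))
  message(sprintf("[%s] done in %.1fs (config %s)", stage,
                  info$elapsed_s, info$config_hash))
  invisible(info)
}

transform_params <- function(cfg, transform) {
  tp <- cfg$transforms[[transform]]
  switch(transform,
         mdwt = do.call(mdwt_params, tp),
         tqwt = do.call(tqwt_params, tp),
         fawt = do.call(fawt_params, tp),
         stop("unknown transform '", transform, "'"))
}

sim_config_from <- function(cfg) {
  s <- cfg$simulate
  profiles <- if (identical(s$profiles, "null")) null_profiles()
              else if (identical(s$profiles, "default")) default_profiles()
              else lapply(s$profiles, function(p) do.call(state_profile, p))
  sim_config(s$n_subjects, s$sessions_per_subject, s$minutes_per_state,
             s$fs, s$channels, profiles, s$master_seed)
}

rec_dir <- function(cfg) file.path(cfg$out_dir, "recordings")

#' Pipeline stage: simulate a labeled synthetic dataset
#'
#' Writes one matrix CSV (+ YAML sidecar) per (subject, session, state)
#' recording under `<out_dir>/recordings/`, plus the segment provenance
#' table, so downstream stages exercise the same I/O path as real data.
#'
#' @param cfg a pipeline config ([load_pipeline_config()]).
#' @return The recordings directory, invisibly.
#' @export
cmd_simulate <- function(cfg = default_pipeline_config()) {
  t0 <- proc.time()
  sc <- sim_config_from(cfg)
  dir.create(rec_dir(cfg), showWarnings = FALSE, recursive = TRUE)
  n_rec <- 0L
  for (su in seq_len(sc$n_subjects))
    for (se in seq_len(sc$sessions_per_subject))
      for (st in names(sc$profiles)) {
        rec <- generate_recording(sc$profiles[[st]], sc, su, se, st)
        write_recording_csv(rec, file.path(
          rec_dir(cfg), sprintf("subj%d_sess%d_%s.csv", su, se, st)))
        n_rec <- n_rec + 1L
      }
  ds <- pipeline_segments(cfg)
  write.csv(ds$provenance, file.path(cfg$out_dir, "segments.csv"),
            row.names = FALSE)
  stage_log("simulate", cfg, t0,
            list(recordings = n_rec, segments = length(ds$segments)))
  invisible(rec_dir(cfg))
}

require_stage <- function(path, stage) {
  if (!file.exists(path))
    stop("missing '", path, "': run the `", stage, "` command first",
         call. = FALSE)
  path
}

#' Load and segment the pipeline dataset (recordings written by
#' [cmd_simulate()] or any directory of matrix CSVs with sidecars)
#' @param cfg pipeline config.
#' @return A `SegmentSet`.
#' @export
pipeline_segments <- function(cfg) {
  dir <- require_stage(rec_dir(cfg), "simulate")
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  segs <- list()
  for (f in files) {
    rec <- load_recording(f, format = "matrix_csv")
    segs <- c(segs, segment_recording(rec, cfg$window_seconds))
  }
  new_segment_set(segs)
}

#' Pipeline stage: store subband decompositions for inspection
#'
#' Decomposes the first `cfg$decompose_limit` segments (all channels) with
#' one transform and serializes each `SubbandSet` under
#' `<out_dir>/subbands/<transform>/`.
#'
#' @param cfg pipeline config.
#' @param transform `"mdwt"`, `"tqwt"` or `"fawt"`.
#' @return The store directory, invisibly.
#' @export
cmd_decompose <- function(cfg = default_pipeline_config(),
                          transform = "mdwt") {
  t0 <- proc.time()
  ds <- pipeline_segments(cfg)
  params <- transform_params(cfg, transform)
  base <- file.path(cfg$out_dir, "subbands", transform)
  n <- min(length(ds$segments), cfg$decompose_limit)
  for (i in seq_len(n)) {
    seg <- ds$segments[[i]]
    for (ch in seq_len(nrow(seg$signal))) {
      sbs <- decompose_channel(seg$signal[ch, ], transform, params)
      write_subband_set(sbs, file.path(base, sprintf("seg%03d_ch%02d", i, ch)))
    }
  }
  stage_log(paste0("decompose_", transform), cfg, t0,
            list(segments_stored = n))
  invisible(base)
}

features_path <- function(cfg, transform)
  file.path(cfg$out_dir, paste0("features_", transform, ".csv"))

#' Pipeline stage: per-subband feature extraction
#' @param cfg pipeline config.
#' @param transform transform id.
#' @param subband_index subband to extract (default: the configured one).
#' @return The written `FeatureMatrix`, invisibly.
#' @export
cmd_features <- function(cfg = default_pipeline_config(),
                         transform = "mdwt",
                         subband_index = cfg$subbands[[transform]]) {
  t0 <- proc.time()
  ds <- pipeline_segments(cfg)
  fm <- extract_subband_features(ds, transform,
                                 transform_params(cfg, transform),
                                 subband_index)
  write_feature_matrix(fm, features_path(cfg, transform))
  stage_log(paste0("features_", transform), cfg, t0,
            list(subband = subband_index, columns = ncol(fm$values)))
  invisible(fm)
}

ranking_path <- function(cfg, transform)
  file.path(cfg$out_dir, paste0("ranking_", transform, ".csv"))

#' Pipeline stage: mRMR feature ranking
#' @param cfg pipeline config; `transform` transform id.
#' @param transform transform id.
#' @return The `FeatureRanking`, invisibly.
#' @export
cmd_rank <- function(cfg = default_pipeline_config(), transform = "mdwt") {
  t0 <- proc.time()
  fm <- read_feature_matrix(require_stage(features_path(cfg, transform),
                                          "features"))
  rk <- rank_features(fm, bins = cfg$ranking$bins)
  write_ranking(rk, ranking_path(cfg, transform))
  stage_log(paste0("rank_", transform), cfg, t0,
            list(top = rk$feature[1]))
  invisible(rk)
}

#' Pipeline stage: cross-transform feature fusion
#'
#' Reads the per-transform feature matrices and rankings and concatenates
#' the top-k feature types of each.
#'
#' @param cfg pipeline config.
#' @param transforms transforms to fuse (default all three).
#' @return The fused `FeatureMatrix`, invisibly.
#' @export
cmd_fuse <- function(cfg = default_pipeline_config(),
                     transforms = c("mdwt", "tqwt", "fawt")) {
  t0 <- proc.time()
  pairs <- lapply(transforms, function(tr) {
    fm <- read_feature_matrix(require_stage(features_path(cfg, tr),
                                            "features"))
    rk_df <- read.csv(require_stage(ranking_path(cfg, tr), "rank"))
    list(fm = fm, ranking = rk_df)
  })
  fused <- fuse_features(pairs, cfg$ranking$k)
  write_feature_matrix(fused, file.path(cfg$out_dir, "features_fused.csv"))
  stage_log("fuse", cfg, t0, list(k = cfg$ranking$k,
                                  columns = ncol(fused$values)))
  invisible(fused)
}

#' Pipeline stage: optimize, evaluate and run iterative majority voting
#'
#' Random-search optimization on the fused features under the configured
#' CV scheme, evaluation of the best learner, and `imv_rounds` of ten-fold
#' CV for the IMV summary. Writes `metrics.csv`, `metrics.json` and
#' `imv.csv` under the output directory.
#'
#' @param cfg pipeline config.
#' @param features_file feature CSV to train on (default the fused one).
#' @return List with `opt`, `report`, `imv`, invisibly.
#' @export
cmd_train_eval <- function(cfg = default_pipeline_config(),
                           features_file = file.path(cfg$out_dir,
                                                     "features_fused.csv")) {
  t0 <- proc.time()
  fm <- read_feature_matrix(require_stage(features_file, "fuse"))
  scheme <- cv_scheme(cfg$classifier$cv)
  opt <- optimize_ensemble(fm, cfg$classifier$budget, scheme,
                           seed = cfg$seed)
  rep <- evaluate_cv(opt$best_spec, fm, scheme, seed = cfg$seed,
                     paper_eq11 = isTRUE(cfg$classifier$paper_eq11))
  imv <- imv_tfcv(opt$best_spec, fm, cfg$classifier$imv_rounds,
                  base_seed = cfg$seed,
                  paper_eq11 = isTRUE(cfg$classifier$paper_eq11))
  write.csv(rep$per_class, file.path(cfg$out_dir, "metrics.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = rep$accuracy, method = opt$best_spec$method,
         cv = cfg$classifier$cv,
         imv_best_overall = imv$best_overall_accuracy,
         imv_best_foldwise = imv$best_foldwise_accuracy),
    file.path(cfg$out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(round = seq_along(imv$round_accuracy),
                       accuracy = imv$round_accuracy),
            file.path(cfg$out_dir, "imv.csv"), row.names = FALSE)
  stage_log("train_eval", cfg, t0,
            list(accuracy = rep$accuracy, method = opt$best_spec$method))
  invisible(list(opt = opt, report = rep, imv = imv))
}

#' Per-subband accuracy table for one transform
#'
#' The subband-screening logic: every subband's feature matrix is
#' evaluated with a fixed bagged-tree ensemble under the given scheme,
#' yielding one accuracy per subband.
#'
#' @param ds a `SegmentSet`.
#' @param transform transform id; `params` its parameter bundle.
#' @param params transform parameter bundle.
#' @param scheme a [cv_scheme()].
#' @param seed RNG seed.
#' @param L screening ensemble size (default 50).
#' @return Data frame with `subband` and `accuracy`.
#' @export
subband_accuracy_table <- function(ds, transform, params,
                                   scheme = cv_scheme("kfold_10"),
                                   seed = 1, L = 50) {
  k <- switch(transform, mdwt = params$levels + 1L, params$B + 1L)
  acc <- vapply(seq_len(k), function(sb) {
    fm <- extract_subband_features(ds, transform, params, sb)
    evaluate_cv(learner_spec("bagged_tree", L = L), fm, scheme,
                seed = seed)$accuracy
  }, numeric(1))
  data.frame(subband = paste0("SB-", seq_len(k)), accuracy = acc)
}

#' Run the full pipeline chain and emit a summary table
#'
#' simulate -> decompose (x3) -> features -> rank -> fuse -> train/eval,
#' with a per-subband accuracy screen for each transform when
#' `cfg$subbands$mode == "auto"` (the best subband of each transform is
#' then used for fusion; with `"fixed"` the configured indices are used
#' and only those subbands are evaluated). The summary has one row per
#' (transform, subband) accuracy plus fusion and IMV rows.
#'
#' @param cfg pipeline config.
#' @return Data frame summary (also written to `<out_dir>/summary.csv`).
#' @export
cmd_reproduce <- function(cfg = default_pipeline_config()) {
  t0 <- proc.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!file.exists(rec_dir(cfg))) cmd_simulate(cfg)
  ds <- pipeline_segments(cfg)
  scheme <- cv_scheme(cfg$classifier$cv)
  rows <- list()
  pairs <- list()
  for (tr in c("mdwt", "tqwt", "fawt")) {
    params <- transform_params(cfg, tr)
    cmd_decompose(cfg, tr)
    if (identical(cfg$subbands$mode, "auto")) {
      tab <- subband_accuracy_table(ds, tr, params, scheme, cfg$seed)
      best_sb <- which.max(tab$accuracy)
      rows[[tr]] <- data.frame(stage = tr, item = tab$subband,
                               accuracy = tab$accuracy)
    } else {
      best_sb <- cfg$subbands[[tr]]
    }
    fm <- extract_subband_features(ds, tr, params, best_sb)
    write_feature_matrix(fm, features_path(cfg, tr))
    rk <- rank_features(fm, bins = cfg$ranking$bins)
    write_ranking(rk, ranking_path(cfg, tr))
    if (!identical(cfg$subbands$mode, "auto")) {
      acc <- evaluate_cv(learner_spec("bagged_tree"), fm, scheme,
                         seed = cfg$seed)$accuracy
      rows[[tr]] <- data.frame(stage = tr,
                               item = paste0("SB-", best_sb),
                               accuracy = acc)
    }
    pairs[[tr]] <- list(fm = fm, ranking = rk)
  }
  fused <- fuse_features(pairs, cfg$ranking$k)
  write_feature_matrix(fused, file.path(cfg$out_dir, "features_fused.csv"))
  res <- cmd_train_eval(cfg)
  rows$fused <- data.frame(
    stage = "fused", item = sprintf("top-%d x 3", cfg$ranking$k),
    accuracy = res$report$accuracy)
  rows$imv <- data.frame(
    stage = "imv", item = c("best_overall", "best_foldwise"),
    accuracy = c(res$imv$best_overall_accuracy,
                 res$imv$best_foldwise_accuracy))
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  write.csv(summary, file.path(cfg$out_dir, "summary.csv"),
            row.names = FALSE)
  stage_log("reproduce", cfg, t0)
  summary
}
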