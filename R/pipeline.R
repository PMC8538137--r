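# End-to-end convenience wrappers over the pipeline stages.

#' Calibrate, orient and featurize a set of recordings
#'
#' For each recording: estimate per-node reference vectors and NEU
#' rotations from the static prefix, rotate all channels into the
#' shared earth frame, run the Mahony AHRS, and extract the windowed
#' feature matrix; the per-trial matrices are stacked.
#'
#' @param recordings list of \code{fall_recording} objects.
#' @param cfg configuration list (\code{\link{default_config}}).
#' @param nodes node ids to include.
#' @return one stacked \code{feature_matrix}.
#' @export
pipeline_features <- function(recordings, cfg = default_config(),
                              nodes = node_ids()) {
  stopifnot(length(recordings) > 0)
  gains <- ahrs_gains(cfg$ahrs$kp, cfg$ahrs$ki)
  feats <- lapply(recordings, function(rec) {
    if (!isTRUE(rec$calibrated)) {
      params <- calibrate_recording(rec, cfg$calibration$n_samples,
                                    cfg$calibration$static_gyro_max)
      rec <- apply_calibration(rec, params)
    }
    ori <- orient_recording(rec, gains = gains, init = cfg$ahrs$init,
                            n_init = cfg$calibration$n_samples)
    extract_features(rec, ori, nodes = nodes,
                     window_s = cfg$features$window_s,
                     hop_s = cfg$features$hop_s,
                     label_rule = cfg$features$label_rule)
  })
  bind_features(feats)
}

#' Simulate, featurize, train and evaluate in one call
#'
#' @param n_subjects subjects to simulate.
#' @param trials_per_activity named trial counts
#'   (\code{\link{default_trial_counts}}).
#' @param seed master seed for simulation and training.
#' @param cfg configuration list.
#' @return list with \code{features}, \code{model} (a
#'   \code{\link{fall_lstm}}) and \code{eval} (a \code{fall_eval}).
#' @export
run_pipeline <- function(n_subjects = 14,
                         trials_per_activity = default_trial_counts(),
                         seed = 1L, cfg = default_config()) {
  recs <- generate_dataset(n_subjects, trials_per_activity,
                           noise = do.call(noise_params, cfg$simulation$noise),
                           seed = seed,
                           sample_rate = cfg$simulation$sample_rate,
                           duration = cfg$simulation$duration)
  features <- pipeline_features(recs, cfg)
  mcfg <- config_to_model(cfg)
  mcfg$seed <- as.integer(seed)
  model <- fall_lstm(features, mcfg)
  list(features = features, model = model, eval = evaluate_detector(model))
}
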