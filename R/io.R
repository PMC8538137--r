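# On-disk formats: per-trial CSV + JSON manifest for recordings,
# CSV feature tables, YAML configuration.

.CSV_COLS <- c("t", "node_id", "ax", "ay", "az", "gx", "gy", "gz",
               "mx", "my", "mz", "label")

#' Write / read one recording
#'
#' Each trial becomes a CSV (columns \code{t, node_id, ax, ay, az, gx,
#' gy, gz, mx, my, mz, label}; units m/s^2, deg/s, uT; one row per node
#' per sample) plus a JSON manifest holding subject, activity, trial,
#' sample rate, node list, static prefix length, seed provenance and —
#' when present — the per-node calibration blocks (v_acc, v_mag, r_neu
#' row-major). A read of a write reproduces every channel to 1e-9.
#'
#' @param recording a \code{fall_recording}.
#' @param dir output directory (created if needed).
#' @return \code{write_recording}: the manifest path, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "fall_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- trial_id(recording)
  csv_path <- file.path(dir, paste0(stem, ".csv"))
  man_path <- file.path(dir, paste0(stem, ".json"))

  tabs <- lapply(names(recording$streams), function(nd) {
    st <- recording$streams[[nd]]
    data.table::data.table(
      t = recording$t, node_id = nd,
      st$accel, st$gyro, st$mag, label = recording$labels)
  })
  tab <- data.table::rbindlist(tabs)
  data.table::setnames(tab, .CSV_COLS)
  data.table::fwrite(tab, csv_path)

  manifest <- list(
    subject_id = recording$subject$subject_id,
    height = recording$subject$height,
    activity = recording$activity,
    trial_index = recording$trial_index,
    sample_rate = recording$sample_rate,
    nodes = names(recording$streams),
    static_prefix_len = recording$static_prefix_len,
    heading_deg = recording$heading_deg,
    seed = recording$seed,
    units = list(accel = "m/s^2", gyro = "deg/s", mag = "uT"),
    files = list(csv = basename(csv_path)))
  if (!is.null(recording$calibration)) {
    manifest$calibration <- lapply(recording$calibration, function(cb) {
      list(v_acc = cb$v_acc, v_mag = cb$v_mag,
           r_neu = as.vector(t(cb$r_neu)))
    })
  }
  if (isTRUE(recording$calibrated)) manifest$calibrated <- TRUE
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man_path)
}

#' @rdname write_recording
#' @param path manifest (.json) path, or the trial stem.
#' @return \code{read_recording}: the reconstructed
#'   \code{fall_recording} (the generator's ground-truth block is not
#'   part of the on-disk format).
#' @export
read_recording <- function(path) {
  if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  csv_path <- file.path(dirname(path), man$files$csv)
  if (!file.exists(csv_path)) stop("recording CSV not found: ", csv_path)
  tab <- data.table::fread(csv_path)
  missing_cols <- setdiff(.CSV_COLS, names(tab))
  if (length(missing_cols)) {
    stop("recording CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  nodes <- man$nodes
  bad <- setdiff(nodes, node_ids())
  if (length(bad)) stop("manifest lists unknown node(s): ",
                        paste(bad, collapse = ", "))
  streams <- vector("list", length(nodes)); names(streams) <- nodes
  labels <- NULL; tvec <- NULL
  for (nd in nodes) {
    sub <- tab[tab$node_id == nd, ]
    if (!nrow(sub)) stop("recording CSV has no rows for node ", nd)
    streams[[nd]] <- list(
      accel = as.matrix(sub[, c("ax", "ay", "az")]),
      gyro = as.matrix(sub[, c("gx", "gy", "gz")]),
      mag = as.matrix(sub[, c("mx", "my", "mz")]))
    labels <- as.integer(sub$label)
    tvec <- sub$t
  }
  rec <- structure(list(
    subject = subject_params(man$subject_id, man$height),
    activity = man$activity,
    is_fall = is_fall_activity(man$activity),
    trial_index = as.integer(man$trial_index),
    sample_rate = man$sample_rate,
    t = tvec, streams = streams, labels = labels,
    static_prefix_len = as.integer(man$static_prefix_len),
    heading_deg = man$heading_deg, seed = man$seed,
    truth = NULL), class = "fall_recording")
  if (!is.null(man$calibration)) {
    rec$calibration <- lapply(man$calibration, function(cb) {
      list(v_acc = unlist(cb$v_acc), v_mag = unlist(cb$v_mag),
           r_neu = matrix(unlist(cb$r_neu), 3, 3, byrow = TRUE))
    })
    names(rec$calibration) <- names(man$calibration)
  }
  if (isTRUE(man$calibrated)) rec$calibrated <- TRUE
  rec
}

#' Write / read a stacked feature matrix
#'
#' CSV with one row per window: the named feature columns
#' (\code{<node>_<channel>_<stat>}) plus \code{label},
#' \code{activity}, \code{subject}, \code{trial}.
#'
#' @param features a \code{feature_matrix}.
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  tab <- data.table::data.table(features$x)
  tab$label <- features$label
  tab$activity <- features$activity
  tab$subject <- features$subject
  tab$trial <- features$trial
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- data.table::fread(path)
  meta <- c("label", "activity", "subject", "trial")
  if (!all(meta %in% names(tab))) {
    stop("feature CSV is missing column(s): ",
         paste(setdiff(meta, names(tab)), collapse = ", "))
  }
  structure(list(
    x = as.matrix(tab[, setdiff(names(tab), meta), with = FALSE]),
    label = as.integer(tab$label),
    activity = tab$activity,
    subject = as.integer(tab$subject),
    trial = tab$trial,
    windows = NULL), class = "feature_matrix")
}

#' Pipeline configuration
#'
#' Nested list of every tunable parameter, overridable from a YAML
#' file: \code{simulation} (sample rate, duration, noise), \code{calibration}
#' (averaging length, static gyro threshold), \code{ahrs} (gains,
#' initialization), \code{features} (window, hop, label rule) and
#' \code{model} (everything in \code{\link{model_config}}).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    simulation = list(sample_rate = 15, duration = 8,
                      noise = unclass(noise_params())),
    calibration = list(n_samples = 15, static_gyro_max = 2),
    ahrs = list(kp = 1.0, ki = 0.0, init = "triad"),
    features = list(window_s = 0.5, hop_s = 0.1, label_rule = "any"),
    model = unclass(model_config()))
}

#' @rdname default_config
#' @param path YAML file with (a subset of) the configuration tree;
#'   missing entries keep their defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' @rdname default_config
#' @param cfg configuration list.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_to_model <- function(cfg) {
  m <- cfg$model
  model_config(lstm_units = m$lstm_units, dense_units = m$dense_units,
               n_classes = m$n_classes, learning_rate = m$learning_rate,
               batch_size = m$batch_size, epochs = m$epochs,
               sequence_length = m$sequence_length,
               sequence_stride = m$sequence_stride,
               train_fraction = m$train_fraction,
               class_weights = m$class_weights,
               standardize = m$standardize,
               max_train_sequences = m$max_train_sequences,
               seed = m$seed)
}
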