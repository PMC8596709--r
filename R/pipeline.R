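#' Pipeline configuration
#'
#' All tunable constants of the processing pipeline in one declarative
#' object. Defaults are the study constants: 0.0061 AAU silence threshold,
#' 3 x IQR temporal outlier fence, 128-sample minimum length, 128-sample
#' STFT window, zero-padding to 8192 samples, GAM basis dimension
#' `max(10, n/50)`, 10-sample minimum autocorrelation peak separation, 1000
#' trees trying 10 variables per split, 70:30 train:validation split.
#'
#' @param threshold Silence threshold, AAU.
#' @param iqr_multiplier Temporal outlier fence width, IQR units.
#' @param min_length Minimum trimmed length, samples.
#' @param window_length STFT window, samples.
#' @param pad_length Zero-padding target, samples.
#' @param gam_k_divisor,gam_k_min Basis dimension rule `max(k_min, n/divisor)`.
#' @param gam_max_trend_frequency Cap (Hz) on the oscillation rate the trend
#'   smooth can represent (see [fit_trend()]).
#' @param acf_min_separation Minimum autocorrelation peak separation, samples.
#' @param acf_min_height Minimum autocorrelation peak height.
#' @param n_trees,vars_per_split Forest size and variables tried per split.
#' @param train_fraction Training fraction of the random split.
#' @param class_sizes Optional named per-class bootstrap sizes.
#' @param impute Impute missing feature values by training medians.
#' @param seed Integer seed for all stochastic steps.
#' @return A `wb_config` list.
#' @export
pipeline_config <- function(threshold = 0.0061, iqr_multiplier = 3,
                            min_length = 128L, window_length = 128L,
                            pad_length = 8192L, gam_k_divisor = 50,
                            gam_k_min = 10, gam_max_trend_frequency = 50,
                            acf_min_separation = 10L,
                            acf_min_height = 0.2, n_trees = 1000,
                            vars_per_split = 10, train_fraction = 0.7,
                            class_sizes = NULL, impute = TRUE, seed = 1) {
  structure(
    list(
      threshold = threshold, iqr_multiplier = iqr_multiplier,
      min_length = min_length, window_length = window_length,
      pad_length = pad_length, gam_k_divisor = gam_k_divisor,
      gam_k_min = gam_k_min,
      gam_max_trend_frequency = gam_max_trend_frequency,
      acf_min_separation = acf_min_separation,
      acf_min_height = acf_min_height, n_trees = n_trees,
      vars_per_split = vars_per_split, train_fraction = train_fraction,
      class_sizes = class_sizes, impute = impute, seed = seed
    ),
    class = "wb_config"
  )
}

#' Run the full pipeline on a corpus
#'
#' Loads (or accepts) a corpus, trims and filters it, extracts the 52
#' features, splits into training and validation, trains the balanced random
#' forest and evaluates it. All stochastic steps derive from `config$seed`,
#' so a rerun with the same inputs and config reproduces every artifact.
#'
#' @param corpus Either a directory of WAV files with a sidecar CSV, or a
#'   list of [wb_recording()] objects.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the trim report, feature
#'   table, classification metrics and a run manifest (JSON, with a config
#'   hash) are written there.
#' @return List with `features`, `trim_report`, `split`, `model`,
#'   `oob_report`, `validation_report`, `importance`, `config`.
#' @export
run_pipeline <- function(corpus, config = NULL, out_dir = NULL) {
  cfg <- config %||% pipeline_config()
  recordings <- if (is.character(corpus)) load_corpus(corpus) else corpus
  features <- extract_corpus(recordings, cfg)
  trim_report <- attr(features, "trim_report")
  if (nrow(features) == 0) {
    warning("no recordings retained; returning empty artifacts", call. = FALSE)
    return(list(
      features = features, trim_report = trim_report, split = NULL,
      model = NULL, oob_report = NULL, validation_report = NULL,
      importance = NULL, config = cfg
    ))
  }
  split <- split_train_validation(features, fraction = cfg$train_fraction, seed = cfg$seed)
  model <- train_balanced_rf(split$train,
    class_sizes = cfg$class_sizes,
    n_trees = cfg$n_trees, vars_per_split = cfg$vars_per_split,
    impute = cfg$impute, seed = cfg$seed
  )
  artifacts <- list(
    features = features, trim_report = trim_report, split = split,
    model = model, oob_report = oob_report(model),
    validation_report = evaluate(model, split$validation),
    importance = importance_table(model), config = cfg
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trim_report, file.path(out_dir, "trim_report.csv"), row.names = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(artifacts$validation_report$metrics,
      file.path(out_dir, "validation_metrics.csv"),
      row.names = FALSE
    )
    utils::write.csv(artifacts$importance, file.path(out_dir, "importance.csv"),
      row.names = FALSE
    )
    manifest <- list(
      package_version = as.character(utils::packageVersion("wingbeat")),
      r_version = R.version.string,
      config = cfg[setdiff(names(cfg), "class_sizes")],
      class_sizes = as.list(cfg$class_sizes),
      config_hash = rlang::hash(cfg),
      n_recordings = length(recordings),
      n_retained = nrow(features)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  artifacts
}
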