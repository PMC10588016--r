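#' Pipeline configuration
#'
#' Validated parameter set for the full segment -> scalogram -> image ->
#' split -> train -> evaluate pipeline.  The defaults mirror the study
#' regime: 500-sample segments at 128 Hz, Morse wavelet with P^2 = 60 and
#' gamma = 3, 12 voices per octave, 227 x 227 images, Adam with learning
#' rate 1e-4, batch size 30, 15 epochs and an 80/20 train/validation
#' split.  Unknown parameters are rejected.
#'
#' @param n_records_per_class Synthetic records per class. Default 30.
#' @param n_samples Samples per synthetic record. Default 10000.
#' @param sampling_rate Hz. Default 128.
#' @param seg_len Segment length in samples. Default 500.
#' @param n_segments_per_record Segments cut per record. Default 20.
#' @param p2,gamma Morse wavelet parameters. Defaults 60 and 3.
#' @param voices_per_octave Filterbank voices per octave. Default 12.
#' @param freq_limits Optional `c(low, high)` Hz filterbank limits.
#' @param image_size `c(height, width)` of rendered images (one number is
#'   recycled). Default 227.
#' @param levels Colormap quantization levels. Default 128.
#' @param train_frac Training fraction of the non-test segments. Default
#'   0.8.
#' @param test_per_class Test segments reserved per class. Default 120.
#' @param learning_rate,batch_size,max_epochs,optimizer Training
#'   hyperparameters (defaults 1e-4, 30, 15, `"adam"`).
#' @param data_seed,split_seed,train_seed Integer seeds for generation,
#'   splitting and training.
#' @param ... Unknown parameters; any use is an error.
#'
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_records_per_class = 30, n_samples = 10000,
                            sampling_rate = 128, seg_len = 500,
                            n_segments_per_record = 20,
                            p2 = 60, gamma = 3, voices_per_octave = 12,
                            freq_limits = NULL,
                            image_size = 227, levels = 128,
                            train_frac = 0.8, test_per_class = 120,
                            learning_rate = 1e-4, batch_size = 30,
                            max_epochs = 15, optimizer = "adam",
                            data_seed = 1, split_seed = 2, train_seed = 3,
                            ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown pipeline parameter(s): ",
         paste(names(extra), collapse = ", "))
  }
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  cfg <- list(
    n_records_per_class = n_records_per_class, n_samples = n_samples,
    sampling_rate = sampling_rate, seg_len = seg_len,
    n_segments_per_record = n_segments_per_record,
    p2 = p2, gamma = gamma, voices_per_octave = voices_per_octave,
    freq_limits = freq_limits, image_size = image_size, levels = levels,
    train_frac = train_frac, test_per_class = test_per_class,
    learning_rate = learning_rate, batch_size = batch_size,
    max_epochs = max_epochs, optimizer = optimizer,
    data_seed = data_seed, split_seed = split_seed, train_seed = train_seed)

  # module preconditions checked up front so a bad config fails before any
  # compute
  morse_params(gamma = cfg$gamma, p2 = cfg$p2)
  stopifnot(cfg$seg_len >= 4, cfg$sampling_rate > 0,
            cfg$n_records_per_class >= 1, cfg$n_segments_per_record >= 1,
            cfg$voices_per_octave >= 1, cfg$levels >= 2,
            all(cfg$image_size >= 32))
  if (cfg$n_samples < cfg$seg_len * cfg$n_segments_per_record) {
    stop("n_samples (", cfg$n_samples, ") cannot hold ",
         cfg$n_segments_per_record, " segments of ", cfg$seg_len, " samples")
  }
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1) {
    stop("`train_frac` must lie strictly between 0 and 1")
  }
  if (cfg$learning_rate <= 0) stop("`learning_rate` must be > 0")
  stopifnot(cfg$batch_size >= 1, cfg$max_epochs >= 0,
            cfg$test_per_class >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Render a table of segments into an image tensor
#'
#' Computes the Morse CWT of every segment and renders each scalogram as a
#' jet RGB image, streaming one segment at a time (scalograms are not
#' retained).
#'
#' @param segments A segments tibble (see [segment_record()]).
#' @param bank A [morse_filterbank()] matching the segment length.
#' @param image_size `c(height, width)` of the rendered images.
#' @param levels Colormap quantization levels.
#' @return An `H x W x 3 x N` array in `[0, 1]`, images in segment order.
#' @export
segments_to_images <- function(segments, bank, image_size = c(227, 227),
                               levels = 128) {
  stopifnot(is.data.frame(segments), "samples" %in% names(segments),
            inherits(bank, "morse_filterbank"))
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  n <- nrow(segments)
  out <- array(0, dim = c(image_size[1], image_size[2], 3L, n))
  for (i in seq_len(n)) {
    sc <- cwt(segments$samples[[i]], bank)
    img <- scalogram_to_image(sc, size = image_size, levels = levels,
                              source_id = segments$segment_id[i])
    out[, , , i] <- img$pixels / 255
  }
  out
}

#' Run the full rhythm-classification pipeline on synthetic data
#'
#' Executes generate -> segment -> scalogram -> image -> split -> train ->
#' evaluate and returns the evaluation report for the held-out test
#' partition.  Identical config gives an identical report.  When
#' `out_dir` is supplied, a run manifest (config and seeds), the split
#' manifest, the training history and the metrics report are written
#' there as JSON/CSV.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for run artifacts.
#' @param verbose Print stage progress.
#'
#' @return A list with `report` (an `ecg_metrics_report` on the test
#'   partition), `confusion` (the test `ecg_confusion`), `classifier`,
#'   `history`, `split` (the split tibble, sans waveforms) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = interactive()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("generating synthetic records")
  dataset <- stage("synthesize", synth_ecg_dataset(
    config$n_records_per_class, config$n_samples, config$sampling_rate,
    seed = config$data_seed))

  say("segmenting")
  segments <- stage("segment", segment_records(
    dataset, seg_len = config$seg_len,
    n_segments = config$n_segments_per_record))

  say("designing filterbank")
  bank <- stage("filterbank", morse_filterbank(
    config$seg_len, config$sampling_rate,
    morse_params(gamma = config$gamma, p2 = config$p2),
    config$voices_per_octave, config$freq_limits))

  say("rendering ", nrow(segments), " scalogram images")
  images <- stage("render", segments_to_images(
    segments, bank, config$image_size, config$levels))

  say("splitting")
  split <- stage("split", make_split(
    segments, train_frac = config$train_frac,
    test_per_class = config$test_per_class, seed = config$split_seed))

  part <- split$partition
  classes <- sort(unique(split$label))
  cfg_train <- train_config(
    optimizer = config$optimizer, learning_rate = config$learning_rate,
    batch_size = config$batch_size, max_epochs = config$max_epochs,
    seed = config$train_seed, class_order = classes)

  say("training reference CNN (", config$max_epochs, " epochs)")
  clf <- stage("build", reference_cnn(config$image_size, length(classes),
                                      seed = config$train_seed))
  fit <- stage("train", train_classifier(
    clf,
    images[, , , part == "train", drop = FALSE], split$label[part == "train"],
    images[, , , part == "validation", drop = FALSE],
    split$label[part == "validation"],
    cfg_train))

  say("evaluating on the test partition")
  pred <- stage("predict", predict(
    fit$classifier, images[, , , part == "test", drop = FALSE]))
  cm <- stage("evaluate", confusion_matrix(
    split$label[part == "test"], as.character(pred$.pred_class),
    class_order = classes))
  report <- metrics_report(cm)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- unclass(config)
    manifest$package_version <- as.character(utils::packageVersion("morsecg"))
    manifest$n_filters <- length(bank$centers_rad)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_split_manifest(split, file.path(out_dir, "split.json"))
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    write_metrics_report(report, file.path(out_dir, "metrics.json"))
  }

  list(report = report, confusion = cm, classifier = fit$classifier,
       history = fit$history,
       split = split[setdiff(names(split), "samples")], config = config)
}
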