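# End-to-end pipeline orchestration: synth -> preprocess -> features ->
# train -> predict -> evaluate, with a replayable manifest.

#' Run the full estimation pipeline
#'
#' Generates (or loads) a cohort, preprocesses every segment, extracts
#' features, trains the requested model on a grouped 80:20 split, predicts
#' the held-out segments and writes metrics, predictions and a manifest
#' under `out_dir`. Every stage seed is fanned out deterministically from
#' the single global `seed`, so the artifact set is reproducible from
#' (config, seed) alone.
#'
#' @param out_dir Output directory (created; existing stage outputs are
#'   only overwritten when `force = TRUE`).
#' @param n_subjects Cohort size when generating synthetic data.
#' @param segments_per_subject Segments per subject.
#' @param seed Global pipeline seed.
#' @param model `"dscnet"` or `"cnn"`.
#' @param config A [model_config()].
#' @param tc A [train_config()] (its seed is overridden by the fan-out).
#' @param filters,framing Filter and framing configurations.
#' @param n_samples,fs Segment geometry.
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with `metrics`, `predictions` (data.frame),
#'   `history` and the `manifest`.
#' @export
run_pipeline <- function(out_dir, n_subjects = 50, segments_per_subject = 2,
                         seed = 0, model = c("dscnet", "cnn"),
                         config = model_config(conv_channels = 32,
                                               primary_maps = 8),
                         tc = train_config(epochs = 30, patience = 8),
                         filters = filter_config(),
                         framing = framing_config(),
                         n_samples = 1700, fs = 115.2, force = FALSE) {
  model <- match.arg(model)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    metrics = file.path(out_dir, "metrics.json"),
    predictions = file.path(out_dir, "predictions.csv"),
    features = file.path(out_dir, "features.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  if (!force && file.exists(paths$metrics)) {
    stop_input("outputs already exist in `", out_dir,
               "`; pass force = TRUE to overwrite")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("synth", generate_cohort(
    n_subjects, segments_per_subject, seed = derive_seed(seed, 1L),
    n_samples = n_samples, fs = fs))
  clean <- stage("preprocess", lapply(cohort$segments, preprocess_segment,
                                      config = filters))
  feats <- stage("features", extract_feature_matrix(clean, framing, filters))
  utils::write.csv(feats, paths$features, row.names = FALSE)
  y <- feats$reference_bgl
  x <- segments_to_array(clean)
  fvm <- t(as.matrix(feats[, feature_names()]))
  sp <- stage("split", split_train_test(feats$subject_id,
                                        fraction = tc$split_fraction,
                                        seed = derive_seed(seed, 2L)))
  tc$seed <- derive_seed(seed, 3L)
  built <- stage("build", if (model == "dscnet") {
    build_dscnet(config, input_len = n_samples, seed = derive_seed(seed, 4L))
  } else {
    build_cnn_baseline(config, attention = config$use_attention,
                       input_len = n_samples,
                       seed = derive_seed(seed, 4L))
  })
  use_fv <- built$fv_dim > 0L
  fit <- stage("train", train_model(
    built, x[, , sp$train, drop = FALSE], y[sp$train],
    fv = if (use_fv) fvm[, sp$train, drop = FALSE] else NULL, tc = tc))
  pred <- stage("predict", predict_bgl(
    fit$model, x[, , sp$test, drop = FALSE],
    fv = if (use_fv) fvm[, sp$test, drop = FALSE] else NULL))
  metrics <- stage("evaluate", compute_metrics(y[sp$test], pred))
  predictions <- data.frame(subject_id = feats$subject_id[sp$test],
                            segment_idx = feats$segment_idx[sp$test],
                            reference_bgl = y[sp$test], predicted_bgl = pred)
  utils::write.csv(predictions, paths$predictions, row.names = FALSE)
  jsonlite::write_json(unclass(metrics), paths$metrics, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    seed = seed,
    stage_seeds = list(synth = derive_seed(seed, 1L),
                       split = derive_seed(seed, 2L),
                       train = derive_seed(seed, 3L),
                       init = derive_seed(seed, 4L)),
    n_subjects = n_subjects, segments_per_subject = segments_per_subject,
    n_samples = n_samples, fs = fs, model = model,
    n_segments = length(clean), n_train = length(sp$train),
    n_test = length(sp$test), n_params = built$n_params,
    package_version = as.character(utils::packageVersion("ppgcaps")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(metrics = metrics, predictions = predictions,
                 history = fit$history, manifest = manifest))
}
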