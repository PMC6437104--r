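# End-to-end pipeline commands: simulate a cohort, extract the data matrix
# and schema feature matrices from WAV inputs, and train/evaluate a
# classifier, each runnable on its own or chained by run_pipeline().

#' Pipeline configuration
#'
#' One flat configuration drives every stage; any section can be replaced.
#'
#' @param cohort A [cohort_config()].
#' @param segmenter A [segmenter_config()].
#' @param schema Schema id: `"ANN40"`, `"EANN5"` or `"P5ANN6"`.
#' @param model `"mlp"` or `"rbfn"` (the RBFN requires the ANN40 schema).
#' @param split A [split_spec()].
#' @param legacy_layout Use the leakage-carrying literal ANN40 layout (study
#'   control only; see [feature_schema()]).
#' @param seed Master seed; stage seeds derive from it.
#' @export
pipeline_config <- function(cohort = cohort_config(), segmenter = segmenter_config(),
                            schema = "ANN40", model = c("mlp", "rbfn"),
                            split = split_spec(), legacy_layout = FALSE,
                            seed = 1L) {
  model <- match.arg(model)
  if (model == "rbfn" && schema != "ANN40") {
    stop("configuration error: the RBFN is defined for the ANN40 schema only")
  }
  seed <- as.integer(seed)
  cohort$seed <- seed
  split$seed <- seed + 1L
  list(cohort = cohort, segmenter = segmenter, schema = schema, model = model,
       split = split, legacy_layout = legacy_layout, seed = seed)
}

#' Simulate a cohort to disk (pipeline stage 1)
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param dry_run If `TRUE`, return the subject table without writing.
#' @return Manifest (or subject table when `dry_run`).
#' @export
cmd_simulate <- function(config = pipeline_config(), out_dir = NULL,
                         dry_run = FALSE) {
  if (dry_run) return(simulate_cohort(config$cohort)$subjects)
  if (is.null(out_dir)) stop("out_dir required unless dry_run")
  generate_cohort(config$cohort, out_dir)
}

#' Extract the data matrix and a schema feature matrix (pipeline stage 2)
#'
#' @param config A [pipeline_config()].
#' @param cohort In-memory cohort from [simulate_cohort()], or `NULL` to read
#'   WAV files listed in `manifest_dir`'s manifest.
#' @param manifest_dir Directory written by [cmd_simulate()].
#' @return List: `data_matrix`, `feature_matrix`, `excluded`.
#' @export
cmd_extract <- function(config = pipeline_config(), cohort = NULL,
                        manifest_dir = NULL) {
  if (is.null(cohort)) {
    if (is.null(manifest_dir)) stop("need an in-memory cohort or a manifest_dir")
    manifest <- utils::read.csv(file.path(manifest_dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
    records <- lapply(seq_len(nrow(manifest)), function(i) {
      read_wav(file.path(manifest_dir, manifest$wav[i]),
               subject_id = manifest$subject_id[i],
               class_label = manifest$class_label[i],
               laugh_id = manifest$laugh_id[i])
    })
    classes <- stats::setNames(manifest$class_label, manifest$subject_id)
  } else {
    records <- lapply(cohort$laughs, `[[`, "record")
    classes <- stats::setNames(cohort$subjects$class_label,
                               cohort$subjects$subject_id)
  }
  if (length(records) == 0) stop("no laugh recordings to extract from")
  tables <- lapply(records, extract_laugh_features, config = config$segmenter)
  if (all(vapply(tables, nrow, 1L) == 0)) {
    stop("no plosives detected in any input recording")
  }
  health <- ifelse(classes == "depression", 1L, 2L)
  dm <- build_data_matrix(tables, health)
  fm <- build_feature_matrix(dm, config$schema, legacy_layout = config$legacy_layout)
  list(data_matrix = dm, feature_matrix = fm, excluded = fm$excluded)
}

#' Split, train and evaluate a classifier (pipeline stage 3)
#'
#' Standardization parameters are fit on the training rows only. The trained
#' model is evaluated at both the laugh and the subject level, and the
#' input-sensitivity ranking is computed on the training matrix.
#'
#' @param config A [pipeline_config()].
#' @param fm Feature matrix from [cmd_extract()].
#' @param max_epochs Optional override of the training epoch cap.
#' @return List: `model`, `split`, `standardization`, `report` (laugh +
#'   subject [evaluate_network()] bundles), `sensitivity`, `train_report`.
#' @export
cmd_train_eval <- function(config = pipeline_config(), fm, max_epochs = NULL) {
  if (config$model == "rbfn" && fm$schema$schema_id != "ANN40") {
    stop("configuration error: the RBFN is defined for the ANN40 schema only")
  }
  sp <- holdout_split(fm, config$split)
  std <- standardize_features(sp$train$X, sp$test$X)
  train_fm <- sp$train; train_fm$X <- std$train
  test_fm <- sp$test; test_fm$X <- std$test

  if (config$model == "mlp") {
    mcfg <- mlp_config(p = fm$schema$p, seed = config$seed)
    if (!is.null(max_epochs)) mcfg$max_epochs <- max_epochs
    model <- mlp_train(mcfg, train_fm$X, train_fm$y)
  } else {
    mcfg <- rbfn_config(input_size = fm$schema$p, seed = config$seed)
    if (!is.null(max_epochs)) mcfg$supervised_epochs <- max_epochs
    model <- rbfn_train(mcfg, train_fm$X, train_fm$y)
  }
  report <- evaluate_network(model, test_fm, level = "both")
  train_report <- evaluate_network(model, train_fm, level = "laugh")
  sens <- input_sensitivity(model, train_fm$X)
  list(model = model, split = sp, standardization = std,
       report = report, train_report = train_report, sensitivity = sens)
}

#' Run the full pipeline in memory
#'
#' Simulate, extract, split, train and evaluate under one master seed.
#'
#' @param config A [pipeline_config()].
#' @param max_epochs Optional training epoch override.
#' @return List: `cohort`, `extraction`, `fit`.
#' @export
run_pipeline <- function(config = pipeline_config(), max_epochs = NULL) {
  cohort <- simulate_cohort(config$cohort)
  extraction <- cmd_extract(config, cohort = cohort)
  fit <- cmd_train_eval(config, extraction$feature_matrix, max_epochs = max_epochs)
  list(cohort = cohort, extraction = extraction, fit = fit)
}
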