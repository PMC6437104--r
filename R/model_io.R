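MODEL_FORMAT_VERSION <- "1.0"

#' Save / load a trained model
#'
#' Single-file JSON format with an embedded format version and the full
#' training configuration; numeric values are written at full double
#' precision so a loaded model reproduces the original's predictions exactly.
#'
#' @param model An `mlp_model` or `rbfn_model`.
#' @param path File path.
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("mlp_model", "rbfn_model"))) {
    stop("model must be an mlp_model or rbfn_model")
  }
  # doubles are stored as C99 hex-float strings: exact round trip, so the
  # loaded model reproduces the original's predictions bit for bit
  enc <- function(v) sprintf("%a", as.numeric(v))
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    model_class = class(model)[1],
    W = lapply(model$W, function(m) list(dim = dim(m), data = enc(m))),
    b = lapply(model$b, enc),
    config = unclass(model$config),
    config_class = class(model$config)[1],
    history = enc(model$history))
  if (inherits(model, "rbfn_model")) {
    payload$centers <- list(dim = dim(model$centers),
                            data = enc(model$centers))
    payload$widths <- enc(model$widths)
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e) {
                        stop("model file unreadable or corrupt: ",
                             conditionMessage(e))
                      })
  required <- c("format_version", "model_class", "W", "b", "config")
  if (!all(required %in% names(payload))) {
    stop("model file integrity error: missing fields ",
         paste(setdiff(required, names(payload)), collapse = ", "))
  }
  if (!identical(as.character(payload$format_version), MODEL_FORMAT_VERSION)) {
    stop("model format version mismatch: file has ", payload$format_version,
         ", this build reads ", MODEL_FORMAT_VERSION)
  }
  dec <- function(v) as.numeric(unlist(v))
  remat <- function(x) {
    d <- as.integer(unlist(x$dim))
    matrix(dec(x$data), d[1], d[2])
  }
  cfg <- lapply(payload$config, function(v)
    if (is.list(v)) unlist(v) else v)
  model <- list(W = lapply(payload$W, remat),
                b = lapply(payload$b, dec),
                config = structure(cfg, class = payload$config_class %||% "list"),
                history = dec(payload$history))
  if (identical(payload$model_class, "rbfn_model")) {
    model$centers <- remat(payload$centers)
    model$widths <- dec(payload$widths)
  }
  structure(model, class = payload$model_class)
}
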