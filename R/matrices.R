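# The per-plosive data matrix (one plosive per row, six sound variables in
# columns, dichotomous health status 1 = depression / 2 = healthy) and the
# three laugh-level network input schemas.

DATA_MATRIX_COLUMNS <- c("laugh_id", "subject_id", "placement", "onset_ms",
                         "duration_ms", "f0_mean_hz", "f1_hz", "f2_hz", "f3_hz",
                         "avg_power", "entropy_bits", "voiced_pct", "health_status")

#' Assemble the plosive data matrix for a set of laughs
#'
#' @param feature_tables List of per-laugh feature tables from
#'   [extract_laugh_features()].
#' @param health_by_subject Named vector mapping `subject_id` to health status
#'   (1 = depression, 2 = healthy).
#' @return Data frame with the canonical column layout.
#' @export
build_data_matrix <- function(feature_tables, health_by_subject) {
  tabs <- Filter(function(t) nrow(t) > 0, feature_tables)
  if (length(tabs) == 0) {
    out <- as.data.frame(stats::setNames(
      replicate(length(DATA_MATRIX_COLUMNS), numeric(0), simplify = FALSE),
      DATA_MATRIX_COLUMNS))
    return(out)
  }
  dm <- do.call(rbind, tabs)
  dm$health_status <- as.integer(unname(health_by_subject[dm$subject_id]))
  dm[, DATA_MATRIX_COLUMNS]
}

validate_data_matrix <- function(dm) {
  missing_cols <- setdiff(DATA_MATRIX_COLUMNS, names(dm))
  if (length(missing_cols)) {
    stop("data matrix schema error; expected columns: ",
         paste(DATA_MATRIX_COLUMNS, collapse = ", "),
         " (missing: ", paste(missing_cols, collapse = ", "), ")")
  }
  if (nrow(dm) && !all(dm$health_status %in% c(1L, 2L))) {
    stop("health_status must be coded 1 (depression) or 2 (healthy)")
  }
  if (nrow(dm) && any(dm$placement < 1)) stop("placement must be >= 1")
  invisible(dm)
}

#' Write / read the plosive data matrix as CSV
#'
#' Comma-separated, `.` decimal, UTF-8, explicit header; the `{1, 2}` health
#' coding is preserved exactly on disk and only mapped to `{+1, -1}` at the
#' network boundary.
#'
#' @param dm Data matrix from [build_data_matrix()].
#' @param path CSV path.
#' @return `path` invisibly; `read_data_matrix()` returns the data frame.
#' @export
write_data_matrix <- function(dm, path) {
  validate_data_matrix(dm)
  utils::write.csv(dm, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_data_matrix
#' @export
read_data_matrix <- function(path) {
  dm <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  extra <- setdiff(names(dm), DATA_MATRIX_COLUMNS)
  if (length(extra)) {
    stop("unknown column(s) ", paste(extra, collapse = ", "),
         " in data matrix; expected header: ",
         paste(DATA_MATRIX_COLUMNS, collapse = ", "))
  }
  validate_data_matrix(dm)
  dm
}

#' Network input schemas
#'
#' Three laugh-level exemplar layouts feed the classifiers:
#' * `ANN40` (p = 40): eight acoustic columns per plosive (duration, F0 mean,
#'   F1-F3, average power, entropy, voiced fraction) for plosives 1-5.
#' * `EANN5` (p = 5): average power of plosives 1-5 only.
#' * `P5ANN6` (p = 6): six variables of the fifth plosive (duration, F0 mean,
#'   F1, F2, average power, entropy).
#'
#' A `legacy_layout` variant of `ANN40` additionally carries the plosive
#' placement index and the subject's health label as per-plosive input
#' channels; feeding the class label to the classifier is target leakage and
#' exists only to demonstrate, as a documented control, why the default layout
#' excludes it.
#'
#' @param schema_id One of `"ANN40"`, `"EANN5"`, `"P5ANN6"`.
#' @return List with `schema_id`, `p`, and the per-plosive column recipe.
#' @export
feature_schema <- function(schema_id = c("ANN40", "EANN5", "P5ANN6")) {
  schema_id <- match.arg(schema_id)
  p <- c(ANN40 = 40L, EANN5 = 5L, P5ANN6 = 6L)[[schema_id]]
  vars <- switch(schema_id,
    ANN40 = c("duration_ms", "f0_mean_hz", "f1_hz", "f2_hz", "f3_hz",
              "avg_power", "entropy_bits", "voiced_pct"),
    EANN5 = "avg_power",
    P5ANN6 = c("duration_ms", "f0_mean_hz", "f1_hz", "f2_hz",
               "avg_power", "entropy_bits"))
  list(schema_id = schema_id, p = p, vars = vars)
}

STRICT_ANN40_VARS <- c("duration_ms", "f0_mean_hz", "f1_hz", "f2_hz",
                       "avg_power", "entropy_bits", "placement", "health_label")

#' Build a laugh-level feature matrix under a schema
#'
#' Laughs contribute one exemplar each, built from their first five plosives;
#' laughs with fewer than five plosives are excluded with a logged reason, as
#' are laughs with undefined F0 or formants under schemas that need them
#' (`EANN5` needs energy only). Health status is mapped 1 -> +1 (depression),
#' 2 -> -1 (control).
#'
#' @param dm Plosive data matrix ([build_data_matrix()]).
#' @param schema A [feature_schema()] or schema id string.
#' @param legacy_layout If `TRUE` (ANN40 only) use the literal layout including
#'   the health-label input channel; see [feature_schema()].
#' @return List of class `feature_matrix`: `X` (n x p), `y` (+1/-1),
#'   `subject_id`, `laugh_id`, `schema`, `excluded` (laugh_id, reason).
#' @export
build_feature_matrix <- function(dm, schema = "ANN40", legacy_layout = FALSE) {
  if (is.character(schema)) schema <- feature_schema(schema)
  if (legacy_layout && schema$schema_id != "ANN40") {
    stop("legacy_layout layout exists for the ANN40 schema only")
  }
  validate_data_matrix(dm)
  vars <- if (legacy_layout) STRICT_ANN40_VARS else schema$vars
  per_plosive <- schema$schema_id != "P5ANN6"
  n_plo <- 5L

  rows <- list(); ys <- c(); sids <- c(); lids <- c()
  excluded <- list()
  for (lid in unique(dm$laugh_id)) {
    g <- dm[dm$laugh_id == lid, , drop = FALSE]
    g <- g[order(g$placement), , drop = FALSE]
    if (nrow(g) < n_plo) {
      excluded[[length(excluded) + 1]] <-
        data.frame(laugh_id = lid, reason = sprintf("n_plosives=%d<5", nrow(g)))
      next
    }
    g <- g[seq_len(n_plo), , drop = FALSE]
    g$health_label <- ifelse(g$health_status == 1L, 1, -1)
    acoustic <- setdiff(vars, c("placement", "health_label"))
    use <- if (per_plosive) g else g[n_plo, , drop = FALSE]
    if (anyNA(use[, acoustic])) {
      excluded[[length(excluded) + 1]] <-
        data.frame(laugh_id = lid, reason = "undefined_feature")
      next
    }
    v <- as.numeric(t(as.matrix(use[, vars])))
    rows[[length(rows) + 1]] <- v
    ys <- c(ys, ifelse(g$health_status[1] == 1L, 1, -1))
    sids <- c(sids, g$subject_id[1])
    lids <- c(lids, lid)
  }
  X <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, schema$p)
  colnames(X) <- if (schema$schema_id == "P5ANN6") {
    paste0("p5_", vars)
  } else {
    as.vector(t(outer(paste0("p", seq_len(n_plo), "_"), vars, paste0)))
  }
  if (ncol(X) != schema$p) {
    stop("schema column-count contract violated: got ", ncol(X),
         " columns, schema requires p = ", schema$p)
  }
  structure(list(X = X, y = ys, subject_id = sids, laugh_id = lids,
                 schema = schema, legacy_layout = legacy_layout,
                 excluded = if (length(excluded)) do.call(rbind, excluded) else
                   data.frame(laugh_id = character(), reason = character())),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> schema %s (p = %d): %d laughs (%d depression / %d control), %d excluded\n",
              x$schema$schema_id, x$schema$p, nrow(x$X),
              sum(x$y == 1), sum(x$y == -1), nrow(x$excluded)))
  invisible(x)
}

#' Z-score standardization fit on the training split only
#'
#' Tanh units saturate on raw Hz scales, so all features are standardized;
#' the parameters come from the training rows and are reapplied to test rows.
#' Constant columns are left centered with unit divisor.
#'
#' @param train_X,test_X Numeric matrices with identical columns.
#' @return List with standardized `train`, `test`, and parameters
#'   `center`/`scale`.
#' @export
standardize_features <- function(train_X, test_X = NULL) {
  center <- colMeans(train_X)
  scale <- apply(train_X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  std <- function(M) sweep(sweep(M, 2, center), 2, scale, "/")
  list(train = std(train_X),
       test = if (is.null(test_X)) NULL else std(test_X),
       center = center, scale = scale)
}
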