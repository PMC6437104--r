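#' Holdout split specification
#'
#' 80% of the data train the networks and the remaining 20% evaluate them.
#' The default split unit is the subject: all laughs of one participant stay
#' on the same side, so evaluation reflects unseen individuals rather than
#' unseen laughs of known individuals.
#'
#' @param train_fraction Fraction of units assigned to training.
#' @param unit `"subject"` or `"laugh"`.
#' @param stratified Preserve class proportions across the split.
#' @param seed Seed for the assignment draw.
#' @export
split_spec <- function(train_fraction = 0.8, unit = c("subject", "laugh"),
                       stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  list(train_fraction = train_fraction, unit = match.arg(unit),
       stratified = stratified, seed = as.integer(seed))
}

subset_feature_matrix <- function(fm, idx) {
  structure(list(X = fm$X[idx, , drop = FALSE], y = fm$y[idx],
                 subject_id = fm$subject_id[idx], laugh_id = fm$laugh_id[idx],
                 schema = fm$schema, legacy_layout = fm$legacy_layout,
                 excluded = fm$excluded),
            class = "feature_matrix")
}

#' Split a feature matrix into train and test sides
#'
#' @param fm A [build_feature_matrix()] result.
#' @param spec A [split_spec()].
#' @return List with `train` and `test` feature matrices.
#' @export
holdout_split <- function(fm, spec = split_spec()) {
  if (length(unique(fm$y)) < 2) stop("both classes must be present to split")
  set.seed(spec$seed)
  unit_id <- if (spec$unit == "subject") fm$subject_id else fm$laugh_id
  units <- unique(data.frame(unit = unit_id, y = fm$y, stringsAsFactors = FALSE))

  draw <- function() {
    test_units <- character(0)
    if (spec$stratified) {
      for (cls in unique(units$y)) {
        u <- units$unit[units$y == cls]
        n_test <- max(1L, round((1 - spec$train_fraction) * length(u)))
        test_units <- c(test_units, sample(u, n_test))
      }
    } else {
      n_test <- max(1L, round((1 - spec$train_fraction) * nrow(units)))
      test_units <- sample(units$unit, n_test)
    }
    test_units
  }

  for (attempt in seq_len(100)) {
    test_units <- draw()
    test_idx <- unit_id %in% test_units
    ok <- length(unique(fm$y[test_idx])) == 2 &&
      length(unique(fm$y[!test_idx])) == 2 && any(test_idx) && any(!test_idx)
    if (ok) {
      if (attempt > 1) warning("redrew split ", attempt - 1,
                               " time(s) to keep both classes on both sides")
      return(list(train = subset_feature_matrix(fm, !test_idx),
                  test = subset_feature_matrix(fm, test_idx)))
    }
  }
  stop("could not produce a split with both classes on both sides in 100 attempts")
}
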