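# Evaluation battery: confusion matrix with row-percent view, validity
# metrics (accuracy, sensitivity, effectiveness = specificity, precision),
# performance metrics (MSE, NMSE, r, %error, AIC, MDL), ROC analysis and
# input-sensitivity ranking.

#' Confusion matrix for a binary screening outcome
#'
#' Positive class is depression (+1). The row-percent view expresses each
#' observed class as percentages over predicted classes, rows summing to 100.
#'
#' @param labels_true,labels_pred Vectors of +1/-1 labels.
#' @return List of class `confusion_matrix`: `tp`, `fn`, `fp`, `tn`, and
#'   `row_percent` (2 x 2 matrix, rows = observed depression/controls).
#' @export
confusion <- function(labels_true, labels_pred) {
  if (length(labels_true) == 0) stop("empty label vectors")
  if (length(labels_true) != length(labels_pred)) stop("length mismatch")
  if (!all(c(labels_true, labels_pred) %in% c(-1, 1))) {
    stop("labels must be coded +1 (depression) / -1 (control)")
  }
  tp <- sum(labels_true == 1 & labels_pred == 1)
  fn <- sum(labels_true == 1 & labels_pred == -1)
  fp <- sum(labels_true == -1 & labels_pred == 1)
  tn <- sum(labels_true == -1 & labels_pred == -1)
  rp <- rbind(
    depression_observed = if (tp + fn > 0) 100 * c(tp, fn) / (tp + fn) else c(NA, NA),
    controls_observed   = if (fp + tn > 0) 100 * c(fp, tn) / (fp + tn) else c(NA, NA))
  colnames(rp) <- c("predicted_depression_pct", "predicted_controls_pct")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, row_percent = rp),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  m <- rbind(c(x$tp, x$fn), c(x$fp, x$tn))
  dimnames(m) <- list(c("depression observed", "controls observed"),
                      c("predicted depression", "predicted controls"))
  print(m)
  cat("row percentages:\n")
  print(round(x$row_percent, 2))
  invisible(x)
}

#' Validity metrics of a classifier
#'
#' Accuracy, sensitivity (true-positive rate), effectiveness and precision.
#' Effectiveness is the true-negative rate (specificity): the reported
#' effectiveness values match the controls-observed row of the corresponding
#' confusion matrices exactly as specificity does. Undefined ratios (empty
#' denominators) are returned as `NA` with a `flags` entry, never silently
#' propagated.
#'
#' @param cm A [confusion()] result.
#' @return List of class `validity_report` with `accuracy`, `sensitivity`,
#'   `effectiveness`, `precision`, `flags`.
#' @export
validity_metrics <- function(cm) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) stop("empty confusion matrix")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    accuracy = (cm$tp + cm$tn) / n,
    sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
    effectiveness = safe_div(cm$tn, cm$tn + cm$fp),
    precision = safe_div(cm$tp, cm$tp + cm$fp))
  out$flags <- names(out)[vapply(out, function(v) is.na(v[1]), TRUE)]
  structure(out, class = "validity_report")
}

#' AIC and MDL model-selection scores for a trained network
#'
#' Both trade training fit against network size: `AIC = n ln(MSE) + 2 k` and
#' `MDL = n ln(MSE) + (k / 2) ln(n)`, with `k` the number of free parameters
#' (all weights and biases) and `n` the number of exemplars. Lower is better.
#'
#' @param mse Mean squared error on the exemplars.
#' @param k Parameter count ([count_weights()]).
#' @param n Number of exemplars.
#' @return List with `aic` and `mdl` (`-Inf` flagged degenerate when `mse`
#'   is 0).
#' @export
model_selection_scores <- function(mse, k, n) {
  if (mse <= 0) {
    return(list(aic = -Inf, mdl = -Inf, degenerate = TRUE))
  }
  list(aic = n * log(mse) + 2 * k, mdl = n * log(mse) + (k / 2) * log(n),
       degenerate = FALSE)
}

#' Performance metrics of network scores against targets
#'
#' @param scores Network outputs.
#' @param targets Coded targets +1/-1.
#' @param model Trained model (for the parameter count), or a number giving
#'   `k` directly.
#' @param threshold Classification cut-off for the error percentage.
#' @return List of class `performance_report`: `mse`, `nmse` (MSE over target
#'   variance; `NA`-flagged when targets are constant), `r` (Pearson
#'   correlation), `pct_error` (100 x misclassified fraction), `aic`, `mdl`,
#'   `k`, `n`.
#' @export
performance_metrics <- function(scores, targets, model, threshold = 0) {
  n <- length(scores)
  if (n == 0 || n != length(targets)) stop("scores/targets length mismatch")
  k <- if (is.numeric(model)) model else count_weights(model)
  mse <- mean((scores - targets)^2)
  tvar <- mean((targets - mean(targets))^2)
  nmse <- if (tvar > 0) mse / tvar else NA_real_
  r <- if (tvar > 0 && stats::sd(scores) > 0) stats::cor(scores, targets) else NA_real_
  pred <- ifelse(scores > threshold, 1, -1)
  pct_error <- 100 * mean(pred != targets)
  sel <- model_selection_scores(mse, k, n)
  structure(list(mse = mse, nmse = nmse, r = r, pct_error = pct_error,
                 aic = sel$aic, mdl = sel$mdl, degenerate = sel$degenerate,
                 k = k, n = n),
            class = "performance_report")
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds sweep the sorted unique scores with infinite sentinels; a row is
#' called positive when its score strictly exceeds the threshold (equal scores
#' collapse into one threshold). AUC by the trapezoid rule.
#'
#' @param scores Numeric scores (higher = more depression-like).
#' @param labels_true Labels +1/-1; both classes must be present.
#' @return List of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc <- function(scores, labels_true) {
  if (length(unique(labels_true)) < 2) {
    stop("ROC needs both classes present")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- sum(labels_true == 1); neg <- sum(labels_true == -1)
  tpr <- vapply(thr, function(t) sum(scores > t & labels_true == 1) / pos, 0)
  fpr <- vapply(thr, function(t) sum(scores > t & labels_true == -1) / neg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Input-sensitivity analysis of a trained network
#'
#' Determines which input channels drive the output most: each channel in
#' turn is swept over its training mean plus/minus one standard deviation in
#' `n_steps` equal steps while all other channels sit at their means; the
#' dispersion (standard deviation) of the network output is the channel's
#' sensitivity. Channels are ranked by descending dispersion. Constant
#' channels get sensitivity 0 and a flag.
#'
#' @param model Trained `mlp_model` or `rbfn_model`.
#' @param X Training input matrix (standardized scale).
#' @param n_steps Number of sweep points.
#' @return List of class `sensitivity_report`: `sensitivity` (named scores),
#'   `rank` (channel indices, most sensitive first), `flags`.
#' @export
input_sensitivity <- function(model, X, n_steps = 50) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  p <- ncol(X)
  fwd <- function(M) if (inherits(model, "rbfn_model")) rbfn_forward(model, M)
                     else mlp_forward(model, M)
  scores <- numeric(p)
  for (j in seq_len(p)) {
    if (!is.finite(sd_[j]) || sd_[j] == 0) { scores[j] <- 0; next }
    grid <- seq(mu[j] - sd_[j], mu[j] + sd_[j], length.out = n_steps)
    M <- matrix(rep(mu, each = n_steps), n_steps, p)
    M[, j] <- grid
    scores[j] <- stats::sd(fwd(M))
  }
  names(scores) <- colnames(X) %||% paste0("x", seq_len(p))
  structure(list(sensitivity = scores, rank = order(scores, decreasing = TRUE),
                 flags = which(sd_ == 0)),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> top channels:\n")
  top <- utils::head(x$rank, 8)
  print(round(x$sensitivity[top], 4))
  invisible(x)
}

#' Full evaluation of a trained network on a test feature matrix
#'
#' Produces the whole battery at the laugh level and, when requested, at the
#' subject level by majority vote over each subject's laugh predictions (ties
#' break toward depression: the screening posture prefers a false alarm to a
#' miss).
#'
#' @param model Trained model.
#' @param fm Test [build_feature_matrix()] (already standardized `X`).
#' @param level `"laugh"`, `"subject"`, or `"both"`.
#' @param threshold Decision cut-off.
#' @return List of class `eval_report` with one entry per level, each holding
#'   `confusion`, `validity`, `performance`, `roc`, `n`.
#' @export
evaluate_network <- function(model, fm, level = c("both", "laugh", "subject"),
                             threshold = 0) {
  level <- match.arg(level)
  if (nrow(fm$X) == 0) stop("empty test matrix")
  pred <- predict_class(model, fm$X, threshold)
  out <- list()
  if (level %in% c("both", "laugh")) {
    cm <- confusion(fm$y, pred$labels)
    out$laugh <- list(
      confusion = cm, validity = validity_metrics(cm),
      performance = performance_metrics(pred$scores, fm$y, model, threshold),
      roc = if (length(unique(fm$y)) == 2) roc(pred$scores, fm$y) else NULL,
      n = length(fm$y))
  }
  if (level %in% c("both", "subject")) {
    subj <- unique(fm$subject_id)
    subj_true <- vapply(subj, function(s) fm$y[fm$subject_id == s][1], 0)
    subj_score <- vapply(subj, function(s) mean(pred$scores[fm$subject_id == s]), 0)
    subj_pred <- vapply(subj, function(s) {
      v <- pred$labels[fm$subject_id == s]
      if (sum(v == 1) >= sum(v == -1)) 1 else -1   # tie -> depression
    }, 0)
    cm <- confusion(subj_true, subj_pred)
    out$subject <- list(
      confusion = cm, validity = validity_metrics(cm),
      performance = performance_metrics(subj_score, subj_true, model, threshold),
      roc = if (length(unique(subj_true)) == 2) roc(subj_score, subj_true) else NULL,
      n = length(subj))
  }
  structure(out, class = "eval_report")
}
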