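# Hybrid radial basis function network: an unsupervised Gaussian prototype
# layer (k-means centers under Euclidean distance, overlap-heuristic widths)
# feeding a supervised tanh hidden layer and tanh output trained by the same
# momentum backpropagation as the MLP.

#' RBFN configuration
#'
#' The reference architecture is 40-8-4-1: 40 inputs, 8 Gaussian prototypes
#' placed by k-means (at most 100 unsupervised epochs), a 4-unit tanh hidden
#' layer (step size 1.0, momentum 0.7) and a single tanh output (step size
#' 0.1, momentum 0.7), supervised for at most 10,000 epochs.
#'
#' @param input_size Input dimensionality (40 for the ANN40 schema).
#' @param n_centers Number of Gaussian prototypes.
#' @param hidden Supervised hidden layer size.
#' @param step_sizes Learning rates for the hidden and output layers.
#' @param momentum Momentum coefficient.
#' @param unsupervised_epochs k-means iteration cap.
#' @param supervised_epochs Backpropagation epoch cap.
#' @param mse_stop_threshold Early-stop MSE floor.
#' @param seed Seed covering center initialization and weight draw.
#' @export
rbfn_config <- function(input_size = 40, n_centers = 8, hidden = 4,
                        step_sizes = c(1.0, 0.1), momentum = 0.7,
                        unsupervised_epochs = 100, supervised_epochs = 10000,
                        mse_stop_threshold = 1e-4, seed = 1L) {
  structure(list(input_size = input_size, n_centers = n_centers,
                 hidden = hidden, step_sizes = step_sizes, momentum = momentum,
                 unsupervised_epochs = unsupervised_epochs,
                 supervised_epochs = supervised_epochs,
                 mse_stop_threshold = mse_stop_threshold, seed = as.integer(seed)),
            class = "rbfn_config")
}

#' Lloyd's k-means under squared Euclidean distance
#'
#' Centers are initialized from distinct data rows; iterations stop on
#' assignment convergence or at `max_epochs`. A cluster left empty is reseeded
#' from the point farthest from its assigned center.
#'
#' @param X Data matrix (n x p), n >= `n_centers`.
#' @param n_centers Number of clusters.
#' @param max_epochs Iteration cap.
#' @param seed Optional seed for the initialization draw.
#' @return List with `centers` (k x p), `assignment`, `distortion` (total
#'   within-cluster squared distance).
#' @export
kmeans_centers <- function(X, n_centers = 8, max_epochs = 100, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_centers) stop("need at least as many exemplars as centers")
  if (!is.null(seed)) set.seed(seed)
  n_distinct <- nrow(unique(X))
  if (n_distinct < n_centers) {
    warning("only ", n_distinct, " distinct exemplars for ", n_centers,
            " centers; duplicated centers will collapse")
  }
  centers <- X[sample.int(n, n_centers), , drop = FALSE]
  assignment <- rep(0L, n)
  dist2 <- function(C) {
    # n x k matrix of squared Euclidean distances
    outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
      outer(rep(1, n), rowSums(C^2))
  }
  for (epoch in seq_len(max_epochs)) {
    D <- dist2(centers)
    new_assignment <- max.col(-D, ties.method = "first")
    for (j in seq_len(n_centers)) {
      members <- which(new_assignment == j)
      if (length(members) == 0) {
        far <- which.max(D[cbind(seq_len(n), new_assignment)])
        centers[j, ] <- X[far, ]
        new_assignment[far] <- j
      } else {
        centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    if (identical(new_assignment, assignment)) break
    assignment <- new_assignment
  }
  D <- dist2(centers)
  list(centers = centers, assignment = assignment,
       distortion = sum(D[cbind(seq_len(n), assignment)]))
}

# Overlap-heuristic widths: sigma_j = mean Euclidean distance from center j to
# its two nearest fellow centers (scale-free; keeps neighboring Gaussians
# overlapping). Degenerate duplicates get the global mean width.
rbf_widths <- function(centers) {
  k <- nrow(centers)
  D <- as.matrix(stats::dist(centers))
  sig <- vapply(seq_len(k), function(j) {
    d <- sort(D[j, -j])
    mean(d[seq_len(min(2, length(d)))])
  }, 0)
  sig[sig <= 0] <- mean(sig[sig > 0])
  if (all(sig <= 0 | !is.finite(sig))) sig[] <- 1
  sig
}

rbf_phi <- function(X, centers, widths) {
  X <- as.matrix(X)
  D2 <- outer(rowSums(X^2), rep(1, nrow(centers))) - 2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  D2[D2 < 0] <- 0
  exp(-sweep(D2, 2, 2 * widths^2, "/"))
}

#' Train the hybrid RBF network
#'
#' Phase 1 (unsupervised): [kmeans_centers()] places the Gaussian prototypes;
#' widths come from the two-nearest-center overlap heuristic. Phase 2
#' (supervised): with centers frozen, the Gaussian activations feed a tanh
#' hidden layer and tanh output trained by momentum backpropagation.
#'
#' @param config An [rbfn_config()].
#' @param X Standardized inputs (n x `input_size`).
#' @param y Targets +1/-1.
#' @return An `rbfn_model` with centers, widths, dense weights and history.
#' @export
rbfn_train <- function(config, X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 exemplars")
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  if (ncol(X) != config$input_size) {
    stop("dimension mismatch: network expects ", config$input_size,
         " inputs, got ", ncol(X))
  }
  if (config$n_centers > nrow(X)) stop("n_centers exceeds training exemplars")
  set.seed(config$seed)
  km <- kmeans_centers(X, config$n_centers, config$unsupervised_epochs)
  widths <- rbf_widths(km$centers)
  Phi <- rbf_phi(X, km$centers, widths)
  net <- init_layers(c(config$n_centers, config$hidden, 1L))
  fit <- train_core(net$W, net$b, Phi, y, config$step_sizes, config$momentum,
                    config$supervised_epochs, config$mse_stop_threshold)
  structure(list(centers = km$centers, widths = widths,
                 W = fit$W, b = fit$b, config = config, history = fit$history),
            class = "rbfn_model")
}

#' Forward pass of a trained RBFN
#'
#' @param model An `rbfn_model`.
#' @param X Input rows in the original (standardized) feature space.
#' @return Scores in `(-1, 1)`.
#' @export
rbfn_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(model$centers)) {
    stop("dimension mismatch: network expects ", ncol(model$centers),
         " inputs, got ", ncol(X))
  }
  Phi <- rbf_phi(X, model$centers, model$widths)
  as.numeric(net_forward(model$W, model$b, Phi)[[length(model$W) + 1]])
}

#' @export
print.rbfn_model <- function(x, ...) {
  cat(sprintf("<rbfn_model> %d-%d-%d-1, %d parameters, trained %d epochs (final MSE %.4g)\n",
              ncol(x$centers), nrow(x$centers), ncol(x$W[[1]]) ,
              count_weights(x), length(x$history), utils::tail(x$history, 1)))
  invisible(x)
}
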