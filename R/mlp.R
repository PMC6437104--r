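# Multilayer perceptron trained from scratch with per-layer step sizes and
# momentum backpropagation, tanh units throughout. Three named architectures
# feed on the laugh-level schemas: ANN (p = 40), EANN (p = 5), 5PANN (p = 6),
# all with 16- and 9-unit hidden layers and a single tanh output.

#' MLP configuration
#'
#' Defaults follow the reference training recipe: hidden layers of 16 and 9
#' tanh units, backpropagation-with-momentum with per-layer step sizes 1.0
#' (first hidden), 0.1 (second hidden) and 0.01 (output), momentum 0.7
#' everywhere, at most 10,000 epochs with MSE as the stop criterion.
#'
#' @param p Input dimensionality.
#' @param hidden Hidden layer sizes.
#' @param step_sizes One learning rate per weight layer (hidden layers then
#'   output).
#' @param momentum Momentum coefficient in `[0, 1)`, shared by all layers.
#' @param max_epochs Epoch cap.
#' @param mse_stop_threshold Stop when epoch MSE falls at or below this floor.
#' @param online If `TRUE` update after every exemplar instead of batch
#'   (epoch-wise) gradient accumulation; off by default.
#' @param seed Seed for weight initialization (uniform in `[-0.5, 0.5]`).
#' @export
mlp_config <- function(p, hidden = c(16, 9), step_sizes = c(1.0, 0.1, 0.01),
                       momentum = 0.7, max_epochs = 10000,
                       mse_stop_threshold = 1e-4, online = FALSE, seed = 1L) {
  layer_sizes <- c(p, hidden, 1L)
  if (any(layer_sizes <= 0)) stop("layer sizes must be positive")
  if (length(step_sizes) != length(layer_sizes) - 1) {
    stop("need one step size per weight layer (", length(layer_sizes) - 1, ")")
  }
  if (any(step_sizes <= 0)) stop("step sizes must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  structure(list(p = p, layer_sizes = layer_sizes, step_sizes = step_sizes,
                 momentum = momentum, max_epochs = max_epochs,
                 mse_stop_threshold = mse_stop_threshold, online = online,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

init_layers <- function(layer_sizes) {
  L <- length(layer_sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::runif(layer_sizes[l] * layer_sizes[l + 1], -0.5, 0.5),
                     layer_sizes[l], layer_sizes[l + 1])
    b[[l]] <- stats::runif(layer_sizes[l + 1], -0.5, 0.5)
  }
  list(W = W, b = b)
}

net_forward <- function(W, b, X) {
  A <- list(X)
  for (l in seq_along(W)) {
    A[[l + 1]] <- tanh(sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+"))
  }
  A
}

# Analytic gradient of MSE = mean over exemplars of (output - target)^2.
net_gradient <- function(W, b, X, y) {
  n <- nrow(X)
  A <- net_forward(W, b, X)
  L <- length(W)
  out <- A[[L + 1]]
  delta <- (2 / n) * (out - y) * (1 - out^2)
  dW <- vector("list", L); db <- vector("list", L)
  for (l in L:1) {
    dW[[l]] <- crossprod(A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(W[[l]])) * (1 - A[[l]]^2)
  }
  list(dW = dW, db = db, mse = mean((out - y)^2))
}

# Shared momentum-backpropagation trainer for the MLP and the supervised
# phase of the RBFN. Update rule per layer l:
#   v(t) = mu * v(t-1) - eta_l * dMSE/dw;  w <- w + v(t)
train_core <- function(W, b, X, y, step_sizes, momentum, max_epochs,
                       mse_stop, online = FALSE) {
  L <- length(W)
  vW <- lapply(W, function(m) m * 0); vb <- lapply(b, function(v) v * 0)
  history <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    if (online) {
      for (i in sample.int(nrow(X))) {
        g <- net_gradient(W, b, X[i, , drop = FALSE], y[i])
        for (l in seq_len(L)) {
          vW[[l]] <- momentum * vW[[l]] - step_sizes[l] * g$dW[[l]]
          vb[[l]] <- momentum * vb[[l]] - step_sizes[l] * g$db[[l]]
          W[[l]] <- W[[l]] + vW[[l]]; b[[l]] <- b[[l]] + vb[[l]]
        }
      }
      out <- net_forward(W, b, X)[[L + 1]]
      mse <- mean((out - y)^2)
    } else {
      g <- net_gradient(W, b, X, y)
      mse <- g$mse
    }
    history[epoch] <- mse
    if (!is.finite(mse) || mse > 1e6) {
      stop("training diverged (MSE = ", format(mse),
           "); try smaller step sizes")
    }
    if (mse <= mse_stop) break
    if (!online) {
      for (l in seq_len(L)) {
        vW[[l]] <- momentum * vW[[l]] - step_sizes[l] * g$dW[[l]]
        vb[[l]] <- momentum * vb[[l]] - step_sizes[l] * g$db[[l]]
        W[[l]] <- W[[l]] + vW[[l]]; b[[l]] <- b[[l]] + vb[[l]]
      }
    }
  }
  list(W = W, b = b, history = history)
}

#' Train an MLP classifier
#'
#' @param config An [mlp_config()].
#' @param X Standardized input matrix (n exemplars x p).
#' @param y Targets coded +1 (depression) / -1 (control).
#' @return An `mlp_model`: weights, biases, config, per-epoch MSE history.
#' @export
mlp_train <- function(config, X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 exemplars")
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  if (ncol(X) != config$p) {
    stop("dimension mismatch: network expects p = ", config$p,
         " inputs, got ", ncol(X))
  }
  set.seed(config$seed)
  net <- init_layers(config$layer_sizes)
  fit <- train_core(net$W, net$b, X, y, config$step_sizes, config$momentum,
                    config$max_epochs, config$mse_stop_threshold, config$online)
  structure(list(W = fit$W, b = fit$b, config = config, history = fit$history),
            class = "mlp_model")
}

#' Forward pass of a trained MLP
#'
#' @param model An `mlp_model`.
#' @param X Input matrix or single row; must have the model's input width.
#' @return Scores in `(-1, 1)`, one per row.
#' @export
mlp_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$W[[1]])) {
    stop("dimension mismatch: network expects p = ", nrow(model$W[[1]]),
         " inputs, got ", ncol(X))
  }
  as.numeric(net_forward(model$W, model$b, X)[[length(model$W) + 1]])
}

#' @export
print.mlp_model <- function(x, ...) {
  sizes <- c(nrow(x$W[[1]]), vapply(x$W, ncol, 1L))
  cat(sprintf("<mlp_model> %s, %d weights, trained %d epochs (final MSE %.4g)\n",
              paste(sizes, collapse = "-"), count_weights(x),
              length(x$history), utils::tail(x$history, 1)))
  invisible(x)
}

#' Number of free parameters (weights and biases) of a model
#'
#' Counts every trainable scalar; for the RBFN this includes the prototype
#' centers and widths set during unsupervised training.
#'
#' @param model An `mlp_model` or `rbfn_model`.
#' @export
count_weights <- function(model) {
  k <- sum(vapply(model$W, length, 1L)) + sum(vapply(model$b, length, 1L))
  if (inherits(model, "rbfn_model")) {
    k <- k + length(model$centers) + length(model$widths)
  }
  k
}

#' Threshold scores into class labels
#'
#' @param model Trained model (`mlp_model` or `rbfn_model`).
#' @param X Input rows.
#' @param threshold Decision cut-off on the tanh output; the label is +1
#'   (depression) iff the score is strictly greater.
#' @return List with `labels` (+1/-1) and raw `scores` (for ROC analysis).
#' @export
predict_class <- function(model, X, threshold = 0) {
  scores <- if (inherits(model, "rbfn_model")) rbfn_forward(model, X)
            else mlp_forward(model, X)
  list(labels = ifelse(scores > threshold, 1, -1), scores = scores)
}
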