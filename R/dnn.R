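# Feed-forward cancer-score network. Architecture: input layer of normalized
# site depths, two hidden layers of 64 rectified-linear units, and a 2-way
# softmax output trained with cross-entropy over 120 epochs. Optimization is
# Adam with mini-batches; weights, shuffling and initialization are all
# driven by the configured seed so a run is exactly reproducible.

#' Network configuration
#'
#' @param input_dim Number of input features (sites).
#' @param hidden Hidden layer widths.
#' @param epochs Training passes over the data.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A `dnn_config` list.
#' @export
dnn_config <- function(input_dim, hidden = c(64L, 64L), epochs = 120L,
                       batch_size = 16L, learning_rate = 1e-3, seed = 1L) {
  stopifnot(input_dim >= 1L, all(hidden >= 1L), epochs >= 1L,
            batch_size >= 1L, learning_rate > 0)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "dnn_config")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the cancer-score network
#'
#' Features are standardized with the training set's own column means and
#' standard deviations (stored in the model and reapplied at scoring time,
#' so no statistics leak from unseen samples). Training runs exactly
#' `config$epochs` passes of mini-batch Adam on the softmax cross-entropy.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Binary labels (logical, 0/1, or a 2-level factor whose second
#'   level is the positive class).
#' @param config From [dnn_config()].
#' @return A `dnn_model` with weights, standardization statistics, and the
#'   per-epoch mean loss trajectory.
#' @export
train_model <- function(x, y, config) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L)
    stop("degenerate training set: only one class present")
  if (ncol(x) != config$input_dim)
    stop("feature dimension ", ncol(x), " does not match config input_dim ",
         config$input_dim)
  if (any(!is.finite(x))) stop("non-finite feature values")
  n <- nrow(x)

  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")

  sizes <- c(config$input_dim, config$hidden, 2L)
  L <- length(sizes) - 1L
  set.seed(config$seed)
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  t_step <- 0L
  target <- cbind(1 - y, y)  # columns: control, case
  loss_trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batch_starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in batch_starts) {
      rows <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- xs[rows, , drop = FALSE]
      tb <- target[rows, , drop = FALSE]
      # forward
      a <- vector("list", L + 1L)
      a[[1L]] <- xb
      for (l in seq_len(L - 1L)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        a[[l + 1L]] <- pmax(z, 0)
      }
      logits <- sweep(a[[L]] %*% W[[L]], 2, b[[L]], "+")
      p <- softmax_rows(logits)
      epoch_loss <- epoch_loss -
        sum(tb * log(pmax(p, 1e-12))) / n
      # backward
      delta <- (p - tb) / nrow(xb)
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(a[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        }
      }
      # Adam update
      t_step <- t_step + 1L
      c1 <- 1 - beta1^t_step; c2 <- 1 - beta2^t_step
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
      }
    }
    loss_trace[epoch] <- epoch_loss
  }
  structure(list(W = W, b = b, mu = mu, sd = sdv,
                 config = config, loss = loss_trace),
            class = "dnn_model")
}

as_binary_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("labels must have exactly 2 levels")
    as.integer(y) - 1L
  } else if (is.logical(y)) {
    as.integer(y)
  } else if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
    as.integer(y)
  } else stop("unsupported label type")
}

#' Cancer score of samples under a trained model
#'
#' The cancer score is the softmax probability of the positive (cancer)
#' output unit.
#'
#' @param model From [train_model()].
#' @param x Samples x features matrix on the model's feature space.
#' @return Numeric vector of scores in [0, 1].
#' @export
score_samples <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$config$input_dim)
    stop("feature dimension ", ncol(x), " does not match model input_dim ",
         model$config$input_dim)
  a <- sweep(sweep(x, 2, model$mu), 2, model$sd, "/")
  L <- length(model$W)
  for (l in seq_len(L - 1L)) {
    a <- pmax(sweep(a %*% model$W[[l]], 2, model$b[[l]], "+"), 0)
  }
  logits <- sweep(a %*% model$W[[L]], 2, model$b[[L]], "+")
  softmax_rows(logits)[, 2L]
}
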