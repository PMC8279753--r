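#' Multilayer perceptron for binary classification
#'
#' Feed-forward network with rectified-linear hidden layers and a logistic
#' output unit, trained by backpropagation with the Adam optimizer on
#' mini-batches of the binary cross-entropy loss plus an L2 weight penalty.
#' The default architecture — six hidden layers of 100 units, L2 penalty
#' 0.01 — is the configuration this pipeline uses as its reference
#' classifier; the remaining defaults (Adam at learning rate 1e-3, batch
#' size `min(200, n)`, 200 epochs, stop when the loss fails to improve by
#' `tol` for `n_iter_no_change` consecutive epochs) follow common MLP
#' implementation practice. Weights use Glorot-uniform initialization,
#' biases start at zero.
#'
#' No compiled multi-hidden-layer perceptron is required: on feature widths
#' of a few hundred the dense matrix products run through BLAS.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Integer 0/1 labels.
#' @param hidden Integer vector of hidden-layer widths.
#' @param alpha L2 penalty coefficient.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (default `min(200, n)`).
#' @param max_iter Maximum number of epochs.
#' @param tol,n_iter_no_change Early-stopping rule on the training loss.
#' @param seed Optional integer seed for initialization and batch
#'   shuffling.
#' @return An object of class `acp_mlp` with `predict()` support
#'   (`type = "prob"` or `"class"`, threshold 0.5).
#' @export
mlp_fit <- function(x, y, hidden = rep(100L, 6L), alpha = 0.01,
                    learning_rate = 1e-3, batch_size = NULL,
                    max_iter = 200L, tol = 1e-4, n_iter_no_change = 10L,
                    seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  if (is.null(batch_size)) batch_size <- min(200L, n)
  sizes <- c(ncol(x), hidden, 1L)
  n_layers <- length(sizes) - 1L
  glorot <- function(fan_in, fan_out) {
    bound <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
  }
  W <- lapply(seq_len(n_layers), function(l) glorot(sizes[l], sizes[l + 1L]))
  b <- lapply(seq_len(n_layers), function(l) numeric(sizes[l + 1L]))
  adam <- list(mW = lapply(W, function(w) w * 0),
               vW = lapply(W, function(w) w * 0),
               mb = lapply(b, function(v) v * 0),
               vb = lapply(b, function(v) v * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  best_loss <- Inf
  stall <- 0L
  loss_curve <- numeric(0)
  for (epoch in seq_len(max_iter)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      nb <- length(idx)
      # forward
      act <- vector("list", n_layers + 1L)
      act[[1]] <- xb
      for (l in seq_len(n_layers)) {
        z <- act[[l]] %*% W[[l]] + rep(b[[l]], each = nrow(act[[l]]))
        act[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else z  # logits out
      }
      logits <- act[[n_layers + 1L]][, 1]
      prob <- 1 / (1 + exp(-logits))
      # stable log-loss from logits
      ll <- mean(pmax(logits, 0) - logits * yb + log1p(exp(-abs(logits))))
      pen <- 0.5 * alpha * sum(vapply(W, function(w) sum(w^2), numeric(1))) / nb
      epoch_loss <- epoch_loss + (ll + pen) * nb
      # backward
      delta <- matrix((prob - yb) / nb, ncol = 1L)
      t_step <- t_step + 1L
      corr1 <- 1 - beta1^t_step
      corr2 <- 1 - beta2^t_step
      for (l in rev(seq_len(n_layers))) {
        gW <- crossprod(act[[l]], delta) + (alpha / nb) * W[[l]]
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * (act[[l]] > 0)
        adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * gW
        adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * gW^2
        W[[l]] <- W[[l]] - learning_rate * (adam$mW[[l]] / corr1) /
          (sqrt(adam$vW[[l]] / corr2) + eps)
        adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * gb
        adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * gb^2
        b[[l]] <- b[[l]] - learning_rate * (adam$mb[[l]] / corr1) /
          (sqrt(adam$vb[[l]] / corr2) + eps)
      }
    }
    epoch_loss <- epoch_loss / n
    loss_curve <- c(loss_curve, epoch_loss)
    if (epoch_loss > best_loss - tol) stall <- stall + 1L else stall <- 0L
    best_loss <- min(best_loss, epoch_loss)
    if (stall >= n_iter_no_change) break
  }
  structure(list(W = W, b = b, hidden = hidden, alpha = alpha,
                 n_iter = length(loss_curve), loss_curve = loss_curve,
                 feature_names = colnames(x)),
            class = "acp_mlp")
}

#' @export
print.acp_mlp <- function(x, ...) {
  cat(sprintf("acp_mlp: %d inputs -> %s -> 1, alpha = %g, %d epochs (final loss %.4f)\n",
              nrow(x$W[[1]]), paste(x$hidden, collapse = "-"), x$alpha,
              x$n_iter, x$loss_curve[length(x$loss_curve)]))
  invisible(x)
}

#' @rdname mlp_fit
#' @param object A fitted `acp_mlp`.
#' @param newdata Numeric matrix of samples to score.
#' @param type `"class"` (0/1 at threshold 0.5) or `"prob"`.
#' @param ... Unused.
#' @export
predict.acp_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  a <- newdata
  n_layers <- length(object$W)
  for (l in seq_len(n_layers)) {
    z <- a %*% object$W[[l]] + rep(object$b[[l]], each = nrow(a))
    a <- if (l < n_layers) pmax(z, 0) else z
  }
  prob <- 1 / (1 + exp(-a[, 1]))
  if (type == "prob") prob else as.integer(prob >= 0.5)
}
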