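# Compact feed-forward multilayer perceptron for the 2-D reduced feature
# space: ReLU hidden layers, softmax output, cross-entropy loss with L2
# penalty, full-batch Adam, and an adaptive learning-rate schedule (the
# rate is divided by 5 after `n_iter_no_change` non-improving iterations;
# training stops once it falls below 1e-6 or at `max_iter`).

#' Fit a multilayer perceptron classifier
#'
#' @param x Numeric matrix (n x d), typically the two PLS-DR coordinates.
#' @param y Class labels (factor or character).
#' @param hidden Hidden layer sizes; default `c(32, 32)`.
#' @param max_iter Maximum full-batch iterations (default 3000).
#' @param learning_rate_init Initial Adam learning rate.
#' @param alpha L2 penalty on the weights.
#' @param tol Minimal loss improvement counted as progress.
#' @param n_iter_no_change Patience before the learning rate is reduced.
#' @param seed Seed for the weight initialization.
#' @return An `mlp` object.
#' @export
mlp_fit <- function(x, y, hidden = c(32L, 32L), max_iter = 3000L,
                    learning_rate_init = 1e-3, alpha = 1e-4, tol = 1e-4,
                    n_iter_no_change = 10L, seed = 1L) {
  x <- as.matrix(x)
  f <- factor(y)
  classes <- levels(f)
  if (length(classes) < 2L) stop("need >= 2 classes to fit an MLP")
  yi <- as.integer(f)
  n <- nrow(x); k <- length(classes)
  sizes <- c(ncol(x), hidden, k)
  target <- matrix(0, n, k); target[cbind(seq_len(n), yi)] <- 1
  nw <- length(sizes) - 1L
  W <- vector("list", nw); b <- vector("list", nw)
  with_seed(seed, {
    for (l in seq_len(nw)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                             sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
  })
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- learning_rate_init
  best <- Inf; stall <- 0L
  for (it in seq_len(max_iter)) {
    acts <- vector("list", nw + 1L)
    acts[[1L]] <- x
    for (l in seq_len(nw)) {
      z <- sweep(acts[[l]] %*% W[[l]], 2L, b[[l]], `+`)
      acts[[l + 1L]] <- if (l < nw) pmax(z, 0) else z
    }
    z <- acts[[nw + 1L]]
    z <- z - apply(z, 1L, max)
    ez <- exp(z)
    prob <- ez / rowSums(ez)
    loss <- -mean(log(pmax(prob[cbind(seq_len(n), yi)], 1e-12))) +
      alpha / (2 * n) * sum(vapply(W, function(w) sum(w^2), 1))
    if (loss < best - tol) {
      best <- loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= n_iter_no_change) {
        lr <- lr / 5
        stall <- 0L
        if (lr < 1e-6) break
      }
    }
    delta <- (prob - target) / n
    for (l in rev(seq_len(nw))) {
      gW <- crossprod(acts[[l]], delta) + alpha / n * W[[l]]
      gb <- colSums(delta)
      if (l > 1L) delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mhW <- mW[[l]] / (1 - beta1^it); vhW <- vW[[l]] / (1 - beta2^it)
      mhb <- mb[[l]] / (1 - beta1^it); vhb <- vb[[l]] / (1 - beta2^it)
      W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  structure(list(W = W, b = b, classes = classes, sizes = sizes,
                 loss = best, n_iter = it, hidden = hidden, seed = seed),
            class = "mlp")
}

#' @export
predict.mlp <- function(object, newx, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  a <- as.matrix(newx)
  nw <- length(object$W)
  for (l in seq_len(nw)) {
    z <- sweep(a %*% object$W[[l]], 2L, object$b[[l]], `+`)
    a <- if (l < nw) pmax(z, 0) else z
  }
  z <- a - apply(a, 1L, max)
  prob <- exp(z) / rowSums(exp(z))
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, "first")], levels = object$classes)
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("MLP %s, %d classes, %d iterations, loss %.4g\n",
              paste(x$sizes, collapse = "-"), length(x$classes),
              x$n_iter, x$loss))
  invisible(x)
}
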