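# Minimal multilayer perceptron: one hidden layer of ReLU units, softmax
# output, cross-entropy loss, Adam updates. Seeded He-normal init and a
# seeded shuffle each epoch make training fully deterministic.

.mlpFit <- function(X, y, hidden = 100L, epochs = 200L, batch = 32L,
                    lr = 1e-3, seed = 0L) {
  lev <- levels(y)
  n <- nrow(X); p <- ncol(X); C <- length(lev)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  set.seed(as.integer(seed %% 2147483647))
  W1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(2 / max(p, 1))), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * C, 0, sqrt(2 / hidden)), hidden, C)
  b2 <- numeric(C)
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(pars, function(x) x * 0)
  v <- lapply(pars, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1, n)]
      xb <- X[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      nb <- length(idx)
      a1 <- sweep(xb %*% pars$W1, 2, pars$b1, "+")
      h1 <- pmax(a1, 0)
      z <- sweep(h1 %*% pars$W2, 2, pars$b2, "+")
      z <- z - apply(z, 1, max)
      ez <- exp(z)
      prob <- ez / rowSums(ez)
      dz <- (prob - yb) / nb
      grads <- list(W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL)
      grads$W2 <- t(h1) %*% dz
      grads$b2 <- colSums(dz)
      dh <- (dz %*% t(pars$W2)) * (a1 > 0)
      grads$W1 <- t(xb) %*% dh
      grads$b1 <- colSums(dh)
      t <- t + 1
      for (k in names(pars)) {
        m[[k]] <- beta1 * m[[k]] + (1 - beta1) * grads[[k]]
        v[[k]] <- beta2 * v[[k]] + (1 - beta2) * grads[[k]]^2
        mhat <- m[[k]] / (1 - beta1^t)
        vhat <- v[[k]] / (1 - beta2^t)
        pars[[k]] <- pars[[k]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  structure(list(pars = pars, levels = lev), class = "molarMlp")
}

.mlpPredict <- function(fit, X) {
  a1 <- sweep(X %*% fit$pars$W1, 2, fit$pars$b1, "+")
  h1 <- pmax(a1, 0)
  z <- sweep(h1 %*% fit$pars$W2, 2, fit$pars$b2, "+")
  factor(fit$levels[max.col(z, ties.method = "first")], levels = fit$levels)
}
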