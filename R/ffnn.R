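# Single-hidden-layer feed-forward network: ReLU hidden units, softmax
# output, cross-entropy loss, Adam minibatch updates, early stopping on a
# held-out validation slice. Written in plain matrix algebra; the sizes in
# play (a few hundred features and hidden units, thousands of records)
# train in seconds on a BLAS-backed R.

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

ffnn_fit <- function(X, y, hidden = 297, epochs = 30, batch = 32,
                     lr = 1e-3, val_frac = 0.1, patience = 5, seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)                       # 1..C
  C <- max(y)
  n <- nrow(X); d <- ncol(X)
  set.seed(seed)
  # validation slice for early stopping
  n_val <- floor(n * val_frac)
  val_idx <- if (n_val >= 1 && n - n_val >= C) sample.int(n, n_val)
             else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
  Ytr <- matrix(0, length(ytr), C); Ytr[cbind(seq_along(ytr), ytr)] <- 1

  # He initialization
  W1 <- matrix(rnorm(d * hidden, 0, sqrt(2 / max(d, 1))), d, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(rnorm(hidden * C, 0, sqrt(2 / hidden)), hidden, C)
  b2 <- numeric(C)
  adam <- list()
  for (nm in c("W1", "b1", "W2", "b2"))
    adam[[nm]] <- list(m = get(nm) * 0, v = get(nm) * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

  ce_loss <- function(Xs, ys) {
    if (!length(ys)) return(NA_real_)
    P <- .softmax_rows(sweep(pmax(sweep(Xs %*% W1, 2, b1, "+"), 0) %*% W2,
                             2, b2, "+"))
    -mean(log(pmax(P[cbind(seq_along(ys), ys)], 1e-12)))
  }

  best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  stall <- 0
  ntr <- nrow(Xtr)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1, ntr, by = batch)
    for (s in starts) {
      idx <- ord[s:min(s + batch - 1, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]
      Yb <- Ytr[idx, , drop = FALSE]
      A1 <- sweep(Xb %*% W1, 2, b1, "+")
      H <- pmax(A1, 0)
      P <- .softmax_rows(sweep(H %*% W2, 2, b2, "+"))
      dZ2 <- (P - Yb) / nrow(Xb)
      gW2 <- crossprod(H, dZ2); gb2 <- colSums(dZ2)
      dH <- dZ2 %*% t(W2)
      dA1 <- dH * (A1 > 0)
      gW1 <- crossprod(Xb, dA1); gb1 <- colSums(dA1)
      t_step <- t_step + 1
      for (nm in c("W1", "b1", "W2", "b2")) {
        g <- get(paste0("g", nm))
        st <- adam[[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        adam[[nm]] <- st
        mhat <- st$m / (1 - beta1^t_step)
        vhat <- st$v / (1 - beta2^t_step)
        assign(nm, get(nm) - lr * mhat / (sqrt(vhat) + eps))
      }
    }
    monitor <- if (length(yval)) ce_loss(Xval, yval) else ce_loss(Xtr, ytr)
    if (monitor < best$loss - 1e-6) {
      best <- list(loss = monitor, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
  }
  list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
       n_classes = C, val_loss = best$loss, epochs_run = epoch)
}

ffnn_predict_prob <- function(fit, X) {
  X <- as.matrix(X)
  H <- pmax(sweep(X %*% fit$W1, 2, fit$b1, "+"), 0)
  .softmax_rows(sweep(H %*% fit$W2, 2, fit$b2, "+"))
}
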