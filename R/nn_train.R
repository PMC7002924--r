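# Minimal dense-network training with the Adam optimizer. Only what the
# attribution workflow needs: ReLU hidden layers, softmax/cross-entropy
# classification or identity/MSE reconstruction, L2 penalty, minibatches.

glorot_init <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

relu_grad <- function(z) (z > 0) * 1

# Train a dense feedforward net. Returns a network_spec plus the loss trace.
train_dense <- function(X, Y, hidden, output_activation = c("softmax", "identity"),
                        alpha = 1e-4, learning_rate = 1e-3, epochs = 200L,
                        batch_size = 32L, seed = 1L, tol = 1e-5,
                        n_iter_no_change = 10L) {
  output_activation <- match.arg(output_activation)
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  set.seed(seed)
  dims <- c(ncol(X), hidden, ncol(Y))
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  mW <- vector("list", L); vW <- vector("list", L)
  mb <- vector("list", L); vb <- vector("list", L)
  for (k in seq_len(L)) {
    W[[k]] <- glorot_init(dims[k], dims[k + 1L])
    b[[k]] <- numeric(dims[k + 1L])
    mW[[k]] <- W[[k]] * 0; vW[[k]] <- W[[k]] * 0
    mb[[k]] <- b[[k]] * 0; vb[[k]] <- b[[k]] * 0
  }
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  batch_size <- max(1L, min(as.integer(batch_size), n))
  t_step <- 0L
  losses <- numeric(epochs)
  best_loss <- Inf; best_obj <- Inf; stall <- 0L

  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      xb <- X[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
      nb <- nrow(xb)

      # forward
      a <- vector("list", L + 1L); z <- vector("list", L)
      a[[1L]] <- xb
      for (k in seq_len(L)) {
        z[[k]] <- sweep(a[[k]] %*% W[[k]], 2, b[[k]], "+")
        a[[k + 1L]] <- if (k < L) pmax(z[[k]], 0)
                       else apply_activation(z[[k]], output_activation)
      }
      out <- a[[L + 1L]]
      loss <- if (output_activation == "softmax")
        -sum(yb * log(pmax(out, 1e-12))) / nb
      else
        sum((out - yb)^2) / (2 * nb)
      epoch_loss <- epoch_loss + loss * nb / n

      # backward: softmax+CE and identity+MSE share delta = (out - y)/nb
      delta <- (out - yb) / nb
      for (k in L:1) {
        gW <- crossprod(a[[k]], delta) + alpha * W[[k]]
        gb <- colSums(delta)
        if (k > 1L) delta <- (delta %*% t(W[[k]])) * relu_grad(z[[k - 1L]])
        t_step <- t_step + 1L
        mW[[k]] <- beta1 * mW[[k]] + (1 - beta1) * gW
        vW[[k]] <- beta2 * vW[[k]] + (1 - beta2) * gW^2
        mb[[k]] <- beta1 * mb[[k]] + (1 - beta1) * gb
        vb[[k]] <- beta2 * vb[[k]] + (1 - beta2) * gb^2
        c1 <- 1 - beta1^t_step; c2 <- 1 - beta2^t_step
        W[[k]] <- W[[k]] - learning_rate * (mW[[k]] / c1) /
          (sqrt(vW[[k]] / c2) + eps)
        b[[k]] <- b[[k]] - learning_rate * (mb[[k]] / c1) /
          (sqrt(vb[[k]] / c2) + eps)
      }
    }
    losses[epoch] <- epoch_loss
    # plateau only when neither the data loss nor the full objective
    # improves: on easy data the loss saturates immediately but weight decay
    # keeps shrinking the penalty (and reshaping the attribution); on hard
    # data growing weights inflate the penalty while the loss still falls
    objective <- epoch_loss +
      0.5 * alpha * sum(vapply(W, function(w) sum(w^2), numeric(1)))
    improved <- FALSE
    if (epoch_loss < best_loss - tol) { best_loss <- epoch_loss
                                        improved <- TRUE }
    if (objective < best_obj - tol) { best_obj <- objective
                                      improved <- TRUE }
    if (improved) stall <- 0L else stall <- stall + 1L
    if (stall >= n_iter_no_change) { losses <- losses[seq_len(epoch)]; break }
  }

  layers <- lapply(seq_len(L), function(k) list(
    w = W[[k]], b = b[[k]],
    activation = if (k < L) "relu" else output_activation))
  list(layers = layers, loss = losses,
       converged = stall >= n_iter_no_change)
}

# Multilayer perceptron classifier (ReLU hidden, softmax output, Adam).
mlp_train <- function(X, labels, hidden_layers = c(100L), alpha = 1e-4,
                      learning_rate = 1e-3, epochs = 200L, batch_size = 32L,
                      seed = 1L, tol = 1e-5, n_iter_no_change = 10L) {
  if (!inherits(labels, "label_set")) labels <- label_set(labels)
  fit <- train_dense(X, labels$one_hot * 1, hidden_layers, "softmax",
                     alpha = alpha, learning_rate = learning_rate,
                     epochs = epochs, batch_size = batch_size, seed = seed,
                     tol = tol, n_iter_no_change = n_iter_no_change)
  fit$net <- network_spec(fit$layers, input_bounds = list(lower = 0, upper = 1))
  fit
}

mlp_predict <- function(net, X) {
  p <- nn_forward(net, X)
  p <- p[[length(p)]]
  max.col(p, ties.method = "first") - 1L
}

# Autoencoder regressor: input -> symmetric encoder/decoder -> input.
# `hidden_layers` gives the encoder stack down to the bottleneck; the decoder
# mirrors it, e.g. c(120, 100) builds hidden sizes 120-100-120.
ae_train <- function(X, hidden_layers = c(50L), alpha = 1e-4,
                     learning_rate = 1e-3, epochs = 200L, batch_size = 32L,
                     seed = 1L, tol = 1e-5, n_iter_no_change = 10L) {
  full <- c(hidden_layers, rev(hidden_layers[-length(hidden_layers)]))
  fit <- train_dense(X, X, full, "identity", alpha = alpha,
                     learning_rate = learning_rate, epochs = epochs,
                     batch_size = batch_size, seed = seed,
                     tol = tol, n_iter_no_change = n_iter_no_change)
  fit$net <- network_spec(fit$layers, input_bounds = list(lower = 0, upper = 1))
  fit
}

# Bernoulli restricted Boltzmann machine trained with stochastic maximum
# likelihood (persistent contrastive divergence). Inputs must lie in [0, 1]
# (probabilistic interpretation of feature activation).
rbm_train <- function(X, n_hidden = 64L, learning_rate = 0.05, n_iter = 20L,
                      batch_size = 32L, seed = 1L) {
  stopifnot(is.matrix(X))
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  W <- matrix(stats::rnorm(p * n_hidden, sd = 0.01), p, n_hidden)
  b_h <- numeric(n_hidden); b_v <- numeric(p)
  batch_size <- max(1L, min(as.integer(batch_size), n))
  sigmoid <- function(z) 1 / (1 + exp(-z))
  # persistent fantasy particles
  v_chain <- X[sample.int(n, batch_size, replace = n < batch_size), ,
               drop = FALSE]
  for (iter in seq_len(n_iter)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      v0 <- X[idx, , drop = FALSE]
      nb <- nrow(v0)
      h0 <- sigmoid(sweep(v0 %*% W, 2, b_h, "+"))
      # one Gibbs step on the persistent chain
      hc <- sigmoid(sweep(v_chain %*% W, 2, b_h, "+"))
      hs <- (matrix(stats::runif(length(hc)), nrow(hc)) < hc) * 1
      vc <- sigmoid(sweep(hs %*% t(W), 2, b_v, "+"))
      v_chain <- (matrix(stats::runif(length(vc)), nrow(vc)) < vc) * 1
      h1 <- sigmoid(sweep(v_chain %*% W, 2, b_h, "+"))
      nc <- nrow(v_chain)
      W <- W + learning_rate *
        (crossprod(v0, h0) / nb - crossprod(v_chain, h1) / nc)
      b_h <- b_h + learning_rate * (colMeans(h0) - colMeans(h1))
      b_v <- b_v + learning_rate * (colMeans(v0) - colMeans(v_chain))
    }
  }
  # single logistic layer visible -> hidden; the LRP engine runs backward
  # from the hidden activations with the z^B rule on the [0,1] input.
  net <- network_spec(
    list(list(w = W, b = b_h, activation = "logistic")),
    input_bounds = list(lower = 0, upper = 1))
  list(net = net, W = W, b_h = b_h, b_v = b_v)
}
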