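# Independent, loop-based reference implementations used as oracles. These
# deliberately avoid the package's vectorized code paths.

# Forward pass, one sample, explicit loops.
oracle_forward <- function(layers, x) {
  acts <- list(x)
  a <- x
  for (l in layers) {
    z <- numeric(ncol(l$w))
    for (k in seq_along(z)) z[k] <- sum(a * l$w[, k]) + l$b[k]
    a <- switch(l$activation,
      relu = pmax(z, 0),
      identity = z,
      logistic = 1 / (1 + exp(-z)),
      softmax = exp(z - max(z)) / sum(exp(z - max(z))))
    acts[[length(acts) + 1L]] <- a
  }
  acts
}

# One-layer relevance redistribution, explicit double loop.
oracle_propagate <- function(R_k, a_j, w, rule, epsilon = 1e-9,
                             lower = 0, upper = 1) {
  J <- length(a_j); K <- length(R_k)
  lower <- rep_len(lower, J); upper <- rep_len(upper, J)
  z <- matrix(0, J, K)
  for (j in seq_len(J)) for (k in seq_len(K)) {
    z[j, k] <- if (rule == "zplus") a_j[j] * max(0, w[j, k])
               else a_j[j] * w[j, k] - lower[j] * max(0, w[j, k]) -
                    upper[j] * min(0, w[j, k])
  }
  R_j <- numeric(J)
  for (k in seq_len(K)) {
    s <- sum(z[, k])
    if (s == 0 && R_k[k] == 0) next
    R_j <- R_j + z[, k] / (s + epsilon * (if (s >= 0) 1 else -1)) * R_k[k]
  }
  R_j
}

# Full backward pass for one sample: zplus everywhere, zB into a bounded
# input layer.
oracle_lrp <- function(layers, x, target, input_bounds = NULL,
                       epsilon = 1e-9) {
  acts <- oracle_forward(layers, x)
  R <- acts[[length(acts)]] * target
  for (k in rev(seq_along(layers))) {
    bounded <- k == 1L && !is.null(input_bounds)
    R <- oracle_propagate(
      R, acts[[k]], layers[[k]]$w,
      rule = if (bounded) "zB" else "zplus", epsilon = epsilon,
      lower = if (bounded) input_bounds$lower else 0,
      upper = if (bounded) input_bounds$upper else 1)
  }
  R
}

# Random fixture network with nonnegative weights (ReLU hidden, identity
# output), dims like c(3, 2, 1).
random_positive_network <- function(dims, seed) {
  set.seed(seed)
  layers <- lapply(seq_len(length(dims) - 1L), function(k) list(
    w = matrix(runif(dims[k] * dims[k + 1L], 0.1, 1), dims[k], dims[k + 1L]),
    b = numeric(dims[k + 1L]),
    activation = if (k < length(dims) - 1L) "relu" else "identity"))
  network_spec(layers)
}

# Small toy fixture shared across tests (fast to generate).
tiny_toy <- function(seed = 7, n_frames_per_state = 60L, rotate = TRUE,
                     noise = 0.01) {
  cfg <- toy_config(n_atoms = 30L, n_states = 2L, n_important_per_state = 5L,
                    n_frames_per_state = n_frames_per_state,
                    noise_amplitude = noise, rotate = rotate, seed = seed)
  sys <- generate_system(cfg)
  traj <- generate_frames(sys)
  list(cfg = cfg, sys = sys, traj = traj,
       labels = label_set(traj$labels, cfg$n_states),
       psi = true_importance(sys))
}
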