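#' Dense feedforward network specification
#'
#' The object the relevance engine walks backward: an ordered list of dense
#' layers, each a list with weight matrix `w` (n_in x n_out), bias vector `b`
#' (length n_out) and an activation tag in `{"relu", "logistic", "identity",
#' "softmax"}`, plus optional per-input bounds (l_j, h_j) used by the z^B rule
#' at the input layer.
#'
#' @param layers list of layers as described above.
#' @param input_bounds `NULL`, or a list/data.frame with numeric `lower` and
#'   `upper` (recycled to the input width).
#' @return a `network_spec`.
#' @export
network_spec <- function(layers, input_bounds = NULL) {
  stopifnot(length(layers) >= 1L)
  for (k in seq_along(layers)) {
    l <- layers[[k]]
    if (!is.matrix(l$w) || length(l$b) != ncol(l$w))
      stop("layer ", k, ": bias length must equal ncol(w)", call. = FALSE)
    if (!l$activation %in% c("relu", "logistic", "identity", "softmax"))
      stop("unsupported activation: ", l$activation, call. = FALSE)
    if (k > 1L && nrow(l$w) != ncol(layers[[k - 1L]]$w))
      stop("layer ", k, ": input width does not match previous layer",
           call. = FALSE)
  }
  if (!is.null(input_bounds)) {
    n_in <- nrow(layers[[1L]]$w)
    lower <- rep_len(as.numeric(input_bounds$lower), n_in)
    upper <- rep_len(as.numeric(input_bounds$upper), n_in)
    if (any(lower > upper))
      stop("input_bounds must satisfy lower <= upper", call. = FALSE)
    input_bounds <- list(lower = lower, upper = upper)
  }
  structure(list(layers = layers, input_bounds = input_bounds),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  dims <- c(nrow(x$layers[[1L]]$w),
            vapply(x$layers, function(l) ncol(l$w), integer(1)))
  cat(sprintf("network_spec: %s (%s)%s\n",
              paste(dims, collapse = "-"),
              paste(vapply(x$layers, `[[`, "", "activation"), collapse = ", "),
              if (is.null(x$input_bounds)) "" else ", bounded input"))
  invisible(x)
}

apply_activation <- function(z, activation) {
  switch(activation,
    relu = pmax(z, 0),
    logistic = 1 / (1 + exp(-z)),
    identity = z,
    softmax = {
      z <- z - apply(z, 1, max)
      e <- exp(z)
      e / rowSums(e)
    },
    stop("unsupported activation: ", activation, call. = FALSE))
}

#' Forward pass through a network
#'
#' @param net a `network_spec`.
#' @param X n_samples x n_inputs matrix.
#' @return list of activation matrices, one per layer boundary; element 1 is
#'   `X` itself, the last element the network output.
#' @export
nn_forward <- function(net, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  acts <- vector("list", length(net$layers) + 1L)
  acts[[1L]] <- X
  for (k in seq_along(net$layers)) {
    l <- net$layers[[k]]
    z <- sweep(acts[[k]] %*% l$w, 2, l$b, "+")
    acts[[k + 1L]] <- apply_activation(z, l$activation)
  }
  acts
}

#' Initialize output-layer relevance
#'
#' Elementwise product R_i = T_i * T'_i of the target mask and the network
#' output: a one-hot class mask for classifiers, a mask of ones for
#' reconstruction networks where every output contributes.
#'
#' @param output network output T' (vector or n x k matrix).
#' @param target mask T of the same shape.
#' @return relevance of the same shape.
#' @export
relevance_init <- function(output, target) {
  if (length(output) != length(target) ||
      (is.matrix(output) && !identical(dim(output), dim(target))))
    stop("output and target shapes differ", call. = FALSE)
  output * target
}

#' Propagate relevance through one dense layer
#'
#' Redistributes upper-layer relevance R_k to the lower layer proportionally
#' to the contributions z_jk = rho(a_j, w_jk):
#' R_j = sum_k z_jk / (eps * sign(z_k) + sum_j' z_j'k) * R_k.
#' The `zplus` rule uses rho = a_j * max(0, w_jk) (unbounded ReLU layers); the
#' `zB` rule, for layers of bounded values such as a \[0,1\]-scaled input,
#' uses rho = a_j w_jk - l_j max(0, w_jk) - h_j min(0, w_jk). Biases receive
#' no relevance. The epsilon stabilizer (default 1e-9) is added to the
#' denominator with the denominator's sign.
#'
#' @param R_k relevance of the upper layer (vector or n x k matrix).
#' @param a_j activations of the lower layer (vector or n x j matrix).
#' @param w j x k weight matrix.
#' @param rule `"zplus"` or `"zB"`.
#' @param epsilon stabilizer added to the denominator.
#' @param lower,upper per-input bounds (zB rule only; recycled).
#' @return lower-layer relevance, same shape convention as `a_j`.
#' @export
propagate_layer <- function(R_k, a_j, w, rule = c("zplus", "zB"),
                            epsilon = 1e-9, lower = 0, upper = 1) {
  rule <- match.arg(rule)
  vec_in <- !is.matrix(a_j)
  if (vec_in) a_j <- matrix(a_j, nrow = 1)
  if (!is.matrix(R_k)) R_k <- matrix(R_k, nrow = nrow(a_j))
  stopifnot(nrow(w) == ncol(a_j), ncol(w) == ncol(R_k))

  if (rule == "zplus") {
    wp <- pmax(w, 0)
    denom <- a_j %*% wp                      # n x k: sum_j z_jk
    s <- stabilized_ratio(R_k, denom, epsilon)
    R_j <- (s %*% t(wp)) * a_j
  } else {
    lower <- rep_len(lower, ncol(a_j)); upper <- rep_len(upper, ncol(a_j))
    wp <- pmax(w, 0); wm <- pmin(w, 0)
    denom <- a_j %*% w -
      matrix(lower, nrow(a_j), ncol(a_j), byrow = TRUE) %*% wp -
      matrix(upper, nrow(a_j), ncol(a_j), byrow = TRUE) %*% wm
    s <- stabilized_ratio(R_k, denom, epsilon)
    R_j <- (s %*% t(w)) * a_j -
      sweep(s %*% t(wp), 2, lower, "*") -
      sweep(s %*% t(wm), 2, upper, "*")
  }
  if (vec_in) R_j <- drop(R_j)
  R_j
}

stabilized_ratio <- function(R_k, denom, epsilon) {
  if (epsilon == 0 && any(denom == 0 & R_k != 0))
    stop("zero denominator in relevance propagation with epsilon = 0",
         call. = FALSE)
  sgn <- ifelse(denom >= 0, 1, -1)
  out <- R_k / (denom + epsilon * sgn)
  out[R_k == 0 & denom == 0] <- 0
  out
}

#' Layer-wise relevance propagation through a network
#'
#' Runs the forward pass, seeds output relevance with
#' [relevance_init()] (targets times output), then propagates backward with
#' the z+ rule through hidden layers and the z^B rule into the input layer
#' when input bounds are set on the network.
#'
#' @param net a `network_spec`.
#' @param X n_samples x n_inputs matrix.
#' @param targets per-sample output mask: an n x n_outputs matrix (e.g.
#'   one-hot rows for a classifier, ones for a reconstruction network), a
#'   single mask vector recycled over samples, or `NULL` for all-ones.
#' @param epsilon denominator stabilizer, default 1e-9.
#' @return n_samples x n_inputs matrix of unnormalized per-sample relevance.
#' @export
lrp <- function(net, X, targets = NULL, epsilon = 1e-9) {
  stopifnot(inherits(net, "network_spec"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  acts <- nn_forward(net, X)
  out <- acts[[length(acts)]]
  if (is.null(targets)) targets <- matrix(1, nrow(out), ncol(out))
  if (!is.matrix(targets))
    targets <- matrix(targets, nrow(out), ncol(out), byrow = TRUE)
  R <- relevance_init(out, targets)
  for (k in rev(seq_along(net$layers))) {
    bounded_input <- k == 1L && !is.null(net$input_bounds)
    R <- propagate_layer(
      R, acts[[k]], net$layers[[k]]$w,
      rule = if (bounded_input) "zB" else "zplus",
      epsilon = epsilon,
      lower = if (bounded_input) net$input_bounds$lower else 0,
      upper = if (bounded_input) net$input_bounds$upper else 1)
    if (!is.matrix(R)) R <- matrix(R, nrow = nrow(X))
  }
  R
}

#' Average per-sample relevance into an importance vector
#'
#' Mean relevance over samples, normalized to an upper bound of 1 by dividing
#' by the maximum (or by the maximum absolute value when no entry is
#' positive, which can occur with mixed-sign masks). An all-zero mean is
#' returned as zeros with attribute `all_zero`.
#'
#' @param R n_samples x n_features relevance matrix.
#' @return numeric importance vector.
#' @export
average_relevance <- function(R) {
  if (!is.matrix(R)) R <- matrix(R, nrow = 1)
  if (nrow(R) < 1L) stop("need at least one sample", call. = FALSE)
  m <- colMeans(R)
  normalize_profile(m)
}

# Divide by max (or max |.| if max <= 0); flag all-zero vectors.
normalize_profile <- function(x) {
  mx <- max(x)
  if (mx <= 0) mx <- max(abs(x))
  if (mx == 0) {
    attr(x, "all_zero") <- TRUE
    return(x)
  }
  x / mx
}

#' Serialize a network to JSON
#' @param net a `network_spec`.
#' @param path output file.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    layers = lapply(net$layers, function(l)
      list(w = l$w, b = l$b, activation = l$activation)),
    input_bounds = net$input_bounds)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a network from JSON
#' @param path file written by [write_network_json()].
#' @return a `network_spec`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(if (is.data.frame(obj$layers)) nrow(obj$layers)
                           else length(obj$layers)), function(k) {
    l <- if (is.data.frame(obj$layers)) lapply(obj$layers, `[[`, k)
         else obj$layers[[k]]
    w <- l$w
    if (is.list(w)) w <- do.call(rbind, w)
    if (!is.matrix(w)) w <- matrix(w, nrow = 1)
    list(w = w, b = as.numeric(l$b), activation = l$activation)
  })
  bounds <- obj$input_bounds
  if (!is.null(bounds)) bounds <- list(lower = bounds$lower,
                                       upper = bounds$upper)
  network_spec(layers, bounds)
}
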