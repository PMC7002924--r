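#' Importance profile container
#'
#' Common result type of all six extractors: a per-feature importance vector
#' normalized to an upper bound of 1, optionally per-state rows (each
#' individually normalized), per-frame relevance (LRP-based methods only), a
#' per-atom aggregation, and provenance (method name, hyperparameters,
#' iteration count, per-feature standard deviation, cross-validated model
#' score for classifiers).
#'
#' @param per_feature numeric vector in \[0, 1\].
#' @param method method name.
#' @param hyperparameters named list.
#' @param per_state optional n_states x n_features matrix.
#' @param per_frame optional n_samples x n_features matrix.
#' @param per_atom optional per-atom aggregation.
#' @param std optional per-feature standard deviation across iterations.
#' @param model_score optional classifier accuracy.
#' @param n_iterations number of averaged iterations.
#' @return an `importance_profile`.
#' @export
importance_profile <- function(per_feature, method, hyperparameters = list(),
                               per_state = NULL, per_frame = NULL,
                               per_atom = NULL, std = NULL,
                               model_score = NULL, n_iterations = 1L) {
  stopifnot(all(is.finite(per_feature)))
  structure(list(per_feature = per_feature, per_state = per_state,
                 per_frame = per_frame, per_atom = per_atom,
                 method = method, hyperparameters = hyperparameters,
                 std = std, model_score = model_score,
                 n_iterations = as.integer(n_iterations)),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("importance_profile [%s]: %d features%s%s%s\n",
              x$method, length(x$per_feature),
              if (!is.null(x$per_state))
                sprintf(", %d states", nrow(x$per_state)) else "",
              if (!is.null(x$per_frame))
                sprintf(", %d frames", nrow(x$per_frame)) else "",
              if (!is.null(x$model_score))
                sprintf(", model score %.3f", x$model_score) else ""))
  top <- order(x$per_feature, decreasing = TRUE)[seq_len(min(5, length(x$per_feature)))]
  cat("  top features:", paste(sprintf("#%d=%.3f", top - 1L,
                                       x$per_feature[top]), collapse = " "),
      "\n")
  invisible(x)
}

scaled_values <- function(fm, require_unit = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  if (require_unit && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("features must be min-max scaled to [0, 1]; call minmax_scale()",
         call. = FALSE)
  v
}

# ---------------------------------------------------------------- PCA ------

#' PCA loading importance
#'
#' Eigendecomposition of the feature covariance; the importance of feature i
#' is R_i = sum_j |lambda_j T_ij| over the leading principal components, with
#' eigenvalues normalized to sum 1. The number of components is chosen by one
#' of three criteria: a fixed count, the smallest leading set whose summed
#' eigenvalue fraction reaches `theta` (cumulative variance), or the eigengap
#' rule that stops before the first component whose predecessor eigenvalue
#' exceeds it by a factor `ratio` (default 10).
#'
#' @param fm a scaled `feature_matrix`.
#' @param criterion `"eigengap"`, `"cumulative_variance"` or `"fixed"`.
#' @param k component count for `"fixed"`.
#' @param theta variance fraction threshold for `"cumulative_variance"`.
#' @param ratio eigengap ratio.
#' @return an `importance_profile` (ensemble only; PCA is unsupervised).
#' @export
pca_importance <- function(fm, criterion = c("eigengap",
                                             "cumulative_variance", "fixed"),
                           k = 1L, theta = 0.75, ratio = 10) {
  criterion <- match.arg(criterion)
  X <- scaled_values(fm)
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2
  lambda <- lambda / sum(lambda)
  n_comp <- length(lambda)
  m <- switch(criterion,
    fixed = min(as.integer(k), n_comp),
    cumulative_variance = which(cumsum(lambda) >= theta)[1L],
    eigengap = {
      gaps <- which(lambda[-n_comp] / pmax(lambda[-1L], .Machine$double.eps)
                    >= ratio)
      if (length(gaps) == 0L) n_comp else gaps[1L]
    })
  if (is.na(m)) m <- n_comp
  R <- abs(pc$rotation[, seq_len(m), drop = FALSE]) %*% lambda[seq_len(m)]
  importance_profile(
    normalize_profile(as.numeric(R)), "PCA",
    hyperparameters = list(criterion = criterion, k = k, theta = theta,
                           ratio = ratio, n_components = m))
}

# ---------------------------------------------------------------- KL -------

#' Symmetric Kullback-Leibler divergence of two discrete distributions
#'
#' (1/2) sum P log(P/Q) + (1/2) sum Q log(Q/P), natural log. Zero entries get
#' a 1e-9 pseudocount before renormalization.
#'
#' @param p,q nonnegative vectors over shared bins.
#' @return symmetric KL divergence in nats.
#' @export
symmetric_kl <- function(p, q) {
  stopifnot(length(p) == length(q))
  p[p == 0] <- 1e-9; q[q == 0] <- 1e-9
  p <- p / sum(p); q <- q / sum(q)
  0.5 * sum(p * log(p / q)) + 0.5 * sum(q * log(q / p))
}

#' Per-feature state separation by symmetric KL divergence
#'
#' For every feature and every state, histograms the in-state samples against
#' all remaining samples on shared bins of width `bin_width_fraction` of the
#' pooled feature range, and scores the feature by the symmetric KL
#' divergence of the two histograms. Per-state rows are normalized to max 1;
#' the ensemble profile is the renormalized mean of the per-state rows.
#'
#' @param fm a `feature_matrix`.
#' @param labels a `label_set` or integer state vector.
#' @param bin_width_fraction bin width as a fraction of the feature range
#'   (default 0.01, i.e. about 100 bins).
#' @return an `importance_profile` with per-state rows.
#' @export
kl_importance <- function(fm, labels, bin_width_fraction = 0.01) {
  X <- scaled_values(fm)
  if (!inherits(labels, "label_set")) labels <- label_set(labels)
  S <- labels$n_states
  counts <- tabulate(labels$state_index + 1L, S)
  if (any(counts == 0L)) stop("empty state in labels", call. = FALSE)
  if (S < 2L) stop("KL importance needs at least 2 states", call. = FALSE)
  n_bins <- max(1L, as.integer(ceiling(1 / bin_width_fraction)))
  P <- matrix(0, S, ncol(X))
  in_state <- lapply(seq_len(S) - 1L, function(s) labels$state_index == s)
  for (f in seq_len(ncol(X))) {
    x <- X[, f]
    lo <- min(x); hi <- max(x)
    if (hi == lo) next  # constant feature separates nothing
    bin <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
    total <- tabulate(bin, n_bins)
    for (s in seq_len(S)) {
      cs <- tabulate(bin[in_state[[s]]], n_bins)
      P[s, f] <- symmetric_kl(cs, total - cs)
    }
  }
  per_state <- t(apply(P, 1, normalize_profile))
  importance_profile(
    normalize_profile(colMeans(per_state)), "KL",
    hyperparameters = list(bin_width_fraction = bin_width_fraction),
    per_state = per_state)
}

# ---------------------------------------------------------------- RF -------

#' Gini impurity of a class-count vector
#' @param counts per-class sample counts at a node.
#' @return 1 - sum p_j^2.
#' @export
gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  1 - sum(p^2)
}

#' Random-forest mean-decrease-impurity importance
#'
#' Fits a random forest (Gini criterion, bootstrap, per-node random feature
#' subsets) and scores each feature by the mean decrease impurity: the
#' fraction of samples reaching a node times the impurity decrease of its
#' split, summed over the feature's nodes and averaged over trees. In
#' `one_vs_rest` mode one binary forest per state yields state-specific rows;
#' `multiclass` yields the ensemble profile only.
#'
#' @param fm a `feature_matrix`.
#' @param labels a `label_set` or integer state vector.
#' @param mode `"multiclass"` or `"one_vs_rest"`.
#' @param n_estimators number of trees.
#' @param max_depth maximal tree depth (`NULL` = unlimited).
#' @param min_samples_leaf minimum samples per leaf.
#' @param mtry features tried per node (`NULL` = floor(sqrt(p))).
#' @param seed RNG seed.
#' @return an `importance_profile`.
#' @export
rf_importance <- function(fm, labels, mode = c("multiclass", "one_vs_rest"),
                          n_estimators = 100L, max_depth = NULL,
                          min_samples_leaf = 1L, mtry = NULL, seed = 1L) {
  mode <- match.arg(mode)
  X <- scaled_values(fm)
  if (!inherits(labels, "label_set")) labels <- label_set(labels)
  if (labels$n_states < 2L)
    stop("random forest needs at least 2 states", call. = FALSE)
  md <- if (is.null(max_depth)) 0L else as.integer(max_depth)
  mt <- if (is.null(mtry)) 0L else as.integer(mtry)
  hp <- list(mode = mode, n_estimators = n_estimators, max_depth = max_depth,
             min_samples_leaf = min_samples_leaf, mtry = mtry, seed = seed)

  if (mode == "multiclass") {
    fit <- .forest_fit(X, labels$state_index, labels$n_states,
                       as.integer(n_estimators), mt, md,
                       as.integer(min_samples_leaf), TRUE, as.integer(seed))
    prof <- importance_profile(normalize_profile(fit$importance), "RF", hp)
    attr(prof, "predict") <- function(Xnew) .forest_predict(fit, Xnew)
    prof
  } else {
    S <- labels$n_states
    per_state <- matrix(0, S, ncol(X))
    fits <- vector("list", S)
    for (s in seq_len(S)) {
      y <- as.integer(labels$state_index == s - 1L)
      fits[[s]] <- .forest_fit(X, y, 2L, as.integer(n_estimators), mt, md,
                               as.integer(min_samples_leaf), TRUE,
                               as.integer(seed) + s)
      per_state[s, ] <- normalize_profile(fits[[s]]$importance)
    }
    prof <- importance_profile(normalize_profile(colMeans(per_state)), "RF",
                               hp, per_state = per_state)
    # one-vs-rest prediction: state whose binary forest votes "in-state";
    # ties broken by first state (used only for CV sanity scoring)
    attr(prof, "predict") <- function(Xnew) {
      votes <- vapply(fits, function(f) .forest_predict(f, Xnew),
                      integer(nrow(Xnew)))
      if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
      max.col(votes, ties.method = "first") - 1L
    }
    prof
  }
}

# ---------------------------------------------------------------- MLP ------

#' MLP classifier importance via layer-wise relevance propagation
#'
#' Trains a feedforward ReLU classifier with the Adam solver on \[0,1\]-scaled
#' features, then runs relevance propagation from the softmax output (masked
#' by the true class of each frame) back to the input layer (z+ rule through
#' hidden layers, z^B at the bounded input). Returns per-frame relevance --
#' the capability unique to the attribution-based methods -- along with
#' per-state and ensemble profiles.
#'
#' @param fm a scaled `feature_matrix` (values in \[0,1\]).
#' @param labels a `label_set` or integer state vector.
#' @param hidden_layers hidden layer sizes.
#' @param alpha L2 penalty.
#' @param learning_rate Adam step size.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param seed RNG seed.
#' @param tol plateau tolerance of the training objective.
#' @param n_iter_no_change epochs without improvement before training stops.
#' @return an `importance_profile` with per-frame and per-state relevance and
#'   the training-set accuracy as `model_score`.
#' @export
mlp_lrp_importance <- function(fm, labels, hidden_layers = c(100L),
                               alpha = 1e-4, learning_rate = 1e-3,
                               epochs = 200L, batch_size = 32L, seed = 1L,
                               tol = 1e-5, n_iter_no_change = 10L) {
  X <- scaled_values(fm, require_unit = TRUE)
  if (!inherits(labels, "label_set")) labels <- label_set(labels)
  fit <- mlp_train(X, labels, hidden_layers, alpha, learning_rate, epochs,
                   batch_size, seed, tol, n_iter_no_change)
  if (!fit$converged)
    warning(sprintf("MLP did not plateau within %d epochs (final loss %.4g)",
                    epochs, fit$loss[length(fit$loss)]), call. = FALSE)
  R <- lrp(fit$net, X, targets = labels$one_hot * 1)
  per_state <- t(vapply(seq_len(labels$n_states) - 1L, function(s)
    normalize_profile(colMeans(R[labels$state_index == s, , drop = FALSE])),
    numeric(ncol(X))))
  acc <- mean(mlp_predict(fit$net, X) == labels$state_index)
  prof <- importance_profile(
    average_relevance(R), "MLP",
    hyperparameters = list(hidden_layers = hidden_layers, alpha = alpha,
                           learning_rate = learning_rate, epochs = epochs,
                           batch_size = batch_size, seed = seed),
    per_state = per_state, per_frame = R, model_score = acc)
  net <- fit$net
  attr(prof, "predict") <- function(Xnew) mlp_predict(net, Xnew)
  prof
}

# ---------------------------------------------------------------- AE -------

#' Autoencoder importance via layer-wise relevance propagation
#'
#' Trains a symmetric encoder/decoder regressor to reconstruct its input
#' (identity output, mean squared error, Adam), then propagates relevance
#' from the reconstructed output -- all outputs masked with ones, since no
#' class seeds the decomposition -- back to the input.
#'
#' @param fm a scaled `feature_matrix` (values in \[0,1\]).
#' @param hidden_layers encoder stack down to the bottleneck; the decoder
#'   mirrors it (e.g. `c(120, 100)` builds hidden sizes 120-100-120).
#' @param epochs,learning_rate,batch_size,alpha,seed training controls.
#' @return an `importance_profile` with per-frame relevance.
#' @export
ae_lrp_importance <- function(fm, hidden_layers = c(50L), seed = 1L,
                              epochs = 200L, learning_rate = 1e-3,
                              batch_size = 32L, alpha = 1e-4,
                              tol = 1e-5, n_iter_no_change = 10L) {
  X <- scaled_values(fm, require_unit = TRUE)
  fit <- ae_train(X, hidden_layers, alpha, learning_rate, epochs, batch_size,
                  seed, tol, n_iter_no_change)
  final_loss <- fit$loss[length(fit$loss)]
  if (!is.finite(final_loss))
    stop("autoencoder reconstruction loss is not finite", call. = FALSE)
  R <- lrp(fit$net, X, targets = NULL)  # ones mask over reconstructed outputs
  importance_profile(
    average_relevance(R), "AE",
    hyperparameters = list(hidden_layers = hidden_layers, alpha = alpha,
                           learning_rate = learning_rate, epochs = epochs,
                           batch_size = batch_size, seed = seed),
    per_frame = R, model_score = NULL)
}

# ---------------------------------------------------------------- RBM ------

#' Bernoulli RBM importance via layer-wise relevance propagation
#'
#' Fits a Bernoulli restricted Boltzmann machine by stochastic maximum
#' likelihood (persistent contrastive divergence) on features scaled to
#' \[0,1\] -- the model reads inputs as activation probabilities -- then runs
#' relevance propagation from the hidden-layer activations to the input with
#' the z^B rule.
#'
#' @param fm a scaled `feature_matrix` with values in \[0,1\].
#' @param n_hidden hidden unit count.
#' @param learning_rate SML learning rate; a value of 1 is known to destroy
#'   performance and triggers a warning.
#' @param n_iter training sweeps.
#' @param batch_size minibatch size.
#' @param seed RNG seed.
#' @return an `importance_profile` with per-frame relevance.
#' @export
rbm_lrp_importance <- function(fm, n_hidden = 64L, learning_rate = 0.05,
                               n_iter = 20L, batch_size = 32L, seed = 1L) {
  X <- fm$values
  if (min(X) < -1e-12 || max(X) > 1 + 1e-12)
    stop("RBM inputs must lie in [0, 1]; min-max scale the features first",
         call. = FALSE)
  if (learning_rate >= 1)
    warning("RBM learning rate >= 1 is known to degrade importance extraction",
            call. = FALSE)
  fit <- rbm_train(X, n_hidden, learning_rate, n_iter, batch_size, seed)
  R <- lrp(fit$net, X, targets = NULL)  # seeded with hidden activations
  importance_profile(
    average_relevance(R), "RBM",
    hyperparameters = list(n_hidden = n_hidden,
                           learning_rate = learning_rate, n_iter = n_iter,
                           batch_size = batch_size, seed = seed),
    per_frame = R)
}

# -------------------------------------------------------- repetition -------

#' Declarative extractor specification
#'
#' Names one of the six methods plus its hyperparameters, for use with
#' [run_repeated()], [run_benchmark()] and [hyperparameter_scan()].
#'
#' @param method one of `"pca"`, `"kl"`, `"rf"`, `"mlp"`, `"ae"`, `"rbm"`.
#' @param ... hyperparameters forwarded to the extractor.
#' @return an `extractor_spec`.
#' @export
extractor_spec <- function(method = c("pca", "kl", "rf", "mlp", "ae", "rbm"),
                           ...) {
  method <- match.arg(method)
  structure(list(method = method, params = list(...)),
            class = "extractor_spec")
}

extractor_is_supervised <- function(spec)
  spec$method %in% c("kl", "rf", "mlp")

#' Run one extractor from its specification
#'
#' @param spec an [extractor_spec()].
#' @param fm a `feature_matrix`.
#' @param labels a `label_set` (ignored by unsupervised methods).
#' @param seed seed for stochastic extractors (overrides the spec's).
#' @return an `importance_profile`.
#' @export
run_extractor <- function(spec, fm, labels = NULL, seed = NULL) {
  stopifnot(inherits(spec, "extractor_spec"))
  p <- spec$params
  if (!is.null(seed) && spec$method %in% c("rf", "mlp", "ae", "rbm"))
    p$seed <- as.integer(seed)
  if (extractor_is_supervised(spec) && is.null(labels))
    stop(spec$method, " is supervised and needs per-frame labels",
         call. = FALSE)
  switch(spec$method,
    pca = do.call(pca_importance, c(list(fm), p)),
    kl = do.call(kl_importance, c(list(fm, labels), p)),
    rf = do.call(rf_importance, c(list(fm, labels), p)),
    mlp = do.call(mlp_lrp_importance, c(list(fm, labels), p)),
    ae = do.call(ae_lrp_importance, c(list(fm), p)),
    rbm = do.call(rbm_lrp_importance, c(list(fm), p)))
}

#' Iterated, cross-validated importance extraction
#'
#' Repeats an extractor over `n_iterations` independent iterations. In each
#' iteration the samples are shuffled (when `reshuffle` is set) and split
#' into `n_folds` folds; the extractor is fitted on each training partition
#' and -- for classifiers -- scored on the held-out fold. Each iteration's
#' profile is the mean over its folds; the final profile is the renormalized
#' mean over iterations, with the per-feature standard deviation across
#' iterations and the mean cross-validated accuracy recorded.
#'
#' @param spec an [extractor_spec()].
#' @param fm a `feature_matrix`.
#' @param labels a `label_set` (required for supervised methods).
#' @param n_iterations independent iterations to average (>= 1).
#' @param n_folds cross-validation folds per iteration.
#' @param seed base seed; iteration i uses `seed + i`.
#' @param reshuffle reshuffle the fold assignment every iteration; with
#'   `FALSE` the folds are fixed, making deterministic extractors (KL, PCA)
#'   reproduce exactly across iterations.
#' @return an `importance_profile` with `std`, `model_score` and
#'   `n_iterations` filled in.
#' @export
run_repeated <- function(spec, fm, labels = NULL, n_iterations = 5L,
                         n_folds = 3L, seed = 1L, reshuffle = TRUE) {
  stopifnot(n_iterations >= 1L, n_folds >= 1L)
  n <- nrow(fm$values)
  if (!is.null(labels) && !inherits(labels, "label_set"))
    labels <- label_set(labels)
  iteration_profiles <- list(); scores <- numeric(0)
  per_state_acc <- NULL
  n_fits <- 0L
  for (it in seq_len(n_iterations)) {
    it_seed <- as.integer(seed) + if (reshuffle) it else 1L
    set.seed(it_seed)
    fold <- sample(rep_len(seq_len(n_folds), n))
    fold_profiles <- list()
    for (f in seq_len(n_folds)) {
      train <- if (n_folds == 1L) rep(TRUE, n) else fold != f
      fm_tr <- feature_matrix(fm$values[train, , drop = FALSE],
                              fm$descriptors, fm$kind, fm$scaling)
      lab_tr <- if (is.null(labels)) NULL
                else label_set(labels$state_index[train], labels$n_states)
      prof <- run_extractor(spec, fm_tr, lab_tr, seed = it_seed * 131L + f)
      fold_profiles[[f]] <- prof$per_feature
      n_fits <- n_fits + 1L
      if (!is.null(prof$per_state)) {
        per_state_acc <- if (is.null(per_state_acc)) prof$per_state
                         else per_state_acc + prof$per_state
      }
      pred_fn <- attr(prof, "predict")
      if (!is.null(pred_fn) && !is.null(labels) && any(!train)) {
        pred <- pred_fn(fm$values[!train, , drop = FALSE])
        scores <- c(scores, mean(pred == labels$state_index[!train]))
      }
    }
    # the iteration's residue profile is the mean over its folds; dispersion
    # is tracked across iterations
    iteration_profiles[[it]] <- colMeans(do.call(rbind, fold_profiles))
  }
  mat <- do.call(rbind, iteration_profiles)
  importance_profile(
    normalize_profile(colMeans(mat)), spec$method,
    hyperparameters = c(spec$params,
                        list(n_iterations = n_iterations, n_folds = n_folds)),
    per_state = if (!is.null(per_state_acc))
      t(apply(per_state_acc / n_fits, 1, normalize_profile)),
    std = if (nrow(mat) > 1L) apply(mat, 2, stats::sd)
          else numeric(ncol(mat)),
    model_score = if (length(scores)) mean(scores),
    n_iterations = n_iterations)
}
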