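raw_fm <- function(values) {
  feature_matrix(
    values, data.frame(atom_i = seq_len(ncol(values)) - 1L,
                       atom_j = seq_len(ncol(values)) - 1L + ncol(values)),
    "distance")
}

scaled_fm <- function(values) minmax_scale(raw_fm(values))

two_cluster_data <- function(n = 60, p = 4, seed = 1, gap = 2) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(runif(n * p, 0, 1e-3), n, p)
  X[, 1] <- X[, 1] + y * gap
  list(fm = raw_fm(X), labels = label_set(y))
}

test_that("PCA component selection follows the three stated criteria", {
  # feature 1 is a +/-1-scale two-cluster split, the rest 1e-3 noise: the
  # leading eigenvalue dominates by far more than the eigengap ratio 10
  d <- two_cluster_data(n = 80, p = 5, seed = 3)
  prof <- pca_importance(d$fm, criterion = "eigengap")
  expect_equal(prof$hyperparameters$n_components, 1)
  expect_equal(which.max(prof$per_feature), 1L)
  expect_equal(max(prof$per_feature), 1)
  fixed <- pca_importance(d$fm, criterion = "fixed", k = 3)
  expect_equal(fixed$hyperparameters$n_components, 3)
  cum <- pca_importance(d$fm, criterion = "cumulative_variance", theta = 0.9)
  expect_gte(sum(prcomp(d$fm$values)$sdev[
    seq_len(cum$hyperparameters$n_components)]^2) /
      sum(prcomp(d$fm$values)$sdev^2), 0.9)
  expect_error(pca_importance(scaled_fm(matrix(1, 1, 2))), "2 samples")
})

test_that("duplicated feature columns receive identical PCA and KL importance", {
  set.seed(4)
  X <- matrix(runif(200), 50, 4)
  X[, 4] <- X[, 1]
  fm <- scaled_fm(X)
  lab <- label_set(rep(0:1, 25))
  p_pca <- pca_importance(fm, "fixed", k = 2)
  expect_equal(p_pca$per_feature[1], p_pca$per_feature[4], tolerance = 1e-9)
  p_kl <- kl_importance(fm, lab)
  expect_equal(p_kl$per_feature[1], p_kl$per_feature[4], tolerance = 1e-12)
})

test_that("symmetric KL divergence matches its closed form and finds separating features", {
  # 0.5*(0.5*log(5/9) + 0.5*log(5)) + 0.5*(0.9*log(1.8) + 0.1*log(0.2))
  expect_equal(symmetric_kl(c(0.5, 0.5), c(0.9, 0.1)), 0.43944,
               tolerance = 1e-4)
  expect_equal(symmetric_kl(c(0.3, 0.7), c(0.3, 0.7)), 0, tolerance = 1e-10)
  # two states with non-overlapping uniform supports in feature 1
  set.seed(5)
  n <- 100
  X <- matrix(runif(n * 3), n, 3)
  y <- rep(0:1, each = n / 2)
  X[y == 0, 1] <- runif(n / 2, 0, 0.4)
  X[y == 1, 1] <- runif(n / 2, 0.6, 1)
  prof <- kl_importance(scaled_fm(X), label_set(y))
  expect_equal(which.max(prof$per_feature), 1L)
  expect_equal(max(prof$per_feature), 1)
  expect_error(kl_importance(scaled_fm(X), label_set(rep(0L, n), 2)),
               "empty state")
})

test_that("KL separation grows monotonically with state separation", {
  # two Gaussians at fixed variance, binned on shared edges as the extractor
  # does; the symmetric divergence must grow with the mean separation
  seps <- c(0, 0.5, 1, 2, 4)
  scores <- vapply(seps, function(s) {
    set.seed(17)
    n <- 4000
    a <- rnorm(n, 0, 1); b <- rnorm(n, s, 1)
    edges <- seq(min(a, b), max(a, b), length.out = 51)
    ca <- table(cut(a, edges, include.lowest = TRUE))
    cb <- table(cut(b, edges, include.lowest = TRUE))
    symmetric_kl(as.numeric(ca), as.numeric(cb))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("Gini impurity and forest importance behave as defined", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(1, 1, 1, 1)), 0.75)
  # a feature equal to the label dominates
  d <- two_cluster_data(n = 80, p = 5, seed = 6)
  prof <- rf_importance(d$fm, d$labels, n_estimators = 50, seed = 2)
  expect_equal(which.max(prof$per_feature), 1L)
  expect_equal(max(prof$per_feature), 1)
  expect_gt(prof$per_feature[1] / (max(prof$per_feature[-1]) + 1e-9), 5)
  expect_error(rf_importance(d$fm, label_set(rep(0L, 80), 1)), "2 states")
})

test_that("one-vs-rest forests rank each state's displaced atoms on top", {
  t <- tiny_toy(seed = 12, n_frames_per_state = 80L)
  fm <- minmax_scale(inverse_distance_features(t$traj, "full"))
  prof <- rf_importance(fm, t$labels, mode = "one_vs_rest",
                        n_estimators = 100, seed = 3)
  expect_equal(nrow(prof$per_state), 2)
  for (s in 1:2) {
    phi <- aggregate_importance_per_atom(prof$per_state[s, ], fm$descriptors)
    top <- order(phi, decreasing = TRUE)[1:8]
    expect_gte(sum(t$sys$important_sets[[s]] %in% top), 4)
  }
})

test_that("MLP attribution separates informative from noise features across seeds", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    y <- rep(0:1, each = 30)
    X <- cbind(y * 0.9 + 0.05 + runif(60, 0, 0.02), runif(60))
    prof <- suppressWarnings(mlp_lrp_importance(
      raw_fm(X), label_set(y), hidden_layers = 8, epochs = 500,
      alpha = 3e-2, seed = s))
    prof$per_feature
  }, numeric(2))
  expect_true(all(hits[1, ] == 1))
  expect_true(all(hits[2, ] < 0.2))
})

test_that("MLP returns per-frame relevance with one row per sample", {
  set.seed(2)
  y <- rep(0:1, each = 20)
  X <- cbind(y * 0.9 + 0.05, matrix(runif(80), 40))
  prof <- suppressWarnings(mlp_lrp_importance(
    raw_fm(X), label_set(y), hidden_layers = 8, epochs = 60, seed = 1))
  expect_equal(dim(prof$per_frame), c(40, 3))
  expect_equal(nrow(prof$per_state), 2)
  expect_equal(max(prof$per_feature), 1)
})

test_that("label shuffling drives cross-validated accuracy to chance", {
  t <- tiny_toy(seed = 30, n_frames_per_state = 60L)
  fm <- minmax_scale(inverse_distance_features(t$traj, "reduced"))
  set.seed(99)
  shuffled <- label_set(sample(t$labels$state_index), t$labels$n_states)
  prof <- run_repeated(extractor_spec("rf", n_estimators = 50), fm, shuffled,
                       n_iterations = 2, n_folds = 3, seed = 4)
  expect_lt(abs(prof$model_score - 0.5), 0.1)
  # and the true labels are learnable
  prof_true <- run_repeated(extractor_spec("rf", n_estimators = 50), fm,
                            t$labels, n_iterations = 1, n_folds = 3, seed = 4)
  expect_gt(prof_true$model_score, 0.9)
})

test_that("autoencoder attribution highlights the only varying feature", {
  set.seed(8)
  X <- cbind(runif(80), matrix(0.3, 80, 3))
  fm <- scaled_fm(X)
  prof <- suppressMessages(
    ae_lrp_importance(fm, hidden_layers = 4, epochs = 300, seed = 2))
  expect_equal(which.max(prof$per_feature), 1L)
  expect_equal(ncol(prof$per_frame), 4)
  prof2 <- suppressMessages(
    ae_lrp_importance(fm, hidden_layers = 4, epochs = 300, seed = 2))
  expect_identical(prof$per_feature, prof2$per_feature)  # determinism
})

rbm_cluster_data <- function(seed, p = 20) {
  set.seed(seed)
  y <- rep(0:1, each = 50)
  X <- cbind(0.02 + 0.96 * y + runif(100, 0, 0.01),
             matrix(0.5 + runif(100 * (p - 1), -0.02, 0.02), 100))
  list(fm = raw_fm(X), labels = label_set(y))
}

test_that("RBM enforces its input domain, warns at learning rate 1, and ranks the split feature", {
  d <- rbm_cluster_data(3)
  bad <- d$fm; bad$values[1, 1] <- 1.5
  expect_error(rbm_lrp_importance(bad), "\\[0, 1\\]")
  expect_warning(
    rbm_lrp_importance(d$fm, n_hidden = 4, learning_rate = 1, n_iter = 2,
                       seed = 1),
    "learning rate")
  ranks <- vapply(1:10, function(s) {
    d <- rbm_cluster_data(s)
    prof <- rbm_lrp_importance(d$fm, n_hidden = 4, learning_rate = 0.1,
                               n_iter = 200, batch_size = 10, seed = s)
    rank(-prof$per_feature)[1]
  }, numeric(1))
  expect_true(all(ranks <= 0.1 * 20))  # top 10% of 20 features
})

test_that("iterated extraction averages profiles and tracks dispersion", {
  t <- tiny_toy(seed = 21, n_frames_per_state = 50L)
  fm <- minmax_scale(inverse_distance_features(t$traj, "reduced"))
  # n_iterations = 1, n_folds = 1 reduces to a single fit
  single <- run_repeated(extractor_spec("kl"), fm, t$labels,
                         n_iterations = 1, n_folds = 1, seed = 2)
  direct <- kl_importance(fm, t$labels)
  expect_equal(single$per_feature, as.numeric(direct$per_feature),
               tolerance = 1e-12)
  expect_equal(single$std, numeric(ncol(fm$values)))
  # deterministic extractor on fixed folds: zero dispersion
  fixed <- run_repeated(extractor_spec("kl"), fm, t$labels,
                        n_iterations = 3, n_folds = 2, seed = 2,
                        reshuffle = FALSE)
  expect_equal(max(fixed$std), 0, tolerance = 1e-12)
  # stochastic extractor: two independent 5-iteration runs agree feature by
  # feature within their combined dispersion and correlate strongly
  it <- run_repeated(extractor_spec("rf", n_estimators = 50), fm, t$labels,
                     n_iterations = 5, n_folds = 3, seed = 2)
  it2 <- run_repeated(extractor_spec("rf", n_estimators = 50), fm, t$labels,
                      n_iterations = 5, n_folds = 3, seed = 900)
  tol <- 2 * (it$std + it2$std) + 0.1
  expect_true(all(abs(it$per_feature - it2$per_feature) <= tol))
  expect_gt(stats::cor(it$per_feature, it2$per_feature), 0.9)
  expect_equal(it$n_iterations, 5L)
})

test_that("feature permutation permutes every method's profile identically", {
  t <- tiny_toy(seed = 14, n_frames_per_state = 40L, rotate = FALSE)
  fm <- minmax_scale(inverse_distance_features(t$traj, "reduced"))
  set.seed(31)
  perm <- sample.int(ncol(fm$values))
  fm_p <- feature_matrix(fm$values[, perm], fm$descriptors[perm, ],
                         fm$kind, fm$scaling[perm, ])
  for (m in c("pca", "kl")) {
    p1 <- run_extractor(extractor_spec(m), fm, t$labels)
    p2 <- run_extractor(extractor_spec(m), fm_p, t$labels)
    expect_equal(p2$per_feature, p1$per_feature[perm], tolerance = 1e-8)
  }
})

test_that("supervised extractors refuse unlabeled input", {
  d <- two_cluster_data(n = 20, p = 2, seed = 1)
  expect_error(run_extractor(extractor_spec("rf"), d$fm, NULL), "supervised")
  expect_error(run_extractor(extractor_spec("kl"), d$fm, NULL), "supervised")
})
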