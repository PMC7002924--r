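#' Paired measured/true importance vectors
#'
#' Validates and pairs a measured per-atom importance phi with the ground
#' truth psi of a toy system. Both accuracy scores operate on l2-normalized
#' copies so they are bounded by 1.
#'
#' @param phi measured importance, nonnegative.
#' @param psi true importance, nonnegative with at least one nonzero entry.
#' @return a `score_vectors` object.
#' @export
score_vectors <- function(phi, psi) {
  if (length(phi) != length(psi))
    stop("phi and psi must have equal length", call. = FALSE)
  if (length(phi) == 0L) stop("zero-length importance vectors", call. = FALSE)
  if (any(phi < 0) || any(psi < 0))
    stop("importance vectors must be nonnegative", call. = FALSE)
  if (all(psi == 0)) stop("psi must have a nonzero entry", call. = FALSE)
  structure(list(phi = as.numeric(phi), psi = as.numeric(psi)),
            class = "score_vectors")
}

l2_normalize <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) x else x / n
}

as_score_vectors <- function(phi, psi) {
  if (inherits(phi, "score_vectors")) phi else score_vectors(phi, psi)
}

#' Accuracy at finding all important atoms
#'
#' 1 - |psi - phi|_2 / (|psi|_2 + |phi|_2) on the l2-normalized copies: a
#' mean-squared-error-style score that is 1 when the measured profile matches
#' the ground truth exactly, tolerates moderate noise, and penalizes missed
#' important atoms. An all-zero phi scores 0.
#'
#' @param phi measured importance (or a [score_vectors()] object).
#' @param psi true importance (ignored when `phi` is a `score_vectors`).
#' @return score in \[0, 1\].
#' @export
find_all_accuracy <- function(phi, psi = NULL) {
  sv <- as_score_vectors(phi, psi)
  ph <- l2_normalize(sv$phi)
  ps <- l2_normalize(sv$psi)
  1 - sqrt(sum((ps - ph)^2)) / (sqrt(sum(ps^2)) + sqrt(sum(ph^2)))
}

#' Accuracy at ignoring irrelevant atoms
#'
#' phi . psi_hat / |phi|_2 with psi_hat unit-normalized: 1 iff phi is
#' proportional to psi restricted to its support, high when phi puts mass
#' only on truly important atoms (not necessarily all of them), 0 when phi
#' has no mass on important atoms. Invariant to positive scaling of phi. An
#' all-zero phi returns 0 with attribute `all_zero`.
#'
#' @inheritParams find_all_accuracy
#' @return score in \[0, 1\].
#' @export
ignore_irrelevant_accuracy <- function(phi, psi = NULL) {
  sv <- as_score_vectors(phi, psi)
  nrm <- sqrt(sum(sv$phi^2))
  if (nrm == 0) {
    out <- 0
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  sum(sv$phi * l2_normalize(sv$psi)) / nrm
}

#' Random-guessing baseline profile
#'
#' I.i.d. uniform \[0,1\] importance, normalized to max 1 like any extractor
#' profile.
#'
#' @param n_atoms number of atoms.
#' @param seed RNG seed.
#' @return numeric importance vector.
#' @export
random_baseline <- function(n_atoms, seed = 1L) {
  stopifnot(n_atoms >= 1L)
  set.seed(seed)
  normalize_profile(stats::runif(n_atoms))
}

#' Default method set for the toy benchmark
#'
#' Hyperparameters follow the best-performing settings of the published
#' hyperparameter scan, chosen per input-feature kind the way each benchmark
#' panel was produced: the MLP uses a weak L2 penalty on Cartesian input
#' (where the rotation-entangled decision surface needs full capacity) and a
#' stronger one on the many-feature inverse-distance inputs (where weight
#' decay suppresses the attribution noise floor of unused inputs).
#'
#' @param include character vector of method names to keep.
#' @param feature_kind optional feature kind the methods will run on; tunes
#'   the MLP penalty as described above.
#' @return named list of [extractor_spec()]s.
#' @export
default_benchmark_methods <- function(include = c("PCA", "RBM", "AE", "KL",
                                                  "RF", "MLP"),
                                      feature_kind = NULL) {
  distance_kind <- !is.null(feature_kind) &&
    feature_kind %in% c("inverse_distance_full", "inverse_distance_reduced")
  mlp <- if (distance_kind)
    # strong weight decay with small batches suppresses the attribution
    # noise floor of the thousands of uninformative distance inputs
    extractor_spec("mlp", hidden_layers = c(100L), epochs = 300L,
                   learning_rate = 2e-3, alpha = 1e-2, batch_size = 32L)
  else
    # the rotation-entangled Cartesian task needs full capacity, clean
    # full-batch gradients and patience through slow-learning phases
    extractor_spec("mlp", hidden_layers = c(100L), epochs = 600L,
                   learning_rate = 2e-3, alpha = 1e-4, batch_size = 200L,
                   n_iter_no_change = 50L)
  all <- list(
    PCA = extractor_spec("pca", criterion = "eigengap"),
    RBM = extractor_spec("rbm", n_hidden = 32L, learning_rate = 0.05,
                         n_iter = 15L),
    AE = extractor_spec("ae", hidden_layers = c(50L), epochs = 150L),
    KL = extractor_spec("kl"),
    RF = extractor_spec("rf", n_estimators = 1000L),
    MLP = mlp)
  all[intersect(include, names(all))]
}

featurize_for_benchmark <- function(coords, kind) {
  fm <- switch(kind,
    cartesian = cartesian_features(coords),
    inverse_distance_full = inverse_distance_features(coords, "full"),
    inverse_distance_reduced = inverse_distance_features(coords, "reduced"),
    stop("unknown feature kind: ", kind, call. = FALSE))
  # zero-variance features (possible at zero toy noise) are dropped before
  # model fitting, as in the real-system pipeline
  fm <- suppressMessages(drop_constant_features(fm))
  minmax_scale(fm)
}

#' Benchmark extractors on toy systems with known ground truth
#'
#' For each of `n_instances` independently generated toy systems, each
#' feature kind and each method, extracts feature importance `n_repeats`
#' times (re-seeding stochastic fits), aggregates it per atom, and scores it
#' against the system's true importance with both accuracy metrics. A
#' random-guessing baseline (`RAND`) is scored alongside. Individual
#' extractor failures are caught, recorded as missing and the run continues.
#'
#' @param methods named list of [extractor_spec()]s, or a function of the
#'   feature kind returning such a list (the way per-panel hyperparameter
#'   choices are expressed; default: [default_benchmark_methods()] per kind).
#' @param config a [toy_config()]; instance k is regenerated with
#'   `seed = config$seed + k`.
#' @param feature_kinds subset of `c("cartesian", "inverse_distance_full",
#'   "inverse_distance_reduced")`.
#' @param n_instances independent toy systems.
#' @param n_repeats importance computations per method and instance.
#' @param include_random add the `RAND` baseline.
#' @param verbose print progress.
#' @return an `accuracy_report`: list with the long-format `results`
#'   data.frame (method, feature_kind, instance, repeat, find_all,
#'   ignore_irrelevant) and the box-plot `summary` from
#'   [summarize_accuracy()].
#' @export
run_benchmark <- function(methods = default_benchmark_methods,
                          config = toy_config(),
                          feature_kinds = c("cartesian",
                                            "inverse_distance_full",
                                            "inverse_distance_reduced"),
                          n_instances = 10L, n_repeats = 10L,
                          include_random = TRUE, verbose = FALSE) {
  methods_for_kind <- if (is.function(methods)) {
    if ("feature_kind" %in% names(formals(methods)))
      function(kind) methods(feature_kind = kind)
    else methods
  } else function(kind) methods
  stopifnot(length(methods_for_kind(feature_kinds[1L])) >= 1L ||
              include_random)
  rows <- list()
  failures <- list()
  for (inst in seq_len(n_instances)) {
    cfg <- config
    cfg$seed <- config$seed + inst
    system <- generate_system(cfg)
    traj <- generate_frames(system)
    psi <- true_importance(system)
    labels <- label_set(traj$labels, cfg$n_states)
    for (kind in feature_kinds) {
      fm <- featurize_for_benchmark(traj$coords, kind)
      kind_methods <- methods_for_kind(kind)
      for (m in seq_along(kind_methods)) {
        mname <- names(kind_methods)[m]
        for (rep_i in seq_len(n_repeats)) {
          seed_i <- cfg$seed * 1009L + m * 211L + rep_i
          res <- tryCatch({
            prof <- run_extractor(kind_methods[[m]], fm, labels,
                                  seed = seed_i)
            phi <- aggregate_importance_per_atom(prof$per_feature,
                                                 fm$descriptors)
            c(find_all_accuracy(phi, psi),
              ignore_irrelevant_accuracy(phi, psi))
          }, error = function(e) {
            failures[[length(failures) + 1L]] <<- sprintf(
              "%s / %s / instance %d / repeat %d: %s",
              mname, kind, inst, rep_i, conditionMessage(e))
            c(NA_real_, NA_real_)
          })
          rows[[length(rows) + 1L]] <- data.frame(
            method = mname, feature_kind = kind, instance = inst,
            repeat_ = rep_i, find_all = res[1], ignore_irrelevant = res[2],
            stringsAsFactors = FALSE)
        }
        if (verbose)
          message(sprintf("instance %d / %s / %s done", inst, kind, mname))
      }
      if (include_random) {
        for (rep_i in seq_len(n_repeats)) {
          phi <- random_baseline(cfg$n_atoms,
                                 seed = cfg$seed * 1013L + rep_i)
          rows[[length(rows) + 1L]] <- data.frame(
            method = "RAND", feature_kind = kind, instance = inst,
            repeat_ = rep_i,
            find_all = find_all_accuracy(phi, psi),
            ignore_irrelevant = ignore_irrelevant_accuracy(phi, psi),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  names(results)[names(results) == "repeat_"] <- "repeat"
  structure(list(results = results, summary = summarize_accuracy(results),
                 failures = unlist(failures), config = config),
            class = "accuracy_report")
}

#' Box-plot summaries of benchmark scores
#'
#' Median, interquartile range, whiskers at 1.5 x IQR (clamped to the data)
#' and outlier count per (method, feature kind, metric).
#'
#' @param results long-format results data.frame from [run_benchmark()].
#' @return summary data.frame.
#' @export
summarize_accuracy <- function(results) {
  long <- rbind(
    data.frame(results[c("method", "feature_kind")], metric = "find_all",
               value = results$find_all, stringsAsFactors = FALSE),
    data.frame(results[c("method", "feature_kind")],
               metric = "ignore_irrelevant",
               value = results$ignore_irrelevant, stringsAsFactors = FALSE))
  long <- long[!is.na(long$value), ]
  if (nrow(long) == 0L) return(NULL)
  out <- do.call(rbind, lapply(
    split(long, list(long$method, long$feature_kind, long$metric),
          drop = TRUE),
    function(g) {
      q <- stats::quantile(g$value, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
      inside <- g$value >= lo_fence & g$value <= hi_fence
      data.frame(method = g$method[1], feature_kind = g$feature_kind[1],
                 metric = g$metric[1], n = nrow(g),
                 median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(g$value[inside]),
                 whisker_high = max(g$value[inside]),
                 n_outliers = sum(!inside), stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy_report: %d scores, %d failures\n",
              nrow(x$results), length(x$failures)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Median score of one report cell
#' @param report an `accuracy_report`.
#' @param method,feature_kind cell selectors.
#' @param metric `"find_all"` or `"ignore_irrelevant"`.
#' @return median score.
#' @export
report_median <- function(report, method, feature_kind,
                          metric = c("find_all", "ignore_irrelevant")) {
  metric <- match.arg(metric)
  r <- report$results
  v <- r[[metric]][r$method == method & r$feature_kind == feature_kind]
  stats::median(v, na.rm = TRUE)
}

#' Grid scan over extractor hyperparameters
#'
#' Evaluates every row of a hyperparameter grid with a (typically reduced)
#' toy benchmark and reports mean scores; the row with the best mean find-all
#' score is flagged.
#'
#' @param method extractor name as in [extractor_spec()].
#' @param grid data.frame; each row is one hyperparameter combination.
#' @param config a [toy_config()].
#' @param feature_kinds feature kinds to evaluate.
#' @param n_instances,n_repeats benchmark size per grid row.
#' @return data.frame: grid columns + mean_find_all, mean_ignore_irrelevant,
#'   best flag.
#' @export
hyperparameter_scan <- function(method, grid, config = toy_config(),
                                feature_kinds = "inverse_distance_reduced",
                                n_instances = 2L, n_repeats = 2L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    params <- lapply(params, function(v) if (is.factor(v)) as.character(v)
                                         else v)
    spec <- do.call(extractor_spec, c(list(method = method), params))
    rep <- run_benchmark(methods = stats::setNames(list(spec), method),
                         config = config, feature_kinds = feature_kinds,
                         n_instances = n_instances, n_repeats = n_repeats,
                         include_random = FALSE)
    c(mean_find_all = mean(rep$results$find_all, na.rm = TRUE),
      mean_ignore_irrelevant = mean(rep$results$ignore_irrelevant,
                                    na.rm = TRUE))
  })
  scores <- do.call(rbind, res)
  out <- cbind(grid, scores)
  out$best <- seq_len(nrow(out)) == which.max(out$mean_find_all)
  out
}

#' Render benchmark box plots
#'
#' One panel per feature kind, grouped boxes per method and metric, written
#' to SVG or PNG depending on the file extension.
#'
#' @param report an `accuracy_report`.
#' @param path output file ending in `.svg` or `.png`.
#' @return the path, invisibly.
#' @export
plot_accuracy_report <- function(report, path) {
  kinds <- unique(report$results$feature_kind)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = 5 * length(kinds), height = 4),
    png = grDevices::png(path, width = 500 * length(kinds), height = 400),
    stop("unsupported plot format: ", ext, call. = FALSE))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(kinds)), mar = c(7, 4, 3, 1))
  for (kind in kinds) {
    r <- report$results[report$results$feature_kind == kind, ]
    vals <- c(r$find_all, r$ignore_irrelevant)
    grp <- factor(paste(rep(r$method, 2),
                        rep(c("find", "ignore"), each = nrow(r))))
    graphics::boxplot(vals ~ grp, las = 2, main = kind, ylab = "accuracy",
                      ylim = c(0, 1), col = "grey85", medcol = "darkorange")
  }
  invisible(path)
}
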