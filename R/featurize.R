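#' Construct a feature matrix object
#'
#' Internal constructor shared by the featurizers. A `feature_matrix` holds a
#' samples-by-features numeric matrix, one descriptor per feature (either an
#' atom/axis pair for Cartesian features or an i < j atom pair for distance
#' features), the feature kind and, after [minmax_scale()], the per-feature
#' (min, max) used for scaling.
#'
#' @param values n_samples x n_features numeric matrix.
#' @param descriptors data.frame with columns `atom_i`, `atom_j` (pair kinds;
#'   0-based, `atom_i < atom_j`) or `atom`, `axis` (Cartesian).
#' @param kind one of `"cartesian"`, `"distance"`, `"inverse_distance_full"`,
#'   `"inverse_distance_reduced"`.
#' @param scaling optional data.frame with columns `min`, `max`, `constant`.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, descriptors, kind, scaling = NULL) {
  stopifnot(is.matrix(values), nrow(descriptors) == ncol(values))
  structure(list(values = values, descriptors = descriptors, kind = kind,
                 scaling = scaling),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%s%s)\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (is.null(x$scaling)) ", unscaled" else ", scaled"))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

is_distance_kind <- function(kind) {
  kind %in% c("distance", "inverse_distance_full", "inverse_distance_reduced")
}

coords_to_array <- function(coords) {
  if (inherits(coords, "toy_trajectory")) coords <- coords$coords
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array", call. = FALSE)
  if (dim(coords)[1] == 0L) stop("empty trajectory", call. = FALSE)
  if (!all(is.finite(coords))) stop("coords must be finite", call. = FALSE)
  coords
}

#' Cartesian coordinate features
#'
#' Flattens each frame into 3N features in column order
#' (atom0.x, atom0.y, atom0.z, atom1.x, ...). Returned unscaled.
#'
#' @param coords n_frames x n_atoms x 3 array (or a `toy_trajectory`).
#' @return a `feature_matrix` of kind `"cartesian"`.
#' @export
cartesian_features <- function(coords) {
  coords <- coords_to_array(coords)
  n_frames <- dim(coords)[1]; n_atoms <- dim(coords)[2]
  vals <- matrix(0, n_frames, 3L * n_atoms)
  for (ax in 1:3) vals[, seq(ax, by = 3L, length.out = n_atoms)] <-
    coords[, , ax]
  desc <- data.frame(atom = rep(0:(n_atoms - 1L), each = 3L),
                     axis = rep(c("x", "y", "z"), n_atoms),
                     stringsAsFactors = FALSE)
  feature_matrix(vals, desc, "cartesian")
}

# 0-based pair index table for full or reduced (i -> i+1..i+4) sets.
distance_pairs <- function(n_atoms, mode) {
  if (mode == "full") {
    i <- rep(0:(n_atoms - 2L), times = (n_atoms - 1L):1L)
    j <- unlist(lapply(1:(n_atoms - 1L), function(k) k:(n_atoms - 1L)))
  } else {
    i <- integer(0); j <- integer(0)
    for (k in 1:4) {
      ii <- 0:(n_atoms - 1L - k)
      if (length(ii) > 0L && ii[1] <= n_atoms - 1L - k) {
        i <- c(i, ii); j <- c(j, ii + k)
      }
    }
    ord <- order(i, j)
    i <- i[ord]; j <- j[ord]
  }
  data.frame(atom_i = i, atom_j = j)
}

#' Inverse interatomic distance features
#'
#' Internal-coordinate featurization: the reciprocal of every pairwise
#' distance (`mode = "full"`, N(N-1)/2 features) or of the reduced
#' triangulation set connecting atom i to atoms i+1..i+4 only
#' (`mode = "reduced"`). Returned unscaled. Inverse distances emphasize
#' contact formation: close pairs get large values.
#'
#' @param coords n_frames x n_atoms x 3 array (or a `toy_trajectory`).
#' @param mode `"full"` or `"reduced"`.
#' @param inverse if `FALSE`, return raw distances (kind `"distance"`), the
#'   form the cutoff filters interpret directly.
#' @return a `feature_matrix`.
#' @export
inverse_distance_features <- function(coords, mode = c("full", "reduced"),
                                      inverse = TRUE) {
  mode <- match.arg(mode)
  coords <- coords_to_array(coords)
  n_atoms <- dim(coords)[2]
  if (n_atoms < 2L) stop("need at least two atoms", call. = FALSE)
  pairs <- distance_pairs(n_atoms, mode)
  i1 <- pairs$atom_i + 1L; j1 <- pairs$atom_j + 1L
  dx <- coords[, i1, 1, drop = FALSE] - coords[, j1, 1, drop = FALSE]
  dy <- coords[, i1, 2, drop = FALSE] - coords[, j1, 2, drop = FALSE]
  dz <- coords[, i1, 3, drop = FALSE] - coords[, j1, 3, drop = FALSE]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  dim(d) <- c(dim(coords)[1], nrow(pairs))
  if (any(d == 0)) {
    hit <- which(d == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero distance in frame %d between atoms %d and %d",
                 hit[1], pairs$atom_i[hit[2]], pairs$atom_j[hit[2]]),
         call. = FALSE)
  }
  kind <- if (!inverse) "distance"
          else if (mode == "full") "inverse_distance_full"
          else "inverse_distance_reduced"
  feature_matrix(if (inverse) 1 / d else d, pairs, kind)
}

# Raw distances of a distance-kind feature matrix (filters reason in nm on
# distances, not on their reciprocals).
raw_distances <- function(fm) {
  if (!is_distance_kind(fm$kind))
    stop("filter requires a distance-kind feature matrix, got ", fm$kind,
         call. = FALSE)
  if (!is.null(fm$scaling))
    stop("filters must run on unscaled distances", call. = FALSE)
  if (fm$kind == "distance") fm$values else 1 / fm$values
}

subset_features <- function(fm, keep) {
  feature_matrix(fm$values[, keep, drop = FALSE],
                 fm$descriptors[keep, , drop = FALSE], fm$kind, fm$scaling)
}

#' Keep only contact-changing pairs
#'
#' Retains a pair iff its distance is below `cutoff` in at least one sample
#' and above `cutoff` in another, i.e. the pair forms and breaks a contact
#' within the dataset.
#'
#' @param fm unscaled distance-kind `feature_matrix`.
#' @param cutoff contact cutoff in the coordinate units (e.g. 1.0 nm).
#' @return filtered `feature_matrix`.
#' @export
filter_contact_changing <- function(fm, cutoff) {
  stopifnot(cutoff > 0)
  d <- raw_distances(fm)
  keep <- matrixStats_colMins(d) < cutoff & matrixStats_colMaxs(d) > cutoff
  message(sprintf("contact-change filter (cutoff %g): %d -> %d features",
                  cutoff, ncol(d), sum(keep)))
  subset_features(fm, keep)
}

#' Drop pairs entirely outside a distance band
#'
#' Removes pairs that stay above `upper` for every sample or below `lower`
#' for every sample; pairs visiting the band \[lower, upper\] at least once
#' are kept.
#'
#' @param fm unscaled distance-kind `feature_matrix`.
#' @param lower,upper band limits, `lower < upper`.
#' @return filtered `feature_matrix`.
#' @export
filter_range <- function(fm, lower, upper) {
  stopifnot(lower < upper)
  d <- raw_distances(fm)
  drop <- matrixStats_colMins(d) > upper | matrixStats_colMaxs(d) < lower
  message(sprintf("range filter (%g, %g): %d -> %d features",
                  lower, upper, ncol(d), sum(!drop)))
  subset_features(fm, !drop)
}

matrixStats_colMins <- function(m) apply(m, 2, min)
matrixStats_colMaxs <- function(m) apply(m, 2, max)

#' Min-max scale features to \[0, 1\]
#'
#' Per-feature (x - min) / (max - min). Constant features map to 0 and are
#' flagged in the scaling record. The (min, max) pairs are stored so
#' [minmax_unscale()] can invert the transform.
#'
#' @param fm a `feature_matrix`.
#' @return scaled `feature_matrix` with a `scaling` record.
#' @export
minmax_scale <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  lo <- matrixStats_colMins(fm$values)
  hi <- matrixStats_colMaxs(fm$values)
  constant <- hi == lo
  rng <- ifelse(constant, 1, hi - lo)
  vals <- sweep(sweep(fm$values, 2, lo, "-"), 2, rng, "/")
  vals[, constant] <- 0
  feature_matrix(vals, fm$descriptors, fm$kind,
                 scaling = data.frame(min = lo, max = hi, constant = constant))
}

#' Invert min-max scaling
#' @param fm a scaled `feature_matrix`.
#' @return `feature_matrix` on the original scale (constant features restored
#'   to their recorded constant value).
#' @export
minmax_unscale <- function(fm) {
  if (is.null(fm$scaling)) stop("feature matrix is not scaled", call. = FALSE)
  sc <- fm$scaling
  rng <- ifelse(sc$constant, 0, sc$max - sc$min)
  vals <- sweep(sweep(fm$values, 2, rng, "*"), 2, sc$min, "+")
  feature_matrix(vals, fm$descriptors, fm$kind)
}

#' Drop zero-variance features
#'
#' Constant features break min-max scaling and KL binning; they are removed
#' before model fitting and the count is reported.
#'
#' @param fm a `feature_matrix`.
#' @return `feature_matrix` without constant columns.
#' @export
drop_constant_features <- function(fm) {
  constant <- matrixStats_colMins(fm$values) == matrixStats_colMaxs(fm$values)
  if (any(constant))
    message(sprintf("dropping %d constant features", sum(constant)))
  subset_features(fm, !constant)
}

#' Per-frame state labels
#'
#' @param state_index integer vector of 0-based state indices, one per sample.
#' @param n_states number of states; defaults to `max(state_index) + 1`.
#' @return a `label_set` with fields `state_index`, `n_states` and the
#'   `one_hot` n_samples x n_states indicator matrix.
#' @export
label_set <- function(state_index, n_states = NULL) {
  state_index <- as.integer(state_index)
  if (is.null(n_states)) n_states <- max(state_index) + 1L
  n_states <- as.integer(n_states)
  if (any(state_index < 0L) || any(state_index >= n_states))
    stop("state indices must lie in [0, n_states)", call. = FALSE)
  one_hot <- matrix(0L, length(state_index), n_states)
  one_hot[cbind(seq_along(state_index), state_index + 1L)] <- 1L
  structure(list(state_index = state_index, n_states = n_states,
                 one_hot = one_hot), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %d samples, %d states (counts: %s)\n",
              length(x$state_index), x$n_states,
              paste(tabulate(x$state_index + 1L, x$n_states),
                    collapse = ", ")))
  invisible(x)
}

#' Shuffle samples in contiguous blocks
#'
#' Permutes rows by contiguous blocks of `block_size` samples (the last block
#' may be shorter), co-permuting the labels. Block shuffling decorrelates
#' folds from simulation time while preserving short-range temporal
#' correlation inside a block.
#'
#' @param fm a `feature_matrix`.
#' @param labels a `label_set` or integer state vector.
#' @param block_size samples per block (>= 1).
#' @param seed RNG seed for the block permutation.
#' @return list with shuffled `fm` and `labels`.
#' @export
block_shuffle <- function(fm, labels, block_size, seed = 1L) {
  stopifnot(block_size >= 1L)
  if (!inherits(labels, "label_set")) labels <- label_set(labels)
  n <- nrow(fm$values)
  starts <- seq(1L, n, by = as.integer(block_size))
  blocks <- lapply(starts, function(s) s:min(s + block_size - 1L, n))
  set.seed(seed)
  perm <- unlist(blocks[sample.int(length(blocks))])
  list(fm = feature_matrix(fm$values[perm, , drop = FALSE], fm$descriptors,
                           fm$kind, fm$scaling),
       labels = label_set(labels$state_index[perm], labels$n_states))
}

#' Aggregate feature importance onto atoms
#'
#' Each atom's score is the sum of the importance of every feature whose
#' descriptor involves the atom (both endpoints of a distance pair; the xyz
#' triplet of a Cartesian atom), normalized to \[0, 1\]. The default
#' `"minmax"` normalization subtracts the minimum atom score before dividing
#' by the range: with pair features every atom shares pairs with the
#' displaced atoms, so raw sums carry a uniform baseline that min-max removes
#' and plain max-division would keep. `"max"` divides by the maximum only,
#' preserving exact zeros for atoms with no importance mass.
#'
#' @param feature_importance numeric vector, one value per feature.
#' @param descriptors the `descriptors` data.frame of the feature matrix the
#'   importance refers to (or a `feature_matrix`).
#' @param normalize `"minmax"` or `"max"`.
#' @return numeric per-atom importance in \[0, 1\]; attribute `all_zero` set
#'   when the input carried no mass.
#' @export
aggregate_importance_per_atom <- function(feature_importance, descriptors,
                                          normalize = c("minmax", "max")) {
  normalize <- match.arg(normalize)
  if (inherits(descriptors, "feature_matrix"))
    descriptors <- descriptors$descriptors
  if (length(feature_importance) != nrow(descriptors))
    stop("importance length does not match descriptor count", call. = FALSE)
  if (!all(is.finite(feature_importance)))
    stop("importance must be finite", call. = FALSE)
  if (!is.null(descriptors$atom)) {
    n_atoms <- max(descriptors$atom) + 1L
    score <- as.numeric(rowsum(feature_importance, descriptors$atom,
                               reorder = TRUE))
    atoms_present <- sort(unique(descriptors$atom))
    full <- numeric(n_atoms)
    full[atoms_present + 1L] <- score
  } else {
    n_atoms <- max(descriptors$atom_j) + 1L
    full <- numeric(n_atoms)
    si <- rowsum(feature_importance, descriptors$atom_i, reorder = TRUE)
    sj <- rowsum(feature_importance, descriptors$atom_j, reorder = TRUE)
    full[as.integer(rownames(si)) + 1L] <- full[as.integer(rownames(si)) + 1L] + si
    full[as.integer(rownames(sj)) + 1L] <- full[as.integer(rownames(sj)) + 1L] + sj
  }
  m <- max(full)
  if (m <= 0) {
    attr(full, "all_zero") <- TRUE
    return(full)
  }
  if (normalize == "max") return(full / m)
  lo <- min(full)
  if (m == lo) return(rep(1, length(full)))  # constant nonzero profile
  (full - lo) / (m - lo)
}
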