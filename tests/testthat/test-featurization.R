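make_coords <- function(m) array(m, dim = c(1, nrow(m), 3))

test_that("Cartesian featurization flattens frames in atom-major xyz order", {
  t <- tiny_toy(seed = 1, n_frames_per_state = 2L)
  fm <- cartesian_features(t$traj)
  expect_equal(ncol(fm$values), 3 * 30)
  fm5 <- cartesian_features(t$traj$coords[, 1:5, , drop = FALSE])
  expect_equal(ncol(fm5$values), 15)
  one <- t$traj$coords[1, 1:5, , drop = FALSE]
  fm1 <- cartesian_features(one)
  expect_equal(as.numeric(fm1$values),
               as.numeric(t(one[1, , ])))  # atom-major x,y,z
  expect_error(cartesian_features(array(0, c(0, 5, 3))), "empty")
})

test_that("inverse distance features count pairs correctly and invert distances", {
  coords5 <- make_coords(matrix(rnorm(15), 5, 3))
  expect_equal(ncol(inverse_distance_features(coords5, "full")$values), 10)
  t <- tiny_toy(seed = 2, n_frames_per_state = 1L)
  big <- array(0, c(1, 100, 3))
  set.seed(1); big[1, , ] <- rnorm(300)
  expect_equal(ncol(inverse_distance_features(big, "reduced")$values),
               99 + 98 + 97 + 96)
  two <- make_coords(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(as.numeric(inverse_distance_features(two, "full")$values), 0.5)
  dup <- make_coords(matrix(c(1, 1, 1, 1, 1, 1), 2, 3, byrow = TRUE))
  expect_error(inverse_distance_features(dup, "full"), "zero distance")
})

test_that("reduced descriptor set is a subset of the full set", {
  coords <- array(rnorm(10 * 3), c(1, 10, 3))
  full <- inverse_distance_features(coords, "full")$descriptors
  red <- inverse_distance_features(coords, "reduced")$descriptors
  key <- function(d) paste(d$atom_i, d$atom_j)
  expect_true(all(key(red) %in% key(full)))
  expect_true(all(red$atom_i < red$atom_j))
})

test_that("contact-change filter keeps exactly the pairs that cross the cutoff", {
  # two frames, engineered distances
  p1 <- matrix(c(0, 0, 0,   0.8, 0, 0,   0, 3, 0,   5, 5, 5), 4, 3,
               byrow = TRUE)
  p2 <- matrix(c(0, 0, 0,   1.2, 0, 0,   0, 0.5, 0, 5, 5, 5), 4, 3,
               byrow = TRUE)
  coords <- array(0, c(2, 4, 3)); coords[1, , ] <- p1; coords[2, , ] <- p2
  fm <- inverse_distance_features(coords, "full", inverse = FALSE)
  # brute-force enumeration oracle
  mins <- apply(fm$values, 2, min); maxs <- apply(fm$values, 2, max)
  expected_keep <- which(mins < 1 & maxs > 1)
  kept <- suppressMessages(filter_contact_changing(fm, 1.0))
  expect_equal(ncol(kept$values), length(expected_keep))
  expect_equal(kept$descriptors, fm$descriptors[expected_keep, ],
               ignore_attr = TRUE)
  # pairs 0-1 (0.8 -> 1.2) and 1-2 (sqrt(.8^2+3^2)=3.1 -> sqrt(.7^2+.5^2)=0.86) cross
  expect_equal(ncol(kept$values), 2)
  # idempotence
  again <- suppressMessages(filter_contact_changing(kept, 1.0))
  expect_equal(again$values, kept$values)
  expect_error(filter_contact_changing(cartesian_features(coords), 1.0),
               "distance")
})

test_that("range filter drops pairs that never visit the band", {
  vals <- cbind(c(0.9, 0.9), c(0.6, 0.6), c(0.45, 0.65), c(0.2, 0.3))
  fm <- feature_matrix(vals, data.frame(atom_i = 0:3, atom_j = 4:7),
                       "distance")
  kept <- suppressMessages(filter_range(fm, 0.5, 0.7))
  # 0.9 always above, 0.2-0.3 always below; 0.6 and 0.45-0.65 stay
  expect_equal(kept$descriptors$atom_i, c(1L, 2L))
})

test_that("min-max scaling maps to [0,1], flags constants and round-trips", {
  vals <- cbind(c(2, 4, 6), c(3, 3, 3), c(-1, 0, 3))
  fm <- feature_matrix(vals, data.frame(atom_i = c(0, 0, 1),
                                        atom_j = c(1, 2, 2)), "distance")
  sc <- minmax_scale(fm)
  expect_equal(sc$values[, 1], c(0, 0.5, 1))
  expect_equal(sc$values[, 2], c(0, 0, 0))
  expect_true(sc$scaling$constant[2])
  expect_false(any(sc$scaling$constant[c(1, 3)]))
  back <- minmax_unscale(sc)
  expect_equal(back$values[, c(1, 3)], vals[, c(1, 3)], tolerance = 1e-12)
  # order preservation
  expect_equal(order(sc$values[, 3]), order(vals[, 3]))
})

test_that("block shuffling permutes whole blocks and keeps (row,label) pairs", {
  vals <- matrix(1:20, nrow = 10)
  fm <- feature_matrix(vals, data.frame(atom_i = c(0, 0), atom_j = c(1, 2)),
                       "distance")
  labels <- label_set(rep(0:1, each = 5))
  # block = n: identity
  sh <- block_shuffle(fm, labels, block_size = 10, seed = 1)
  expect_equal(sh$fm$values, vals)
  # block 5 on 10 samples: one of the two enumerable block orders
  sh5 <- block_shuffle(fm, labels, block_size = 5, seed = 3)
  orders <- list(1:10, c(6:10, 1:5))
  expect_true(any(vapply(orders, function(o)
    identical(sh5$fm$values, vals[o, ]), logical(1))))
  # block 1: multiset of (row, label) preserved
  sh1 <- block_shuffle(fm, labels, block_size = 1, seed = 5)
  key <- function(v, l) sort(paste(v[, 1], v[, 2], l))
  expect_equal(key(sh1$fm$values, sh1$labels$state_index),
               key(vals, labels$state_index))
})

test_that("per-atom aggregation follows the summation rule under both normalizations", {
  desc <- data.frame(atom_i = c(0L, 0L, 1L), atom_j = c(1L, 2L, 2L))
  # raw sums (1.0, 1.5, 1.5): max-division gives (2/3, 1, 1)
  agg <- aggregate_importance_per_atom(c(0.5, 0.5, 1.0), desc,
                                       normalize = "max")
  expect_equal(agg, c(2 / 3, 1, 1), tolerance = 1e-12)
  # single nonzero pair
  one <- aggregate_importance_per_atom(c(0, 1, 0), desc, normalize = "max")
  expect_equal(one, c(1, 0, 1))
  # Cartesian triplet
  cdesc <- data.frame(atom = rep(0:1, each = 3),
                      axis = rep(c("x", "y", "z"), 2))
  cart <- aggregate_importance_per_atom(c(0.2, 0.3, 0.5, 0, 0, 0), cdesc)
  expect_equal(cart, c(1, 0))
  # all-zero flagged
  zero <- aggregate_importance_per_atom(c(0, 0, 0), desc)
  expect_true(isTRUE(attr(zero, "all_zero")))
  expect_error(aggregate_importance_per_atom(c(1, 2), desc), "length")
})

test_that("aggregation is equivariant under atom relabeling", {
  set.seed(11)
  coords <- array(rnorm(1 * 6 * 3), c(1, 6, 3))
  fm <- inverse_distance_features(coords, "full")
  imp <- runif(ncol(fm$values))
  agg <- aggregate_importance_per_atom(imp, fm$descriptors)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)  # new position of each atom (1-based)
  coords_p <- coords[, order(perm), , drop = FALSE]
  fm_p <- inverse_distance_features(coords_p, "full")
  # map each original pair's importance onto the permuted pair table
  d <- fm$descriptors
  pi_ <- pmin(perm[d$atom_i + 1L], perm[d$atom_j + 1L]) - 1L
  pj <- pmax(perm[d$atom_i + 1L], perm[d$atom_j + 1L]) - 1L
  key_p <- paste(fm_p$descriptors$atom_i, fm_p$descriptors$atom_j)
  imp_p <- imp[match(key_p, paste(pi_, pj))]
  agg_p <- aggregate_importance_per_atom(imp_p, fm_p$descriptors)
  expect_equal(agg_p[perm], agg, tolerance = 1e-12)
})
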