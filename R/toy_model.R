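#' Configuration for the synthetic multi-state toy model
#'
#' The toy model mimics a macromolecule whose metastable states are defined by
#' the displacement of a small, state-specific set of atoms away from a shared
#' equilibrium configuration. Atoms are placed uniformly at random in a cubic
#' box; each state displaces its own disjoint set of "important" atoms, either
#' linearly (one shared displacement vector per state) or nonlinearly (a chain
#' of rotations about the previously displaced atom). Frames are i.i.d. draws:
#' displaced coordinates plus uniform noise on all atoms, optionally followed
#' by a uniformly random rotation of the whole frame about the origin, which
#' emulates the arbitrary global orientation of unaligned trajectories.
#'
#' Defaults correspond to the benchmark's standard setting: 100 atoms in a box
#' spanning \[-1, 1\] per axis, three states with 10 displaced atoms each,
#' displacement magnitude 0.1, noise amplitude 0.01 and 1200 frames per state.
#'
#' @param n_atoms number of atoms.
#' @param box_half_width half-width b of the cubic box \[-b, b\]^3.
#' @param n_states number of metastable states.
#' @param n_important_per_state number of displaced atoms per state; the
#'   per-state sets are sampled disjointly, so
#'   `n_states * n_important_per_state <= n_atoms` is required.
#' @param displacement_magnitude Euclidean norm of the per-state displacement
#'   applied to important atoms (linear mode) or of the seed displacement
#'   (nonlinear mode).
#' @param noise_amplitude half-width of the uniform per-coordinate noise added
#'   to every atom of every frame.
#' @param n_frames_per_state frames generated per state.
#' @param displacement_mode `"linear"` or `"nonlinear"`.
#' @param rotate logical; apply a fresh uniformly random rotation about the
#'   origin to each frame.
#' @param nonlinear_axis unit axis about which nonlinear-mode chain rotations
#'   are performed (default z).
#' @param nonlinear_angle_per_state rotation angle used in nonlinear mode for
#'   state s (0-based) is `nonlinear_angle_per_state * (s + 1)`.
#' @param seed integer seed controlling system generation and frame noise.
#' @return an object of class `toy_config`.
#' @export
toy_config <- function(n_atoms = 100L,
                       box_half_width = 1,
                       n_states = 3L,
                       n_important_per_state = 10L,
                       displacement_magnitude = 0.1,
                       noise_amplitude = 0.01,
                       n_frames_per_state = 1200L,
                       displacement_mode = c("linear", "nonlinear"),
                       rotate = TRUE,
                       nonlinear_axis = c(0, 0, 1),
                       nonlinear_angle_per_state = pi / 4,
                       seed = 1L) {
  displacement_mode <- match.arg(displacement_mode)
  cfg <- structure(list(
    n_atoms = as.integer(n_atoms),
    box_half_width = as.numeric(box_half_width),
    n_states = as.integer(n_states),
    n_important_per_state = as.integer(n_important_per_state),
    displacement_magnitude = as.numeric(displacement_magnitude),
    noise_amplitude = as.numeric(noise_amplitude),
    n_frames_per_state = as.integer(n_frames_per_state),
    displacement_mode = displacement_mode,
    rotate = isTRUE(rotate),
    nonlinear_axis = as.numeric(nonlinear_axis) /
      sqrt(sum(as.numeric(nonlinear_axis)^2)),
    nonlinear_angle_per_state = as.numeric(nonlinear_angle_per_state),
    seed = as.integer(seed)
  ), class = "toy_config")
  validate_toy_config(cfg)
  cfg
}

validate_toy_config <- function(cfg) {
  stopifnot(inherits(cfg, "toy_config"))
  if (cfg$n_atoms < 1L || cfg$n_states < 1L ||
      cfg$n_important_per_state < 1L || cfg$n_frames_per_state < 1L)
    stop("counts must be >= 1", call. = FALSE)
  if (cfg$box_half_width <= 0)
    stop("box_half_width must be > 0", call. = FALSE)
  if (cfg$displacement_magnitude < 0 || cfg$noise_amplitude < 0)
    stop("lengths must be >= 0", call. = FALSE)
  if (cfg$n_states * cfg$n_important_per_state > cfg$n_atoms)
    stop(sprintf(
      "infeasible config: %d states x %d important atoms exceeds %d atoms (important sets must be disjoint)",
      cfg$n_states, cfg$n_important_per_state, cfg$n_atoms), call. = FALSE)
  invisible(cfg)
}

#' Uniformly random rotation matrix
#'
#' Draws a rotation uniformly on SO(3) via a normalized 4-dimensional Gaussian
#' quaternion.
#'
#' @param n number of rotation matrices.
#' @return a single 3x3 matrix if `n == 1`, else a list of matrices.
#' @export
random_rotation_matrix <- function(n = 1L) {
  one <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), nrow = 3, byrow = TRUE)
  }
  if (n == 1L) return(one())
  lapply(seq_len(n), function(i) one())
}

# Rotate point p about center by angle around unit axis (Rodrigues).
rotate_about <- function(p, center, axis, angle) {
  v <- p - center
  k <- axis
  v_rot <- v * cos(angle) + pracma_cross(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
  center + v_rot
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a toy system with known important atoms
#'
#' Places atoms uniformly in the box, samples disjoint per-state important
#' sets without replacement, and constructs per-state displaced coordinates.
#' In linear mode every important atom of state s is translated by a single
#' shared vector of norm `displacement_magnitude` whose direction depends on
#' the state index. In nonlinear mode the first important atom is translated
#' with state-dependent size and direction, and each subsequent important atom
#' is rotated about the (displaced) position of the previous atom of the same
#' state.
#'
#' @param config a [toy_config()].
#' @return an object of class `toy_system` with fields `equilibrium_coords`
#'   (n_atoms x 3), `important_sets` (list of 1-based integer vectors, one per
#'   state), `per_state_displaced_coords` (list of n_atoms x 3 matrices) and
#'   `config`.
#' @export
generate_system <- function(config) {
  validate_toy_config(config)
  set.seed(config$seed)
  n <- config$n_atoms
  b <- config$box_half_width
  eq <- matrix(stats::runif(n * 3, -b, b), ncol = 3)

  pool <- sample.int(n, config$n_states * config$n_important_per_state)
  important_sets <- split(
    pool, rep(seq_len(config$n_states), each = config$n_important_per_state))
  important_sets <- lapply(important_sets, sort)
  names(important_sets) <- NULL

  displaced <- vector("list", config$n_states)
  for (s in seq_len(config$n_states)) {
    coords <- eq
    idx <- important_sets[[s]]
    if (config$displacement_mode == "linear") {
      # one shared vector per state, direction a deterministic function of the
      # state index, norm displacement_magnitude
      dir <- state_direction(s - 1L, config$n_states)
      shift <- config$displacement_magnitude * dir
      coords[idx, ] <- sweep(coords[idx, , drop = FALSE], 2, shift, "+")
    } else {
      dir <- state_direction(s - 1L, config$n_states)
      scale <- config$displacement_magnitude * (1 + (s - 1L) / config$n_states)
      coords[idx[1L], ] <- coords[idx[1L], ] + scale * dir
      angle <- config$nonlinear_angle_per_state * s
      if (length(idx) > 1L) {
        for (k in 2:length(idx)) {
          coords[idx[k], ] <- rotate_about(
            coords[idx[k], ], coords[idx[k - 1L], ],
            config$nonlinear_axis, angle)
        }
      }
    }
    displaced[[s]] <- coords
  }

  structure(list(
    equilibrium_coords = eq,
    important_sets = important_sets,
    per_state_displaced_coords = displaced,
    config = config
  ), class = "toy_system")
}

# Deterministic unit direction for a 0-based state index: points spread on the
# unit sphere via a Fibonacci lattice so states displace along distinct
# directions regardless of n_states.
state_direction <- function(state, n_states) {
  i <- state + 0.5
  phi <- acos(1 - 2 * i / n_states)
  theta <- pi * (1 + sqrt(5)) * i
  c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate i.i.d. toy-model frames
#'
#' For each state, draws `n_frames_per_state` frames as the state's displaced
#' coordinates plus independent uniform noise in
#' \[-noise_amplitude, +noise_amplitude\] on every coordinate of every atom,
#' then (if `rotate`) applies a fresh uniformly random rotation about the
#' origin to the whole frame. No temporal correlation is modeled.
#'
#' @param system a `toy_system` from [generate_system()].
#' @return an object of class `toy_trajectory` with `coords`
#'   (n_frames x n_atoms x 3 array), integer `labels` (0-based state index per
#'   frame) and `system`.
#' @export
generate_frames <- function(system) {
  stopifnot(inherits(system, "toy_system"))
  cfg <- system$config
  set.seed(cfg$seed + 1L)
  n_frames <- cfg$n_states * cfg$n_frames_per_state
  coords <- array(0, dim = c(n_frames, cfg$n_atoms, 3))
  labels <- integer(n_frames)
  f <- 0L
  for (s in seq_len(cfg$n_states)) {
    base <- system$per_state_displaced_coords[[s]]
    for (r in seq_len(cfg$n_frames_per_state)) {
      f <- f + 1L
      frame <- base
      if (cfg$noise_amplitude > 0) {
        frame <- frame + matrix(
          stats::runif(cfg$n_atoms * 3, -cfg$noise_amplitude,
                       cfg$noise_amplitude), ncol = 3)
      }
      if (cfg$rotate) frame <- frame %*% t(random_rotation_matrix())
      coords[f, , ] <- frame
      labels[f] <- s - 1L
    }
  }
  structure(list(coords = coords, labels = labels, system = system),
            class = "toy_trajectory")
}

#' Ground-truth importance vector of a toy system
#'
#' Binary indicator over atoms (1 for displaced atoms of the requested state,
#' or of any state when `state` is omitted), l2-normalized so that the
#' ignore-irrelevant benchmark score is bounded by 1.
#'
#' @param system a `toy_system`.
#' @param state optional 0-based state index; omitted means the union over all
#'   states (the ensemble ground truth).
#' @return numeric vector of length `n_atoms` with unit Euclidean norm.
#' @export
true_importance <- function(system, state = NULL) {
  stopifnot(inherits(system, "toy_system"))
  n <- system$config$n_atoms
  psi <- numeric(n)
  if (is.null(state)) {
    psi[unlist(system$important_sets)] <- 1
  } else {
    s <- as.integer(state)
    if (s < 0L || s >= system$config$n_states)
      stop("invalid state index: ", state, call. = FALSE)
    psi[system$important_sets[[s + 1L]]] <- 1
  }
  psi / sqrt(sum(psi^2))
}

#' @export
print.toy_system <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "toy_system: %d atoms, %d states x %d important atoms, %s displacement %.3g, noise %.3g\n",
    cfg$n_atoms, cfg$n_states, cfg$n_important_per_state,
    cfg$displacement_mode, cfg$displacement_magnitude, cfg$noise_amplitude))
  invisible(x)
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf("toy_trajectory: %d frames x %d atoms, %d states\n",
              dim(x$coords)[1], dim(x$coords)[2], x$system$config$n_states))
  invisible(x)
}
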