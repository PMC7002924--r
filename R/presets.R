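#' Analysis presets for the three published biological recipes
#'
#' Returns a run configuration preloaded with the hyperparameters of one of
#' the three real-system analyses the protocol was developed on:
#'
#' * `"cam"` -- calmodulin C-terminal states: inverse C-alpha distances,
#'   block shuffling in blocks of 100 frames, 1.0 nm contact-change filter,
#'   PCA with a 75% cumulative-variance cutoff, AE/MLP hidden layers
#'   (120, 100), RF with 500 trees in one-vs-rest mode, threefold cross
#'   validation, profiles averaged over 5 iterations.
#' * `"gpcr"` -- beta-2 adrenergic receptor activation: inverse C-alpha
#'   distances over all residues, PCA components kept until an eigenvalue
#'   drops by an order of magnitude, RF with 1000 trees, fourfold cross
#'   validation, 30 iterations.
#' * `"vsd"` -- voltage-sensor domain states: inverse heavy-atom residue
#'   distances, (0.5, 0.7) nm range filter, RF with 100 trees, threefold
#'   cross validation, 5 iterations.
#'
#' The trajectories themselves are external deposited data and are not
#' bundled; presets only set featurization and method parameters.
#'
#' @param name `"cam"`, `"gpcr"` or `"vsd"`.
#' @return a run-configuration list as consumed by [cli_extract()].
#' @export
preset_config <- function(name = c("cam", "gpcr", "vsd")) {
  name <- match.arg(name)
  switch(name,
    cam = list(
      preset = "cam",
      featurization = list(
        kind = "inverse_distance_full",
        block_shuffle = list(block_size = 100L),
        filter = list(type = "contact_changing", cutoff = 1.0)),
      methods = list(
        list(method = "pca", criterion = "cumulative_variance", theta = 0.75),
        list(method = "ae", hidden_layers = c(120L, 100L)),
        list(method = "kl"),
        list(method = "rf", mode = "one_vs_rest", n_estimators = 500L),
        list(method = "mlp", hidden_layers = c(120L, 100L)),
        list(method = "rbm")),
      n_iterations = 5L, n_folds = 3L, seed = 1L),
    gpcr = list(
      preset = "gpcr",
      featurization = list(kind = "inverse_distance_full"),
      methods = list(
        list(method = "pca", criterion = "eigengap", ratio = 10),
        list(method = "rf", mode = "multiclass", n_estimators = 1000L)),
      n_iterations = 30L, n_folds = 4L, seed = 1L),
    vsd = list(
      preset = "vsd",
      featurization = list(
        kind = "inverse_distance_full",
        filter = list(type = "range", lower = 0.5, upper = 0.7)),
      methods = list(
        list(method = "rf", mode = "one_vs_rest", n_estimators = 100L)),
      n_iterations = 5L, n_folds = 3L, seed = 1L))
}
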