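# Plain-text interchange: multi-model PDB trajectories (CA-per-atom
# convention), labels CSV, feature-matrix CSV with a descriptor header and
# JSON sidecar, importance-profile CSV, and run manifests. Atom and residue
# indices are 0-based internally and 1-based in every file written.

#' Write a coordinate ensemble as a multi-model PDB
#'
#' One MODEL block per frame; each atom is written as a CA record of residue
#' ALA with 1-based serial and residue numbers. Optional per-atom B-factors
#' (e.g. a projected importance) are clamped to \[0, 99.99\].
#'
#' @param coords n_frames x n_atoms x 3 array (or a `toy_trajectory`).
#' @param path output file.
#' @param bfactors optional per-atom values for the B-factor column.
#' @return the path, invisibly.
#' @export
write_multimodel_pdb <- function(coords, path, bfactors = NULL) {
  coords <- coords_to_array(coords)
  n_frames <- dim(coords)[1]; n_atoms <- dim(coords)[2]
  if (is.null(bfactors)) bfactors <- numeric(n_atoms)
  bfactors <- pmin(pmax(rep_len(bfactors, n_atoms), 0), 99.99)
  con <- file(path, "w")
  on.exit(close(con))
  atom_ids <- seq_len(n_atoms)
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      atom_ids, atom_ids, coords[f, , 1], coords[f, , 2], coords[f, , 3],
      1.0, bfactors), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-model) PDB
#'
#' Parses ATOM/HETATM records by fixed columns. Models are stacked into a
#' coordinate array; per-atom metadata (serial, residue number, B-factor) is
#' taken from the first model.
#'
#' @param path PDB file.
#' @return list with `coords` (n_models x n_atoms x 3), `atoms` data.frame
#'   (`serial`, `resid`, `bfactor`, both 1-based as in the file).
#' @export
read_multimodel_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_break <- startsWith(lines, "ENDMDL")
  model_id <- cumsum(model_break) + 1L
  model_id[model_break] <- NA
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  if (length(atom_lines) == 0L) stop("no ATOM records in ", path,
                                     call. = FALSE)
  n_models <- max(atom_model)
  per_model <- tabulate(atom_model, n_models)
  if (length(unique(per_model)) != 1L)
    stop("models differ in atom count", call. = FALSE)
  n_atoms <- per_model[1L]
  num <- function(l, from, to) as.numeric(substr(l, from, to))
  x <- num(atom_lines, 31, 38); y <- num(atom_lines, 39, 46)
  z <- num(atom_lines, 47, 54)
  coords <- array(0, dim = c(n_models, n_atoms, 3))
  for (m in seq_len(n_models)) {
    sel <- atom_model == m
    coords[m, , 1] <- x[sel]; coords[m, , 2] <- y[sel]
    coords[m, , 3] <- z[sel]
  }
  first <- atom_lines[atom_model == 1L]
  atoms <- data.frame(
    serial = as.integer(substr(first, 7, 11)),
    resid = as.integer(substr(first, 23, 26)),
    bfactor = num(first, 61, 66))
  list(coords = coords, atoms = atoms)
}

#' Write per-frame labels as CSV
#' @param labels a `label_set` or integer state vector.
#' @param path output file; columns `frame` (0-based) and `state`.
#' @export
write_labels_csv <- function(labels, path) {
  if (!inherits(labels, "label_set")) labels <- label_set(labels)
  utils::write.csv(
    data.frame(frame = seq_along(labels$state_index) - 1L,
               state = labels$state_index),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-frame labels from CSV
#' @param path CSV with columns `frame`, `state`.
#' @return a `label_set` ordered by frame.
#' @export
read_labels_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("frame", "state") %in% names(d)))
    stop("labels CSV needs columns frame,state", call. = FALSE)
  label_set(d$state[order(d$frame)])
}

descriptor_names <- function(descriptors) {
  if (!is.null(descriptors$atom))
    sprintf("a%d.%s", descriptors$atom + 1L, descriptors$axis)
  else
    sprintf("d%d-%d", descriptors$atom_i + 1L, descriptors$atom_j + 1L)
}

parse_descriptor_names <- function(nms) {
  if (all(grepl("^a\\d+\\.[xyz]$", nms))) {
    data.frame(atom = as.integer(sub("^a(\\d+)\\..*$", "\\1", nms)) - 1L,
               axis = sub("^a\\d+\\.", "", nms), stringsAsFactors = FALSE)
  } else if (all(grepl("^d\\d+-\\d+$", nms))) {
    data.frame(atom_i = as.integer(sub("^d(\\d+)-\\d+$", "\\1", nms)) - 1L,
               atom_j = as.integer(sub("^d\\d+-(\\d+)$", "\\1", nms)) - 1L)
  } else stop("unrecognized descriptor header", call. = FALSE)
}

#' Write a feature matrix to CSV with a JSON descriptor sidecar
#'
#' The CSV header carries the 1-based descriptor tags (`a3.x` for atom 3's x
#' coordinate, `d3-7` for the pair 3--7); the sidecar `<path>.json` records
#' kind and scaling.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @export
write_feature_csv <- function(fm, path) {
  m <- fm$values
  colnames(m) <- descriptor_names(fm$descriptors)
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(kind = fm$kind, scaling = fm$scaling),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#' @param path CSV path; the `<path>.json` sidecar is used when present.
#' @return a `feature_matrix`.
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  desc <- parse_descriptor_names(names(d))
  kind <- if (!is.null(desc$atom)) "cartesian" else "distance"
  scaling <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$kind)) kind <- meta$kind
    if (!is.null(meta$scaling) && length(meta$scaling))
      scaling <- as.data.frame(meta$scaling)
  }
  feature_matrix(as.matrix(d), desc, kind, scaling)
}

#' Write an importance profile to CSV
#'
#' Long format: feature descriptor, state (`ensemble` or the 0-based state
#' index), importance, standard deviation.
#'
#' @param profile an `importance_profile`.
#' @param descriptors descriptor data.frame (or the `feature_matrix` used).
#' @param path output file.
#' @export
write_profile_csv <- function(profile, descriptors, path) {
  if (inherits(descriptors, "feature_matrix"))
    descriptors <- descriptors$descriptors
  nms <- descriptor_names(descriptors)
  rows <- data.frame(feature = nms, state = "ensemble",
                     importance = as.numeric(profile$per_feature),
                     std = if (is.null(profile$std)) NA_real_
                           else profile$std, stringsAsFactors = FALSE)
  if (!is.null(profile$per_state)) {
    for (s in seq_len(nrow(profile$per_state))) {
      rows <- rbind(rows, data.frame(
        feature = nms, state = as.character(s - 1L),
        importance = as.numeric(profile$per_state[s, ]), std = NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run-metadata JSON
#'
#' Records the configuration, seeds, package and R versions, input checksums
#' and the per-stage feature-count audit trail, so a deterministic run can be
#' reproduced bit-comparably.
#'
#' @param path output JSON file.
#' @param config the run configuration (any list).
#' @param seeds named seeds used.
#' @param inputs character vector of input paths to checksum.
#' @param feature_counts named list of per-stage feature counts.
#' @export
write_manifest <- function(path, config, seeds = list(), inputs = character(),
                           feature_counts = list()) {
  checks <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else NULL
  jsonlite::write_json(list(
    package = "mdrelevance",
    version = as.character(utils::packageVersion("mdrelevance")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, seeds = seeds, input_checksums = checks,
    feature_counts = feature_counts),
    path, digits = NA, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Project per-residue importance onto a structure's B-factor column
#'
#' Every atom of a residue receives B-factor = importance x 100 (importance
#' lives in \[0,1\] and the PDB B-factor field has two decimals), clamped to
#' 99.99. Coordinates are untouched; only the first model of the topology is
#' written.
#'
#' @param per_residue importance vector, one value per residue in residue
#'   order.
#' @param topology path to a PDB file (or the result of
#'   [read_multimodel_pdb()]).
#' @param path output PDB path.
#' @return the path, invisibly.
#' @export
project_importance_to_structure <- function(per_residue, topology, path) {
  top <- if (is.character(topology)) read_multimodel_pdb(topology)
         else topology
  resids <- sort(unique(top$atoms$resid))
  if (length(per_residue) != length(resids))
    stop(sprintf("profile has %d residues but topology has %d",
                 length(per_residue), length(resids)), call. = FALSE)
  b_by_res <- stats::setNames(pmin(per_residue * 100, 99.99),
                              as.character(resids))
  b <- as.numeric(b_by_res[as.character(top$atoms$resid)])
  coords <- top$coords[1, , , drop = FALSE]
  write_multimodel_pdb(coords, path, bfactors = b)
}
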