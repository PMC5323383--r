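#' Ligand pose
#'
#' One docked ligand conformation in the fixed receptor frame: labeled heavy
#' atoms, coordinates, and an estimated binding free energy.
#'
#' @param labels unique atom names (heavy atoms).
#' @param coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param energy binding free energy, kcal/mol (`NA` for a reference pose).
#' @param run_id docking run index.
#' @return object of class `ligand_pose`.
#' @export
ligand_pose <- function(labels, coords, energy = NA_real_, run_id = NA_integer_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(labels))
    ds_format_error("coords must be an n x 3 matrix matching %d labels",
                    length(labels))
  if (anyDuplicated(labels)) ds_format_error("atom labels must be unique")
  if (!all(is.finite(coords))) ds_value_error("non-finite pose coordinates")
  if (length(energy) != 1L || (!is.na(energy) && !is.finite(energy)))
    ds_value_error("energy must be a single finite value or NA")
  dimnames(coords) <- list(labels, c("x", "y", "z"))
  structure(list(labels = as.character(labels), coords = coords,
                 energy = as.numeric(energy), run_id = as.integer(run_id)),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("Ligand pose: %d heavy atoms, energy %s kcal/mol, run %s\n",
              length(x$labels),
              ifelse(is.na(x$energy), "NA", sprintf("%.2f", x$energy)),
              ifelse(is.na(x$run_id), "NA", x$run_id)))
  invisible(x)
}

DLG_ENERGY_TAG <- "Estimated Free Energy of Binding"

#' Read an AutoDock DLG docking log
#'
#' Parses the `DOCKED:` records of an AutoDock 4 docking log: one MODEL block
#' per run with a USER line carrying the estimated free energy of binding and
#' ATOM/HETATM coordinate records. Hydrogens are skipped; energies are
#' kcal/mol as written.
#'
#' @param path DLG file.
#' @return list of [ligand_pose()] objects, one per docked run.
#' @export
read_docking_log <- function(path) {
  if (!file.exists(path)) ds_format_error("docking log not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  docked <- lines[startsWith(lines, "DOCKED:")]
  if (!length(docked))
    ds_format_error("no DOCKED records in %s (empty or not a DLG file)", path)
  body <- sub("^DOCKED:\\s?", "", docked)
  starts <- grep("^MODEL", body)
  ends <- grep("^ENDMDL", body)
  if (!length(starts)) ds_format_error("no MODEL blocks in %s", path)
  if (length(ends) < length(starts))
    ds_format_error("truncated MODEL block (run index %d) in %s",
                    length(ends) + 1L, path)
  lapply(seq_along(starts), function(i) {
    block <- body[starts[i]:ends[i]]
    run <- suppressWarnings(as.integer(sub("^MODEL\\s+", "", block[1])))
    if (is.na(run)) run <- i
    eline <- grep(DLG_ENERGY_TAG, block, fixed = TRUE, value = TRUE)
    if (!length(eline))
      ds_format_error("run %d in %s lacks its binding-energy line", run, path)
    energy <- suppressWarnings(as.numeric(
      sub(".*=\\s*([-+0-9.eE]+).*", "\\1", eline[1])))
    if (is.na(energy))
      ds_format_error("unparsable energy line for run %d in %s", run, path)
    atoms <- block[grepl("^(ATOM|HETATM)", block)]
    if (!length(atoms)) ds_format_error("run %d in %s has no atom records", run, path)
    parsed <- parse_pdb_atom_lines(atoms, path)
    heavy <- parsed$element != "H"
    ligand_pose(parsed$elety[heavy],
                cbind(parsed$x, parsed$y, parsed$z)[heavy, , drop = FALSE],
                energy = energy, run_id = run)
  })
}

# fixed-column PDB ATOM/HETATM parser used for DLG blocks (bio3d expects
# whole files, not extracted record lines)
parse_pdb_atom_lines <- function(atoms, path) {
  elety <- trimws(substr(atoms, 13, 16))
  x <- suppressWarnings(as.numeric(substr(atoms, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(atoms, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(atoms, 47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    ds_format_error("unparsable ATOM record in %s: '%s'",
                    path, atoms[which(is.na(x) | is.na(y) | is.na(z))[1]])
  element <- toupper(trimws(substr(atoms, 77, 78)))
  blank <- !nzchar(element)
  element[blank] <- substr(elety[blank], 1, 1)
  list(elety = elety, x = x, y = y, z = z, element = element)
}

#' Read a pose set from a multi-MODEL PDB plus an energy table
#'
#' Generic alternative to DLG input: the poses as MODEL blocks of one PDB
#' file and a TSV of per-model energies (columns `model`, `energy`, header
#' optional).
#'
#' @param coords_path multi-MODEL PDB of ligand poses.
#' @param energies_path TSV with one energy row per model.
#' @return list of [ligand_pose()].
#' @export
read_pose_set <- function(coords_path, energies_path) {
  if (!file.exists(coords_path)) ds_format_error("pose file not found: %s", coords_path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(coords_path, multi = TRUE, verbose = FALSE)),
    error = function(e) ds_format_error("cannot parse %s: %s",
                                        coords_path, conditionMessage(e)))
  n_models <- nrow(pdb$xyz)
  lines <- readLines(energies_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "[\t ]+")
  if (length(fields) && is.na(suppressWarnings(as.numeric(fields[[1]][1]))))
    fields <- fields[-1]
  if (length(fields) != n_models)
    ds_format_error("%d MODEL blocks in %s but %d energy rows in %s",
                    n_models, coords_path, length(fields), energies_path)
  energies <- vapply(fields, function(f) suppressWarnings(as.numeric(f[2])), 1)
  if (anyNA(energies)) ds_format_error("unparsable energy row in %s", energies_path)
  heavy <- toupper(ifelse(nzchar(trimws(pdb$atom$elesy)), trimws(pdb$atom$elesy),
                          substr(trimws(pdb$atom$elety), 1, 1))) != "H"
  labels <- trimws(pdb$atom$elety)[heavy]
  idx <- which(heavy)
  lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    ligand_pose(labels, xyz, energy = energies[m], run_id = m)
  })
}

#' Read a single reference pose from a PDB file
#'
#' Uses the first MODEL; all heavy atoms (ATOM and HETATM) become the labeled
#' reference. This is the product pose against which docking-pose RMSDs are
#' measured.
#'
#' @param path single-pose PDB.
#' @return a [ligand_pose()] with `energy = NA`.
#' @export
read_reference_pose <- function(path) {
  model <- read_structure(path)
  a <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  if (!nrow(a)) ds_format_error("no heavy atoms in reference pose %s", path)
  ligand_pose(a$elety, as.matrix(a[, c("x", "y", "z")]))
}

#' Docking-pose ensemble
#'
#' All docked poses of one receptor variant plus the reference product pose.
#' Every pose must carry exactly the reference's atom-label set; poses are
#' stored with atoms reordered to the reference order so downstream RMSDs
#' need no per-pose matching.
#'
#' @param poses list of [ligand_pose()] (length >= 1).
#' @param reference a [ligand_pose()]; the product pose.
#' @param variant_id receptor variant (`"wild-type"` or a mutation string).
#' @param ligand_name free-text ligand identifier.
#' @return object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(poses, reference, variant_id = "wild-type",
                          ligand_name = "ligand") {
  if (!length(poses)) ds_format_error("a pose ensemble needs at least one pose")
  stopifnot(inherits(reference, "ligand_pose"))
  poses <- lapply(poses, function(p) {
    stopifnot(inherits(p, "ligand_pose"))
    if (!setequal(p$labels, reference$labels) ||
        length(p$labels) != length(reference$labels))
      ds_stop("dockscape_correspondence_error",
              "pose run %s atom labels do not match the reference", p$run_id)
    ord <- match(reference$labels, p$labels)
    p$coords <- p$coords[ord, , drop = FALSE]
    p$labels <- reference$labels
    p
  })
  structure(list(variant_id = variant_id, ligand_name = ligand_name,
                 poses = poses, reference = reference),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("Pose ensemble '%s': %d poses of %s (%d heavy atoms)\n",
              x$variant_id, length(x$poses), x$ligand_name,
              length(x$reference$labels)))
  invisible(x)
}
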