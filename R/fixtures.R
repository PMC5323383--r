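# Plain-text fixture writers. Each emits a format the corresponding reader
# consumes; generated objects are quantized (coordinates to 0.001 A, energies
# to 1e-4 kcal/mol) so write -> read round-trips are exact.

pdb_atom_line <- function(record, serial, name, resid, chain, resno, xyz,
                          element) {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Write a pose list as an AutoDock-style DLG docking log
#'
#' @param poses list of [ligand_pose()] or a [pose_ensemble()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dlg <- function(poses, path) {
  if (inherits(poses, "pose_ensemble")) poses <- poses$poses
  if (!length(poses)) ds_value_error("refusing to write an empty pose set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("AutoDock-style docking log (synthetic)", ""), con)
  for (p in poses) {
    if (is.na(p$energy))
      ds_value_error("pose run %s has no energy; DLG requires one", p$run_id)
    writeLines(sprintf("DOCKED: MODEL %8d", p$run_id), con)
    writeLines(sprintf(
      "DOCKED: USER    Estimated Free Energy of Binding    = %s kcal/mol  [=(1)+(2)+(3)-(4)]",
      format(p$energy, nsmall = 4, scientific = FALSE)), con)
    for (a in seq_along(p$labels))
      writeLines(paste0("DOCKED: ",
                        pdb_atom_line("ATOM", a, p$labels[a], "LIG", "A", 1L,
                                      p$coords[a, ], substr(p$labels[a], 1, 1))),
                 con)
    writeLines("DOCKED: ENDMDL", con)
  }
  invisible(path)
}

#' Write a pose list as a multi-MODEL PDB plus an energy TSV
#'
#' @param poses list of [ligand_pose()] or a [pose_ensemble()].
#' @param coords_path,energies_path output files.
#' @return invisibly, `coords_path`.
#' @export
write_pose_pdb <- function(poses, coords_path, energies_path) {
  if (inherits(poses, "pose_ensemble")) poses <- poses$poses
  if (!length(poses)) ds_value_error("refusing to write an empty pose set")
  con <- file(coords_path, "w")
  on.exit(close(con))
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    writeLines(sprintf("MODEL %8d", i), con)
    for (a in seq_along(p$labels))
      writeLines(pdb_atom_line("HETATM", a, p$labels[a], "LIG", "A", 1L,
                               p$coords[a, ], substr(p$labels[a], 1, 1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  energies <- vapply(poses, `[[`, 1, "energy")
  utils::write.table(
    data.frame(model = seq_along(poses),
               energy = format(energies, nsmall = 4, scientific = FALSE)),
    energies_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(coords_path)
}

#' Write a single reference pose as PDB
#' @param pose a [ligand_pose()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_reference_pdb <- function(pose, path) {
  stopifnot(inherits(pose, "ligand_pose"))
  lines <- vapply(seq_along(pose$labels), function(a)
    pdb_atom_line("HETATM", a, pose$labels[a], "LIG", "A", 1L,
                  pose$coords[a, ], substr(pose$labels[a], 1, 1)), "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure model as PDB
#' @param model a [structure_model()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  lines <- vapply(seq_len(nrow(a)), function(i)
    pdb_atom_line(if (a$het[i]) "HETATM" else "ATOM", i, a$elety[i],
                  a$resid[i], a$chain[i], a$resno[i],
                  c(a$x[i], a$y[i], a$z[i]), a$element[i]), "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a subfamily alignment as aligned FASTA plus a groups TSV
#'
#' @param aln a [subfamily_alignment()].
#' @param fasta_path aligned FASTA output.
#' @param groups_path two-column TSV output (id, group), no header.
#' @return invisibly, `fasta_path`.
#' @export
write_alignment_fasta <- function(aln, fasta_path, groups_path = NULL) {
  stopifnot(inherits(aln, "subfamily_alignment"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$rows), fasta_path)
  if (!is.null(groups_path))
    utils::write.table(data.frame(names(aln$group_of), unname(aln$group_of)),
                       groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(fasta_path)
}

#' Write a selection table as TSV
#' @param table a [site_selection_table()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_selection_tsv <- function(table, path) {
  stopifnot(inherits(table, "site_selection_table"))
  df <- data.frame(position = table$position, residue = table$residue,
                   posterior = format(table$posterior, scientific = FALSE,
                                      trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bundle of synthetic fixtures
#'
#' Convenience wrapper dispatching each supplied object to its writer.
#'
#' @param out_dir output directory (created if needed).
#' @param ensemble optional [pose_ensemble()]; written both as DLG and as
#'   multi-MODEL PDB + energy TSV, plus the reference pose PDB.
#' @param alignment optional [subfamily_alignment()].
#' @param table optional [site_selection_table()].
#' @param receptor optional [structure_model()].
#' @param prefix file-name prefix for the ensemble files.
#' @return named list of written paths.
#' @export
write_fixtures <- function(out_dir, ensemble = NULL, alignment = NULL,
                           table = NULL, receptor = NULL, prefix = "poses") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) ds_stop("dockscape_io_error",
                                    "cannot create directory %s", out_dir)
  paths <- list()
  if (!is.null(ensemble)) {
    paths$dlg <- file.path(out_dir, paste0(prefix, ".dlg"))
    write_dlg(ensemble, paths$dlg)
    paths$pose_pdb <- file.path(out_dir, paste0(prefix, ".pdb"))
    paths$energies <- file.path(out_dir, paste0(prefix, "_energies.tsv"))
    write_pose_pdb(ensemble, paths$pose_pdb, paths$energies)
    paths$reference <- file.path(out_dir, "reference_pose.pdb")
    write_reference_pdb(ensemble$reference, paths$reference)
  }
  if (!is.null(alignment)) {
    paths$fasta <- file.path(out_dir, "alignment.fasta")
    paths$groups <- file.path(out_dir, "groups.tsv")
    write_alignment_fasta(alignment, paths$fasta, paths$groups)
  }
  if (!is.null(table)) {
    paths$selection <- file.path(out_dir, "selection.tsv")
    write_selection_tsv(table, paths$selection)
  }
  if (!is.null(receptor)) {
    paths$receptor <- file.path(out_dir, "receptor.pdb")
    write_structure_pdb(receptor, paths$receptor)
  }
  paths
}
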