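#' Simulate a complete synthetic input bundle
#'
#' Generates every input the pipeline consumes, with planted truth mirroring
#' the study design the pipeline was built for: a 14-sequence two-group MSA
#' with nine planted SSP columns (including sites 107, 110 and 196), a
#' selection table with planted positively selected sites 109 and 197, a toy
#' receptor whose screen retains exactly sites 107/110/196/197, the mock
#' product pose, and a wild-type pose ensemble plus one ensemble per mutant
#' with planted group-III energy shifts.
#'
#' @param seed master seed; every generator derives its own seed from it.
#' @param out_dir when given, all fixtures are written there and the returned
#'   bundle carries a ready-to-run pipeline config pointing at the files.
#' @param effects named group-III shifts per mutation string
#'   (default [default_mutant_effects()]).
#' @param msa_config,ensemble_config optional overrides of the generator
#'   configurations; seeds inside them are replaced by seeds derived from
#'   `seed`.
#' @return list with the generated objects (`msa`, `selection`, `receptor`,
#'   `reference`, `wild_type`, `mutants`, `effects`), the planted truths, and
#'   (with `out_dir`) `paths` and `config`.
#' @export
simulate_inputs <- function(seed = 1L, out_dir = NULL,
                            effects = default_mutant_effects(),
                            msa_config = NULL, ensemble_config = NULL) {
  seed <- as.integer(seed)
  ssp_cols <- c(50L, 77L, 93L, 107L, 110L, 125L, 150L, 180L, 196L)
  ref_res <- c("107" = "E", "109" = "V", "110" = "R", "196" = "E", "197" = "I")
  if (is.null(msa_config))
    msa_config <- synthetic_msa_config(n_per_group = 7L, length = 220L,
                                       n_ssp = 9L, n_conserved = 100L,
                                       noise_rate = 0.1, gap_rate = 0,
                                       ssp_columns = ssp_cols,
                                       ref_residues = ref_res, seed = seed)
  msa_config$seed <- seed
  msa <- make_subfamily_msa(msa_config)
  wt_map <- reference_residues(msa$alignment)

  psd_positives <- c(109L, 197L)
  sel <- make_selection_table(seq_len(220L), positives = psd_positives,
                              wt_residues = wt_map, seed = seed + 1000L)

  candidate_pos <- sort(c(msa$ssp_columns, psd_positives))
  roles <- stats::setNames(rep("distant", length(candidate_pos)),
                           candidate_pos)
  roles[c("107", "110", "196", "197")] <- "retain"
  roles[c("50", "125", "109")] <- "network"
  reference <- make_mock_ligand(12L, 12)
  receptor <- make_mock_receptor(
    data.frame(position = candidate_pos,
               residue = unname(wt_map[as.character(candidate_pos)]),
               role = unname(roles[as.character(candidate_pos)]),
               stringsAsFactors = FALSE),
    reference_ligand = reference)

  if (is.null(ensemble_config)) ensemble_config <- synthetic_ensemble_config()
  ensemble_config$seed <- seed + 2000L
  wt <- sample_ensemble(ensemble_config, reference, variant_id = "wild-type")
  mutants <- list()
  for (i in seq_along(effects)) {
    cfg_m <- ensemble_config
    cfg_m$seed <- seed + 2000L + i
    mutants[[names(effects)[i]]] <-
      sample_ensemble(cfg_m, reference, effect = effects[[i]],
                      variant_id = names(effects)[i])
  }

  out <- list(msa = msa, selection = sel, receptor = receptor,
              reference = reference, wild_type = wt, mutants = mutants,
              effects = effects, psd_positives = psd_positives,
              loop_positions = c(196L, 197L), seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "alignment.fasta"),
      groups = file.path(out_dir, "groups.tsv"),
      selection = file.path(out_dir, "selection.tsv"),
      receptor = file.path(out_dir, "receptor.pdb"),
      reference = file.path(out_dir, "reference_pose.pdb"),
      wild_type = file.path(out_dir, "wild_type.dlg"))
    write_alignment_fasta(msa$alignment, paths$fasta, paths$groups)
    write_selection_tsv(sel$table, paths$selection)
    write_structure_pdb(receptor$model, paths$receptor)
    write_reference_pdb(reference, paths$reference)
    write_dlg(wt$ensemble, paths$wild_type)
    paths$mutants <- stats::setNames(
      file.path(out_dir, paste0(names(mutants), ".dlg")), names(mutants))
    for (m in names(mutants)) write_dlg(mutants[[m]]$ensemble, paths$mutants[[m]])
    out$paths <- paths
    out$config <- list(
      seed = seed,
      alignment = list(path = paths$fasta, format = "fasta",
                       groups_path = paths$groups, reference_id = "g1_s1"),
      ssp = list(min_conservation = 1, max_gap_fraction = 0.2),
      selection = list(path = paths$selection, dialect = "tsv",
                       threshold = 0.95),
      structure = list(path = paths$receptor, chain = "A",
                       catalytic = c(36L, 48L, 191L), include_ligand = TRUE,
                       distance_cutoff = 10, protect_network = TRUE),
      panel = list(loop_positions = c(196L, 197L)),
      landscape = list(reference_path = paths$reference, k = 4,
                       flip_threshold = 6, epsilon = 0.5,
                       wild_type = list(dlg = paths$wild_type),
                       mutants = lapply(paths$mutants, function(p)
                         list(dlg = p))))
  }
  out
}
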