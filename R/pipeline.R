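#' Run the full mutation-design pipeline
#'
#' Orchestrates the flowchart end to end: SSP detection from the two-group
#' alignment, positive-selection site extraction, candidate merging,
#' structural screening, mutation-panel enumeration, per-variant RMSD--energy
#' landscapes, group-III comparisons, and a ranked report. Stages are
#' skippable: a config that supplies `candidates` directly (or only the
#' `landscape` block) runs in landscape-only mode.
#'
#' @param config a named list, or the path to a YAML file holding one. Blocks
#'   (all optional except `landscape` when the landscape/compare stages run):
#'   \describe{
#'     \item{alignment}{`path`, `format`, `groups_path`, `reference_id`.}
#'     \item{ssp}{`min_conservation`, `max_gap_fraction`.}
#'     \item{selection}{`path`, `dialect`, `threshold`.}
#'     \item{structure}{`path`, `chain`, `catalytic` (residue numbers),
#'       `include_ligand`, `distance_cutoff`, `protect_network`,
#'       `hbond_dist_cutoff`, `hbond_angle_cutoff`.}
#'     \item{panel}{`loop_positions`.}
#'     \item{landscape}{`reference_path`, `k`, `flip_threshold`, `epsilon`,
#'       `energy_top_fraction`, `wild_type` (list with `dlg` or
#'       `coords`+`energies`), `mutants` (named list of the same).}
#'     \item{candidates}{`positions`, `residues` -- bypasses the sequence
#'       stages.}
#'   }
#' @param out_dir run directory; every intermediate artifact is written there
#'   (default: none written).
#' @param seed recorded in the report; the pipeline itself is deterministic
#'   given its inputs.
#' @param stages subset of `c("ssp","psd","screen","panel","landscape",
#'   "compare")`; later stages consume whatever earlier ones produced.
#' @return object of class `ranking_report`: `report` (one row per compared
#'   mutation with origin, screen metrics, `delta_e_iii`, `verdict` and
#'   `rank`), plus `ssps`, `candidates`, `screen`, `panel`, `landscapes`,
#'   `comparisons` and `meta` (seed, config/input digests).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         stages = c("ssp", "psd", "screen", "panel",
                                    "landscape", "compare")) {
  if (is.character(config)) {
    if (!file.exists(config)) ds_config_error("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) ds_config_error("config must be a list or a YAML path")
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- seed %||% config$seed
  out_dir <- out_dir %||% config$out_dir

  do_landscape <- any(c("landscape", "compare") %in% stages)
  if (do_landscape) {
    ls_cfg <- config$landscape
    if (is.null(ls_cfg)) ds_config_error("config lacks the 'landscape' block")
    if (is.null(ls_cfg$reference_path))
      ds_config_error("config lacks landscape$reference_path (the product pose)")
    if (!file.exists(ls_cfg$reference_path))
      ds_config_error("reference pose file not found: %s", ls_cfg$reference_path)
    if (is.null(ls_cfg$wild_type))
      ds_config_error("config lacks landscape$wild_type pose input")
    if ("compare" %in% stages && !length(ls_cfg$mutants))
      ds_config_error("compare stage requested but no landscape$mutants given")
  }

  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(obj, name, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    obj
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, dockscape_error = function(e)
      ds_stop("dockscape_stage_error", "stage '%s' failed: %s",
              name, conditionMessage(e)))
  }

  ssps <- candidates <- screen <- panel <- NULL
  wt_map <- NULL

  if ("ssp" %in% stages && !is.null(config$alignment)) {
    a <- config$alignment
    aln <- run_stage("ssp", read_alignment(a$path, a$format %||% "fasta",
                                           a$groups_path, a$reference_id))
    wt_map <- reference_residues(aln)
    s <- config$ssp %||% list()
    ssps <- run_stage("ssp", detect_ssps(aln, s$min_conservation %||% 1.0,
                                         s$max_gap_fraction %||% 0.2))
    emit(ssps, "ssp.tsv", function(o, p) write_ssp_report(o, tsv_path = p))
  }

  psd_sites <- NULL
  if ("psd" %in% stages && !is.null(config$selection)) {
    psd_sites <- run_stage("psd", {
      s <- config$selection
      tab <- read_selection_table(s$path, s$dialect %||% "tsv")
      select_positive_sites(tab, s$threshold %||% 0.95)
    })
  }

  if (!is.null(config$candidates)) {
    candidates <- data.frame(position = as.integer(config$candidates$positions),
                             residue = toupper(config$candidates$residues),
                             origin = "given", stringsAsFactors = FALSE)
  } else if (!is.null(ssps) || !is.null(psd_sites)) {
    candidates <- run_stage("merge", {
      if (is.null(wt_map))
        ds_config_error("candidate merging needs the alignment block for reference numbering")
      merge_candidates(
        stats::na.omit(ssps$ref_position) %||% integer(0),
        psd_sites$position %||% integer(0), wt_map)
    })
    emit(candidates, "candidates.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  sites <- candidates
  if ("screen" %in% stages && !is.null(config$structure) && !is.null(candidates)) {
    screen <- run_stage("screen", {
      st <- config$structure
      model <- read_structure(st$path)
      act <- active_site(st$catalytic, chain = st$chain %||% "A",
                         include_ligand = st$include_ligand %||% TRUE)
      screen_candidates(model, candidates, act,
                        distance_cutoff = st$distance_cutoff %||% 10,
                        protect_network = st$protect_network %||% TRUE,
                        hbond_dist_cutoff = st$hbond_dist_cutoff %||% 3.5,
                        hbond_angle_cutoff = st$hbond_angle_cutoff %||% 120,
                        chain = st$chain %||% "A")
    })
    emit(screen, "screen.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
    sites <- retained_sites(screen)
  }

  if ("panel" %in% stages && !is.null(sites) && nrow(sites)) {
    panel <- run_stage("panel", {
      enumerate_panel(sites, loop_positions =
                        as.integer(config$panel$loop_positions %||% integer(0)))
    })
    emit(panel, "panel.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  landscapes <- list()
  comparisons <- list()
  report <- NULL
  if (do_landscape) {
    ls_cfg <- config$landscape
    reference <- run_stage("landscape",
                           read_reference_pose(ls_cfg$reference_path))
    fit_one <- function(input, variant) run_stage("landscape", {
      poses <- if (!is.null(input$dlg)) read_docking_log(input$dlg)
        else if (!is.null(input$coords) && !is.null(input$energies))
          read_pose_set(input$coords, input$energies)
        else ds_config_error("pose input for '%s' needs $dlg or $coords+$energies",
                             variant)
      ens <- pose_ensemble(poses, reference, variant_id = variant)
      cluster_groups(build_landscape(ens), k = ls_cfg$k %||% 4L,
                     flip_threshold = ls_cfg$flip_threshold %||% 6.0,
                     seed = seed,
                     energy_top_fraction = ls_cfg$energy_top_fraction %||% 1.0)
    })
    landscapes[["wild-type"]] <- fit_one(ls_cfg$wild_type, "wild-type")
    if (!is.null(out_dir))
      write_landscape(landscapes[["wild-type"]],
                      file.path(out_dir, "landscape_wild-type.tsv"),
                      file.path(out_dir, "groups_wild-type.json"))
    for (m in names(ls_cfg$mutants)) {
      landscapes[[m]] <- fit_one(ls_cfg$mutants[[m]], m)
      if (!is.null(out_dir))
        write_landscape(landscapes[[m]],
                        file.path(out_dir, sprintf("landscape_%s.tsv", m)),
                        file.path(out_dir, sprintf("groups_%s.json", m)))
    }
    if ("compare" %in% stages) {
      eps <- ls_cfg$epsilon %||% 0.5
      for (m in names(ls_cfg$mutants))
        comparisons[[m]] <- run_stage("compare",
          compare_mutant(landscapes[["wild-type"]], landscapes[[m]], eps))
      report <- build_ranking_report(comparisons, candidates, screen, panel, eps)
    }
  }

  meta <- list(seed = seed,
               stages = stages,
               config_digest = digest_object(config),
               input_digests = input_file_digests(config))
  out <- structure(list(report = report, ssps = ssps, candidates = candidates,
                        screen = screen, panel = panel,
                        landscapes = landscapes, comparisons = comparisons,
                        meta = meta),
                   class = "ranking_report")
  if (!is.null(out_dir)) {
    yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
    if (!is.null(report)) {
      utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(report = report, meta = meta),
                           file.path(out_dir, "report.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA,
                           na = "null")
    }
  }
  out
}

build_ranking_report <- function(comparisons, candidates, screen, panel, eps) {
  rows <- lapply(names(comparisons), function(m) {
    cmp <- comparisons[[m]]
    pos <- suppressWarnings(as.integer(gsub("[^0-9]", "", m)))
    origin <- if (!is.null(candidates) && pos %in% candidates$position)
      candidates$origin[match(pos, candidates$position)] else NA_character_
    scr <- if (!is.null(screen) && pos %in% screen$position)
      screen[match(pos, screen$position), c("min_distance", "hbond_member")]
      else data.frame(min_distance = NA_real_, hbond_member = NA)
    in_panel <- !is.null(panel) && m %in% panel$mutation
    data.frame(mutation = m, position = pos, origin = origin,
               min_distance = scr$min_distance,
               hbond_member = scr$hbond_member, in_panel = in_panel,
               delta_e_iii = cmp$delta_e_iii, verdict = cmp$verdict,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  ord <- order(report$delta_e_iii, report$mutation)
  report <- report[ord, , drop = FALSE]
  report$rank <- seq_len(nrow(report))
  rownames(report) <- NULL
  attr(report, "epsilon") <- eps
  report
}

digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(x, tmp)
  unname(tools::md5sum(tmp))
}

input_file_digests <- function(config) {
  paths <- character(0)
  grab <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x) &&
        !dir.exists(x)) paths <<- c(paths, x)
    else if (is.list(x)) lapply(x, grab)
    invisible(NULL)
  }
  grab(config)
  if (!length(paths)) return(character(0))
  digests <- tools::md5sum(unique(paths))
  stats::setNames(unname(digests), basename(names(digests)))
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("Mutation-design pipeline report\n")
  if (!is.null(x$ssps)) cat(sprintf("  SSPs detected: %d\n", nrow(x$ssps)))
  if (!is.null(x$candidates))
    cat(sprintf("  candidate sites: %d\n", nrow(x$candidates)))
  if (!is.null(x$screen))
    cat(sprintf("  retained after screen: %d\n",
                sum(x$screen$verdict == "retain")))
  if (!is.null(x$panel))
    cat(sprintf("  designed mutations: %d\n", nrow(x$panel)))
  if (!is.null(x$report)) {
    cat(sprintf("  compared mutants (epsilon = %.2f kcal/mol):\n",
                attr(x$report, "epsilon")))
    print(x$report[, c("rank", "mutation", "origin", "delta_e_iii", "verdict")],
          row.names = FALSE)
  }
  invisible(x)
}
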