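#' Structural model container
#'
#' A flat atom table for one receptor model. Hetero (ligand) atoms are kept
#' and flagged rather than discarded, since the reference product pose or a
#' docked substrate may be part of the active-site definition.
#'
#' @param atoms data.frame with columns `chain`, `resno` (1-based integer),
#'   `resid` (3-letter residue name), `elety` (atom name), `element`, `x`,
#'   `y`, `z` (Angstrom), `het` (logical).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z", "het")
  if (!all(need %in% names(atoms)))
    ds_format_error("atom table lacks columns: %s",
                    paste(setdiff(need, names(atoms)), collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) ds_format_error("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    ds_format_error("duplicate atom record: %s", key[duplicated(key)][1])
  atoms$resno <- as.integer(atoms$resno)
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure model: %d atoms, %d residues, %d hetero atoms\n",
              nrow(a), length(unique(paste(a$chain, a$resno)[!a$het])),
              sum(a$het)))
  invisible(x)
}

#' Read a PDB structural model
#'
#' Only the first MODEL of a multi-model file is used. Hetero records are
#' flagged as ligand atoms. Insertion codes are rejected.
#'
#' @param path PDB file.
#' @return a [structure_model()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) ds_format_error("PDB file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) ds_format_error("cannot parse PDB %s: %s",
                                        path, conditionMessage(e)))
  a <- pdb$atom
  if (!nrow(a)) ds_format_error("no ATOM/HETATM records in %s", path)
  if (any(nzchar(a$insert) & !is.na(a$insert)))
    ds_format_error("insertion codes are not supported (%s)", path)
  element <- a$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  element[blank] <- substr(trimws(a$elety[blank]), 1, 1)
  chain <- a$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  structure_model(data.frame(
    chain = chain, resno = as.integer(a$resno), resid = trimws(a$resid),
    elety = trimws(a$elety), element = toupper(trimws(element)),
    x = a$x, y = a$y, z = a$z, het = a$type == "HETATM",
    stringsAsFactors = FALSE))
}

#' Active-site definition
#'
#' @param residues catalytic residues: an integer vector of residue numbers
#'   (with `chain` recycled) or a data.frame with columns `chain`, `resno`.
#' @param chain chain id used when `residues` is a plain vector.
#' @param include_ligand when `TRUE`, hetero atoms of the model count as part
#'   of the active site (the reference product/substrate position).
#' @return object of class `active_site`.
#' @export
active_site <- function(residues, chain = "A", include_ligand = TRUE) {
  if (is.data.frame(residues)) {
    stopifnot(all(c("chain", "resno") %in% names(residues)))
    df <- data.frame(chain = as.character(residues$chain),
                     resno = as.integer(residues$resno),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(chain = chain, resno = as.integer(residues),
                     stringsAsFactors = FALSE)
  }
  if (!nrow(df)) ds_value_error("active site needs at least one catalytic residue")
  structure(list(catalytic = df, include_ligand = isTRUE(include_ligand)),
            class = "active_site")
}

# heavy atoms of the model belonging to the active site definition
active_site_atoms <- function(model, active) {
  a <- model$atoms
  key <- paste(a$chain, a$resno)
  akey <- paste(active$catalytic$chain, active$catalytic$resno)
  sel <- (key %in% akey & !a$het) & a$element != "H"
  if (active$include_ligand) sel <- sel | (a$het & a$element != "H")
  a[sel, , drop = FALSE]
}

residue_atoms <- function(model, site) {
  a <- model$atoms
  a[a$chain == site[[1]] & a$resno == as.integer(site[[2]]) & !a$het, ,
    drop = FALSE]
}

min_pair_distance <- function(xyz1, xyz2) {
  # cross squared distances via the expansion |p-q|^2 = |p|^2 + |q|^2 - 2 p.q
  cross <- outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") - 2 * xyz1 %*% t(xyz2)
  sqrt(max(0, min(cross)))
}

#' Minimum heavy-atom distance from a residue to the active site
#'
#' @param model a [structure_model()].
#' @param site `c(chain, residue_number)` (list or vector).
#' @param active an [active_site()].
#' @return distance in Angstrom; `0` when the site residue is itself listed
#'   among the catalytic residues.
#' @export
min_distance_to_active_site <- function(model, site, active) {
  res <- residue_atoms(model, site)
  res <- res[res$element != "H", , drop = FALSE]
  if (!nrow(res))
    ds_reference_error("residue %s:%s absent from the model",
                       site[[1]], site[[2]])
  in_active <- any(active$catalytic$chain == site[[1]] &
                   active$catalytic$resno == as.integer(site[[2]]))
  if (in_active) return(0)
  act <- active_site_atoms(model, active)
  if (!nrow(act)) ds_reference_error("no active-site atoms found in the model")
  min_pair_distance(as.matrix(res[, c("x", "y", "z")]),
                    as.matrix(act[, c("x", "y", "z")]))
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Hydrogen-bond membership of a site in the catalytic network
#'
#' A site is a network member when any of its side-chain N/O heavy atoms lies
#' within `dist_cutoff` of an N/O atom of a catalytic residue or of the
#' ligand. When the model contains hydrogens, a donor--H...acceptor angle of
#' at least `angle_cutoff` is additionally required; models without hydrogens
#' (the common case for docking receptors) use the heavy-atom criterion only.
#'
#' @inheritParams min_distance_to_active_site
#' @param dist_cutoff heavy-atom N/O--N/O distance cutoff, Angstrom.
#' @param angle_cutoff donor--H...acceptor angle cutoff, degrees (applied only
#'   when hydrogens are present).
#' @return list with `member` (logical) and `partners` (data.frame of
#'   contacting atom pairs with distances).
#' @export
hbond_network_member <- function(model, site, active,
                                 dist_cutoff = 3.5, angle_cutoff = 120) {
  res <- residue_atoms(model, site)
  if (!nrow(res))
    ds_reference_error("residue %s:%s absent from the model", site[[1]], site[[2]])
  donors <- res[res$element %in% c("N", "O") &
                !(res$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  act <- active_site_atoms(model, active)
  # the site itself may be listed as catalytic; its own atoms are not partners
  act <- act[!(act$chain == site[[1]] & act$resno == as.integer(site[[2]])), ,
             drop = FALSE]
  acceptors <- act[act$element %in% c("N", "O"), , drop = FALSE]
  empty <- data.frame(site_atom = character(), partner_chain = character(),
                      partner_resno = integer(), partner_atom = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(donors) || !nrow(acceptors))
    return(list(member = FALSE, partners = empty))
  d <- as.matrix(donors[, c("x", "y", "z")])
  p <- as.matrix(acceptors[, c("x", "y", "z")])
  d2 <- outer(rowSums(d^2), rowSums(p^2), "+") - 2 * d %*% t(p)
  dist <- sqrt(pmax(d2, 0))   # pmax(x, 0) keeps the dim attribute of x
  hit <- which(dist <= dist_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(list(member = FALSE, partners = empty))
  hydrogens <- model$atoms[model$atoms$element == "H", , drop = FALSE]
  keep <- rep(TRUE, nrow(hit))
  if (nrow(hydrogens)) {
    hxyz <- as.matrix(hydrogens[, c("x", "y", "z")])
    for (i in seq_len(nrow(hit))) {
      dn <- d[hit[i, 1], ]; ac <- p[hit[i, 2], ]
      keep[i] <- any(vapply(seq_len(nrow(hxyz)), function(h) {
        hp <- hxyz[h, ]
        attached <- sqrt(sum((hp - dn)^2)) <= 1.2 || sqrt(sum((hp - ac)^2)) <= 1.2
        if (!attached) return(FALSE)
        heavy <- if (sqrt(sum((hp - dn)^2)) <= 1.2) dn else ac
        other <- if (identical(heavy, dn)) ac else dn
        v1 <- heavy - hp; v2 <- other - hp
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        ang >= angle_cutoff
      }, logical(1)))
    }
  }
  hit <- hit[keep, , drop = FALSE]
  if (!nrow(hit)) return(list(member = FALSE, partners = empty))
  partners <- data.frame(
    site_atom = donors$elety[hit[, 1]],
    partner_chain = acceptors$chain[hit[, 2]],
    partner_resno = acceptors$resno[hit[, 2]],
    partner_atom = acceptors$elety[hit[, 2]],
    distance = dist[hit], stringsAsFactors = FALSE)
  list(member = TRUE, partners = partners[order(partners$distance), , drop = FALSE])
}

#' Structural screen of candidate mutation sites
#'
#' Codifies the structural inspection step: a candidate is retained when its
#' residue lies within `distance_cutoff` of the active site and (when
#' `protect_network` is on) its side chain does not hydrogen-bond directly
#' into the catalytic network.
#'
#' @param model a [structure_model()].
#' @param candidates a `candidate_sites` data.frame (see
#'   [merge_candidates()]) or any data.frame with `position` and `residue`.
#' @param active an [active_site()].
#' @param distance_cutoff Angstrom; default 10.
#' @param protect_network drop sites hydrogen-bonded to the catalytic
#'   network (default `TRUE`).
#' @param hbond_dist_cutoff,hbond_angle_cutoff see [hbond_network_member()].
#' @param chain chain holding the candidate residues.
#' @return data.frame of class `screen_report`: per candidate, the model
#'   residue, `min_distance`, `hbond_member`, `verdict` (`retain`/`drop`) and
#'   `reason`. A `wt_mismatch` flag marks candidates whose stated wild-type
#'   residue disagrees with the model (reported, never silently corrected).
#' @export
screen_candidates <- function(model, candidates, active,
                              distance_cutoff = 10, protect_network = TRUE,
                              hbond_dist_cutoff = 3.5, hbond_angle_cutoff = 120,
                              chain = "A") {
  stopifnot(is.data.frame(candidates), all(c("position", "residue") %in%
                                           names(candidates)))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    pos <- candidates$position[i]
    site <- list(chain, pos)
    res <- residue_atoms(model, site)
    if (!nrow(res)) {
      return(data.frame(position = pos, residue = candidates$residue[i],
                        model_residue = NA_character_, wt_mismatch = NA,
                        min_distance = NA_real_, hbond_member = NA,
                        verdict = "drop", reason = "unmodeled",
                        stringsAsFactors = FALSE))
    }
    model_res <- bio3d::aa321(res$resid[1])
    mismatch <- !is.na(model_res) && model_res != candidates$residue[i]
    dmin <- min_distance_to_active_site(model, site, active)
    hb <- hbond_network_member(model, site, active,
                               hbond_dist_cutoff, hbond_angle_cutoff)
    retain <- dmin <= distance_cutoff && !(hb$member && protect_network)
    reason <- if (retain) "near active site" else if (dmin > distance_cutoff)
      sprintf("%.1f A beyond %.1f A cutoff", dmin, distance_cutoff) else
      "hydrogen-bonds into catalytic network"
    data.frame(position = pos, residue = candidates$residue[i],
               model_residue = model_res, wt_mismatch = mismatch,
               min_distance = dmin, hbond_member = hb$member,
               verdict = if (retain) "retain" else "drop", reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$wt_mismatch %in% TRUE))
    message(sprintf(
      "note: wild-type residue mismatch between candidates and model at position(s) %s",
      paste(out$position[out$wt_mismatch %in% TRUE], collapse = ", ")))
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Retained sites of a screen report
#' @param report a `screen_report`.
#' @return data.frame of retained candidates.
#' @export
retained_sites <- function(report) {
  report[report$verdict == "retain", c("position", "residue"), drop = FALSE]
}
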