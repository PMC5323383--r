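#' Default physicochemical panel configuration
#'
#' One representative substitution per side-chain class: non-polar (Ala),
#' aromatic (Phe), non-charged polar (Gln), basic (His), acidic (Glu). When
#' the wild-type residue *is* a class representative, the class contributes
#' its within-class alternate instead (A<->V, F<->W, Q<->N, H<->R, E<->D), so
#' an acidic site like Glu107 yields E107D rather than a self-substitution.
#'
#' @return list with `representatives` and `alternates`, both named character
#'   vectors; override entries to change the panel.
#' @export
panel_config <- function() {
  list(representatives = c("non-polar" = "A", aromatic = "F", polar = "Q",
                           basic = "H", acidic = "E"),
       alternates = c(A = "V", F = "W", Q = "N", H = "R", E = "D"))
}

#' Enumerate the mutation panel for one site
#'
#' Produces about five representative substitutions per site, one per
#' physicochemical class, plus a proline substitution for loop sites.
#'
#' @param position 1-based reference position.
#' @param wt wild-type residue (standard one-letter code).
#' @param is_loop append the proline mutant (used for loop sites where a
#'   backbone-rigidifying substitution is informative).
#' @param config a [panel_config()] list (overridable).
#' @return data.frame of class `mutation_panel`: `position`, `wt`, `mutant`,
#'   `class`, `mutation` (e.g. `"I197P"`). Never contains the wild-type
#'   residue as a mutant.
#' @export
enumerate_mutations <- function(position, wt, is_loop = FALSE,
                                config = panel_config()) {
  wt <- toupper(wt)
  if (!wt %in% AA_LETTERS)
    ds_value_error("'%s' is not a standard amino-acid letter", wt)
  reps <- config$representatives
  alts <- config$alternates
  mut <- character(0); cls <- character(0)
  for (k in names(reps)) {
    m <- reps[[k]]
    if (m == wt) m <- alts[[m]]
    if (is.null(m) || is.na(m) || m == wt) next
    mut <- c(mut, m); cls <- c(cls, k)
  }
  if (isTRUE(is_loop) && wt != "P") {
    mut <- c(mut, "P"); cls <- c(cls, "proline")
  }
  keep <- !duplicated(mut)
  out <- data.frame(position = as.integer(position), wt = wt,
                    mutant = mut[keep], class = cls[keep],
                    stringsAsFactors = FALSE)
  out$mutation <- sprintf("%s%d%s", out$wt, out$position, out$mutant)
  class(out) <- c("mutation_panel", "data.frame")
  out
}

#' Enumerate mutation panels for a table of retained sites
#'
#' @param sites data.frame with columns `position`, `residue` (e.g. from
#'   [retained_sites()]); an optional logical `is_loop` column marks loop
#'   sites.
#' @param loop_positions positions treated as loop sites when `sites` has no
#'   `is_loop` column.
#' @param config a [panel_config()] list.
#' @return row-bound `mutation_panel` over all sites.
#' @export
enumerate_panel <- function(sites, loop_positions = integer(),
                            config = panel_config()) {
  stopifnot(is.data.frame(sites), all(c("position", "residue") %in% names(sites)))
  loops <- if ("is_loop" %in% names(sites)) sites$is_loop else
    sites$position %in% loop_positions
  out <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
    enumerate_mutations(sites$position[i], sites$residue[i], loops[i], config)))
  class(out) <- c("mutation_panel", "data.frame")
  out
}
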