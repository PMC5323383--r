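#' Per-site positive-selection table
#'
#' Posterior probabilities that individual reference positions evolve under
#' positive selection, as produced by branch-site Bayes empirical Bayes
#' analyses. This package only consumes such tables; it never runs the tree
#' inference or the codon-model likelihood computation.
#'
#' @param position integer vector of 1-based reference positions (unique).
#' @param residue wild-type one-letter residues at those positions.
#' @param posterior posterior probabilities in \[0, 1\].
#' @param method_tag free-text provenance (e.g. `"branch-site BEB"`).
#' @return data.frame of class `site_selection_table`, sorted by position,
#'   with attribute `method_tag`.
#' @export
site_selection_table <- function(position, residue, posterior,
                                 method_tag = "branch-site BEB") {
  position <- as.integer(position)
  posterior <- as.numeric(posterior)
  residue <- toupper(as.character(residue))
  if (length(position) != length(residue) || length(position) != length(posterior))
    ds_format_error("position, residue and posterior must have equal length")
  if (anyNA(posterior) || any(posterior < 0 | posterior > 1))
    ds_value_error("posterior probabilities must lie in [0, 1]")
  if (anyDuplicated(position))
    ds_format_error("duplicate reference position %d in selection table",
                    position[duplicated(position)][1])
  if (length(residue) && !all(residue %in% AA_LETTERS))
    ds_value_error("non-standard residue letter in selection table")
  ord <- order(position)
  out <- data.frame(position = position[ord], residue = residue[ord],
                    posterior = posterior[ord], stringsAsFactors = FALSE)
  attr(out, "method_tag") <- method_tag
  class(out) <- c("site_selection_table", "data.frame")
  out
}

#' Read a positive-selection site table
#'
#' Two dialects are supported: `"tsv"` (three columns: position, residue,
#' posterior; an optional header line is skipped) and `"beb_block"`, the
#' "Positively selected sites" text block of codeml output, whose lines look
#' like `   197 I      0.962*`.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"beb_block"`.
#' @return a [site_selection_table()].
#' @export
read_selection_table <- function(path, dialect = c("tsv", "beb_block")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) ds_format_error("selection table not found: %s", path)
  if (dialect == "tsv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) ds_format_error("empty selection table: %s", path)
    fields <- strsplit(lines, "[\t ]+")
    # tolerate a header line
    if (is.na(suppressWarnings(as.numeric(fields[[1]][1]))))
      fields <- fields[-1]
    if (!length(fields)) ds_format_error("no data rows in %s", path)
    bad <- vapply(fields, length, 1L) < 3L
    if (any(bad)) ds_format_error("malformed row in %s: '%s'", path,
                                  paste(fields[bad][[1]], collapse = " "))
    m <- do.call(rbind, fields)
    site_selection_table(as.integer(m[, 1]), m[, 2],
                         suppressWarnings(as.numeric(m[, 3])),
                         method_tag = "tsv")
  } else {
    lines <- readLines(path, warn = FALSE)
    start <- grep("Positively selected sites", lines, fixed = TRUE)
    if (!length(start))
      ds_format_error("no 'Positively selected sites' block in %s", path)
    body <- lines[(start[1] + 1L):length(lines)]
    pat <- "^\\s*(\\d+)\\s+([A-Za-z])\\s+([0-9]*\\.?[0-9]+)\\*{0,2}(\\s.*)?$"
    keep <- grepl(pat, body)
    # the block ends at the first non-matching line after data began
    if (any(keep)) {
      first <- which(keep)[1]
      run_end <- first
      while (run_end < length(body) && grepl(pat, body[run_end + 1L]))
        run_end <- run_end + 1L
      body <- body[first:run_end]
    } else ds_format_error("no parsable site lines in BEB block of %s", path)
    pos <- as.integer(sub(pat, "\\1", body))
    res <- toupper(sub(pat, "\\2", body))
    pp <- as.numeric(sub(pat, "\\3", body))
    site_selection_table(pos, res, pp, method_tag = "codeml BEB block")
  }
}

#' Threshold a selection table into positively selected sites
#'
#' @param table a [site_selection_table()].
#' @param threshold posterior-probability cutoff; sites with posterior
#'   strictly greater than `threshold` are kept (default 0.95).
#' @return data.frame with columns `position`, `residue`, sorted by position.
#' @export
select_positive_sites <- function(table, threshold = 0.95) {
  stopifnot(inherits(table, "site_selection_table"))
  keep <- table$posterior > threshold
  out <- data.frame(position = table$position[keep],
                    residue = table$residue[keep], stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Merge SSP and positively selected positions into the candidate-site set
#'
#' Set union of the two position lists, tagged with the origin of each site
#' (`SSP`, `PSD`, or `both`).
#'
#' @param ssp_sites integer vector of reference positions from SSP detection.
#' @param psd_sites integer vector of reference positions from positive
#'   selection.
#' @param wt_map wild-type residues: either a named character vector (names =
#'   reference positions, e.g. from [reference_residues()]) or a single
#'   ungapped reference sequence string.
#' @return data.frame of class `candidate_sites` with columns `position`,
#'   `residue`, `origin`, sorted by position.
#' @export
merge_candidates <- function(ssp_sites, psd_sites, wt_map) {
  ssp_sites <- unique(as.integer(ssp_sites))
  psd_sites <- unique(as.integer(psd_sites))
  if (is.character(wt_map) && is.null(names(wt_map)) && length(wt_map) == 1L) {
    letters1 <- strsplit(toupper(wt_map), "", fixed = TRUE)[[1]]
    wt_map <- stats::setNames(letters1, seq_along(letters1))
  }
  pos <- sort(union(ssp_sites, psd_sites))
  res <- wt_map[as.character(pos)]
  if (anyNA(res))
    ds_reference_error("position %d has no wild-type residue in the reference",
                       pos[is.na(res)][1])
  origin <- ifelse(pos %in% ssp_sites & pos %in% psd_sites, "both",
                   ifelse(pos %in% ssp_sites, "SSP", "PSD"))
  out <- data.frame(position = pos, residue = unname(res), origin = origin,
                    stringsAsFactors = FALSE)
  class(out) <- c("candidate_sites", "data.frame")
  out
}
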