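#' Two-group subfamily alignment
#'
#' Container for a protein multiple sequence alignment whose sequences are
#' partitioned into exactly two subfamily groups (e.g. type-II vs type-I
#' chalcone--flavonone isomerases), with one sequence designated as the
#' reference that defines residue numbering.
#'
#' @param rows named character vector of aligned sequences (upper-case
#'   one-letter amino-acid codes plus `-` for gaps), all of equal length.
#' @param group_of named integer/numeric vector mapping every sequence id in
#'   `rows` to group `1` or `2`. Each group must have at least two members.
#' @param reference_id id of the sequence used for position numbering; must
#'   be a name of `rows`.
#'
#' @return An object of class `subfamily_alignment`: a list with elements
#'   `rows`, `group_of` (integer), and `reference_id`.
#' @seealso [read_alignment()], [detect_ssps()], [map_to_reference()]
#' @export
subfamily_alignment <- function(rows, group_of, reference_id) {
  if (length(rows) < 4L || is.null(names(rows)))
    ds_format_error("alignment needs at least 4 named sequences (2 per group)")
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L || widths[1] < 1L)
    ds_format_error("aligned sequences must all have equal length >= 1")
  bad <- grepl(sprintf("[^%s-]", paste(AA_LETTERS, collapse = "")), rows)
  if (any(bad))
    ds_format_error("sequence '%s' contains characters outside the 20 amino-acid letters and '-'",
                    names(rows)[bad][1])
  missing <- setdiff(names(rows), names(group_of))
  if (length(missing))
    ds_label_error("sequence '%s' has no group label", missing[1])
  group_of <- as.integer(group_of[names(rows)])
  names(group_of) <- names(rows)
  if (anyNA(group_of) || !all(group_of %in% c(1L, 2L)))
    ds_label_error("group labels must be exactly 1 or 2")
  if (any(tabulate(group_of, 2L) < 2L))
    ds_label_error("each group needs at least 2 member sequences")
  if (!reference_id %in% names(rows))
    ds_reference_error("reference sequence '%s' is not in the alignment", reference_id)
  structure(list(rows = rows, group_of = group_of, reference_id = reference_id),
            class = "subfamily_alignment")
}

#' @export
print.subfamily_alignment <- function(x, ...) {
  cat(sprintf("Subfamily alignment: %d sequences x %d columns\n",
              length(x$rows), nchar(x$rows[1])))
  cat(sprintf("  group 1: %s\n", paste(names(x$group_of)[x$group_of == 1L], collapse = ", ")))
  cat(sprintf("  group 2: %s\n", paste(names(x$group_of)[x$group_of == 2L], collapse = ", ")))
  cat(sprintf("  reference (numbering): %s\n", x$reference_id))
  invisible(x)
}

#' Alignment length (columns)
#' @param aln a `subfamily_alignment`.
#' @return integer number of alignment columns.
#' @export
alignment_length <- function(aln) nchar(aln$rows[[1]])

#' Read a two-group protein alignment
#'
#' Loads an aligned FASTA or Clustal file together with a two-column TSV
#' assigning every sequence to subfamily group 1 or 2.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param groups_path TSV with two columns: sequence id, group (1 or 2); no
#'   header.
#' @param reference_id sequence id used for residue numbering.
#' @return a [subfamily_alignment()]; sequence order is preserved as read.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           groups_path, reference_id) {
  format <- match.arg(format)
  if (!file.exists(path)) ds_format_error("alignment file not found: %s", path)
  seqs <- tryCatch({
    if (format == "fasta") {
      s <- Biostrings::readAAStringSet(path)
      stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
    } else {
      a <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
      as.character(Biostrings::unmasked(a))
    }
  }, error = function(e) ds_format_error("cannot parse %s as %s: %s",
                                         path, format, conditionMessage(e)))
  if (length(unique(nchar(seqs))) != 1L)
    ds_format_error("sequences in %s have unequal aligned lengths", path)
  gr <- utils::read.table(groups_path, header = FALSE, sep = "\t",
                          colClasses = "character", col.names = c("id", "group"),
                          strip.white = TRUE)
  group_of <- stats::setNames(suppressWarnings(as.integer(gr$group)), gr$id)
  subfamily_alignment(seqs, group_of, reference_id)
}

#' Consensus residue of an alignment column
#'
#' The consensus is the most frequent non-gap letter, accepted only when its
#' frequency among non-gap entries reaches `min_conservation` and the gap
#' fraction of the column does not exceed `max_gap_fraction`.
#'
#' @param residues character vector of one-letter residues/`-` gaps.
#' @param min_conservation required non-gap frequency in (0, 1].
#' @param max_gap_fraction maximum tolerated gap fraction of the column.
#' @return a single amino-acid letter, or `NA_character_` when no letter
#'   qualifies (including frequency ties at the top).
#' @export
column_consensus <- function(residues, min_conservation = 1.0,
                             max_gap_fraction = 0.2) {
  if (!length(residues)) ds_usage_error("column_consensus() needs a non-empty column")
  residues <- toupper(residues)
  gap_frac <- mean(residues == "-")
  if (gap_frac > max_gap_fraction) return(NA_character_)
  nongap <- residues[residues != "-"]
  if (!length(nongap)) return(NA_character_)
  tab <- table(nongap)
  top <- max(tab)
  if (top / length(nongap) < min_conservation) return(NA_character_)
  winners <- names(tab)[tab == top]
  if (length(winners) > 1L) return(NA_character_)   # ambiguous column
  winners
}

#' Map an alignment column to reference numbering
#'
#' Counts non-gap reference residues up to and including `column`.
#'
#' @param aln a `subfamily_alignment`.
#' @param column 1-based alignment column index.
#' @return 1-based position in the ungapped reference sequence, or
#'   `NA_integer_` when the reference has a gap at that column.
#' @export
map_to_reference <- function(aln, column) {
  len <- alignment_length(aln)
  if (!is.numeric(column) || length(column) != 1L || is.na(column) ||
      column < 1L || column > len)
    ds_bounds_error("column %s out of range 1..%d", format(column), len)
  column <- as.integer(column)
  ref <- strsplit(aln$rows[[aln$reference_id]], "", fixed = TRUE)[[1]]
  if (ref[column] == "-") return(NA_integer_)
  sum(ref[seq_len(column)] != "-")
}

#' Detect subfamily-specific positions (SSPs)
#'
#' An SSP is an alignment column where each of the two groups has its own
#' consensus residue (conserved within the group at `min_conservation`) and
#' the two consensuses differ between the groups.
#'
#' @param aln a `subfamily_alignment`.
#' @param min_conservation within-group conservation required for a group
#'   consensus (default 1, i.e. strict identity within each group).
#' @param max_gap_fraction per-group, per-column gap tolerance.
#' @return data.frame of class `ssp_report` with columns `column`,
#'   `ref_position` (NA where the reference is gapped), `group1_residue`,
#'   `group2_residue`, sorted by column.
#' @export
detect_ssps <- function(aln, min_conservation = 1.0, max_gap_fraction = 0.2) {
  stopifnot(inherits(aln, "subfamily_alignment"))
  len <- alignment_length(aln)
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  g1 <- mat[aln$group_of == 1L, , drop = FALSE]
  g2 <- mat[aln$group_of == 2L, , drop = FALSE]
  ref <- mat[aln$reference_id, ]
  ref_pos <- cumsum(ref != "-")
  hits <- vector("list", len)
  n <- 0L
  for (j in seq_len(len)) {
    c1 <- column_consensus(g1[, j], min_conservation, max_gap_fraction)
    if (is.na(c1)) next
    c2 <- column_consensus(g2[, j], min_conservation, max_gap_fraction)
    if (is.na(c2) || c1 == c2) next
    n <- n + 1L
    hits[[n]] <- data.frame(
      column = j,
      ref_position = if (ref[j] == "-") NA_integer_ else ref_pos[j],
      group1_residue = c1, group2_residue = c2,
      stringsAsFactors = FALSE)
  }
  out <- if (n) do.call(rbind, hits[seq_len(n)]) else
    data.frame(column = integer(), ref_position = integer(),
               group1_residue = character(), group2_residue = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("ssp_report", "data.frame")
  out
}

#' Residues of the ungapped reference sequence
#'
#' @param aln a `subfamily_alignment`.
#' @return named character vector: names are 1-based reference positions,
#'   values the reference residues.
#' @export
reference_residues <- function(aln) {
  ref <- strsplit(aln$rows[[aln$reference_id]], "", fixed = TRUE)[[1]]
  ref <- ref[ref != "-"]
  stats::setNames(ref, seq_along(ref))
}

#' Write an SSP report
#'
#' @param ssps output of [detect_ssps()].
#' @param tsv_path,json_path output paths; either may be `NULL`.
#' @return invisibly, the report.
#' @export
write_ssp_report <- function(ssps, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(ssps, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(ssps, json_path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  invisible(ssps)
}
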