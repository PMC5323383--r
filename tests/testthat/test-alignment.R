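test_that("read_alignment round-trips clustal and fasta with group labels", {
  rows <- c(s1 = "ACDEF", s2 = "ACDEF", s3 = "AGDEF", s4 = "AGDEF")
  aln_file <- withr::local_tempfile(fileext = ".aln")
  groups_file <- withr::local_tempfile(fileext = ".tsv")
  write_clustal_fixture(aln_file, rows)
  writeLines(sprintf("s%d\t%d", 1:4, c(1, 1, 2, 2)), groups_file)

  aln <- read_alignment(aln_file, "clustal", groups_file, "s1")
  expect_s3_class(aln, "subfamily_alignment")
  expect_identical(aln$rows, rows)
  expect_identical(names(aln$rows), c("s1", "s2", "s3", "s4"))
  expect_identical(unname(aln$group_of), c(1L, 1L, 2L, 2L))

  fasta_file <- withr::local_tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(rows)), rows)), fasta_file)
  aln_f <- read_alignment(fasta_file, "fasta", groups_file, "s2")
  expect_identical(aln_f$rows, rows)
  expect_identical(aln_f$reference_id, "s2")
})

test_that("read_alignment rejects missing labels, bad reference, ragged rows", {
  rows <- c(s1 = "ACDEF", s2 = "ACDEF", s3 = "AGDEF", s4 = "AGDEF")
  fasta_file <- withr::local_tempfile(fileext = ".fasta")
  groups_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(as.vector(rbind(paste0(">", names(rows)), rows)), fasta_file)

  writeLines(sprintf("s%d\t%d", 1:3, c(1, 1, 2)), groups_file)  # s4 missing
  expect_error(read_alignment(fasta_file, "fasta", groups_file, "s1"),
               class = "dockscape_label_error")

  writeLines(sprintf("s%d\t%d", 1:4, c(1, 1, 2, 2)), groups_file)
  expect_error(read_alignment(fasta_file, "fasta", groups_file, "s9"),
               class = "dockscape_reference_error")

  writeLines(c(">s1", "ACDEF", ">s2", "ACDE", ">s3", "AGDEF", ">s4", "AGDEF"),
             fasta_file)
  expect_error(read_alignment(fasta_file, "fasta", groups_file, "s1"),
               class = "dockscape_format_error")
})

test_that("synthetic FASTA round-trips byte-identically", {
  msa <- make_subfamily_msa(synthetic_msa_config(n_per_group = 4, length = 60,
                                                 n_ssp = 5, n_conserved = 20,
                                                 seed = 11))
  fa <- withr::local_tempfile(fileext = ".fasta")
  gr <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_fasta(msa$alignment, fa, gr)
  back <- read_alignment(fa, "fasta", gr, "g1_s1")
  expect_identical(back$rows, msa$alignment$rows)
  expect_identical(back$group_of, msa$alignment$group_of)
})

test_that("column_consensus applies conservation and gap thresholds", {
  expect_identical(column_consensus(c("A", "A", "A"), 1.0), "A")
  expect_identical(column_consensus(c("A", "A", "G"), 1.0), NA_character_)
  expect_identical(column_consensus(c("A", "A", "G"), 0.6), "A")
  # 2 gaps of 5 = 0.4 gap fraction, above the 0.2 default
  expect_identical(column_consensus(c("A", "A", "A", "-", "-"), 1.0),
                   NA_character_)
  expect_identical(column_consensus(c("A", "A", "A", "-", "-"), 1.0,
                                    max_gap_fraction = 0.5), "A")
  # top-frequency tie is ambiguous
  expect_identical(column_consensus(c("A", "A", "G", "G"), 0.5), NA_character_)
  expect_error(column_consensus(character(0)), class = "dockscape_usage_error")
})

test_that("map_to_reference counts non-gap reference positions", {
  rows <- c(r = "A-CD", a = "AACD", b = "AACD", c = "GGCD")
  aln <- subfamily_alignment(rows, c(r = 1, a = 1, b = 2, c = 2), "r")
  expect_identical(map_to_reference(aln, 3), 2L)
  expect_identical(map_to_reference(aln, 2), NA_integer_)
  expect_identical(map_to_reference(aln, 1), 1L)
  expect_error(map_to_reference(aln, 5), class = "dockscape_bounds_error")
  expect_error(map_to_reference(aln, 0), class = "dockscape_bounds_error")
})

test_that("map_to_reference matches a cumulative-count oracle on gapped rows", {
  set.seed(42)
  letters20 <- c("A", "C", "D", "E")
  ref <- sample(c(letters20, "-"), 300, replace = TRUE, prob = c(rep(0.2, 4), 0.2))
  ref[1] <- "A"
  other <- function() paste(sample(letters20, 300, TRUE), collapse = "")
  rows <- c(r = paste(ref, collapse = ""), a = other(), b = other(), c = other())
  aln <- subfamily_alignment(rows, c(r = 1, a = 1, b = 2, c = 2), "r")
  for (j in seq_len(300)) {
    expected <- if (ref[j] == "-") NA_integer_ else
      sum(ref[seq_len(j)] != "-")
    expect_identical(map_to_reference(aln, j), expected)
  }
})

test_that("detect_ssps finds differing conserved columns and skips identical ones", {
  rows <- c(a = "A", b = "A", c = "A", d = "G", e = "G", f = "G")
  aln <- subfamily_alignment(rows, c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2), "a")
  hit <- detect_ssps(aln)
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$group1_residue, "A")
  expect_identical(hit$group2_residue, "G")
  expect_identical(hit$ref_position, 1L)

  same <- subfamily_alignment(
    c(a = "W", b = "W", c = "W", d = "W"),
    c(a = 1, b = 1, c = 2, d = 2), "a")
  expect_equal(nrow(detect_ssps(same)), 0L)
})

test_that("detect_ssps equals the exhaustive column oracle on random alignments", {
  set.seed(7)
  for (i in 1:40) {
    aln <- random_alignment(n_per_group = sample(2:5, 1),
                            len = sample(10:60, 1))
    for (mc in c(1.0, 0.7)) {
      got <- detect_ssps(aln, min_conservation = mc)
      want <- ssp_oracle(aln, min_conservation = mc)
      expect_identical(got$column, want$column)
      expect_identical(got$group1_residue, want$group1_residue)
      expect_identical(got$group2_residue, want$group2_residue)
    }
  }
})

test_that("raising min_conservation never increases the SSP count", {
  set.seed(13)
  for (i in 1:20) {
    aln <- random_alignment(n_per_group = 4, len = 40)
    counts <- vapply(c(0.5, 0.7, 0.9, 1.0),
                     function(mc) nrow(detect_ssps(aln, mc)), 1L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("zero-noise synthetic alignments yield exactly the planted SSP columns", {
  for (seed in 1:8) {
    msa <- make_subfamily_msa(synthetic_msa_config(
      n_per_group = 7, length = 220, n_ssp = 9, n_conserved = 100,
      noise_rate = 0, gap_rate = 0, seed = seed))
    hit <- detect_ssps(msa$alignment)
    expect_identical(hit$column, msa$ssp_columns)
    # gap-free alignment: reference numbering equals column numbering
    expect_identical(hit$ref_position, msa$ssp_columns)
  }
})

test_that("ssp reports serialize to TSV and JSON", {
  msa <- make_subfamily_msa(synthetic_msa_config(n_per_group = 3, length = 40,
                                                 n_ssp = 4, n_conserved = 10,
                                                 seed = 2))
  hit <- detect_ssps(msa$alignment)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_ssp_report(hit, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(back$column, hit$column)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$column, hit$column)
})
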