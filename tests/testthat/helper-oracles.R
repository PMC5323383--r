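# Independent oracles and small generators used across the suite. The
# oracles deliberately use naive element-wise loops so they share no code
# path with the implementation they check.

rmsd_oracle <- function(pose, reference) {
  total <- 0
  for (lab in reference$labels) {
    p <- pose$coords[match(lab, pose$labels), ]
    r <- reference$coords[match(lab, reference$labels), ]
    total <- total + (p[1] - r[1])^2 + (p[2] - r[2])^2 + (p[3] - r[3])^2
  }
  unname(sqrt(total / length(reference$labels)))
}

random_pose <- function(n_atoms = 8, scale = 10, energy = NULL) {
  ligand_pose(sprintf("C%d", seq_len(n_atoms)),
              matrix(stats::runif(3 * n_atoms, -scale, scale), ncol = 3),
              energy = if (is.null(energy)) stats::runif(1, -9, -4) else energy,
              run_id = sample.int(10000L, 1))
}

# exhaustive per-column SSP scan, written as plain counting loops
ssp_oracle <- function(aln, min_conservation = 1, max_gap_fraction = 0.2) {
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  g1 <- which(aln$group_of == 1L)
  g2 <- which(aln$group_of == 2L)
  consensus <- function(v) {
    if (sum(v == "-") / length(v) > max_gap_fraction) return(NA)
    v <- v[v != "-"]
    if (!length(v)) return(NA)
    best <- NA; best_n <- 0; tie <- FALSE
    for (a in unique(v)) {
      n <- sum(v == a)
      if (n > best_n) { best <- a; best_n <- n; tie <- FALSE }
      else if (n == best_n) tie <- TRUE
    }
    if (tie || best_n / length(v) < min_conservation) NA else best
  }
  hits <- integer(0); r1 <- character(0); r2 <- character(0)
  for (j in seq_len(ncol(mat))) {
    c1 <- consensus(mat[g1, j]); c2 <- consensus(mat[g2, j])
    if (!is.na(c1) && !is.na(c2) && c1 != c2) {
      hits <- c(hits, j); r1 <- c(r1, c1); r2 <- c(r2, c2)
    }
  }
  data.frame(column = hits, group1_residue = r1, group2_residue = r2,
             stringsAsFactors = FALSE)
}

random_alignment <- function(n_per_group = 3, len = 20, gap_rate = 0.1) {
  alphabet <- c("A", "C", "D", "G", "-")
  n <- 2 * n_per_group
  mat <- matrix(sample(alphabet, n * len, replace = TRUE,
                       prob = c(rep((1 - gap_rate) / 4, 4), gap_rate)),
                nrow = n)
  # keep the reference's first column residue so the row is never all-gap
  mat[1, 1] <- "A"
  ids <- sprintf("s%d", seq_len(n))
  rows <- stats::setNames(apply(mat, 1, paste, collapse = ""), ids)
  subfamily_alignment(rows, stats::setNames(rep(1:2, each = n_per_group), ids),
                      reference_id = "s1")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

write_clustal_fixture <- function(path, rows) {
  ids <- format(names(rows), width = 15)
  writeLines(c("CLUSTAL format alignment (fixture)", "", "",
               paste0(ids, " ", unname(rows)), ""), path)
}

make_points <- function(rmsd, energy, run_id = seq_along(rmsd)) {
  structure(data.frame(run_id = run_id, rmsd = rmsd, energy = energy),
            class = c("landscape_points", "data.frame"))
}
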