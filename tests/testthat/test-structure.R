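make_pdb_fixture <- function(path, extra_model = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A  10       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A  10      -1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A  11       3.000   4.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  SER A  12       6.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  OG  SER A  12       5.000   0.000   0.000  1.00  0.00           O",
    "HETATM    6  C1  LIG A 900       0.500   0.500   0.500  1.00  0.00           C")
  if (extra_model)
    lines <- c("MODEL        1", lines, "ENDMDL", "MODEL        2",
               sub("0.000   0.000   0.000", "9.000   9.000   9.000", lines[1]),
               "ENDMDL")
  writeLines(c(lines, "END"), path)
  path
}

test_that("read_structure parses atoms, flags ligand, keeps first MODEL only", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_pdb_fixture(f)
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 6L)
  expect_equal(sum(m$atoms$het), 1L)
  expect_equal(sort(unique(m$atoms$resno[!m$atoms$het])), c(10L, 11L, 12L))

  make_pdb_fixture(f, extra_model = TRUE)
  m1 <- read_structure(f)
  expect_equal(nrow(m1$atoms), 6L)        # second MODEL discarded
  expect_equal(m1$atoms$x[1], 0)
})

test_that("synthetic receptors round-trip through the PDB writer", {
  rec <- make_mock_receptor(
    data.frame(position = c(107L, 150L), residue = c("E", "A"),
               role = c("retain", "distant")),
    reference_ligand = make_mock_ligand(6, 6))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(rec$model, f)
  back <- read_structure(f)
  expect_equal(back$atoms$x, rec$model$atoms$x)
  expect_equal(back$atoms$resno, rec$model$atoms$resno)
  expect_equal(back$atoms$elety, rec$model$atoms$elety)
  expect_equal(back$atoms$het, rec$model$atoms$het)
})

test_that("min_distance_to_active_site computes the closest heavy-atom pair", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_pdb_fixture(f)
  m <- read_structure(f)
  act <- active_site(10L, include_ligand = FALSE)
  # residue 11 CA at (3,4,0); nearest active atom is residue 10 N at origin
  expect_equal(min_distance_to_active_site(m, list("A", 11L), act), 5.0)
  # a residue listed as catalytic is at distance zero by convention
  expect_equal(min_distance_to_active_site(m, list("A", 10L), act), 0)
  expect_error(min_distance_to_active_site(m, list("A", 99L), act),
               class = "dockscape_reference_error")
})

test_that("min distance matches a brute-force all-pairs scan on random models", {
  set.seed(31)
  for (rep in 1:10) {
    n_res <- 10
    atoms <- do.call(rbind, lapply(seq_len(n_res), function(r)
      data.frame(chain = "A", resno = r, resid = "ALA",
                 elety = c("CA", "CB"), element = "C",
                 x = runif(2, -20, 20), y = runif(2, -20, 20),
                 z = runif(2, -20, 20), het = FALSE)))
    m <- structure_model(atoms)
    act <- active_site(c(1L, 2L), include_ligand = FALSE)
    for (site in 3:10) {
      got <- min_distance_to_active_site(m, list("A", site), act)
      best <- Inf
      s <- atoms[atoms$resno == site, ]
      a <- atoms[atoms$resno %in% 1:2, ]
      for (i in seq_len(nrow(s))) for (j in seq_len(nrow(a)))
        best <- min(best, sqrt((s$x[i] - a$x[j])^2 + (s$y[i] - a$y[j])^2 +
                                 (s$z[i] - a$z[j])^2))
      expect_equal(got, best, tolerance = 1e-12)
    }
  }
})

test_that("hbond_network_member detects planted polar contacts", {
  atoms <- rbind(
    data.frame(chain = "A", resno = 1L, resid = "GLU", elety = c("CA", "OE1"),
               element = c("C", "O"), x = c(1, 0), y = 0, z = 0, het = FALSE),
    data.frame(chain = "A", resno = 5L, resid = "SER", elety = c("CA", "OG"),
               element = c("C", "O"), x = c(3, 2.8), y = 0, z = 0, het = FALSE),
    data.frame(chain = "A", resno = 6L, resid = "THR", elety = c("CA", "OG1"),
               element = c("C", "O"), x = c(6, 5), y = 0, z = 0, het = FALSE))
  m <- structure_model(atoms)
  act <- active_site(1L, include_ligand = FALSE)
  near <- hbond_network_member(m, list("A", 5L), act)
  expect_true(near$member)           # OG at 2.8 A from catalytic OE1
  expect_equal(near$partners$partner_atom, "OE1")
  expect_equal(near$partners$distance, 2.8)
  far <- hbond_network_member(m, list("A", 6L), act)
  expect_false(far$member)           # nearest polar pair at 5.0 A
})

test_that("hbond partner lists equal a brute-force polar-pair enumeration", {
  set.seed(17)
  for (rep in 1:8) {
    elems <- sample(c("C", "N", "O"), 12, TRUE)
    atoms <- data.frame(chain = "A",
                        resno = rep(1:6, each = 2), resid = "ALA",
                        elety = paste0(sample(c("CB", "OG", "ND", "CG",
                                                "OE", "NE"), 12, TRUE),
                                       seq_len(12)),
                        element = elems,
                        x = runif(12, -4, 4), y = runif(12, -4, 4),
                        z = runif(12, -4, 4), het = FALSE)
    m <- structure_model(atoms)
    act <- active_site(1:2, include_ligand = FALSE)
    for (site in 3:6) {
      got <- hbond_network_member(m, list("A", site), act, dist_cutoff = 3.5)
      want <- 0L
      s <- atoms[atoms$resno == site & atoms$element %in% c("N", "O"), ]
      a <- atoms[atoms$resno %in% 1:2 & atoms$element %in% c("N", "O"), ]
      if (nrow(s) && nrow(a))
        for (i in seq_len(nrow(s))) for (j in seq_len(nrow(a)))
          if (sqrt((s$x[i] - a$x[j])^2 + (s$y[i] - a$y[j])^2 +
                     (s$z[i] - a$z[j])^2) <= 3.5) want <- want + 1L
      expect_equal(nrow(got$partners), want)
      expect_equal(got$member, want > 0L)
    }
  }
})

planted_candidates <- function() {
  pos <- c(50L, 77L, 93L, 107L, 109L, 110L, 125L, 150L, 180L, 196L, 197L)
  data.frame(position = pos, residue = rep("A", 11),
             role = ifelse(pos %in% c(107, 110, 196, 197), "retain",
                           ifelse(pos %in% c(50, 109, 125), "network",
                                  "distant")),
             stringsAsFactors = FALSE)
}

test_that("screen_candidates retains exactly the planted near-active sites", {
  cand <- planted_candidates()
  rec <- make_mock_receptor(cand, reference_ligand = make_mock_ligand())
  rep <- screen_candidates(rec$model, cand, rec$active)
  expect_s3_class(rep, "screen_report")
  expect_equal(nrow(rep), 11L)
  expect_setequal(retained_sites(rep)$position, c(107L, 110L, 196L, 197L))
  expect_true(all(rep$hbond_member[rep$position %in% c(50, 109, 125)]))
})

test_that("unresolvable candidates are dropped as unmodeled", {
  cand <- planted_candidates()
  rec <- make_mock_receptor(cand)
  extra <- rbind(cand[, c("position", "residue")],
                 data.frame(position = 999L, residue = "G"))
  rep <- screen_candidates(rec$model, extra, rec$active)
  expect_equal(rep$verdict[rep$position == 999], "drop")
  expect_equal(rep$reason[rep$position == 999], "unmodeled")
})

test_that("loosening the distance cutoff never shrinks the retained set", {
  cand <- planted_candidates()
  rec <- make_mock_receptor(cand, reference_ligand = make_mock_ligand())
  kept <- lapply(c(5, 10, 15, 25), function(cut)
    retained_sites(screen_candidates(rec$model, cand, rec$active,
                                     distance_cutoff = cut))$position)
  for (i in seq_len(length(kept) - 1))
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
})

test_that("verdicts are a pure function of the recorded metrics", {
  cand <- planted_candidates()
  rec <- make_mock_receptor(cand, reference_ligand = make_mock_ligand())
  rep <- screen_candidates(rec$model, cand, rec$active,
                           distance_cutoff = 10, protect_network = TRUE)
  rederived <- ifelse(rep$min_distance <= 10 & !rep$hbond_member,
                      "retain", "drop")
  expect_identical(rep$verdict, rederived)
})
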