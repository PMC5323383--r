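test_that("ligand_rmsd evaluates the fixed-frame formula", {
  ref <- make_mock_ligand(6, 6)
  expect_equal(ligand_rmsd(ref, ref), 0)
  shifted <- ref
  shifted$coords <- ref$coords + matrix(c(3, 0, 0), 6, 3, byrow = TRUE)
  expect_equal(ligand_rmsd(shifted, ref), 3)
  # 3 atoms with per-atom deviations 0, 0, 3 -> sqrt(9/3) = sqrt(3)
  a <- ligand_pose(c("C1", "C2", "C3"), rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  b <- ligand_pose(c("C1", "C2", "C3"), rbind(c(0, 0, 0), c(1, 0, 0), c(2, 3, 0)))
  expect_equal(ligand_rmsd(b, a), sqrt(3))
  # label order must not matter (correspondence is by name)
  swapped <- ligand_pose(c("C3", "C1", "C2"),
                         b$coords[c(3, 1, 2), ])
  expect_equal(ligand_rmsd(swapped, a), sqrt(3))
  expect_error(ligand_rmsd(ligand_pose("X1", rbind(c(0, 0, 0))), a),
               class = "dockscape_correspondence_error")
})

test_that("ligand_rmsd matches the brute-force oracle on random pose pairs", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    a <- random_pose(n)
    b <- random_pose(n)
    expect_equal(ligand_rmsd(a, b), rmsd_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("ligand_rmsd behaves as a metric on fixed-label pose space", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    a <- random_pose(n); b <- random_pose(n); c <- random_pose(n)
    dab <- ligand_rmsd(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, ligand_rmsd(b, a))
    expect_lte(ligand_rmsd(a, c), dab + ligand_rmsd(b, c) + 1e-12)
  }
  a <- random_pose(8)
  expect_identical(ligand_rmsd(a, a), 0)
})

test_that("build_landscape emits one point per pose in input order", {
  ref <- make_mock_ligand(6, 8)
  poses <- lapply(1:5, function(i) {
    p <- ref
    p$coords <- ref$coords + matrix(c(i / 2, 0, 0), 6, 3, byrow = TRUE)
    p$energy <- -5 - i / 10; p$run_id <- i
    p
  })
  ens <- pose_ensemble(poses, ref)
  pts <- build_landscape(ens)
  expect_equal(nrow(pts), 5L)
  expect_equal(pts$run_id, 1:5)
  expect_equal(pts$rmsd, (1:5) / 2)
  expect_equal(pts$energy, -5 - (1:5) / 10)

  same <- pose_ensemble(lapply(1:3, function(i) {
    p <- ref; p$energy <- -6; p$run_id <- i; p
  }), ref)
  expect_true(all(build_landscape(same)$rmsd == 0))
})

test_that("representative picks min energy with rmsd then run_id tie-breaks", {
  pts <- make_points(rmsd = c(1.0, 2.0, 3.0), energy = c(-6.1, -7.3, -5.0))
  expect_equal(representative(pts)$energy, -7.3)
  tie <- make_points(rmsd = c(1.2, 0.8), energy = c(-7.3, -7.3))
  expect_equal(representative(tie)$rmsd, 0.8)
  tie2 <- make_points(rmsd = c(1, 1), energy = c(-7, -7), run_id = c(9L, 4L))
  expect_equal(representative(tie2)$run_id, 4L)
  expect_error(representative(pts[0, ]), class = "dockscape_usage_error")

  set.seed(3)
  for (i in 1:20) {
    m <- make_points(rmsd = runif(100, 0, 8), energy = runif(100, -9, -4))
    got <- representative(m)
    expect_equal(got$energy, min(m$energy))
  }
})

test_that("cluster_groups recovers planted modes and labels the flip mode IV", {
  set.seed(55)
  truth <- sample(1:4, 1200, replace = TRUE)
  centers <- c(0.5, 1.8, 3.5, 7.5)
  means <- c(-5.5, -6.5, -7.5, -7.0)
  pts <- make_points(rmsd = pmax(0.01, centers[truth] + rnorm(1200, 0, 0.08)),
                     energy = means[truth] + rnorm(1200, 0, 0.1))
  lg <- cluster_groups(pts, k = 4)
  expect_s3_class(lg, "landscape_groups")
  expect_equal(sort(lg$groups$label), sort(c("I", "II", "III", "IV")))
  expect_gte(ari(lg$points$group, truth), 0.999)
  expect_equal(lg$groups$label[which.max(lg$groups$rep_rmsd)], "IV")
  expect_gt(lg$groups$rep_rmsd[lg$groups$label == "IV"], 6.0)
  # labels I..III strictly descending in representative energy
  e <- lg$groups$rep_energy[match(c("I", "II", "III"), lg$groups$label)]
  expect_true(all(diff(e) < 0))
  # membership partitions the points
  expect_equal(sum(lg$groups$n), nrow(pts))
  expect_false(anyNA(lg$points$group))
})

test_that("cluster_groups handles k = 1, absent flip modes and degenerate input", {
  pts <- make_points(rmsd = c(0.4, 0.6, 1.9, 3.4, 3.6), energy = c(-5, -6, -7, -8, -6.5))
  one <- cluster_groups(pts, k = 1)
  expect_equal(nrow(one$groups), 1L)
  expect_equal(one$groups$rep_energy, -8)
  expect_equal(one$groups$n, 5L)

  set.seed(66)
  truth <- sample(1:3, 600, replace = TRUE)
  centers <- c(0.5, 1.8, 3.5)
  pts3 <- make_points(rmsd = pmax(0.01, centers[truth] + rnorm(600, 0, 0.05)),
                      energy = c(-5.5, -6.5, -7.5)[truth] + rnorm(600, 0, 0.1))
  lg3 <- cluster_groups(pts3, k = 3)
  expect_setequal(lg3$groups$label, c("I", "II", "III"))

  expect_error(cluster_groups(make_points(rmsd = rep(1, 10),
                                          energy = runif(10, -8, -5)), k = 4),
               class = "dockscape_degenerate_error")
})

test_that("energy_top_fraction clusters only the lowest-energy poses", {
  set.seed(8)
  pts <- make_points(rmsd = runif(400, 0, 5), energy = runif(400, -9, -4))
  lg <- cluster_groups(pts, k = 3, energy_top_fraction = 0.5)
  expect_equal(sum(is.na(lg$points$group)), 200L)
  kept <- pts$energy[!is.na(lg$points$group)]
  expect_lte(max(kept), min(pts$energy[is.na(lg$points$group)]))
})

test_that("compare_mutant applies the group-III decision band", {
  set.seed(12)
  mk <- function(shift) {
    truth <- rep(1:4, each = 100)
    centers <- c(0.5, 1.8, 3.5, 7.5)
    means <- c(-5.5, -6.5, -7.5, -7.0)
    e <- means[truth]
    e[truth == 3] <- e[truth == 3] + shift
    cluster_groups(make_points(
      rmsd = pmax(0.01, centers[truth] + rnorm(400, 0, 0.05)),
      energy = e + rnorm(400, 0, 0.02)))
  }
  wt <- mk(0)
  expect_equal(compare_mutant(wt, mk(-1.2))$verdict, "beneficial")
  expect_equal(compare_mutant(wt, mk(0.9))$verdict, "detrimental")
  self <- compare_mutant(wt, wt)
  expect_equal(self$delta_e_iii, 0)
  expect_equal(self$verdict, "neutral")

  # antisymmetry at epsilon = 0: mirroring group-III energies about the
  # wild-type representative flips the verdict
  dn <- compare_mutant(wt, mk(-0.8), epsilon = 0)
  up <- compare_mutant(wt, mk(0.8), epsilon = 0)
  expect_equal(dn$verdict, "beneficial")
  expect_equal(up$verdict, "detrimental")
  expect_equal(dn$delta_e_iii, -up$delta_e_iii, tolerance = 0.1)
})

test_that("compare_mutant requires a group III on both sides", {
  set.seed(4)
  truth <- rep(1:2, each = 50)
  pts <- make_points(rmsd = pmax(0.01, c(0.5, 7.5)[truth] + rnorm(100, 0, 0.05)),
                     energy = c(-5.5, -7)[truth] + rnorm(100, 0, 0.05))
  lg <- cluster_groups(pts, k = 2)   # groups I and IV only
  full <- cluster_groups(make_points(rmsd = pmax(0.01, runif(100, 0, 4)),
                                     energy = runif(100, -8, -5)), k = 3)
  expect_error(compare_mutant(lg, full), class = "dockscape_comparison_error")
  expect_error(compare_mutant(full, lg), class = "dockscape_comparison_error")
})

test_that("landscape TSV/JSON outputs reproduce the fit", {
  set.seed(19)
  truth <- sample(1:4, 400, TRUE)
  pts <- make_points(rmsd = pmax(0.01, c(0.5, 1.8, 3.5, 7.5)[truth] +
                                   rnorm(400, 0, 0.05)),
                     energy = c(-5.5, -6.5, -7.5, -7)[truth] + rnorm(400, 0, 0.05))
  lg <- cluster_groups(pts)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_landscape(lg, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(back$group, lg$points$group)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$groups$rep_energy, lg$groups$rep_energy)
  expect_equal(j$flip_threshold, 6)
})

test_that("DLG and pose-set readers validate their inputs", {
  f <- withr::local_tempfile(fileext = ".dlg")
  writeLines(character(0), f)
  expect_error(read_docking_log(f), class = "dockscape_format_error")
  writeLines(c("DOCKED: MODEL        1",
               "DOCKED: ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
               "DOCKED: ENDMDL"), f)
  expect_error(read_docking_log(f), class = "dockscape_format_error",
               regexp = "run 1")
  writeLines(c("DOCKED: MODEL        1",
               "DOCKED: USER    Estimated Free Energy of Binding    = -7.2 kcal/mol"),
             f)
  expect_error(read_docking_log(f), class = "dockscape_format_error",
               regexp = "truncated")

  sim <- sample_ensemble(synthetic_ensemble_config(n_poses = 5, seed = 2),
                         make_mock_ligand())
  pdb <- withr::local_tempfile(fileext = ".pdb")
  etsv <- withr::local_tempfile(fileext = ".tsv")
  write_pose_pdb(sim$ensemble, pdb, etsv)
  expect_length(read_pose_set(pdb, etsv), 5L)
  writeLines(c("model\tenergy", sprintf("%d\t-7.0", 1:6)), etsv)
  expect_error(read_pose_set(pdb, etsv), class = "dockscape_format_error")
})
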