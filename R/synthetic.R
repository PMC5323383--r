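#' Mock ligand scaffold
#'
#' A rigid planar zig-zag of labeled heavy atoms spanning `length` Angstrom
#' along its long axis, centered at the origin of the toy receptor frame. It
#' stands in for the docked substrate/product: rigid-body perturbations of it
#' generate pose ensembles with known RMSD structure.
#'
#' @param n_atoms number of heavy atoms (>= 3).
#' @param length end-to-end extent along the long axis, Angstrom.
#' @return a [ligand_pose()] with atoms `C1..Cn` (coordinates quantized to
#'   the 0.001-Angstrom PDB precision so written fixtures round-trip exactly).
#' @export
make_mock_ligand <- function(n_atoms = 12L, length = 12) {
  if (!is.numeric(n_atoms) || n_atoms < 3L)
    ds_value_error("a mock ligand needs at least 3 atoms")
  if (!is.numeric(length) || length <= 0)
    ds_value_error("ligand length must be positive")
  n_atoms <- as.integer(n_atoms)
  x <- seq(-length / 2, length / 2, length.out = n_atoms)
  y <- rep_len(c(0.5, -0.5), n_atoms)
  coords <- cbind(x, y - mean(y), 0)
  coords <- sweep(coords, 2, colMeans(coords))
  ligand_pose(sprintf("C%d", seq_len(n_atoms)), round(coords, 3))
}

#' Flip a pose 180 degrees about a perpendicular axis through its centroid
#'
#' Reproduces the opposite-orientation binding mode: the pose is rotated by
#' pi about the second principal axis (perpendicular to the long axis,
#' through the centroid), which for an extended ligand yields a receptor-frame
#' RMSD of roughly 0.6 x its length.
#'
#' @param pose a [ligand_pose()].
#' @return the flipped [ligand_pose()].
#' @export
flip_pose <- function(pose) {
  stopifnot(inherits(pose, "ligand_pose"))
  cen <- colMeans(pose$coords)
  centered <- sweep(pose$coords, 2, cen)
  u <- svd(centered)$v[, 2]
  rot <- 2 * tcrossprod(u) - diag(3)       # rotation by pi about u
  out <- pose
  out$coords <- round(sweep(centered %*% rot, 2, cen, `+`), 3)
  dimnames(out$coords) <- dimnames(pose$coords)
  out
}

# Rodrigues rotation matrix about unit axis u by angle theta
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Synthetic pose-ensemble configuration
#'
#' Describes the planted structure of a docking-pose ensemble: RMSD modes
#' near the product (defaults 0.5, 1.8, 3.5 Angstrom) plus one flipped mode
#' built by the 180-degree construction, and per-mode Gaussian binding
#' energies honoring the landscape ordering E(I) > E(II) > E(III), with
#' group IV between II and III.
#'
#' @param n_poses ensemble size (default 2000, the scale of an AutoDock
#'   landscape run).
#' @param mode_rmsd_centers RMSD centers of the near-product modes, Angstrom.
#' @param mode_weights sampling weights of all modes (near-product modes
#'   followed by the flip mode); must sum to 1.
#' @param energy_means mode energy means, kcal/mol, same order as the
#'   weights; defaults -5.5/-6.5/-7.5 for modes I..III and -7.0 for the flip.
#' @param energy_sd within-mode energy standard deviation, kcal/mol.
#' @param flip_jitter_sd translation jitter applied to flipped poses,
#'   Angstrom.
#' @param rmsd_tolerance relative spread of realized RMSDs about each mode
#'   center.
#' @param flip_threshold Angstrom; near-product centers must stay below it.
#' @param seed RNG seed used by [sample_ensemble()].
#' @return list of class `synthetic_ensemble_config`.
#' @export
synthetic_ensemble_config <- function(n_poses = 2000L,
                                      mode_rmsd_centers = c(0.5, 1.8, 3.5),
                                      mode_weights = c(0.35, 0.25, 0.25, 0.15),
                                      energy_means = c(-5.5, -6.5, -7.5, -7.0),
                                      energy_sd = 0.05,
                                      flip_jitter_sd = 0.2,
                                      rmsd_tolerance = 0.03,
                                      flip_threshold = 6.0,
                                      seed = 1L) {
  n_modes <- length(mode_rmsd_centers) + 1L   # + flip mode
  if (length(mode_weights) != n_modes || length(energy_means) != n_modes)
    ds_config_error("need %d mode weights and energy means (%d near-product modes + 1 flip)",
                    n_modes, length(mode_rmsd_centers))
  if (abs(sum(mode_weights) - 1) > 1e-8 || any(mode_weights < 0))
    ds_config_error("mode weights must be non-negative and sum to 1")
  if (any(!is.finite(mode_rmsd_centers)) || any(mode_rmsd_centers <= 0))
    ds_config_error("mode RMSD centers must be positive and finite")
  if (any(mode_rmsd_centers >= flip_threshold))
    ds_config_error("near-product RMSD center %.1f A is unreachable: it lies in the flipped regime (>= %.1f A)",
                    max(mode_rmsd_centers), flip_threshold)
  if (energy_sd <= 0) ds_config_error("energy_sd must be positive")
  if (n_poses < 1L) ds_config_error("n_poses must be >= 1")
  structure(list(n_poses = as.integer(n_poses),
                 mode_rmsd_centers = mode_rmsd_centers,
                 mode_weights = mode_weights, energy_means = energy_means,
                 energy_sd = energy_sd, flip_jitter_sd = flip_jitter_sd,
                 rmsd_tolerance = rmsd_tolerance,
                 flip_threshold = flip_threshold, seed = as.integer(seed)),
            class = "synthetic_ensemble_config")
}

# rigid perturbation of centered coords hitting an exact target rmsd:
# small random rotation about the centroid, then a translation along a
# random direction solved from rmsd^2 = r0^2 + 2 s (e . dbar) + s^2
perturb_to_rmsd <- function(centered, target) {
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  theta <- 0.2
  rot <- rotation_matrix(u, theta)
  d <- centered %*% t(rot) - centered
  r0 <- sqrt(mean(rowSums(d * d)))
  if (r0 > 0.5 * target && r0 > 0) {
    theta <- theta * 0.5 * target / r0
    rot <- rotation_matrix(u, theta)
    d <- centered %*% t(rot) - centered
    r0 <- sqrt(mean(rowSums(d * d)))
  }
  it <- 0L
  while (r0 >= 0.9 * target && it < 30L) {
    theta <- theta / 2
    rot <- rotation_matrix(u, theta)
    d <- centered %*% t(rot) - centered
    r0 <- sqrt(mean(rowSums(d * d)))
    it <- it + 1L
  }
  e <- stats::rnorm(3); e <- e / sqrt(sum(e^2))
  dbar <- colMeans(d)
  b <- sum(e * dbar)
  s <- -b + sqrt(b * b + target * target - r0 * r0)
  centered + d + matrix(s * e, nrow(centered), 3, byrow = TRUE)
}

#' Sample a synthetic docking-pose ensemble with planted group structure
#'
#' Draws poses per mode by rigid perturbation of the reference (random small
#' rotation plus a translation solved to hit the mode's RMSD center, up to
#' the configured tolerance); the flip mode uses the 180-degree construction
#' of [flip_pose()] plus translation jitter. Energies are Gaussian per mode;
#' an optional `effect` shifts the group-III mode mean, emulating a mutation
#' that stabilizes or destabilizes the lowest-energy near-product pose.
#'
#' @param cfg a [synthetic_ensemble_config()].
#' @param reference a [ligand_pose()], e.g. [make_mock_ligand()].
#' @param effect planted group-III energy shift, kcal/mol (`NULL` = none).
#' @param variant_id receptor variant id stored in the ensemble.
#' @return list with `ensemble` (a [pose_ensemble()]), `truth` (planted mode
#'   index per pose; the flip mode is the last index), `flip_mode`,
#'   `iii_mode` (index of the lowest-energy near-product mode) and `config`.
#' @export
sample_ensemble <- function(cfg, reference = make_mock_ligand(),
                            effect = NULL, variant_id = "wild-type") {
  stopifnot(inherits(cfg, "synthetic_ensemble_config"),
            inherits(reference, "ligand_pose"))
  set.seed(cfg$seed)
  n_modes <- length(cfg$mode_rmsd_centers) + 1L
  flip_mode <- n_modes
  nonflip_means <- cfg$energy_means[seq_len(n_modes - 1L)]
  iii_mode <- which.min(nonflip_means)
  modes <- sample.int(n_modes, cfg$n_poses, replace = TRUE,
                      prob = cfg$mode_weights)
  cen <- colMeans(reference$coords)
  centered <- sweep(reference$coords, 2, cen)
  flipped <- flip_pose(reference)$coords
  means <- cfg$energy_means
  poses <- vector("list", cfg$n_poses)
  for (i in seq_len(cfg$n_poses)) {
    m <- modes[i]
    xyz <- if (m == flip_mode) {
      flipped + matrix(stats::rnorm(3, sd = cfg$flip_jitter_sd),
                       nrow(flipped), 3, byrow = TRUE)
    } else {
      target <- cfg$mode_rmsd_centers[m] *
        (1 + stats::runif(1, -cfg$rmsd_tolerance, cfg$rmsd_tolerance))
      sweep(perturb_to_rmsd(centered, target), 2, cen, `+`)
    }
    mu <- means[m] + if (!is.null(effect) && m == iii_mode) effect else 0
    poses[[i]] <- ligand_pose(reference$labels, round(xyz, 3),
                              energy = round(stats::rnorm(1, mu, cfg$energy_sd), 4),
                              run_id = i)
  }
  list(ensemble = pose_ensemble(poses, reference, variant_id = variant_id),
       truth = modes, flip_mode = flip_mode, iii_mode = iii_mode, config = cfg)
}

#' Synthetic two-group MSA configuration
#'
#' @param n_per_group sequences per subfamily group (default 7, the scale of
#'   the 14-homolog study design).
#' @param length alignment columns (default 220, a CHI-like core).
#' @param n_ssp planted subfamily-specific columns (default 9).
#' @param n_conserved columns identical across all sequences.
#' @param noise_rate per-cell substitution probability on the remaining
#'   columns.
#' @param gap_rate per-cell gap probability on the remaining columns (SSP and
#'   conserved columns are kept gap-free so the planted signal is exact).
#' @param ssp_columns optional fixed SSP column indices (otherwise sampled).
#' @param ref_residues optional named vector (names = columns) forcing the
#'   group-1/reference residue at those columns; non-SSP forced columns are
#'   made conserved.
#' @param seed RNG seed.
#' @return list of class `synthetic_msa_config`.
#' @export
synthetic_msa_config <- function(n_per_group = 7L, length = 220L, n_ssp = 9L,
                                 n_conserved = 100L, noise_rate = 0.1,
                                 gap_rate = 0.02, ssp_columns = NULL,
                                 ref_residues = NULL, seed = 1L) {
  if (n_ssp + n_conserved > length)
    ds_value_error("n_ssp + n_conserved (%d) exceeds alignment length (%d)",
                   n_ssp + n_conserved, length)
  if (noise_rate < 0 || noise_rate > 1 || gap_rate < 0 || gap_rate > 1)
    ds_value_error("noise_rate and gap_rate must lie in [0, 1]")
  if (n_per_group < 2L) ds_value_error("need at least 2 sequences per group")
  if (!is.null(ssp_columns) && length(unique(ssp_columns)) != n_ssp)
    ds_value_error("ssp_columns must supply %d distinct columns", n_ssp)
  structure(list(n_per_group = as.integer(n_per_group),
                 length = as.integer(length), n_ssp = as.integer(n_ssp),
                 n_conserved = as.integer(n_conserved),
                 noise_rate = noise_rate, gap_rate = gap_rate,
                 ssp_columns = if (is.null(ssp_columns)) NULL else
                   sort(as.integer(ssp_columns)),
                 ref_residues = ref_residues, seed = as.integer(seed)),
            class = "synthetic_msa_config")
}

#' Generate a two-group MSA with planted subfamily-specific positions
#'
#' SSP columns carry residue `a` in every group-1 sequence and a different
#' residue `b` in every group-2 sequence (zero within-group noise); conserved
#' columns carry one residue everywhere; the remaining columns start from a
#' base residue and are substituted/gapped at the configured rates.
#'
#' @param cfg a [synthetic_msa_config()].
#' @return list with `alignment` (a [subfamily_alignment()], reference =
#'   first group-1 sequence) and `ssp_columns` (sorted planted columns).
#' @export
make_subfamily_msa <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_msa_config"))
  set.seed(cfg$seed)
  L <- cfg$length; n <- 2L * cfg$n_per_group
  ssp_cols <- if (is.null(cfg$ssp_columns))
    sort(sample.int(L, cfg$n_ssp)) else cfg$ssp_columns
  forced <- if (is.null(cfg$ref_residues)) integer(0) else
    as.integer(names(cfg$ref_residues))
  pool <- setdiff(seq_len(L), c(ssp_cols, forced))
  cons_extra <- setdiff(forced, ssp_cols)
  n_cons_rand <- max(0L, cfg$n_conserved - length(cons_extra))
  cons_cols <- c(cons_extra, sample(pool, min(n_cons_rand, length(pool))))
  free_cols <- setdiff(seq_len(L), c(ssp_cols, cons_cols))
  base <- sample(AA_LETTERS, L, replace = TRUE)
  if (!is.null(cfg$ref_residues))
    base[forced] <- toupper(cfg$ref_residues)
  mat <- matrix(rep(base, each = n), nrow = n)
  # subfamily signal: group 2 gets a different residue at every SSP column
  g2 <- seq.int(cfg$n_per_group + 1L, n)
  for (j in ssp_cols) {
    alt <- sample(setdiff(AA_LETTERS, base[j]), 1L)
    mat[g2, j] <- alt
  }
  if (length(free_cols) && cfg$noise_rate > 0) {
    for (j in free_cols) {
      hit <- which(stats::runif(n) < cfg$noise_rate)
      for (i in hit) mat[i, j] <- sample(setdiff(AA_LETTERS, mat[i, j]), 1L)
    }
  }
  if (length(free_cols) && cfg$gap_rate > 0) {
    for (j in free_cols) {
      gap <- stats::runif(n) < cfg$gap_rate
      mat[gap, j] <- "-"
    }
  }
  ids <- c(sprintf("g1_s%d", seq_len(cfg$n_per_group)),
           sprintf("g2_s%d", seq_len(cfg$n_per_group)))
  rows <- stats::setNames(apply(mat, 1, paste, collapse = ""), ids)
  group_of <- stats::setNames(rep(c(1L, 2L), each = cfg$n_per_group), ids)
  list(alignment = subfamily_alignment(rows, group_of, reference_id = ids[1]),
       ssp_columns = sort(ssp_cols), config = cfg)
}

#' Generate a selection table with planted positively selected sites
#'
#' Positive sites receive posteriors uniform on (high, 1], all others uniform
#' on \[0, low), so thresholding at `high` recovers the planted set exactly.
#'
#' @param positions reference positions covered by the table.
#' @param positives subset of `positions` planted as positively selected.
#' @param high lower bound of positive-site posteriors (default 0.95).
#' @param low upper bound of background posteriors (default 0.5).
#' @param wt_residues optional named residue vector (names = positions);
#'   random residues otherwise.
#' @param seed RNG seed.
#' @return list with `table` (a [site_selection_table()]) and `positives`.
#' @export
make_selection_table <- function(positions, positives = integer(0),
                                 high = 0.95, low = 0.5, wt_residues = NULL,
                                 seed = 1L) {
  if (high <= low)
    ds_value_error("high (%.2f) must exceed low (%.2f)", high, low)
  positions <- sort(unique(as.integer(positions)))
  positives <- sort(unique(as.integer(positives)))
  if (!all(positives %in% positions))
    ds_value_error("positives must be a subset of positions")
  set.seed(seed)
  pp <- stats::runif(length(positions), 0, low)
  # strictly above `high` even after the 6-decimal quantization below
  pp[positions %in% positives] <-
    pmin(1, pmax(stats::runif(length(positives), high, 1), high + 1e-4))
  res <- if (is.null(wt_residues))
    sample(AA_LETTERS, length(positions), replace = TRUE) else
    unname(wt_residues[as.character(positions)])
  list(table = site_selection_table(positions, res, round(pp, 6),
                                    method_tag = "synthetic planted"),
       positives = positives)
}

#' Build a toy receptor model with planted screening outcomes
#'
#' Constructs a deterministic structural model: catalytic residues ring the
#' origin with inward-pointing polar atoms, and each candidate residue is
#' placed according to its role -- `"retain"` (near the active site, apolar
#' side chain), `"network"` (side-chain oxygen hydrogen-bonded to a catalytic
#' atom, hence dropped under network protection) or `"distant"` (beyond any
#' reasonable distance cutoff).
#'
#' @param candidates data.frame with columns `position`, `residue`, `role`.
#' @param catalytic_positions residue numbers of the catalytic residues.
#' @param reference_ligand optional [ligand_pose()] embedded as hetero atoms.
#' @param chain chain id.
#' @return list with `model` (a [structure_model()]) and `active` (an
#'   [active_site()]).
#' @export
make_mock_receptor <- function(candidates,
                               catalytic_positions = c(36L, 48L, 191L),
                               reference_ligand = NULL, chain = "A") {
  stopifnot(is.data.frame(candidates),
            all(c("position", "residue", "role") %in% names(candidates)))
  if (any(candidates$position %in% catalytic_positions))
    ds_value_error("candidate positions collide with catalytic positions")
  rows <- list()
  add <- function(resno, resid, elety, element, xyz, het = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, elety = elety,
      element = element, x = round(xyz[1], 3), y = round(xyz[2], 3),
      z = round(xyz[3], 3), het = het, stringsAsFactors = FALSE)
  ncat <- length(catalytic_positions)
  cat_names <- rep_len(c("GLU", "THR", "ASN"), ncat)
  cat_polar <- rep_len(c("OE1", "OG1", "OD1"), ncat)
  polar_xyz <- matrix(0, ncat, 3)
  for (j in seq_len(ncat)) {
    phi <- 2 * pi * (j - 1) / ncat
    polar_xyz[j, ] <- c(3 * cos(phi), 3 * sin(phi), 0)
    add(catalytic_positions[j], cat_names[j], "CA", "C",
        c(4.5 * cos(phi), 4.5 * sin(phi), 0.8))
    add(catalytic_positions[j], cat_names[j], cat_polar[j], "O", polar_xyz[j, ])
  }
  for (i in seq_len(nrow(candidates))) {
    pos <- candidates$position[i]
    res3 <- bio3d::aa123(candidates$residue[i])
    psi <- 2 * pi * (i - 1) / nrow(candidates) + 0.3
    switch(candidates$role[i],
      retain = {
        add(pos, res3, "CA", "C", c(8 * cos(psi), 8 * sin(psi), 2))
        add(pos, res3, "CB", "C", c(7 * cos(psi), 7 * sin(psi), 1.5))
      },
      network = {
        jcat <- 1L + (i %% ncat)
        add(pos, res3, "CA", "C", c(6 * cos(psi), 6 * sin(psi), 3))
        add(pos, res3, "OG", "O", polar_xyz[jcat, ] + c(0, 0, 2.8))
      },
      distant = {
        add(pos, res3, "CA", "C", c(25 * cos(psi), 25 * sin(psi), 5))
        add(pos, res3, "CB", "C", c(24 * cos(psi), 24 * sin(psi), 5))
      },
      ds_value_error("unknown candidate role '%s'", candidates$role[i]))
  }
  if (!is.null(reference_ligand)) {
    for (a in seq_along(reference_ligand$labels))
      add(900L, "LIG", reference_ligand$labels[a], "C",
          reference_ligand$coords[a, ], het = TRUE)
  }
  model <- structure_model(do.call(rbind, rows))
  list(model = model,
       active = active_site(catalytic_positions, chain = chain,
                            include_ligand = !is.null(reference_ligand)))
}

#' Planted mutant effects mirroring a validated activity sign pattern
#'
#' Group-III energy shifts (kcal/mol) for six mutants: two beneficial
#' (negative shift), one neutral (zero), three detrimental (positive). The
#' magnitudes are the generator's own; only the sign pattern reflects the
#' validated activity changes.
#'
#' @return named numeric vector of group-III energy shifts.
#' @export
default_mutant_effects <- function() {
  c(I197P = -1.5, R110A = -1.2, E107D = 0.0,
    E107Q = 0.8, R110E = 0.6, R110H = 1.0)
}
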