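#' Receptor-frame ligand RMSD
#'
#' Root-mean-square deviation between matched heavy atoms of two poses in the
#' same receptor frame, *without* superposition: both poses are docking
#' outcomes (or the crystal product) in one fixed coordinate system, so the
#' deviation measures displacement within the active site. Atom
#' correspondence is by name; no symmetry correction is applied.
#'
#' @param pose,reference [ligand_pose()] objects with identical label sets.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pose, reference) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(reference, "ligand_pose"))
  if (length(pose$labels) != length(reference$labels) ||
      !setequal(pose$labels, reference$labels))
    ds_stop("dockscape_correspondence_error",
            "atom labels of the two poses do not correspond")
  ord <- match(reference$labels, pose$labels)
  d <- pose$coords[ord, , drop = FALSE] - reference$coords
  sqrt(mean(rowSums(d * d)))
}

#' Build the RMSD--energy landscape of an ensemble
#'
#' @param ensemble a [pose_ensemble()].
#' @return data.frame of class `landscape_points` with one row per pose:
#'   `run_id`, `rmsd` (Angstrom vs the reference product pose), `energy`
#'   (kcal/mol); input order preserved.
#' @export
build_landscape <- function(ensemble) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  ref <- ensemble$reference$coords
  out <- data.frame(
    run_id = vapply(ensemble$poses, `[[`, 1L, "run_id"),
    rmsd = vapply(ensemble$poses, function(p) {
      d <- p$coords - ref                  # atoms pre-ordered by pose_ensemble()
      sqrt(mean(rowSums(d * d)))
    }, 1),
    energy = vapply(ensemble$poses, `[[`, 1, "energy"))
  attr(out, "variant_id") <- ensemble$variant_id
  class(out) <- c("landscape_points", "data.frame")
  out
}

#' Lowest-energy representative of a pose group
#'
#' @param members data.frame with columns `rmsd`, `energy`, `run_id`.
#' @return the single member row with minimum energy; ties broken by lower
#'   RMSD, then lower run id.
#' @export
representative <- function(members) {
  if (!NROW(members)) ds_usage_error("representative() of an empty group")
  ord <- order(members$energy, members$rmsd, members$run_id)
  members[ord[1], , drop = FALSE]
}

# deterministic quantile initialization for 1-D k-means: k centers at evenly
# spaced quantiles of the rmsd values; falls back to evenly spaced distinct
# values when quantiles coincide
kmeans_init_1d <- function(x, k) {
  centers <- as.numeric(stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                                        names = FALSE, type = 7))
  if (anyDuplicated(centers)) {
    ux <- sort(unique(x))
    centers <- ux[unique(round(seq(1, length(ux), length.out = k)))]
  }
  centers
}

#' Cluster landscape points into groups I--IV
#'
#' One-dimensional k-means on the RMSD axis (Lloyd iterations from a
#' deterministic quantile initialization), followed by the labeling policy:
#' clusters whose lowest-energy representative lies beyond `flip_threshold`
#' are the flipped-orientation group IV; the remaining clusters are labeled
#' I, II, III, ... in strictly descending representative-energy order, so
#' group I is the highest-energy (initial binding) mode and group III the
#' lowest-energy near-product mode.
#'
#' @param points a `landscape_points` data.frame (see [build_landscape()]).
#' @param k number of clusters (default 4).
#' @param flip_threshold RMSD above which a cluster is the flipped
#'   orientation, Angstrom (default 6).
#' @param seed recorded for provenance; the procedure itself is deterministic.
#' @param energy_top_fraction optionally cluster only this lowest-energy
#'   fraction of the poses (default 1 = all poses); excluded poses get group
#'   `NA`.
#' @return object of class `landscape_groups`: `points` (input plus a `group`
#'   label column), `groups` (per-group summary with representative pose,
#'   RMSD range and size), and the clustering settings.
#' @export
cluster_groups <- function(points, k = 4L, flip_threshold = 6.0, seed = NULL,
                           energy_top_fraction = 1.0) {
  stopifnot(is.data.frame(points), all(c("rmsd", "energy", "run_id") %in%
                                       names(points)))
  k <- as.integer(k)
  if (k < 1L) ds_usage_error("k must be >= 1")
  active <- rep(TRUE, nrow(points))
  if (energy_top_fraction < 1) {
    n_keep <- max(k, ceiling(energy_top_fraction * nrow(points)))
    active <- rank(points$energy, ties.method = "first") <= n_keep
  }
  x <- points$rmsd[active]
  if (length(unique(x)) < k)
    ds_stop("dockscape_degenerate_error",
            "only %d distinct RMSD values for k = %d; use a smaller k",
            length(unique(x)), k)
  run_km <- function(centers)
    tryCatch(suppressWarnings(
      stats::kmeans(matrix(x, ncol = 1), centers = matrix(centers, ncol = 1),
                    iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL)
  fit <- if (k == 1L) list(cluster = rep(1L, length(x)), iter = 0L) else
    run_km(kmeans_init_1d(x, k))
  if (k > 1L && (is.null(fit) || length(unique(fit$cluster)) < k)) {
    # quantile seeding can drop a sparse mode; fall back to evenly spaced
    # distinct values, which cannot seed two centers on one tied value
    ux <- sort(unique(x))
    fit <- run_km(ux[round(seq(1, length(ux), length.out = k))])
  }
  if (is.null(fit) || length(unique(fit$cluster)) < k)
    ds_stop("dockscape_degenerate_error",
            "clustering into %d groups left empty groups; use a smaller k", k)
  assign <- rep(NA_integer_, nrow(points))
  assign[active] <- fit$cluster
  reps <- do.call(rbind, lapply(seq_len(k), function(g)
    representative(points[which(assign == g), , drop = FALSE])))
  sizes <- tabulate(assign, k)
  is_flip <- reps$rmsd > flip_threshold
  label <- character(k)
  if (any(is_flip)) {
    flips <- which(is_flip)[order(-reps$energy[is_flip])]
    label[flips] <- if (length(flips) == 1L) "IV" else
      paste0("IV", letters[seq_along(flips)])
  }
  if (any(!is_flip)) {
    nf <- which(!is_flip)[order(-reps$energy[!is_flip], reps$rmsd[!is_flip])]
    romans <- setdiff(as.character(utils::as.roman(seq_len(k + 1L))), "IV")
    label[nf] <- romans[seq_along(nf)]
  }
  groups <- data.frame(
    label = label, n = sizes,
    rmsd_min = vapply(seq_len(k), function(g) min(points$rmsd[which(assign == g)]), 1),
    rmsd_max = vapply(seq_len(k), function(g) max(points$rmsd[which(assign == g)]), 1),
    rep_run_id = reps$run_id, rep_rmsd = reps$rmsd, rep_energy = reps$energy,
    stringsAsFactors = FALSE)
  groups <- groups[order(match(groups$label, c(as.character(utils::as.roman(1:10))),
                               nomatch = 99L)), , drop = FALSE]
  rownames(groups) <- NULL
  points$group <- label[assign]
  structure(list(points = points, groups = groups, k = k,
                 flip_threshold = flip_threshold, seed = seed,
                 energy_top_fraction = energy_top_fraction,
                 variant_id = attr(points, "variant_id")),
            class = "landscape_groups")
}

#' Representative of one labeled group
#' @param x a `landscape_groups` object.
#' @param label group label, e.g. `"III"`.
#' @return one-row data.frame (`run_id`, `rmsd`, `energy`) or `NULL` when the
#'   label is absent.
#' @export
group_representative <- function(x, label) {
  stopifnot(inherits(x, "landscape_groups"))
  g <- x$groups[x$groups$label == label, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  data.frame(run_id = g$rep_run_id, rmsd = g$rep_rmsd, energy = g$rep_energy)
}

#' @export
print.landscape_groups <- function(x, ...) {
  cat(sprintf("RMSD-energy landscape%s: %d poses, k = %d, flip threshold %.1f A\n",
              if (!is.null(x$variant_id)) sprintf(" (%s)", x$variant_id) else "",
              nrow(x$points), x$k, x$flip_threshold))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' @export
summary.landscape_groups <- function(object, ...) {
  cat(sprintf("Landscape of %d docking poses in %d groups\n",
              nrow(object$points), nrow(object$groups)))
  g <- object$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  group %-3s %5d poses, rmsd %.2f-%.2f A, representative run %d: %.2f A, %.2f kcal/mol\n",
                g$label[i], g$n[i], g$rmsd_min[i], g$rmsd_max[i],
                g$rep_run_id[i], g$rep_rmsd[i], g$rep_energy[i]))
  invisible(g)
}

#' Plot the RMSD--binding-energy landscape
#'
#' Scatter of binding energy against RMSD to the product pose, colored by
#' group, with group representatives marked. With `overlay`, a second
#' landscape (e.g. a mutant over the wild type) is drawn in red.
#'
#' @param x a `landscape_groups` object.
#' @param overlay optional second `landscape_groups` drawn in red.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.landscape_groups <- function(x, overlay = NULL, ...) {
  pts <- x$points
  labs <- unique(stats::na.omit(pts$group))
  pal <- stats::setNames(grDevices::hcl.colors(max(3L, length(labs)), "Dark 2"),
                         sort(labs))
  col <- if (is.null(overlay)) pal[pts$group] else
    grDevices::adjustcolor("steelblue", 0.5)
  graphics::plot(pts$rmsd, pts$energy, pch = 16, cex = 0.4, col = col,
                 xlab = "RMSD to product pose (Å)",
                 ylab = "binding energy (kcal/mol)", ...)
  if (!is.null(overlay)) {
    graphics::points(overlay$points$rmsd, overlay$points$energy, pch = 16,
                     cex = 0.4, col = grDevices::adjustcolor("firebrick", 0.5))
    graphics::legend("topright", legend = c(x$variant_id %||% "wild-type",
                                            overlay$variant_id %||% "mutant"),
                     col = c("steelblue", "firebrick"), pch = 16, bty = "n")
  } else {
    graphics::points(x$groups$rep_rmsd, x$groups$rep_energy, pch = 8, cex = 1.2)
    graphics::text(x$groups$rep_rmsd, x$groups$rep_energy, x$groups$label,
                   pos = 3, cex = 0.9)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-III decision rule: compare a mutant landscape with the wild type
#'
#' The group-III representative is the lowest-energy near-product pose. A
#' mutation that lowers this energy by more than `epsilon` is predicted
#' beneficial for activity; one that raises it by more than `epsilon`,
#' detrimental; otherwise neutral.
#'
#' @param wt,mut `landscape_groups` for the wild-type and mutant ensembles;
#'   both must contain a group III.
#' @param epsilon decision band, kcal/mol (default 0.5, a typical
#'   docking-score noise scale).
#' @return object of class `mutant_comparison` with `delta_e_iii`
#'   (mutant minus wild-type representative energy), `verdict`, `epsilon`,
#'   and the two representatives.
#' @export
compare_mutant <- function(wt, mut, epsilon = 0.5) {
  stopifnot(inherits(wt, "landscape_groups"), inherits(mut, "landscape_groups"))
  rw <- group_representative(wt, "III")
  rm_ <- group_representative(mut, "III")
  if (is.null(rw) || is.null(rm_))
    ds_stop("dockscape_comparison_error",
            "group III missing from the %s landscape",
            if (is.null(rw)) "wild-type" else "mutant")
  delta <- rm_$energy - rw$energy
  verdict <- if (delta < -epsilon) "beneficial" else
    if (delta > epsilon) "detrimental" else "neutral"
  structure(list(delta_e_iii = delta, verdict = verdict, epsilon = epsilon,
                 wt_representative = rw, mut_representative = rm_,
                 wt_variant = wt$variant_id %||% "wild-type",
                 mut_variant = mut$variant_id %||% "mutant"),
            class = "mutant_comparison")
}

#' @export
print.mutant_comparison <- function(x, ...) {
  cat(sprintf("Group-III comparison %s vs %s:\n", x$mut_variant, x$wt_variant))
  cat(sprintf("  delta E(III) = %+.3f kcal/mol (epsilon = %.2f) -> %s\n",
              x$delta_e_iii, x$epsilon, x$verdict))
  invisible(x)
}

#' Write landscape outputs
#'
#' @param groups a `landscape_groups` object.
#' @param tsv_path per-pose table (`run_id`, `rmsd`, `energy`, `group`).
#' @param json_path group summary (representatives, ranges) as JSON.
#' @return invisibly, `groups`.
#' @export
write_landscape <- function(groups, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(groups, "landscape_groups"))
  if (!is.null(tsv_path))
    utils::write.table(groups$points, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(variant_id = groups$variant_id, k = groups$k,
           flip_threshold = groups$flip_threshold,
           groups = groups$groups),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(groups)
}
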