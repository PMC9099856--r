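#' Scored ligand pose ensemble
#'
#' All poses share one ligand topology (the `template` structure); each
#' pose is a coordinate replacement plus a free-energy score and a source
#' receptor-state identifier, the unit of ensemble binding-space analysis.
#'
#' @param template ligand `mol_structure` defining topology and atom order.
#' @param xyz list of n x 3 coordinate matrices, one per pose.
#' @param delta_g numeric pose scores, kcal/mol (`NA` allowed until
#'   filtering).
#' @param state character source receptor-state id per pose.
#' @param site_label optional per-pose site label (`"S1"`, `"S2"`,
#'   `"intermediate"`).
#' @return an object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(template, xyz, delta_g = rep(NA_real_, length(xyz)),
                          state = rep("state1", length(xyz)),
                          site_label = rep(NA_character_, length(xyz))) {
  stopifnot(inherits(template, "mol_structure"))
  n_atom <- nrow(template$atoms)
  ok <- vapply(xyz, function(m) is.matrix(m) && nrow(m) == n_atom &&
                 ncol(m) == 3, logical(1))
  if (!all(ok)) stop("all poses must share the template atom count")
  if (length(delta_g) != length(xyz) || length(state) != length(xyz))
    stop("delta_g and state must have one entry per pose")
  structure(list(template = template, xyz = xyz,
                 delta_g = as.numeric(delta_g), state = as.character(state),
                 site_label = site_label),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("<pose_ensemble: %d poses, %d atoms, states: %s>\n",
              length(x$xyz), nrow(x$template$atoms),
              paste(unique(x$state), collapse = ", ")))
  invisible(x)
}

#' @export
length.pose_ensemble <- function(x) length(x$xyz)

#' Materialize ensemble poses as structures
#' @param ensemble a `pose_ensemble` or a list of `mol_structure` poses.
#' @return list of `mol_structure` objects.
#' @export
ensemble_poses <- function(ensemble) {
  if (inherits(ensemble, "pose_ensemble")) {
    lapply(ensemble$xyz, function(m) {
      s <- ensemble$template; coords(s) <- m; s
    })
  } else if (is.list(ensemble)) {
    ensemble
  } else stop("not a pose ensemble")
}

#' Retain the most energetically favourable poses
#'
#' Keeps the `max_n` poses with the lowest (most favourable) free energy,
#' sorted ascending; ties are broken by input order. Idempotent.
#'
#' @param ensemble a `pose_ensemble`; every pose must be scored.
#' @param max_n maximum number of poses retained (default 80).
#' @return the filtered, sorted `pose_ensemble`.
#' @export
filter_top_poses <- function(ensemble, max_n = 80) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  if (anyNA(ensemble$delta_g))
    stop("input error: unscored pose(s) in ensemble")
  ord <- order(ensemble$delta_g)  # stable for ties
  keep <- ord[seq_len(min(length(ord), max_n))]
  pose_ensemble(ensemble$template, ensemble$xyz[keep],
                ensemble$delta_g[keep], ensemble$state[keep],
                ensemble$site_label[keep])
}

#' @keywords internal
rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Kabsch optimal rigid superposition of b onto a (both k x 3)
#' @keywords internal
kabsch_superpose <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(b0, a0)
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(b0 %*% t(rot), 2, ca, "+")
}

#' Root-mean-square deviation between two poses
#'
#' Heavy atoms only, identical atom order required. Without superposition
#' the rmsd is measured in the common receptor frame (binding-mode
#' displacement); with `superpose = TRUE` it is computed after optimal
#' rigid (Kabsch) alignment, reflecting intramolecular flexibility only.
#'
#' @param a,b ligand `mol_structure` poses with identical atom order.
#' @param superpose align `b` onto `a` first.
#' @return rmsd in Angstrom.
#' @export
pose_rmsd <- function(a, b, superpose = FALSE) {
  if (nrow(a$atoms) != nrow(b$atoms))
    stop("input error: atom-count mismatch")
  h <- heavy_idx(a)
  xa <- coords(a)[h, , drop = FALSE]
  xb <- coords(b)[h, , drop = FALSE]
  if (superpose) xb <- kabsch_superpose(xa, xb)
  rmsd_xyz(xa, xb)
}

#' @keywords internal
ensemble_rmsd_matrix <- function(ensemble, superpose = FALSE) {
  h <- heavy_idx(ensemble$template)
  xs <- lapply(ensemble$xyz, function(m) m[h, , drop = FALSE])
  n <- length(xs)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xj <- if (superpose) kabsch_superpose(xs[[i]], xs[[j]]) else xs[[j]]
      d[i, j] <- d[j, i] <- rmsd_xyz(xs[[i]], xj)
    }
  }
  d
}

#' Parameterize the binding space of a scored pose ensemble
#'
#' Summary statistics of the pose free energies (sample mean and SD, mode
#' as the centre of the most populated 0.5 kcal/mol bin anchored at the
#' minimum, range), the sensitivity score (free-energy range divided by the
#' mean pairwise superposed conformational rmsd: the capacity of the ligand
#' to vary its free energy by adjusting its own conformation), the mean
#' pairwise displacement rmsd (no superposition: exploration of the binding
#' site), and per-receptor-state pose counts.
#'
#' @param ensemble a scored `pose_ensemble`.
#' @param bin_width mode bin width in kcal/mol.
#' @return object of class `binding_space_summary` (a list).
#' @export
binding_space_summary <- function(ensemble, bin_width = 0.5) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  dg <- ensemble$delta_g
  if (!length(dg) || anyNA(dg)) stop("input error: ensemble must be scored")
  n <- length(dg)
  bins <- floor((dg - min(dg)) / bin_width)
  counts <- table(bins)
  top_bin <- as.integer(names(counts)[which.max(counts)])
  mode_dg <- min(dg) + (top_bin + 0.5) * bin_width
  out <- list(
    n_poses = n,
    mean_dg = mean(dg),
    sd_dg = if (n >= 2) stats::sd(dg) else NA_real_,
    mode_dg = mode_dg,
    range_dg = max(dg) - min(dg),
    sensitivity_score = NA_real_,
    mean_pairwise_rmsd = NA_real_,
    per_state_counts = table(factor(ensemble$state))
  )
  if (n >= 2) {
    d_disp <- ensemble_rmsd_matrix(ensemble, superpose = FALSE)
    d_conf <- ensemble_rmsd_matrix(ensemble, superpose = TRUE)
    ut <- upper.tri(d_disp)
    out$mean_pairwise_rmsd <- mean(d_disp[ut])
    mean_conf <- mean(d_conf[ut])
    out$sensitivity_score <- if (mean_conf > 1e-9)
      out$range_dg / mean_conf else NA_real_
  }
  class(out) <- "binding_space_summary"
  out
}

#' @export
print.binding_space_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Binding-space summary (n = %d poses)\n",
           "  dG   mean %.2f  sd %s  mode %.2f  range %.2f kcal/mol\n",
           "  sensitivity %.3f  mean pairwise rmsd %.2f A\n"),
    x$n_poses, x$mean_dg,
    ifelse(is.na(x$sd_dg), "NA", sprintf("%.2f", x$sd_dg)),
    x$mode_dg, x$range_dg,
    x$sensitivity_score, x$mean_pairwise_rmsd))
  cat("  poses per state:\n")
  print(x$per_state_counts)
  invisible(x)
}

#' Greedy leader clustering of a pose ensemble
#'
#' Poses are scanned in input order on non-superposed rmsd: a pose joins
#' the first existing cluster whose leader lies within `threshold`,
#' otherwise it founds a new cluster. The representative pose is the medoid
#' (minimum summed rmsd) of the most populated cluster; ties are broken by
#' lower free energy, then lower pose index.
#'
#' @param ensemble a `pose_ensemble`.
#' @param threshold leader rmsd threshold in Angstrom (default 2).
#' @return list of class `cluster_result` with `labels`,
#'   `representative_index`, `threshold`, `cluster_sizes`.
#' @export
cluster_poses <- function(ensemble, threshold = 2.0) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  h <- heavy_idx(ensemble$template)
  xs <- lapply(ensemble$xyz, function(m) m[h, , drop = FALSE])
  n <- length(xs)
  labels <- integer(n)
  leaders <- integer(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (cl in seq_along(leaders)) {
      if (rmsd_xyz(xs[[leaders[cl]]], xs[[i]]) <= threshold) {
        labels[i] <- cl; placed <- TRUE; break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      labels[i] <- length(leaders)
    }
  }
  sizes <- tabulate(labels)
  top <- which.max(sizes)  # first (lowest id) cluster on ties
  members <- which(labels == top)
  if (length(members) == 1L) {
    rep_idx <- members
  } else {
    sums <- vapply(members, function(i)
      sum(vapply(members, function(j) rmsd_xyz(xs[[i]], xs[[j]]),
                 numeric(1))), numeric(1))
    dg <- ensemble$delta_g[members]
    dg[is.na(dg)] <- Inf
    ord <- order(round(sums, 9), dg, members)
    rep_idx <- members[ord[1]]
  }
  structure(list(labels = labels, representative_index = rep_idx,
                 threshold = threshold, cluster_sizes = sizes),
            class = "cluster_result")
}

#' @keywords internal
ligand_axis <- function(s, tags = NULL) {
  if (is.null(tags)) tags <- assign_pharmacophore_types(s)
  cat_atoms <- tags$atom[tags$tag == "cation"]
  arom <- tags$atom[tags$tag == "aromatic_ring_member"]
  if (!length(cat_atoms) || !length(arom))
    stop("input error: ligand axis needs a cation and an aromatic ring")
  xyz <- coords(s)
  nh <- cat_atoms[!s$atoms$is_h[cat_atoms]]
  from <- xyz[nh[1], ]
  to <- colMeans(xyz[arom, , drop = FALSE])
  unit(to - from)
}

#' Classify a pose orientation against two reference poses
#'
#' The ligand axis is the unit vector from the cationic amine nitrogen to
#' the aromatic-ring centroid. The pose is labelled after the reference
#' whose axis it matches within `max_angle` (the smaller of the two when
#' both qualify): `ref_a` is the serotonin-like orientation, `ref_b` the
#' escitalopram-like one; otherwise the pose is `intermediate`.
#'
#' @param p ligand pose to classify.
#' @param ref_a serotonin-like reference pose (same ligand topology).
#' @param ref_b escitalopram-like reference pose.
#' @param max_angle qualification threshold in degrees (default 40).
#' @return list with `label` (one of `"serotonin_like"`,
#'   `"escitalopram_like"`, `"intermediate"`) and `angle_to_refs` (named
#'   numeric, degrees).
#' @export
classify_orientation <- function(p, ref_a, ref_b, max_angle = 40) {
  ax <- ligand_axis(p)
  aa <- vec_angle(ax, ligand_axis(ref_a))
  ab <- vec_angle(ax, ligand_axis(ref_b))
  label <- "intermediate"
  if (aa <= max_angle && aa <= ab) label <- "serotonin_like"
  else if (ab <= max_angle) label <- "escitalopram_like"
  list(label = label,
       angle_to_refs = c(serotonin_like = aa, escitalopram_like = ab))
}
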