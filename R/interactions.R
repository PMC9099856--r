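#' Geometric criteria for typed noncovalent interactions
#'
#' Distance cutoffs in Angstrom, angles in degrees. Hydrogen bonds are
#' measured donor-heavy to acceptor-heavy with a D-H...A angle window;
#' strong H-bonds use the tighter distance and wider angle thresholds.
#' Aromatic interactions use ring centroid-to-centroid distances with a
#' 5 A cutoff and interplanar angle windows (parallel vs edge-to-face).
#'
#' @param hbond_max_dist maximum donor-acceptor heavy-atom distance.
#' @param hbond_min_angle minimum D-H...A angle.
#' @param hbond_strong_dist distance at or below which an H-bond is strong.
#' @param hbond_strong_angle angle at or above which an H-bond is strong.
#' @param salt_bridge_max_dist maximum charged-group N+...O- distance.
#' @param pi_centroid_max_dist maximum ring centroid separation.
#' @param pi_parallel_max_angle interplanar angle at or below which a pi-pi
#'   contact is parallel.
#' @param pi_edge_min_angle interplanar angle at or above which it is
#'   edge-to-face.
#' @param cation_pi_max_dist maximum cation-centroid to ring-centroid
#'   distance.
#' @return an object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_max_dist = 3.5,
                                 hbond_min_angle = 120,
                                 hbond_strong_dist = 3.0,
                                 hbond_strong_angle = 150,
                                 salt_bridge_max_dist = 4.0,
                                 pi_centroid_max_dist = 5.0,
                                 pi_parallel_max_angle = 30,
                                 pi_edge_min_angle = 60,
                                 cation_pi_max_dist = 5.0) {
  c_ <- list(hbond_max_dist = hbond_max_dist,
             hbond_min_angle = hbond_min_angle,
             hbond_strong_dist = hbond_strong_dist,
             hbond_strong_angle = hbond_strong_angle,
             salt_bridge_max_dist = salt_bridge_max_dist,
             pi_centroid_max_dist = pi_centroid_max_dist,
             pi_parallel_max_angle = pi_parallel_max_angle,
             pi_edge_min_angle = pi_edge_min_angle,
             cation_pi_max_dist = cation_pi_max_dist)
  dists <- c_[grep("dist", names(c_))]
  if (any(unlist(dists) <= 0)) stop("all distance cutoffs must be > 0")
  if (hbond_strong_dist > hbond_max_dist ||
      hbond_strong_angle < hbond_min_angle)
    stop("strong H-bond thresholds must be at least as strict as weak ones")
  structure(c_, class = "interaction_criteria")
}

# Extract interaction features (donors, acceptors, ions, rings) from a
# tagged structure, optionally restricted to a set of atom indices.
#' @keywords internal
interaction_features <- function(s, tags, restrict = NULL) {
  if (!is.null(restrict)) tags <- tags[tags$atom %in% restrict, , drop = FALSE]
  xyz <- coords(s)
  don <- tags[tags$tag == "hbond_donor", , drop = FALSE]
  acc <- tags[tags$tag == "hbond_acceptor", , drop = FALSE]
  ani <- tags[tags$tag == "anion", , drop = FALSE]
  cat_tags <- tags[tags$tag == "cation", , drop = FALSE]
  cations <- list()
  if (nrow(cat_tags)) {
    for (g in unique(cat_tags$group)) {
      idx <- cat_tags$atom[cat_tags$group %in% g]
      cations[[length(cations) + 1L]] <- list(
        atoms = idx, centroid = colMeans(xyz[idx, , drop = FALSE]), group = g)
    }
  }
  arom <- tags[tags$tag == "aromatic_ring_member", , drop = FALSE]
  rings <- list()
  if (nrow(arom)) {
    for (rid in unique(arom$ring)) {
      idx <- arom$atom[arom$ring == rid]
      if (length(idx) < 3) next
      p <- xyz[idx, , drop = FALSE]
      ctr <- colMeans(p)
      sv <- svd(sweep(p, 2, ctr))
      rings[[length(rings) + 1L]] <- list(
        id = rid, atoms = idx, centroid = ctr, normal = sv$v[, 3])
    }
  }
  list(donors = don, acceptors = acc, anions = ani, cations = cations,
       rings = rings, xyz = xyz)
}

#' Detect typed ligand-receptor interactions
#'
#' Enumerates hydrogen bonds (weak/strong), salt bridges, parallel and
#' edge-to-face pi-pi stacking, and cation-pi contacts between a ligand
#' pose and the active-site residues of a receptor, under explicit
#' geometric criteria. A salt bridge is reported in addition to (not
#' instead of) an H-bond when both criteria hold. pi-pi contacts with an
#' interplanar angle between the parallel and edge windows are reported as
#' parallel with `displaced = TRUE`.
#'
#' @param pose ligand `mol_structure` (tags assignable).
#' @param receptor receptor `mol_structure`.
#' @param site `active_site` restricting the receptor residues examined.
#' @param criteria an `interaction_criteria` object.
#' @param pose_tags,receptor_tags optional precomputed tag tables from
#'   [assign_pharmacophore_types()]; computed on the fly when `NULL`.
#' @return data.frame of class `interaction_records` with columns `kind`,
#'   `lig_label`, `lig_atoms`, `res_key`, `chain`, `resno`, `resname`,
#'   `rec_label`, `distance`, `angle`, `displaced`, sorted by
#'   (residue, kind, distance).
#' @export
detect_interactions <- function(pose, receptor, site,
                                criteria = interaction_criteria(),
                                pose_tags = NULL, receptor_tags = NULL) {
  if (is.null(pose_tags)) pose_tags <- assign_pharmacophore_types(pose)
  if (is.null(receptor_tags))
    receptor_tags <- suppressWarnings(assign_pharmacophore_types(receptor))
  if (nrow(pose_tags) == 0L)
    stop("precondition error: no pharmacophore tags on the ligand pose")
  restrict <- site_atom_idx(receptor, site)
  lf <- interaction_features(pose, pose_tags)
  rf <- interaction_features(receptor, receptor_tags, restrict)
  rk <- residue_keys(receptor)
  rec <- list()
  emit <- function(kind, lig_label, lig_atoms, res_atom_or_key, rec_label,
                   distance, angle = NA_real_, displaced = FALSE) {
    key <- if (is.character(res_atom_or_key)) res_atom_or_key else
      rk[res_atom_or_key]
    rec[[length(rec) + 1L]] <<- data.frame(
      kind = kind, lig_label = lig_label,
      lig_atoms = paste(lig_atoms, collapse = ","),
      res_key = key, distance = distance, angle = angle,
      displaced = displaced, stringsAsFactors = FALSE)
  }
  hb <- function(dframe, d_xyz, aframe, a_xyz, lig_is_donor) {
    # one record per (donor heavy atom, acceptor atom) pair, best hydrogen
    if (!nrow(dframe) || !nrow(aframe)) return()
    dheavy <- unique(dframe$atom)
    for (di in dheavy) {
      hs <- dframe$h[dframe$atom == di]
      hs <- hs[!is.na(hs)]
      for (ai in unique(aframe$atom)) {
        d <- vnorm(d_xyz[di, ] - a_xyz[ai, ])
        if (d > criteria$hbond_max_dist) next
        ang <- NA_real_
        if (length(hs)) {
          angs <- vapply(hs, function(h)
            vec_angle(d_xyz[di, ] - d_xyz[h, ], a_xyz[ai, ] - d_xyz[h, ]),
            numeric(1))
          ang <- max(angs)
          if (ang < criteria$hbond_min_angle) next
        }
        strong <- d <= criteria$hbond_strong_dist &&
          (is.na(ang) || ang >= criteria$hbond_strong_angle)
        kind <- if (strong) "hbond_strong" else "hbond_weak"
        if (lig_is_donor) {
          emit(kind, pose$atoms$name[di], di, ai, receptor$atoms$name[ai],
               d, ang)
        } else {
          emit(kind, pose$atoms$name[ai], ai, di, receptor$atoms$name[di],
               d, ang)
        }
      }
    }
  }
  hb(lf$donors, lf$xyz, rf$acceptors, rf$xyz, lig_is_donor = TRUE)
  hb(rf$donors, rf$xyz, lf$acceptors, lf$xyz, lig_is_donor = FALSE)
  # salt bridges: cation heavy atom vs anion atom
  sb <- function(cat_list, cat_xyz, ani_frame, ani_xyz, lig_is_cation) {
    for (cg in cat_list) {
      for (ci in cg$atoms) {
        for (ai in unique(ani_frame$atom)) {
          d <- vnorm(cat_xyz[ci, ] - ani_xyz[ai, ])
          if (d > criteria$salt_bridge_max_dist) next
          if (lig_is_cation)
            emit("salt_bridge", pose$atoms$name[ci], ci, ai,
                 receptor$atoms$name[ai], d)
          else
            emit("salt_bridge", pose$atoms$name[ai], ai, ci,
                 receptor$atoms$name[ci], d)
        }
      }
    }
  }
  sb(lf$cations, lf$xyz, rf$anions, rf$xyz, lig_is_cation = TRUE)
  sb(rf$cations, rf$xyz, lf$anions, lf$xyz, lig_is_cation = FALSE)
  # pi-pi stacking
  for (lr in lf$rings) {
    for (rr in rf$rings) {
      d <- vnorm(lr$centroid - rr$centroid)
      if (d > criteria$pi_centroid_max_dist) next
      ang <- vec_angle(lr$normal, rr$normal)
      ang <- min(ang, 180 - ang)
      res_atom <- rr$atoms[1]
      if (ang <= criteria$pi_parallel_max_angle) {
        emit("pi_pi_parallel", paste0("ring", lr$id), lr$atoms, res_atom,
             paste0("ring", rr$id), d, ang)
      } else if (ang >= criteria$pi_edge_min_angle) {
        emit("pi_pi_edge", paste0("ring", lr$id), lr$atoms, res_atom,
             paste0("ring", rr$id), d, ang)
      } else {
        emit("pi_pi_parallel", paste0("ring", lr$id), lr$atoms, res_atom,
             paste0("ring", rr$id), d, ang, displaced = TRUE)
      }
    }
  }
  # cation-pi (both directions)
  for (cg in lf$cations) {
    for (rr in rf$rings) {
      d <- vnorm(cg$centroid - rr$centroid)
      if (d <= criteria$cation_pi_max_dist)
        emit("cation_pi", paste(pose$atoms$name[cg$atoms], collapse = "+"),
             cg$atoms, rr$atoms[1], paste0("ring", rr$id), d)
    }
  }
  for (cg in rf$cations) {
    for (lr in lf$rings) {
      d <- vnorm(cg$centroid - lr$centroid)
      if (d <= criteria$cation_pi_max_dist)
        emit("cation_pi", paste0("ring", lr$id), lr$atoms, cg$atoms[1],
             paste(receptor$atoms$name[cg$atoms], collapse = "+"), d)
    }
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(kind = character(), lig_label = character(),
               lig_atoms = character(), res_key = character(),
               distance = numeric(), angle = numeric(),
               displaced = logical(), stringsAsFactors = FALSE)
  parts <- strsplit(out$res_key, ":")
  out$chain <- vapply(parts, `[`, "", 1)
  out$resno <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  out$resname <- vapply(parts, `[`, "", 3)
  out <- out[order(out$res_key, out$kind, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Per-residue contact occurrence profile over a pose ensemble
#'
#' For every active-site residue, the relative occurrence is the fraction
#' of poses making at least one contact with it: either a typed interaction
#' record (`mode = "typed_only"`) or any heavy-atom pair within
#' `any_contact_dist` (`mode = "any_contact"`).
#'
#' @param ensemble a `pose_ensemble` (see [pose_ensemble()]) or list of
#'   ligand `mol_structure` poses.
#' @param receptor receptor `mol_structure`.
#' @param site `active_site`.
#' @param criteria `interaction_criteria` (typed mode).
#' @param mode `"typed_only"` or `"any_contact"`.
#' @param any_contact_dist heavy-atom cutoff for any-contact mode (A).
#' @return data.frame of class `contact_profile` with columns `res_key`,
#'   `chain`, `resno`, `resname`, `n_contacting`, `occurrence`; attributes
#'   `n_poses` and `mode`.
#' @export
contact_profile <- function(ensemble, receptor, site,
                            criteria = interaction_criteria(),
                            mode = c("typed_only", "any_contact"),
                            any_contact_dist = 4.0) {
  mode <- match.arg(mode)
  poses <- ensemble_poses(ensemble)
  if (!length(poses)) stop("input error: empty ensemble")
  rtags <- suppressWarnings(assign_pharmacophore_types(receptor))
  ptags <- assign_pharmacophore_types(poses[[1]])
  keys <- site$residues$key
  hits <- matrix(FALSE, nrow = length(poses), ncol = length(keys),
                 dimnames = list(NULL, keys))
  restrict <- site_atom_idx(receptor, site)
  rxyz <- coords(receptor)
  rheavy <- intersect(heavy_idx(receptor), restrict)
  rkeys_atom <- residue_keys(receptor)
  for (p in seq_along(poses)) {
    if (mode == "typed_only") {
      recs <- detect_interactions(poses[[p]], receptor, site, criteria,
                                  pose_tags = ptags, receptor_tags = rtags)
      hits[p, unique(recs$res_key[recs$res_key %in% keys])] <- TRUE
    } else {
      lxyz <- coords(poses[[p]])[heavy_idx(poses[[p]]), , drop = FALSE]
      d <- cross_dist(rxyz[rheavy, , drop = FALSE], lxyz)
      near <- rkeys_atom[rheavy][apply(d, 1, min) <= any_contact_dist]
      hits[p, unique(near[near %in% keys])] <- TRUE
    }
  }
  n_contacting <- colSums(hits)
  out <- data.frame(
    res_key = keys,
    chain = site$residues$chain, resno = site$residues$resno,
    resname = site$residues$resname,
    n_contacting = as.integer(n_contacting),
    occurrence = as.numeric(n_contacting) / length(poses),
    stringsAsFactors = FALSE
  )
  attr(out, "n_poses") <- length(poses)
  attr(out, "mode") <- mode
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Tabulate interaction records by residue and kind
#'
#' @param records a single `interaction_records` data.frame or a list of
#'   them (one per pose).
#' @return data.frame with one row per (residue, kind) and a `count`
#'   column; the counts sum to the total number of typed records.
#' @export
occurrence_table <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  all <- do.call(rbind, lapply(records, as.data.frame))
  if (is.null(all) || !nrow(all)) {
    return(data.frame(res_key = character(), kind = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  tab <- stats::aggregate(list(count = rep(1L, nrow(all))),
                          by = list(res_key = all$res_key, kind = all$kind),
                          FUN = sum)
  tab <- tab[order(tab$res_key, tab$kind), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Monitor ligand-receptor pair distances along a trajectory
#'
#' Each pair names a set of ligand atoms and a set of receptor atoms; the
#' distance recorded per step is centroid-to-centroid (single atoms are
#' their own centroid), so ring-ring and charged-group pairs use group
#' centroids.
#'
#' @param traj an `mc_trajectory` from [run_mc()].
#' @param pairs list of pairs, each `list(label =, ligand = <atom idx>,
#'   receptor = <atom idx>)`.
#' @return data.frame with columns `step`, `pair`, `distance` (one row per
#'   step and pair; step 0 is the initial state).
#' @export
monitor_pair_distances <- function(traj, pairs) {
  rxyz <- coords(traj$receptor)
  n_lig <- nrow(traj$snapshots[[1]])
  for (p in pairs) {
    if (is.null(p$ligand) || is.null(p$receptor) ||
        any(p$ligand < 1 | p$ligand > n_lig) ||
        any(p$receptor < 1 | p$receptor > nrow(rxyz)))
      stop("input error: invalid monitored pair")
  }
  out <- list()
  for (k in seq_along(traj$snapshots)) {
    lxyz <- traj$snapshots[[k]]
    for (p in pairs) {
      lc <- colMeans(lxyz[p$ligand, , drop = FALSE])
      rc <- colMeans(rxyz[p$receptor, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        step = k - 1L,
        pair = if (!is.null(p$label)) p$label else
          paste0("pair", match(list(p), pairs)),
        distance = vnorm(lc - rc), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
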