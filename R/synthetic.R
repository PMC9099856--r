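# Ideal-geometry residue templates for toy pockets. Each template is built
# in a local frame: the interacting tip (carboxylate midpoint, ammonium N,
# ring centroid, hydroxyl O, amide tip, CA for GLY) sits at the origin and
# the backbone extends along +y, so that placing a residue on a cylindrical
# shell points its functional group at the site axis. Geometry is idealized
# (standard bond lengths, simplified angles): these are pharmacophoric
# stand-ins, not folded protein.

#' @keywords internal
.bb <- function(attach, zig = 1) {
  ca <- attach + c(0.85 * zig, 1.26, 0)
  n  <- ca + c(-0.70 * zig, 1.29, 0)
  h  <- n + c(-0.60 * zig, 0.82, 0)
  cc <- ca + c(1.33 * zig, 0.75, 0)
  o  <- cc + c(0.90 * zig, 0.84, 0)
  rbind(CA = ca, N = n, H = h, C = cc, O = o)
}

#' @keywords internal
.template_df <- function(side, bb) {
  m <- rbind(side, bb)
  el <- substr(rownames(m), 1, 1)
  el[el %in% c("1", "2", "3")] <- "H"
  data.frame(name = rownames(m), element = el,
             x = m[, 1], y = m[, 2], z = m[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @keywords internal
make_residue_templates <- function() {
  t <- list()
  # GLU: carboxylate tip (midpoint of OE1/OE2 at origin)
  side <- rbind(OE1 = c(-1.1, 0, 0), OE2 = c(1.1, 0, 0), CD = c(0, 0.6, 0),
                CG = c(0, 2.12, 0), CB = c(0.85, 3.38, 0))
  t$GLU <- .template_df(side, .bb(side["CB", ], zig = -1))
  # ASP: one CH2 shorter
  side <- rbind(OD1 = c(-1.1, 0, 0), OD2 = c(1.1, 0, 0), CG = c(0, 0.6, 0),
                CB = c(0.85, 1.86, 0))
  t$ASP <- .template_df(side, .bb(side["CB", ], zig = -1))
  # ARG: guanidinium tip
  side <- rbind(NH1 = c(-1.15, -0.1, 0), NH2 = c(1.15, -0.1, 0),
                CZ = c(0, 0.6, 0), NE = c(0, 1.95, 0),
                HH11 = c(-1.75, -0.9, 0), HH12 = c(-2.05, 0.35, 0),
                HH21 = c(1.75, -0.9, 0), HH22 = c(2.05, 0.35, 0),
                HE = c(-0.95, 2.30, 0),
                CD = c(0.85, 3.21, 0), CG = c(1.70, 4.47, 0),
                CB = c(0.85, 5.73, 0))
  t$ARG <- .template_df(side, .bb(side["CB", ], zig = 1))
  # LYS: ammonium tip
  side <- rbind(NZ = c(0, 0, 0),
                HZ1 = c(0.94, -0.33, 0), HZ2 = c(-0.47, -0.33, 0.82),
                HZ3 = c(-0.47, -0.33, -0.82),
                CE = c(0, 1.49, 0), CD = c(0.85, 2.75, 0),
                CG = c(0, 4.01, 0), CB = c(0.85, 5.27, 0))
  t$LYS <- .template_df(side, .bb(side["CB", ], zig = -1))
  # PHE: ring centroid at origin, ring in the local xy-plane
  ring <- rbind(CG = c(0, 1.39, 0), CD1 = c(1.2037, 0.695, 0),
                CD2 = c(-1.2037, 0.695, 0), CE1 = c(1.2037, -0.695, 0),
                CE2 = c(-1.2037, -0.695, 0), CZ = c(0, -1.39, 0))
  hr <- ring[c("CD1", "CD2", "CE1", "CE2", "CZ"), ] * (2.48 / 1.39)
  rownames(hr) <- c("HD1", "HD2", "HE1", "HE2", "HZ")
  side <- rbind(ring, hr, CB = c(0, 2.91, 0))
  t$PHE <- .template_df(side, .bb(side["CB", ], zig = -1))
  # TYR: PHE with para-hydroxyl instead of HZ
  side <- rbind(ring, hr[c("HD1", "HD2", "HE1", "HE2"), , drop = FALSE],
                OH = c(0, -2.75, 0), HH = c(0.55, -3.55, 0),
                CB = c(0, 2.91, 0))
  t$TYR <- .template_df(side, .bb(side["CB", ], zig = -1))
  # THR: hydroxyl tip
  side <- rbind(OG1 = c(0, 0, 0), HG1 = c(0.55, -0.80, 0),
                CB = c(0, 1.43, 0), CG2 = c(1.2, 1.95, 0.9))
  t$THR <- .template_df(side, .bb(side["CB", ], zig = -1))
  # GLN: primary amide tip
  side <- rbind(OE1 = c(-1.1, 0, 0), NE2 = c(1.15, -0.05, 0),
                HE21 = c(1.75, -0.85, 0), HE22 = c(2.10, 0.30, 0),
                CD = c(0, 0.6, 0), CG = c(0, 2.12, 0), CB = c(0.85, 3.38, 0))
  t$GLN <- .template_df(side, .bb(side["CB", ], zig = -1))
  # GLY: bare backbone, CA at the tip
  bb <- .bb(c(0, -1.26 - 0.85, 0) * 0, zig = 1)  # CA offset from origin
  bb <- sweep(bb, 2, bb["CA", ])                 # put CA exactly at origin
  el <- rownames(bb)
  t$GLY <- data.frame(name = el, element = substr(el, 1, 1),
                      x = bb[, 1], y = bb[, 2], z = bb[, 3],
                      stringsAsFactors = FALSE, row.names = NULL)
  t
}

.RESIDUE_TEMPLATES <- make_residue_templates()

# pharmacophoric role used by the ensemble planter, per template
.TEMPLATE_ROLE <- c(GLU = "anion", ASP = "anion", ARG = "cation",
                    LYS = "cation", PHE = "aromatic", TYR = "aromatic",
                    THR = "hbond", GLN = "hbond", GLY = "backbone")

#' Specification of a toy binding pocket
#'
#' Residues are placed on a cylindrical shell around the site (z) axis with
#' their functional tips pointing inward.
#'
#' @param roster character vector of residue names (supported: GLU, ASP,
#'   ARG, LYS, PHE, TYR, THR, GLN, GLY), or a data.frame with columns
#'   `resname` and `radius` (tip distance from the axis, A).
#' @param radius default placement radius used when the roster does not
#'   give one (default 4.5 A).
#' @param jitter seeded angular/axial jitter amplitude (default 0.2 A).
#' @param seed RNG seed.
#' @return object of class `pocket_spec`.
#' @export
pocket_spec <- function(roster, radius = 4.5, jitter = 0.2, seed = 1) {
  if (is.character(roster))
    roster <- data.frame(resname = roster, radius = radius,
                         stringsAsFactors = FALSE)
  if (is.null(roster$radius)) roster$radius <- radius
  if (!nrow(roster)) stop("spec error: empty roster")
  bad <- setdiff(roster$resname, names(.RESIDUE_TEMPLATES))
  if (length(bad)) stop("spec error: unsupported residue(s): ",
                        paste(bad, collapse = ", "))
  structure(list(roster = roster, jitter = jitter, seed = as.integer(seed)),
            class = "pocket_spec")
}

#' @keywords internal
place_template <- function(tmpl, theta, radius, z = 0) {
  u <- c(cos(theta), sin(theta), 0)     # outward radial
  tg <- c(-sin(theta), cos(theta), 0)   # tangent
  rot <- cbind(tg, u, c(0, 0, 1))       # template (x,y,z) -> world
  xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(rot)
  sweep(xyz, 2, u * radius + c(0, 0, z), "+")
}

#' Build a toy binding pocket
#'
#' Places the roster residues (internal ideal-geometry templates, polar
#' hydrogens included) at equally spaced angles on the shell, with small
#' seeded jitter; retries the jitter when any two residues come closer
#' than `min_sep`. Deterministic under the spec seed. Bonds are perceived
#' and template partial charges assigned.
#'
#' @param spec a `pocket_spec`.
#' @param min_sep minimum inter-residue heavy-atom distance, A.
#' @param max_retries placement retries before failing.
#' @return receptor `mol_structure`.
#' @export
make_toy_pocket <- function(spec, min_sep = 2.5, max_retries = 20) {
  stopifnot(inherits(spec, "pocket_spec"))
  set.seed(spec$seed)
  n <- nrow(spec$roster)
  base_theta <- 2 * pi * (seq_len(n) - 1) / n
  for (try in seq_len(max_retries)) {
    tabs <- vector("list", n)
    for (i in seq_len(n)) {
      rn <- spec$roster$resname[i]
      tmpl <- .RESIDUE_TEMPLATES[[rn]]
      th <- base_theta[i] + stats::runif(1, -1, 1) * spec$jitter / 2
      zz <- stats::runif(1, -1, 1) * spec$jitter
      xyz <- place_template(tmpl, th, spec$roster$radius[i], zz)
      tabs[[i]] <- data.frame(
        element = tmpl$element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        name = tmpl$name, chain = "A", resno = i, resname = rn,
        stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, tabs)
    s <- mol_structure(atoms, role = "receptor")
    # check inter-residue separation (heavy atoms)
    ok <- TRUE
    hv <- heavy_idx(s)
    xyz <- coords(s)[hv, , drop = FALSE]
    res <- s$atoms$resno[hv]
    d <- cross_dist(xyz, xyz)
    same <- outer(res, res, "==")
    if (any(d[!same] < min_sep)) ok <- FALSE
    if (ok) {
      s <- perceive_bonds_and_rings(s)
      s <- assign_partial_charges(s)
      return(s)
    }
  }
  stop("spec error: infeasible placement after ", max_retries, " retries")
}

#' @keywords internal
make_mdma_like <- function() {
  r <- 1.39; h <- r * sqrt(3) / 2
  atoms <- rbind(
    C1 = c(1.39, 0, 0), C2 = c(0.695, 1.2037, 0), C3 = c(-0.695, 1.2037, 0),
    C4 = c(-1.39, 0, 0), C5 = c(-0.695, -1.2037, 0), C6 = c(0.695, -1.2037, 0),
    O1 = c(-1.52, 2.32, 0), O2 = c(-2.62, 0.50, 0),
    C7 = c(-2.896, 1.887, 0.45),
    C8 = c(2.90, 0, 0), C9 = c(3.65, 1.31, 0), C10 = c(4.60, 0.81, 1.08),
    N1 = c(4.38, 2.575, 0), C11 = c(5.68, 3.075, 0.45),
    H2 = c(1.24, 2.15, 0), H5 = c(-1.24, -2.15, 0), H6 = c(1.24, -2.15, 0),
    H71 = c(-2.896, 1.887, 1.54), H72 = c(-2.896, 1.887, -0.64),
    H81 = c(2.60, -0.60, 0.85), H82 = c(2.60, -0.60, -0.85),
    H9 = c(3.10, 1.66, -0.85),
    H101 = c(5.60, 0.61, 1.38), H102 = c(4.30, 0.26, 1.93),
    H103 = c(4.95, -0.19, 1.18),
    HN1 = c(4.03, 3.175, 0.75), HN2 = c(4.03, 3.175, -0.75),
    H111 = c(6.58, 3.475, 0.85), H112 = c(5.88, 2.575, -0.45),
    H113 = c(5.88, 4.025, 0.15))
  el <- substr(rownames(atoms), 1, 1)
  data.frame(name = rownames(atoms), element = el,
             x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a toy ligand
#'
#' `mdma_like`: an entactogen-like cationic ligand with a benzene ring
#' fused to a methylenedioxy (dioxole) ring, a propylamine chain and a
#' protonated N-methyl secondary amine (net formal charge +1; 3 rotatable
#' bonds: aryl-CH2, CH2-CH, CH-N). `probe_amine`: methylammonium.
#' `probe_ring`: benzene. `probe_chain`: an 11-carbon united-atom alkane
#' with 8 rotatable bonds, for conformational-search exercises. Bonds and
#' rings are perceived and built-in charges assigned.
#'
#' @param kind one of `"mdma_like"`, `"probe_amine"`, `"probe_ring"`,
#'   `"probe_chain"`.
#' @return ligand `mol_structure`; attribute `rotor_count` documents the
#'   fixture's rotatable-bond count.
#' @export
make_toy_ligand <- function(kind = c("mdma_like", "probe_amine",
                                     "probe_ring", "probe_chain")) {
  kind <- match.arg(kind)
  if (kind == "mdma_like") {
    df <- make_mdma_like(); rotors <- 3L
  } else if (kind == "probe_amine") {
    m <- rbind(N1 = c(0, 0, 0), C1 = c(1.49, 0, 0),
               HN1 = c(-0.47, -0.33, 0.82), HN2 = c(-0.47, -0.33, -0.82),
               HN3 = c(-0.47, 0.88, 0),
               H11 = c(1.96, 0.33, 0.82), H12 = c(1.96, 0.33, -0.82),
               H13 = c(1.96, -0.88, 0))
    df <- data.frame(name = rownames(m), element = substr(rownames(m), 1, 1),
                     x = m[, 1], y = m[, 2], z = m[, 3],
                     stringsAsFactors = FALSE, row.names = NULL)
    rotors <- 0L
  } else if (kind == "probe_ring") {
    ring <- rbind(C1 = c(0, 1.39, 0), C2 = c(1.2037, 0.695, 0),
                  C3 = c(1.2037, -0.695, 0), C4 = c(0, -1.39, 0),
                  C5 = c(-1.2037, -0.695, 0), C6 = c(-1.2037, 0.695, 0))
    hs <- ring * (2.48 / 1.39)
    rownames(hs) <- paste0("H", 1:6)
    m <- rbind(ring, hs)
    df <- data.frame(name = rownames(m), element = substr(rownames(m), 1, 1),
                     x = m[, 1], y = m[, 2], z = m[, 3],
                     stringsAsFactors = FALSE, row.names = NULL)
    rotors <- 0L
  } else {
    k <- 11
    m <- cbind(1.26 * (seq_len(k) - 1), 0.425 * (seq_len(k) %% 2), 0)
    rownames(m) <- paste0("C", seq_len(k))
    df <- data.frame(name = rownames(m), element = "C",
                     x = m[, 1], y = m[, 2], z = m[, 3],
                     stringsAsFactors = FALSE, row.names = NULL)
    rotors <- 8L
  }
  df$chain <- "L"; df$resno <- 1L; df$resname <- "LIG"
  s <- mol_structure(df, role = "ligand")
  s <- perceive_bonds_and_rings(s)
  s <- assign_partial_charges(s)
  attr(s, "rotor_count") <- rotors
  s
}

#' Specification of a planted pose ensemble
#'
#' @param n_poses number of poses.
#' @param per_state data.frame with columns `state`, `mean`, `sd` and
#'   optionally `n` (poses per state; even split by default): the
#'   per-receptor-state normal distribution of pose free energies,
#'   kcal/mol.
#' @param n_centres number of cluster centres, or a matrix of centre
#'   positions (one row each).
#' @param centre_sep spacing of auto-placed centres along the site axis, A.
#' @param spread Gaussian positional spread of poses about their centre, A.
#' @param frequencies named numeric vector: target contact frequency per
#'   pocket residue number (names are resno values as characters) or per
#'   residue name; all in [0, 1], summing to at most 1 (contact sets are
#'   disjoint by construction).
#' @param orientation_mix named fractions over `serotonin_like`,
#'   `escitalopram_like`, `intermediate`; must sum to 1.
#' @param conformer_jitter rms torsional perturbation applied per pose,
#'   degrees (default 0: all poses share the template conformation, so
#'   planted cluster and orientation recovery are exact; positive values
#'   add intramolecular variety and make them approximate).
#' @param seed RNG seed.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_poses,
                          per_state = data.frame(state = "state1",
                                                 mean = -7, sd = 1),
                          n_centres = 1, centre_sep = 10, spread = 0.5,
                          frequencies = NULL,
                          orientation_mix = c(serotonin_like = 1,
                                              escitalopram_like = 0,
                                              intermediate = 0),
                          conformer_jitter = 0, seed = 1) {
  stopifnot(n_poses >= 1, all(per_state$sd >= 0))
  if (!is.null(frequencies)) {
    if (any(frequencies < 0 | frequencies > 1))
      stop("spec error: frequencies must lie in [0, 1]")
    if (sum(frequencies) > 1 + 1e-9)
      stop("spec error: geometric conflict - disjoint contact sets need sum(frequencies) <= 1")
  }
  if (abs(sum(orientation_mix) - 1) > 1e-9)
    stop("spec error: orientation fractions must sum to 1")
  structure(list(n_poses = as.integer(n_poses), per_state = per_state,
                 n_centres = n_centres, centre_sep = centre_sep,
                 spread = spread, frequencies = frequencies,
                 orientation_mix = orientation_mix,
                 conformer_jitter = conformer_jitter,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' @keywords internal
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- vnorm(v); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(p - sum(p * a) * a)
    v <- ax; s <- 0; cth <- -1
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    return(diag(3) + 2 * vx %*% vx)
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

# largest-remainder rounding of fractions to integer counts summing to n
#' @keywords internal
allocate_counts <- function(fracs, n) {
  raw <- fracs * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Plant a pose ensemble with known statistical structure
#'
#' Generates `n_poses` copies of the ligand with (i) per-state free
#' energies drawn from the stated normal distributions, (ii) cluster
#' structure: pose centroids at the cluster centres plus Gaussian spread,
#' (iii) an enforced orientation mix (poses rigidly rotated so their
#' cation-to-ring axis matches the serotonin-like reference, its opposite,
#' or an orthogonal intermediate), and (iv) exact planted contact
#' frequencies: for each target residue, `round(f * n)` poses are
#' translated so the residue's typed interaction criterion is met, and all
#' other poses are kept clear of it (axial displacement), so recovery
#' tolerances test the detector rather than sampling noise. Pure function
#' of spec + seed.
#'
#' @param pocket receptor `mol_structure` from [make_toy_pocket()].
#' @param ligand ligand `mol_structure` (default topology:
#'   [make_toy_ligand()]).
#' @param spec an `ensemble_spec`.
#' @param criteria `interaction_criteria` used to verify planted contacts.
#' @return list with `ensemble` (a `pose_ensemble`), `refs` (list of
#'   serotonin-like and escitalopram-like reference poses),
#'   `orientation_labels`, `contact_assignment` (list residue -> pose
#'   indices), and `centre_assignment`.
#' @export
plant_pose_ensemble <- function(pocket, ligand, spec,
                                criteria = interaction_criteria()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  n <- spec$n_poses
  lig0 <- ligand
  axis0 <- ligand_axis(lig0)
  ctr0 <- colMeans(coords(lig0))
  # references: base conformer and its axis-flipped copy
  ref_a <- lig0
  ref_b <- lig0
  coords(ref_b) <- sweep(sweep(coords(lig0), 2, ctr0) %*%
                           t(rotation_between(axis0, -axis0)), 2, ctr0, "+")
  ortho <- unit(if (abs(axis0[3]) < 0.9) {
    v <- c(0, 0, 1); v - sum(v * axis0) * axis0
  } else {
    v <- c(1, 0, 0); v - sum(v * axis0) * axis0
  })
  # states and free energies
  ps <- spec$per_state
  n_state <- if (!is.null(ps$n)) as.integer(ps$n) else
    allocate_counts(rep(1 / nrow(ps), nrow(ps)), n)
  if (sum(n_state) != n) stop("spec error: per-state counts must sum to n_poses")
  state <- rep(ps$state, n_state)
  dg <- unlist(lapply(seq_len(nrow(ps)),
                      function(i) stats::rnorm(n_state[i], ps$mean[i], ps$sd[i])))
  # cluster centres
  centres <- if (is.matrix(spec$n_centres)) spec$n_centres else {
    k <- spec$n_centres
    cbind(0, 0, spec$centre_sep * (seq_len(k) - (k + 1) / 2))
  }
  centre_of <- rep_len(seq_len(nrow(centres)), n)
  # orientation targets
  n_orient <- allocate_counts(spec$orientation_mix[c("serotonin_like",
                                                     "escitalopram_like",
                                                     "intermediate")], n)
  orient <- rep(c("serotonin_like", "escitalopram_like", "intermediate"),
                n_orient)
  targets <- list(serotonin_like = axis0, escitalopram_like = -axis0,
                  intermediate = ortho)
  # positional jitter: normal truncated at 2 sigma, so intra-cluster
  # displacement is bounded and a planted blob cannot leak past a leader
  # threshold of 4 x spread
  jitter3 <- function(sd) {
    if (sd <= 0) return(c(0, 0, 0))
    repeat {
      v <- stats::rnorm(3, 0, sd)
      if (vnorm(v) <= 2 * sd) return(v)
    }
  }
  rotors <- list_rotatable_bonds(lig0)
  xyz_list <- vector("list", n)
  for (p in seq_len(n)) {
    conf <- if (spec$conformer_jitter > 0 && nrow(rotors))
      coords(perturb_torsions(lig0, rotors, spec$conformer_jitter)) else
      coords(lig0)
    rot <- rotation_between(axis0, targets[[orient[p]]])
    x <- sweep(sweep(conf, 2, ctr0) %*% t(rot), 2, ctr0, "+")
    pos <- centres[centre_of[p], ] + jitter3(spec$spread)
    xyz_list[[p]] <- sweep(x, 2, colMeans(x) - pos, "-")
  }
  contact_assignment <- list()
  if (!is.null(spec$frequencies)) {
    res <- plant_contacts(pocket, lig0, xyz_list, spec$frequencies, criteria)
    xyz_list <- res$xyz_list
    contact_assignment <- res$assignment
  }
  ens <- pose_ensemble(lig0, xyz_list, delta_g = dg, state = state)
  list(ensemble = ens, refs = list(serotonin_like = ref_a,
                                   escitalopram_like = ref_b),
       orientation_labels = orient, contact_assignment = contact_assignment,
       centre_assignment = centre_of)
}

# Translate designated poses onto a residue's typed-contact geometry and
# push all other poses clear of it along the site axis.
#' @keywords internal
plant_contacts <- function(pocket, ligand, xyz_list, frequencies, criteria) {
  n <- length(xyz_list)
  rost <- pocket$atoms[!duplicated(pocket$atoms$resno),
                       c("resno", "resname")]
  resolve <- function(nm) {
    if (nm %in% as.character(rost$resno)) as.integer(nm) else {
      hit <- rost$resno[rost$resname == nm]
      if (!length(hit)) stop("spec error: no pocket residue named ", nm)
      hit[1]
    }
  }
  tags <- assign_pharmacophore_types(ligand)
  amine <- tags$atom[tags$tag == "cation"]
  amine <- amine[!ligand$atoms$is_h[amine]][1]
  ring_atoms <- tags$atom[tags$tag == "aromatic_ring_member" &
                            tags$ring == tags$ring[1]]
  acc <- tags$atom[tags$tag == "hbond_acceptor"]
  site <- select_active_site(pocket, {
    s <- ligand; coords(s) <- xyz_list[[1]]; s
  }, radius = 50)
  rtags <- suppressWarnings(assign_pharmacophore_types(pocket))
  pxyz <- coords(pocket)
  assignment <- list()
  pool <- seq_len(n)
  reskeys <- residue_keys(pocket)
  for (nm in names(frequencies)) {
    resno <- resolve(nm)
    nf <- round(frequencies[[nm]] * n)
    if (nf > length(pool)) stop("spec error: geometric conflict in frequencies")
    chosen <- pool[seq_len(nf)]
    pool <- setdiff(pool, chosen)
    role <- .TEMPLATE_ROLE[[rost$resname[rost$resno == resno]]]
    ratoms <- which(pocket$atoms$resno == resno)
    inward <- -unit(c(colMeans(pxyz[ratoms, 1:2, drop = FALSE]), 0))
    # source atom/centroid on the ligand and target point near the residue
    if (role == "anion") {
      o1 <- ratoms[pocket$atoms$name[ratoms] %in% c("OE1", "OD1")][1]
      o2 <- ratoms[pocket$atoms$name[ratoms] %in% c("OE2", "OD2")][1]
      target <- colMeans(pxyz[c(o1, o2), , drop = FALSE]) + 3.0 * inward
      src <- amine
    } else if (role == "aromatic") {
      rring <- ratoms[pocket$atoms$name[ratoms] %in%
                        c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")]
      target <- colMeans(pxyz[rring, , drop = FALSE]) + 3.8 * inward
      src <- ring_atoms
    } else if (role == "cation") {
      cat_at <- ratoms[pocket$atoms$name[ratoms] %in%
                         c("NE", "NH1", "NH2", "NZ")]
      target <- colMeans(pxyz[cat_at, , drop = FALSE]) + 4.0 * inward
      src <- ring_atoms
    } else {  # hbond: residue donor/acceptor tip to a ligand acceptor
      tip <- ratoms[pocket$atoms$name[ratoms] %in% c("OG1", "OE1")][1]
      target <- pxyz[tip, ] + 2.9 * inward
      src <- acc[1]
    }
    for (p in chosen) {
      srcpos <- if (length(src) > 1)
        colMeans(xyz_list[[p]][src, , drop = FALSE]) else xyz_list[[p]][src, ]
      shift0 <- target - srcpos
      placed <- FALSE
      for (h in seq(0, 6, by = 1)) {
        cand <- sweep(xyz_list[[p]], 2, shift0 + c(0, 0, h), "+")
        s <- ligand; coords(s) <- cand
        recs <- detect_interactions(s, pocket, site, criteria,
                                    pose_tags = tags, receptor_tags = rtags)
        keys_hit <- unique(pocket$atoms$resno[match(recs$res_key, reskeys)])
        others <- vapply(names(frequencies), resolve, integer(1))
        others <- setdiff(others, resno)
        if (resno %in% keys_hit && !any(others %in% keys_hit)) {
          xyz_list[[p]] <- cand; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("spec error: geometric conflict planting contact with residue ",
             nm)
    }
    assignment[[nm]] <- chosen
  }
  # push non-assigned poses clear of every frequency residue
  freq_res <- vapply(names(frequencies), resolve, integer(1))
  for (p in seq_len(n)) {
    owner <- names(assignment)[vapply(assignment, function(a) p %in% a,
                                      logical(1))]
    avoid <- setdiff(freq_res, if (length(owner))
      vapply(owner, resolve, integer(1)) else integer(0))
    if (!length(avoid)) next
    for (h in c(0, 1:10)) {
      cand <- sweep(xyz_list[[p]], 2, c(0, 0, h), "+")
      s <- ligand; coords(s) <- cand
      recs <- detect_interactions(s, pocket, site, criteria,
                                  pose_tags = tags, receptor_tags = rtags)
      hit <- unique(pocket$atoms$resno[match(recs$res_key, reskeys)])
      if (!any(avoid %in% hit)) { xyz_list[[p]] <- cand; break }
      if (h == 10)
        stop("spec error: geometric conflict keeping pose ", p,
             " clear of planted residues")
    }
  }
  list(xyz_list = xyz_list, assignment = assignment)
}

#' Build a ready-to-run Monte Carlo system
#'
#' Constructs a two/three-residue pocket (GLU and PHE, plus TYR) and
#' places the ligand with one planted salt bridge (cationic amine to the
#' glutamate carboxylate) and one planted aromatic contact (benzene ring
#' stacked near the phenylalanine ring), mirroring the monitored
#' amine-carboxylate and ring-ring pairs of an interaction-stability run.
#' `monitored_pairs` are prefilled accordingly.
#'
#' @param ligand ligand `mol_structure` (default `mdma_like`).
#' @param seed RNG seed (small coordinate jitter).
#' @param jitter amplitude of the seeded jitter, A.
#' @return list with `pose`, `receptor`, `site`, `monitored_pairs`.
#' @export
make_mc_system <- function(ligand = make_toy_ligand("mdma_like"), seed = 42,
                           jitter = 0.05) {
  set.seed(seed)
  tags <- assign_pharmacophore_types(ligand)
  amine <- tags$atom[tags$tag == "cation"]
  amine <- amine[!ligand$atoms$is_h[amine]][1]
  ring_atoms <- tags$atom[tags$tag == "aromatic_ring_member" &
                            tags$ring == tags$ring[1]]
  lxyz <- coords(ligand)
  ring_ctr <- colMeans(lxyz[ring_atoms, , drop = FALSE])
  npos <- lxyz[amine, ]
  axis_nr <- unit(ring_ctr - npos)
  # glutamate: carboxylate midpoint 3.2 A beyond the amine, pointing away
  tmpl_xyz <- function(rn) as.matrix(.RESIDUE_TEMPLATES[[rn]][, c("x", "y", "z")])
  # carboxylate sits along the amine N-H bisector: salt-bridge geometry
  # without clashing the N-methyl
  amine_h <- tags$h[tags$tag == "hbond_donor" & tags$atom == amine]
  amine_h <- amine_h[!is.na(amine_h)]
  glu_tip_dir <- if (length(amine_h))
    unit(colMeans(lxyz[amine_h, , drop = FALSE]) - npos) else -axis_nr
  rot <- rotation_between(c(0, 1, 0), glu_tip_dir)  # template +y = away
  glu_xyz <- tmpl_xyz("GLU") %*% t(rot)
  glu_xyz <- sweep(glu_xyz, 2, npos + 3.2 * glu_tip_dir, "+")
  # phenylalanine: ring stacked 3.7 A above the ligand benzene centroid
  phe_xyz <- sweep(tmpl_xyz("PHE"), 2, ring_ctr + c(0, 0, 3.7), "+")
  # tyrosine: off to the side for site variety
  side_dir <- unit(c(axis_nr[2], -axis_nr[1], 0))
  rot_t <- rotation_between(c(0, 1, 0), side_dir)
  tyr_xyz <- tmpl_xyz("TYR") %*% t(rot_t)
  tyr_xyz <- sweep(tyr_xyz, 2, ring_ctr + 9.0 * side_dir, "+")
  build <- function(tmpl, xyz, resno, rn) {
    data.frame(element = tmpl$element,
               x = xyz[, 1] + stats::rnorm(nrow(xyz), 0, jitter),
               y = xyz[, 2] + stats::rnorm(nrow(xyz), 0, jitter),
               z = xyz[, 3] + stats::rnorm(nrow(xyz), 0, jitter),
               name = tmpl$name, chain = "A", resno = resno, resname = rn,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(build(.RESIDUE_TEMPLATES$GLU, glu_xyz, 1L, "GLU"),
                 build(.RESIDUE_TEMPLATES$PHE, phe_xyz, 2L, "PHE"),
                 build(.RESIDUE_TEMPLATES$TYR, tyr_xyz, 3L, "TYR"))
  receptor <- assign_partial_charges(
    perceive_bonds_and_rings(mol_structure(atoms, role = "receptor")))
  site <- select_active_site(receptor, ligand, radius = 6.0)
  glu_o <- which(receptor$atoms$resno == 1 &
                   receptor$atoms$name %in% c("OE1", "OE2"))
  phe_ring <- which(receptor$atoms$resno == 2 &
                      receptor$atoms$name %in%
                      c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  pairs <- list(
    list(label = "amine-carboxylate", ligand = amine, receptor = glu_o),
    list(label = "ring-ring", ligand = ring_atoms, receptor = phe_ring))
  list(pose = ligand, receptor = receptor, site = site,
       monitored_pairs = pairs)
}

#' Build a pose set with monotonically planted favourable contacts
#'
#' Constructs a three-residue pocket (GLU, PHE, THR) positioned against
#' the ligand's functional groups and four rigid poses of the same
#' conformer engaging 0, 1 (salt bridge), 2 (+ pi stacking) and 3
#' (+ H-bond) of them, verified with the interaction detector at build
#' time. Used to exercise the ranking behaviour of the free-energy
#' estimator: more planted favourable contacts must score better.
#'
#' @param seed RNG seed for the small coordinate jitter.
#' @param jitter jitter amplitude, A.
#' @param criteria `interaction_criteria` used for build-time verification.
#' @return list with `poses` (list of 4 ligand structures, in order of 0:3
#'   planted contacts), `receptor`, `site`, `n_contacts` (0:3).
#' @export
make_ranked_contact_set <- function(seed = 1, jitter = 0.03,
                                    criteria = interaction_criteria()) {
  set.seed(seed)
  ligand <- make_toy_ligand("mdma_like")
  tags <- assign_pharmacophore_types(ligand)
  amine <- tags$atom[tags$tag == "cation"]
  amine <- amine[!ligand$atoms$is_h[amine]][1]
  ring_atoms <- tags$atom[tags$tag == "aromatic_ring_member" &
                            tags$ring == tags$ring[1]]
  lxyz <- coords(ligand)
  ring_ctr <- colMeans(lxyz[ring_atoms, , drop = FALSE])
  npos <- lxyz[amine, ]
  amine_h <- tags$h[tags$tag == "hbond_donor" & tags$atom == amine]
  amine_h <- amine_h[!is.na(amine_h)]
  hdir <- unit(colMeans(lxyz[amine_h, , drop = FALSE]) - npos)
  tmpl_xyz <- function(rn) as.matrix(.RESIDUE_TEMPLATES[[rn]][, c("x", "y", "z")])
  # GLU carboxylate along the amine N-H bisector
  glu <- tmpl_xyz("GLU") %*% t(rotation_between(c(0, 1, 0), hdir))
  glu <- sweep(glu, 2, npos + 3.2 * hdir, "+")
  # PHE stacked under the benzene ring, laterally offset so that an
  # upward shift of the ligand disengages the pi contact before the salt
  # bridge
  phe <- sweep(tmpl_xyz("PHE"), 2, ring_ctr + c(1.5, -1.5, -3.5), "+")
  # THR hydroxyl donating to a dioxole oxygen, approaching from below
  o1 <- which(ligand$atoms$name == "O1")
  odir <- c(0, 0, -1)
  thr <- tmpl_xyz("THR") %*% t(rotation_between(c(0, 1, 0), odir))
  thr <- sweep(thr, 2, lxyz[o1, ] + 2.9 * odir, "+")
  build <- function(tmpl, xyz, resno, rn) {
    data.frame(element = tmpl$element,
               x = xyz[, 1] + stats::rnorm(nrow(xyz), 0, jitter),
               y = xyz[, 2] + stats::rnorm(nrow(xyz), 0, jitter),
               z = xyz[, 3] + stats::rnorm(nrow(xyz), 0, jitter),
               name = tmpl$name, chain = "A", resno = resno, resname = rn,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(build(.RESIDUE_TEMPLATES$GLU, glu, 1L, "GLU"),
                 build(.RESIDUE_TEMPLATES$PHE, phe, 2L, "PHE"),
                 build(.RESIDUE_TEMPLATES$THR, thr, 3L, "THR"))
  receptor <- assign_partial_charges(
    perceive_bonds_and_rings(mol_structure(atoms, role = "receptor")))
  site <- select_active_site(receptor, ligand, radius = 8.0)
  rtags <- suppressWarnings(assign_pharmacophore_types(receptor))
  contacted <- function(pose_xyz) {
    s <- ligand; coords(s) <- pose_xyz
    recs <- detect_interactions(s, receptor, site, criteria,
                                pose_tags = tags, receptor_tags = rtags)
    sort(unique(recs$resno))
  }
  # the contacts have staggered cutoff margins along +z: the H-bond
  # (2.9 A, cutoff 3.5) dies first, the pi stack (4.1 A, cutoff 5) second,
  # the in-plane salt bridge (3.4 A, cutoff 4) last. Poses are pure
  # vertical shifts of one conformer, verified with the detector.
  shift_z <- function(z) sweep(lxyz, 2, c(0, 0, z), "+")
  pose3 <- shift_z(0)
  pose2 <- shift_z(0.8)
  pose1 <- shift_z(1.6)
  pose0 <- shift_z(18)
  if (length(contacted(pose0)) != 0L ||
      !identical(contacted(pose1), 1L) ||
      !identical(contacted(pose2), c(1L, 2L)) ||
      !identical(contacted(pose3), c(1L, 2L, 3L)))
    stop("spec error: ranked-contact construction failed verification")
  poses <- lapply(list(pose0, pose1, pose2, pose3), function(x) {
    s <- ligand; coords(s) <- x; s
  })
  list(poses = poses, receptor = receptor, site = site, n_contacts = 0:3)
}
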