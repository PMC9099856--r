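#' Coefficients of the component-structured binding free-energy estimate
#'
#' All coefficients are declared defaults chosen for sane magnitudes and
#' are fully configurable; the estimate preserves the term inventory of an
#' enthalpic-entropic scoring scheme (nonbonded enthalpy, H-bond rewards,
#' Born-like polar desolvation, lost-H-bond penalties, nonpolar solvation,
#' internal strain, rotor-freezing entropy) without reproducing any
#' proprietary calibration.
#'
#' @param hbond_strong reward per strong H-bond, kcal/mol.
#' @param hbond_weak reward per weak H-bond, kcal/mol.
#' @param salt_bridge reward per salt bridge, kcal/mol.
#' @param born_scale dielectric transfer factor on the Born term; the
#'   default `1/4 - 1/80` is the water-to-protein two-dielectric transfer.
#' @param born_radius_offset Born radius = covalent radius + this offset
#'   (A).
#' @param lost_hbond penalty per buried unsatisfied donor/acceptor.
#' @param nonpolar_per_area nonpolar solvation reward per buried Angstrom^2
#'   (negative).
#' @param entropy_per_rotor penalty per frozen rotatable bond.
#' @param buried_threshold buried fraction above which a polar atom counts
#'   as buried.
#' @param contact_dist heavy-atom distance defining receptor contact for
#'   rotor freezing (A).
#' @param points_per_atom SAS sampling density used for burial estimates.
#' @return object of class `dg_params`.
#' @export
dg_params <- function(hbond_strong = -1.0, hbond_weak = -0.5,
                      salt_bridge = -1.0,
                      born_scale = 1 / 4 - 1 / 80,
                      born_radius_offset = 0.5,
                      lost_hbond = 0.6, nonpolar_per_area = -0.025,
                      entropy_per_rotor = 0.65, buried_threshold = 0.5,
                      contact_dist = 4.0, points_per_atom = 128) {
  structure(list(hbond_strong = hbond_strong, hbond_weak = hbond_weak,
                 salt_bridge = salt_bridge, born_scale = born_scale,
                 born_radius_offset = born_radius_offset,
                 lost_hbond = lost_hbond,
                 nonpolar_per_area = nonpolar_per_area,
                 entropy_per_rotor = entropy_per_rotor,
                 buried_threshold = buried_threshold,
                 contact_dist = contact_dist,
                 points_per_atom = points_per_atom),
            class = "dg_params")
}

#' @keywords internal
per_atom_area <- function(s, p, occluders = NULL) {
  pts <- sample_sas(s, p, occluders = occluders)
  area <- numeric(nrow(s$atoms))
  if (nrow(pts)) {
    agg <- tapply(pts$area, pts$atom, sum)
    area[as.integer(names(agg))] <- as.numeric(agg)
  }
  area
}

#' Component-structured binding free-energy estimate
#'
#' Scores one ligand pose against the receptor active site as a sum of
#' interpretable components: Lennard-Jones and Coulomb enthalpy from the
#' Monte Carlo energy model, H-bond and salt-bridge rewards from the typed
#' interaction detector, Born-like polar desolvation of ligand charges,
#' penalties for buried unsatisfied donors/acceptors, nonpolar solvation
#' proportional to buried surface, internal conformational strain relative
#' to the relaxed free ligand, and an entropic penalty per rotor frozen by
#' receptor contact. Pure function of its inputs.
#'
#' @param pose ligand `mol_structure` (bonds perceived, charges assigned).
#' @param receptor receptor `mol_structure` (charges assigned).
#' @param site `active_site`.
#' @param params a `dg_params`.
#' @param criteria `interaction_criteria` for the detector.
#' @param model `energy_model` for the enthalpic terms.
#' @return object of class `dg_breakdown`: all components plus `total`
#'   (kcal/mol).
#' @export
estimate_dg <- function(pose, receptor, site, params = dg_params(),
                        criteria = interaction_criteria(),
                        model = energy_model()) {
  if (all(pose$atoms$charge == 0))
    stop("input error: pose has no partial charges; run assign_partial_charges()")
  comp <- system_energy(pose, receptor, site, model, components = TRUE)
  recs <- detect_interactions(pose, receptor, site, criteria)
  e_hbond <- params$hbond_strong * sum(recs$kind == "hbond_strong") +
    params$hbond_weak * sum(recs$kind == "hbond_weak") +
    params$salt_bridge * sum(recs$kind == "salt_bridge")
  # burial from per-atom SAS with and without the receptor
  sasp <- ec_params(points_per_atom = params$points_per_atom)
  free_area <- per_atom_area(pose, sasp)
  rec_site <- receptor
  keep <- site_atom_idx(receptor, site)
  rec_site$atoms <- receptor$atoms[keep, , drop = FALSE]
  rec_site$bonds <- matrix(integer(), ncol = 2); rec_site$rings <- list()
  bound_area <- per_atom_area(pose, sasp, occluders = rec_site)
  bf <- ifelse(free_area > 0, pmax(0, 1 - bound_area / free_area), 0)
  q <- pose$atoms$charge
  r_born <- element_radius(pose$atoms$element, "covalent") +
    params$born_radius_offset
  polar_desolv <- sum(params$born_scale * 166 * q^2 * bf / r_born)
  # buried unsatisfied polar atoms
  tags <- assign_pharmacophore_types(pose)
  polar_atoms <- unique(tags$atom[tags$tag %in%
                                    c("hbond_donor", "hbond_acceptor")])
  bonded_atoms <- unique(unlist(lapply(
    strsplit(recs$lig_atoms[recs$kind %in%
                              c("hbond_weak", "hbond_strong", "salt_bridge")],
             ","), as.integer)))
  unsat <- setdiff(polar_atoms[bf[polar_atoms] > params$buried_threshold],
                   bonded_atoms)
  lost_hbond_penalty <- params$lost_hbond * length(unsat)
  nonpolar_solv <- params$nonpolar_per_area *
    max(0, sum(free_area) - sum(bound_area))
  # internal strain vs the relaxed free ligand
  ctx_free <- energy_context(pose, NULL, NULL, model)
  e_conf <- as.numeric(energy_eval(coords(pose), ctx_free))
  relaxed <- minimize_in_context(coords(pose), ctx_free, n_steps = 50)
  internal_strain <- max(0, e_conf - relaxed$energy)
  # rotor freezing: terminal fragment in receptor contact
  ctx <- energy_context(pose, receptor, site, model)
  frozen <- 0L
  if (nrow(ctx$rotors) && nrow(ctx$rec_xyz)) {
    rec_heavy <- ctx$rec_xyz[!receptor$atoms$is_h[keep], , drop = FALSE]
    for (r in seq_len(nrow(ctx$rotors))) {
      frag <- ctx$movers[[r]]$set
      frag <- frag[!pose$atoms$is_h[frag]]
      if (!length(frag)) next
      d <- cross_dist(coords(pose)[frag, , drop = FALSE], rec_heavy)
      if (min(d) <= params$contact_dist) frozen <- frozen + 1L
    }
  }
  entropy_penalty <- params$entropy_per_rotor * frozen
  out <- list(e_vdw = comp$vdw, e_coulomb = comp$coulomb, e_hbond = e_hbond,
              polar_desolvation = polar_desolv,
              lost_hbond_penalty = lost_hbond_penalty,
              nonpolar_solvation = nonpolar_solv,
              internal_strain = internal_strain,
              entropy_penalty = entropy_penalty,
              n_frozen_rotors = frozen)
  out$total <- out$e_vdw + out$e_coulomb + out$e_hbond +
    out$polar_desolvation + out$lost_hbond_penalty +
    out$nonpolar_solvation + out$internal_strain + out$entropy_penalty
  class(out) <- "dg_breakdown"
  out
}

#' @export
print.dg_breakdown <- function(x, ...) {
  cat("Binding free-energy breakdown (kcal/mol):\n")
  for (nm in c("e_vdw", "e_coulomb", "e_hbond", "polar_desolvation",
               "lost_hbond_penalty", "nonpolar_solvation",
               "internal_strain", "entropy_penalty"))
    cat(sprintf("  %-20s %8.3f\n", nm, x[[nm]]))
  cat(sprintf("  %-20s %8.3f\n", "total", x$total))
  invisible(x)
}

#' Breakdown table for a set of poses
#'
#' @param poses list of ligand `mol_structure` poses or a `pose_ensemble`.
#' @param receptor,site,params,criteria,model as in [estimate_dg()].
#' @return data.frame with one row per pose and one column per component.
#' @export
dg_breakdown_table <- function(poses, receptor, site, params = dg_params(),
                               criteria = interaction_criteria(),
                               model = energy_model()) {
  poses <- ensemble_poses(poses)
  rows <- lapply(seq_along(poses), function(i) {
    b <- estimate_dg(poses[[i]], receptor, site, params, criteria, model)
    data.frame(pose = i, e_vdw = b$e_vdw, e_coulomb = b$e_coulomb,
               e_hbond = b$e_hbond, polar_desolvation = b$polar_desolvation,
               lost_hbond_penalty = b$lost_hbond_penalty,
               nonpolar_solvation = b$nonpolar_solvation,
               internal_strain = b$internal_strain,
               entropy_penalty = b$entropy_penalty, total = b$total)
  })
  do.call(rbind, rows)
}
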