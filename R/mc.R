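#' Monte Carlo configuration
#'
#' Defaults reproduce the Boltzmann-jump protocol: temperature 1000 K,
#' per-move torsion rmsd 60 degrees, 1000 steps, 20 minimization steps per
#' move, Metropolis acceptance.
#'
#' @param temperature simulation temperature in Kelvin.
#' @param torsion_rms exact rms of the proposal torsion deltas, degrees.
#' @param n_steps number of Monte Carlo steps.
#' @param minimize_steps steepest-descent iterations after each move.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param monitored_pairs list of monitored pairs (see
#'   [monitor_pair_distances()]).
#' @param exact_rms if `FALSE`, draws are left unscaled and `torsion_rms`
#'   acts as the width of the normal proposal instead of an exact per-move
#'   rms.
#' @return object of class `mc_config`.
#' @export
mc_config <- function(temperature = 1000, torsion_rms = 60, n_steps = 1000,
                      minimize_steps = 20, seed = 42,
                      monitored_pairs = list(), exact_rms = TRUE) {
  stopifnot(temperature > 0, torsion_rms > 0, torsion_rms <= 180,
            n_steps >= 0, minimize_steps >= 0)
  structure(list(temperature = temperature, torsion_rms = torsion_rms,
                 n_steps = n_steps, minimize_steps = minimize_steps,
                 seed = as.integer(seed), monitored_pairs = monitored_pairs,
                 exact_rms = exact_rms),
            class = "mc_config")
}

#' Minimal intermolecular energy model
#'
#' Lennard-Jones 12-6 plus Coulomb electrostatics under a
#' distance-dependent dielectric (epsilon = `dielectric_factor` * r) and a
#' 3-fold torsion potential on rotatable bonds. A deliberately simple
#' stand-in force field: absolute energies are not meant to be compared
#' with published binding energies, only the search protocol's behaviour
#' matters.
#'
#' @param dielectric_factor distance-dependent dielectric prefactor
#'   (epsilon = factor * r; default 4).
#' @param torsion_barrier 3-fold torsion barrier height, kcal/mol.
#' @param nonbonded_cutoff pair cutoff, Angstrom.
#' @param overlap_dist below this separation the repulsion is evaluated at
#'   the cap distance and flagged.
#' @return object of class `energy_model`.
#' @export
energy_model <- function(dielectric_factor = 4, torsion_barrier = 1.4,
                         nonbonded_cutoff = 10, overlap_dist = 0.1) {
  structure(list(coulomb_k = .COULOMB_K,
                 dielectric_factor = dielectric_factor,
                 torsion_barrier = torsion_barrier,
                 nonbonded_cutoff = nonbonded_cutoff,
                 overlap_dist = overlap_dist),
            class = "energy_model")
}

# Precomputed immutable evaluation context for one ligand/receptor pair.
#' @keywords internal
energy_context <- function(ligand, receptor, site, model) {
  sidx <- if (is.null(receptor) || is.null(site)) integer(0) else
    site_atom_idx(receptor, site)
  lj_l <- lj_params_for(ligand$atoms$element)
  lj_r <- lj_params_for(if (length(sidx)) receptor$atoms$element[sidx]
                        else character(0))
  ctx <- list(
    model = model,
    rec_xyz = if (length(sidx)) coords(receptor)[sidx, , drop = FALSE] else
      matrix(numeric(), 0, 3),
    q_rec = if (length(sidx)) receptor$atoms$charge[sidx] else numeric(0),
    q_lig = ligand$atoms$charge,
    eps_ij = sqrt(outer(lj_l$eps, lj_r$eps)),
    rmin_ij = outer(lj_l$rmin, lj_r$rmin, "+"),
    rotors = list_rotatable_bonds(ligand),
    ligand = ligand
  )
  n <- nrow(ligand$atoms)
  # intra-ligand nonbonded: pairs 4+ bonds apart (1-2/1-3/1-4 are handled
  # by fixed geometry and the torsion term)
  if (nrow(ligand$bonds)) {
    g <- igraph::graph_from_edgelist(ligand$bonds, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    topo <- igraph::distances(g)
    pr <- which(upper.tri(topo) & topo >= 4, arr.ind = TRUE)
  } else pr <- matrix(integer(), ncol = 2)
  ctx$intra_pairs <- pr
  if (nrow(pr)) {
    ctx$intra_eps <- sqrt(lj_l$eps[pr[, 1]] * lj_l$eps[pr[, 2]])
    ctx$intra_rmin <- lj_l$rmin[pr[, 1]] + lj_l$rmin[pr[, 2]]
    ctx$intra_qq <- ctx$q_lig[pr[, 1]] * ctx$q_lig[pr[, 2]]
  }
  # torsion quadruples a-i-j-b (all substituent pairs, averaged per bond
  # so the term is invariant to atom relabeling) and mover sets per rotor
  k <- nrow(ctx$rotors)
  quads <- matrix(integer(), 0, 4)
  quad_w <- numeric(0)
  movers <- list()
  if (k) {
    for (r in seq_len(k)) {
      i <- ctx$rotors[r, 1]; j <- ctx$rotors[r, 2]
      nb_i <- setdiff(neighbours_of(ligand, i), j)
      nb_j <- setdiff(neighbours_of(ligand, j), i)
      combs <- expand.grid(a = nb_i, b = nb_j)
      quads <- rbind(quads, cbind(combs$a, i, j, combs$b))
      quad_w <- c(quad_w, rep(1 / nrow(combs), nrow(combs)))
      side_j <- bond_fragment(ligand, i, j)
      side_i <- setdiff(seq_len(n), side_j)
      if (length(side_j) <= length(side_i)) {
        movers[[r]] <- list(set = setdiff(side_j, j), from = i, about = j)
      } else {
        movers[[r]] <- list(set = setdiff(side_i, i), from = j, about = i)
      }
    }
  }
  ctx$quads <- quads
  ctx$quad_w <- quad_w
  ctx$movers <- movers
  ctx
}

#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] / vnorm(b2) - n1[3] * b2[2] / vnorm(b2),
          n1[3] * b2[1] / vnorm(b2) - n1[1] * b2[3] / vnorm(b2),
          n1[1] * b2[2] / vnorm(b2) - n1[2] * b2[1] / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# pair energy pieces, vectorized over distance vectors/matrices
#' @keywords internal
lj_energy <- function(r, eps, rmin) {
  sr6 <- (rmin / r)^6
  eps * (sr6^2 - 2 * sr6)
}

#' @keywords internal
energy_eval <- function(lig_xyz, ctx, components = FALSE) {
  m <- ctx$model
  flagged <- FALSE
  e_lj <- 0; e_coul <- 0
  if (nrow(ctx$rec_xyz)) {
    d <- cross_dist(lig_xyz, ctx$rec_xyz)
    if (any(d < m$overlap_dist)) { d[d < m$overlap_dist] <- m$overlap_dist
      flagged <- TRUE }
    inr <- d <= m$nonbonded_cutoff
    if (any(inr)) {
      e_lj <- sum(lj_energy(d[inr], ctx$eps_ij[inr], ctx$rmin_ij[inr]))
      qq <- outer(ctx$q_lig, ctx$q_rec)
      e_coul <- sum(m$coulomb_k * qq[inr] /
                      (m$dielectric_factor * d[inr]^2))
    }
  }
  e_lj_i <- 0; e_coul_i <- 0
  if (nrow(ctx$intra_pairs)) {
    pr <- ctx$intra_pairs
    dv <- lig_xyz[pr[, 1], , drop = FALSE] - lig_xyz[pr[, 2], , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    if (any(d < m$overlap_dist)) { d[d < m$overlap_dist] <- m$overlap_dist
      flagged <- TRUE }
    ok <- d <= m$nonbonded_cutoff
    e_lj_i <- sum(lj_energy(d[ok], ctx$intra_eps[ok], ctx$intra_rmin[ok]))
    e_coul_i <- sum(m$coulomb_k * ctx$intra_qq[ok] /
                      (m$dielectric_factor * d[ok]^2))
  }
  e_tors <- 0
  if (nrow(ctx$quads)) {
    for (r in seq_len(nrow(ctx$quads))) {
      q <- ctx$quads[r, ]
      phi <- dihedral_angle(lig_xyz[q[1], ], lig_xyz[q[2], ],
                            lig_xyz[q[3], ], lig_xyz[q[4], ])
      e_tors <- e_tors + ctx$quad_w[r] * m$torsion_barrier / 2 *
        (1 + cos(3 * phi * pi / 180))
    }
  }
  total <- e_lj + e_coul + e_lj_i + e_coul_i + e_tors
  if (!components) return(structure(total, flagged = flagged))
  list(total = total, vdw = e_lj, coulomb = e_coul,
       intra_vdw = e_lj_i, intra_coulomb = e_coul_i, torsion = e_tors,
       internal = e_lj_i + e_coul_i + e_tors, flagged = flagged)
}

#' Ligand-receptor system energy
#'
#' Pure function: Lennard-Jones + Coulomb over ligand/active-site pairs
#' within the cutoff, intra-ligand nonbonded terms for atom pairs four or
#' more bonds apart, and a 3-fold torsion term per rotatable bond.
#' Overlapping atoms (closer than the cap distance) contribute a capped
#' repulsion and set the `flagged` attribute.
#'
#' @param ligand ligand `mol_structure` (typed, charged, bonds perceived).
#' @param receptor receptor `mol_structure` (charged).
#' @param site `active_site`.
#' @param model an `energy_model`.
#' @param components return the term breakdown instead of a scalar.
#' @return total energy in kcal/mol (attribute `flagged`), or a list of
#'   components when `components = TRUE`.
#' @export
system_energy <- function(ligand, receptor, site, model = energy_model(),
                          components = FALSE) {
  ctx <- energy_context(ligand, receptor, site, model)
  energy_eval(coords(ligand), ctx, components = components)
}

# apply a torsion offset vector sequentially (fixed rotor order); axes are
# taken from the running coordinates so fragments stay rigid-valid
#' @keywords internal
apply_torsions_xyz <- function(xyz, ctx, theta) {
  for (r in seq_along(theta)) {
    if (theta[r] == 0) next
    mv <- ctx$movers[[r]]
    if (!length(mv$set)) next
    axis <- xyz[mv$about, ] - xyz[mv$from, ]
    xyz[mv$set, ] <- rotate_points(xyz[mv$set, , drop = FALSE],
                                   xyz[mv$about, ], axis, theta[r])
  }
  xyz
}

#' Random torsional perturbation with exact rms
#'
#' Torsion deltas are drawn from a zero-mean normal distribution and
#' rescaled so their root-mean-square equals `torsion_rms` exactly; each
#' rotatable bond is then rotated about its axis, moving the smaller
#' fragment. Uses R's global RNG stream.
#'
#' @param conformer ligand `mol_structure` with bonds perceived.
#' @param rotors rotor matrix from [list_rotatable_bonds()] (computed when
#'   `NULL`).
#' @param torsion_rms target rms of the deltas, degrees.
#' @param exact_rms rescale draws to the exact rms (default) or leave them
#'   as a width-`torsion_rms` normal sample.
#' @return the perturbed conformer, with attribute `torsion_deltas`.
#' @export
perturb_torsions <- function(conformer, rotors = NULL, torsion_rms = 60,
                             exact_rms = TRUE) {
  if (is.null(rotors)) rotors <- list_rotatable_bonds(conformer)
  k <- nrow(rotors)
  if (!k) {
    warning("no rotatable bonds: perturbation is a no-op")
    attr(conformer, "torsion_deltas") <- numeric(0)
    return(conformer)
  }
  deltas <- stats::rnorm(k)
  if (exact_rms) {
    deltas <- deltas * torsion_rms / sqrt(mean(deltas^2))
  } else {
    deltas <- deltas * torsion_rms
  }
  for (r in seq_len(k)) {
    conformer <- rotate_about_bond(conformer, rotors[r, 1], rotors[r, 2],
                                   deltas[r])
  }
  attr(conformer, "torsion_deltas") <- deltas
  conformer
}

#' Torsion-space steepest-descent minimization
#'
#' Performs exactly `n_steps` steepest-descent iterations on the ligand's
#' rotatable dihedrals (numeric gradient, backtracking step control). The
#' energy is non-increasing across the iterations; receptor coordinates
#' are never touched.
#'
#' @param ligand ligand `mol_structure`.
#' @param receptor receptor `mol_structure`.
#' @param site `active_site`.
#' @param model `energy_model`.
#' @param n_steps iteration count (default 20).
#' @param step0 initial step length in degrees.
#' @return minimized ligand, with attributes `energy` (final) and
#'   `n_iterations`.
#' @export
minimize_ligand <- function(ligand, receptor, site, model = energy_model(),
                            n_steps = 20, step0 = 10) {
  ctx <- energy_context(ligand, receptor, site, model)
  res <- minimize_in_context(coords(ligand), ctx, n_steps, step0)
  coords(ligand) <- res$xyz
  attr(ligand, "energy") <- res$energy
  attr(ligand, "n_iterations") <- res$n_iterations
  ligand
}

#' @keywords internal
minimize_in_context <- function(xyz, ctx, n_steps, step0 = 10, dtheta = 0.5) {
  e <- as.numeric(energy_eval(xyz, ctx))
  k <- nrow(ctx$rotors)
  iters <- 0L
  if (k == 0L || n_steps == 0L)
    return(list(xyz = xyz, energy = e, n_iterations = as.integer(n_steps)))
  for (it in seq_len(n_steps)) {
    iters <- iters + 1L
    g <- numeric(k)
    for (r in seq_len(k)) {
      th <- numeric(k)
      th[r] <- dtheta
      ep <- as.numeric(energy_eval(apply_torsions_xyz(xyz, ctx, th), ctx))
      th[r] <- -dtheta
      em <- as.numeric(energy_eval(apply_torsions_xyz(xyz, ctx, th), ctx))
      g[r] <- (ep - em) / (2 * dtheta)
    }
    gn <- vnorm(g)
    if (gn < 1e-10) next  # stationary; iteration still counts
    dir <- -g / gn
    step <- step0
    improved <- FALSE
    while (step > 1e-3) {
      cand <- apply_torsions_xyz(xyz, ctx, dir * step)
      ec <- as.numeric(energy_eval(cand, ctx))
      if (ec < e) { xyz <- cand; e <- ec; improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) next  # keep current point: energy never increases
  }
  list(xyz = xyz, energy = e, n_iterations = iters)
}

#' Metropolis acceptance rule
#'
#' Downhill moves (`delta_e <= 0`) are always accepted; uphill moves are
#' accepted with probability `exp(-delta_e / (R T))`,
#' R = 1.987204e-3 kcal/(mol K). Consumes one uniform draw from R's global
#' RNG stream for uphill moves.
#'
#' @param delta_e energy change in kcal/mol.
#' @param temperature temperature in Kelvin.
#' @return logical acceptance flag.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  stopifnot(temperature > 0)
  if (delta_e <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_e / (.R_KCAL * temperature))
}

#' Run a Metropolis Monte Carlo torsional search
#'
#' Boltzmann-jump protocol: each step draws a torsional perturbation with
#' exact rms `torsion_rms`, applies `minimize_steps` steepest-descent
#' iterations, and subjects the post-minimization energy to the Metropolis
#' criterion against the current state. Rejected proposals restore the
#' previous conformer. The receptor is held rigid throughout. Fully
#' reproducible from the config seed.
#'
#' @param pose starting ligand `mol_structure` (typed, charged).
#' @param receptor receptor `mol_structure` (charged).
#' @param site `active_site`.
#' @param cfg an `mc_config`.
#' @param model an `energy_model`.
#' @return object of class `mc_trajectory`: `steps` data.frame (`index`,
#'   `proposed_energy`, `post_min_energy`, `delta_e`, `accepted`,
#'   `energy`), `torsion_deltas` matrix, `snapshots` (list of ligand
#'   coordinate matrices; element 1 is the initial state, element k+1 the
#'   state after step k), `monitored` distance series, plus the inputs.
#' @export
run_mc <- function(pose, receptor, site, cfg = mc_config(),
                   model = energy_model()) {
  set.seed(cfg$seed)
  ctx <- energy_context(pose, receptor, site, model)
  k <- nrow(ctx$rotors)
  if (!k) warning("ligand has no rotatable bonds; trajectory is static")
  rec_xyz_in <- coords(receptor)
  xyz <- coords(pose)
  e_cur <- as.numeric(energy_eval(xyz, ctx))
  n <- cfg$n_steps
  steps <- data.frame(index = seq_len(n),
                      proposed_energy = rep(NA_real_, n),
                      post_min_energy = rep(NA_real_, n),
                      delta_e = rep(NA_real_, n),
                      accepted = rep(NA, n), energy = rep(NA_real_, n))
  deltas_m <- matrix(0, n, max(1, k))
  snapshots <- vector("list", n + 1L)
  snapshots[[1L]] <- xyz
  for (st in seq_len(n)) {
    if (k) {
      d <- stats::rnorm(k)
      d <- if (cfg$exact_rms) d * cfg$torsion_rms / sqrt(mean(d^2)) else
        d * cfg$torsion_rms
      prop <- apply_torsions_xyz(xyz, ctx, d)
      deltas_m[st, seq_len(k)] <- d
    } else prop <- xyz
    e_prop <- as.numeric(energy_eval(prop, ctx))
    mres <- minimize_in_context(prop, ctx, cfg$minimize_steps)
    de <- mres$energy - e_cur
    acc <- metropolis_accept(de, cfg$temperature)
    if (acc) { xyz <- mres$xyz; e_cur <- mres$energy }
    steps$proposed_energy[st] <- e_prop
    steps$post_min_energy[st] <- mres$energy
    steps$delta_e[st] <- de
    steps$accepted[st] <- acc
    steps$energy[st] <- e_cur
    snapshots[[st + 1L]] <- xyz
  }
  stopifnot(identical(rec_xyz_in, coords(receptor)))  # receptor held rigid
  traj <- structure(list(steps = steps,
                         torsion_deltas = deltas_m[, seq_len(max(1, k)),
                                                   drop = FALSE],
                         snapshots = snapshots, receptor = receptor,
                         ligand = pose, site = site, config = cfg,
                         model = model, monitored = NULL),
                    class = "mc_trajectory")
  if (length(cfg$monitored_pairs))
    traj$monitored <- monitor_pair_distances(traj, cfg$monitored_pairs)
  traj
}

#' @export
print.mc_trajectory <- function(x, ...) {
  n <- nrow(x$steps)
  acc <- if (n) mean(x$steps$accepted) else NA
  cat(sprintf("<mc_trajectory: %d steps, acceptance %.2f, T = %g K>\n",
              n, acc, x$config$temperature))
  invisible(x)
}

#' Fit the effective temperature of uphill Metropolis acceptance
#'
#' Maximum-likelihood fit of T in `p(accept | dE) = exp(-dE/(R T))` from
#' observed uphill accept/reject outcomes.
#'
#' @param delta_e positive energy increases, kcal/mol.
#' @param accepted logical outcomes.
#' @param interval search interval for T in Kelvin.
#' @return fitted temperature in Kelvin.
#' @export
fit_acceptance_temperature <- function(delta_e, accepted,
                                       interval = c(10, 1e5)) {
  stopifnot(length(delta_e) == length(accepted), all(delta_e > 0))
  nll <- function(tt) {
    p <- exp(-delta_e / (.R_KCAL * tt))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(accepted, log(p), log(1 - p)))
  }
  stats::optimize(nll, interval)$minimum
}
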