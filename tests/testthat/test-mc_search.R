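test_that("torsional proposals hit the requested rms exactly", {
  chain <- make_toy_ligand("probe_chain")  # 8 rotors
  rot <- list_rotatable_bonds(chain)
  expect_equal(nrow(rot), 8L)
  set.seed(1)
  p <- perturb_torsions(chain, rot, torsion_rms = 60)
  d <- attr(p, "torsion_deltas")
  expect_equal(sqrt(mean(d^2)), 60, tolerance = 1e-9)
  # single rotor: |delta| equals the rms
  but <- simple_structure(cbind(c(0, 1.26, 2.52, 3.78),
                                c(0, 0.85, 0, 0.85), 0))
  set.seed(2)
  p1 <- perturb_torsions(but, torsion_rms = 60)
  expect_equal(abs(attr(p1, "torsion_deltas")), 60, tolerance = 1e-9)
  # determinism under a fixed seed
  set.seed(9); a <- perturb_torsions(chain, rot, 60)
  set.seed(9); b <- perturb_torsions(chain, rot, 60)
  expect_identical(coords(a), coords(b))
  # no rotors: warning and identity
  ring <- make_toy_ligand("probe_ring")
  expect_warning(pr <- perturb_torsions(ring), "no rotatable")
  expect_identical(coords(pr), coords(ring))
})

test_that("torsion rotations move only the smaller bond fragment", {
  lig <- fx_ligand()
  rot <- list_rotatable_bonds(lig)
  before <- coords(lig)
  after <- coords(rotate_about_bond(lig, rot[1, 1], rot[1, 2], 35))
  moved <- rowSums((after - before)^2) > 1e-12
  expect_lt(sum(moved), nrow(before) / 2 + 1)
  # bond lengths are preserved by the rotation
  dl <- function(x) sqrt(rowSums((x[lig$bonds[, 1], ] -
                                    x[lig$bonds[, 2], ])^2))
  expect_equal(dl(after), dl(before), tolerance = 1e-9)
})

test_that("system energy matches closed forms", {
  sys <- fx_mc_system()
  # infinite separation: no intermolecular terms
  far <- sys$pose
  coords(far) <- sweep(coords(far), 2, c(500, 0, 0), "+")
  comp <- system_energy(far, sys$receptor, sys$site, components = TRUE)
  expect_equal(comp$vdw, 0)
  expect_equal(comp$coulomb, 0)
  # two opposite unit charges at 2 A under eps = 4r:
  # 332.06 * (-1) / (4 * 2^2) = -20.75375
  mk_ion <- function(el, q, x, role) {
    s <- mol_structure(data.frame(element = el, x = x, y = 0, z = 0,
                                  name = el, chain = "A", resno = 1L,
                                  resname = "NA"), role = role)
    s$atoms$charge <- q
    s
  }
  lig <- mk_ion("NA", 1, 0, "ligand")
  rec <- mk_ion("CL", -1, 2, "receptor")
  site <- select_active_site(rec, lig, radius = 10)
  m <- energy_model()
  comp2 <- system_energy(lig, rec, site, m, components = TRUE)
  expect_equal(comp2$coulomb, 332.06 * (-1) / (4 * 2^2), tolerance = 1e-9)
  # energy is symmetric in atom relabeling of the pose
  lig2 <- fx_ligand()
  perm <- rev(seq_len(nrow(lig2$atoms)))
  lp <- lig2
  lp$atoms <- lig2$atoms[perm, ]
  rownames(lp$atoms) <- NULL
  remap <- match(seq_len(nrow(lig2$atoms)), perm)
  lp$bonds <- matrix(remap[lig2$bonds], ncol = 2)
  lp$rings <- lapply(lig2$rings, function(r) {
    r$atoms <- remap[r$atoms]; r })
  e1 <- as.numeric(system_energy(lig2, sys$receptor, sys$site))
  e2 <- as.numeric(system_energy(lp, sys$receptor, sys$site))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("overlapping atoms are capped and flagged", {
  mk <- function(x) {
    s <- mol_structure(data.frame(element = "C", x = x, y = 0, z = 0,
                                  name = "C1", chain = "A", resno = 1L,
                                  resname = "LIG"),
                       role = if (x == 0) "ligand" else "receptor")
    s
  }
  lig <- mk(0); rec <- mk(0.05)
  site <- select_active_site(rec, lig, radius = 5)
  e <- system_energy(lig, rec, site)
  expect_true(attr(e, "flagged"))
  expect_true(is.finite(as.numeric(e)))
})

test_that("minimization runs exactly n non-increasing steps", {
  sys <- fx_mc_system()
  m0 <- minimize_ligand(sys$pose, sys$receptor, sys$site, n_steps = 0)
  expect_identical(coords(m0), coords(sys$pose))
  e_before <- as.numeric(system_energy(sys$pose, sys$receptor, sys$site))
  m20 <- minimize_ligand(sys$pose, sys$receptor, sys$site, n_steps = 20)
  expect_equal(attr(m20, "n_iterations"), 20L)
  expect_lte(attr(m20, "energy"), e_before)
  # random starts: energy never increases
  set.seed(4)
  for (k in 1:3) {
    p <- perturb_torsions(sys$pose, torsion_rms = 40)
    e0 <- as.numeric(system_energy(p, sys$receptor, sys$site))
    mk <- minimize_ligand(p, sys$receptor, sys$site, n_steps = 5)
    expect_lte(attr(mk, "energy"), e0 + 1e-9)
  }
})

test_that("the Metropolis rule reproduces the Boltzmann acceptance law", {
  expect_true(metropolis_accept(0, 1000))
  expect_true(metropolis_accept(-3, 1))
  # closed form: dE = R*T at T = 1000 K accepts with p = exp(-1)
  R <- 1.987204e-3
  set.seed(11)
  acc <- replicate(20000, metropolis_accept(R * 1000, 1000))
  expect_equal(mean(acc), exp(-1), tolerance = 0.02)
  # dE = R*T*ln(2): acceptance 1/2
  set.seed(12)
  acc2 <- replicate(20000, metropolis_accept(R * 1000 * log(2), 1000))
  expect_equal(mean(acc2), 0.5, tolerance = 0.02)
  # near-zero temperature: no uphill acceptance
  set.seed(13)
  expect_false(any(replicate(200, metropolis_accept(0.01, 1e-6))))
})

test_that("fitted acceptance temperature recovers the true temperature", {
  set.seed(21)
  de <- runif(10000, 0.5, 6)
  acc <- vapply(de, metropolis_accept, logical(1), temperature = 1000)
  t_hat <- fit_acceptance_temperature(de, acc)
  expect_lt(abs(t_hat - 1000) / 1000, 0.05)
})

test_that("run_mc is reproducible, bounded and leaves the receptor intact", {
  sys <- fx_mc_system()
  cfg <- mc_config(n_steps = 8, minimize_steps = 2, seed = 5,
                   monitored_pairs = sys$monitored_pairs)
  rec_before <- coords(sys$receptor)
  t1 <- run_mc(sys$pose, sys$receptor, sys$site, cfg)
  t2 <- run_mc(sys$pose, sys$receptor, sys$site, cfg)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$steps, t2$steps)
  expect_identical(coords(sys$receptor), rec_before)
  expect_equal(nrow(t1$steps), 8L)
  expect_length(t1$snapshots, 9L)
  # per-step proposal rms is exact
  k <- nrow(list_rotatable_bonds(sys$pose))
  rms <- sqrt(rowMeans(t1$torsion_deltas[, seq_len(k), drop = FALSE]^2))
  expect_equal(rms, rep(60, 8), tolerance = 1e-9)
  # zero steps: initial snapshot only
  t0 <- run_mc(sys$pose, sys$receptor, sys$site,
               mc_config(n_steps = 0, seed = 1))
  expect_equal(nrow(t0$steps), 0L)
  expect_length(t0$snapshots, 1L)
})

test_that("at vanishing temperature the energy series is non-increasing", {
  sys <- fx_mc_system()
  cfg <- mc_config(n_steps = 12, minimize_steps = 2, seed = 2,
                   temperature = 1e-6)
  traj <- run_mc(sys$pose, sys$receptor, sys$site, cfg)
  expect_true(all(diff(traj$steps$energy) <= 1e-9))
  expect_false(any(traj$steps$accepted & traj$steps$delta_e > 0))
})
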