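# helper: one GLU + one PHE pocket with the ligand at a controlled offset
planted_complex <- function(dz_ring = 0) {
  sys <- fx_mc_system()
  list(pose = sys$pose, receptor = sys$receptor, site = sys$site)
}

test_that("criteria validation enforces positivity and strictness ordering", {
  expect_error(interaction_criteria(hbond_max_dist = -1), "> 0")
  expect_error(interaction_criteria(hbond_strong_dist = 3.6),
               "strict")
  c0 <- interaction_criteria()
  expect_equal(c0$pi_centroid_max_dist, 5.0)
})

test_that("a planted carboxylate near the amine yields a salt bridge", {
  sys <- fx_mc_system()
  recs <- detect_interactions(sys$pose, sys$receptor, sys$site)
  sb <- recs[recs$kind == "salt_bridge", ]
  expect_gte(nrow(sb), 1L)
  expect_true(all(sb$resname == "GLU"))
  expect_true(all(sb$distance <= 4.0))
})

test_that("parallel rings inside/outside the centroid cutoff", {
  # receptor = one PHE whose ring centroid sits at a controlled distance
  mk <- function(sep) {
    tmpl <- bindingspace:::.RESIDUE_TEMPLATES$PHE
    rec <- perceive_bonds_and_rings(mol_structure(
      data.frame(element = tmpl$element, x = tmpl$x, y = tmpl$y,
                 z = tmpl$z + sep, name = tmpl$name, chain = "A",
                 resno = 1L, resname = "PHE"), role = "receptor"))
    lig <- make_toy_ligand("probe_ring")
    site <- select_active_site(rec, lig, radius = 50)
    detect_interactions(lig, rec, site)
  }
  near <- mk(4.9)
  expect_true(any(near$kind == "pi_pi_parallel" & !near$displaced))
  expect_lt(near$distance[near$kind == "pi_pi_parallel"][1], 5.0)
  far <- mk(5.1)
  expect_false(any(grepl("pi_pi", far$kind)))
})

test_that("H-bond strength splits on the distance and angle thresholds", {
  # donor ligand: O-H pointing at an acceptor backbone O
  mk_lig <- function(d_oo) {
    df <- data.frame(element = c("O", "H"),
                     x = c(0, 0), y = c(0, 0), z = c(d_oo, d_oo - 0.97),
                     name = c("O1", "HO1"), chain = "L", resno = 1L,
                     resname = "LIG")
    perceive_bonds_and_rings(mol_structure(df, role = "ligand"))
  }
  gly <- bindingspace:::.RESIDUE_TEMPLATES$GLY
  # rotate template so the carbonyl O sits at the origin
  rec <- perceive_bonds_and_rings(mol_structure(
    data.frame(element = gly$element, x = gly$x - gly$x[5],
               y = gly$y - gly$y[5], z = gly$z, name = gly$name,
               chain = "A", resno = 1L, resname = "GLY"), role = "receptor"))
  expect_equal(rec$atoms$name[5], "O")
  site_of <- function(l) select_active_site(rec, l, radius = 50)
  strong <- detect_interactions(mk_lig(2.8), rec, site_of(mk_lig(2.8)))
  expect_true("hbond_strong" %in% strong$kind)  # 2.8 A, angle 180
  weak <- detect_interactions(mk_lig(3.3), rec, site_of(mk_lig(3.3)))
  expect_true("hbond_weak" %in% weak$kind)      # 3.3 A > strong cutoff
  none <- detect_interactions(mk_lig(3.8), rec, site_of(mk_lig(3.8)))
  expect_false(any(grepl("hbond", none$kind)))
})

test_that("detector agrees with the brute-force all-pairs oracle", {
  crit <- interaction_criteria()
  sys <- fx_mc_system()
  set.seed(31)
  for (k in 1:6) {
    pose <- sys$pose
    shift <- stats::rnorm(3, 0, 1.2)
    coords(pose) <- sweep(coords(pose), 2, shift, "+")
    got <- detect_interactions(pose, sys$receptor, sys$site, crit)
    exp <- oracle_detect(pose, sys$receptor, sys$site, crit)
    expect_equal(record_signature(as.data.frame(got)),
                 record_signature(exp))
  }
})

test_that("shrinking any cutoff never adds records", {
  sys <- fx_mc_system()
  base <- interaction_criteria()
  n_base <- nrow(detect_interactions(sys$pose, sys$receptor, sys$site, base))
  shrunk <- list(
    interaction_criteria(hbond_max_dist = 3.0, hbond_strong_dist = 2.6),
    interaction_criteria(salt_bridge_max_dist = 3.0),
    interaction_criteria(pi_centroid_max_dist = 3.0),
    interaction_criteria(cation_pi_max_dist = 3.0))
  for (c2 in shrunk) {
    n2 <- nrow(detect_interactions(sys$pose, sys$receptor, sys$site, c2))
    expect_lte(n2, n_base)
  }
})

test_that("strong H-bonds are a subset of all H-bonds", {
  sys <- fx_mc_system()
  crit <- interaction_criteria()
  recs <- detect_interactions(sys$pose, sys$receptor, sys$site, crit)
  loose <- interaction_criteria(hbond_strong_dist = crit$hbond_max_dist,
                                hbond_strong_angle = crit$hbond_min_angle)
  all_hb <- detect_interactions(sys$pose, sys$receptor, sys$site, loose)
  expect_lte(sum(recs$kind == "hbond_strong"),
             sum(grepl("hbond", all_hb$kind)))
})

test_that("contact profile counts poses, not records", {
  pk <- fx_pocket(); lig <- fx_ligand()
  planted <- plant_pose_ensemble(
    pk, lig, ensemble_spec(n_poses = 10, frequencies = c(GLU = 0.7),
                           seed = 4))
  site <- select_active_site(pk, ensemble_poses(planted$ensemble)[[1]],
                             radius = 30)
  prof <- contact_profile(planted$ensemble, pk, site)
  expect_equal(prof$occurrence[prof$resname == "GLU"], 0.7)
  # occurrence * n_poses is integral
  expect_equal(prof$occurrence * attr(prof, "n_poses"),
               round(prof$occurrence * attr(prof, "n_poses")))
  # single pose: every contacted residue at 1.0
  one <- pose_ensemble(planted$ensemble$template, planted$ensemble$xyz[1],
                       delta_g = planted$ensemble$delta_g[1])
  p1 <- contact_profile(one, pk, site)
  expect_true(all(p1$occurrence %in% c(0, 1)))
  expect_error(contact_profile(list(), pk, site), "empty ensemble")
})

test_that("profiles are invariant under pose order and typed <= any_contact", {
  pk <- fx_pocket(); lig <- fx_ligand()
  planted <- plant_pose_ensemble(
    pk, lig, ensemble_spec(n_poses = 12, frequencies = c(GLU = 0.5),
                           seed = 9))
  ens <- planted$ensemble
  site <- select_active_site(pk, ensemble_poses(ens)[[1]], radius = 30)
  prof <- contact_profile(ens, pk, site)
  perm <- rev(seq_along(ens$xyz))
  ens2 <- pose_ensemble(ens$template, ens$xyz[perm], ens$delta_g[perm],
                        ens$state[perm])
  prof2 <- contact_profile(ens2, pk, site)
  expect_equal(prof$occurrence, prof2$occurrence)
  any_c <- contact_profile(ens, pk, site, mode = "any_contact")
  expect_true(all(prof$occurrence <= any_c$occurrence + 1e-12))
  expect_equal(attr(any_c, "mode"), "any_contact")
})

test_that("occurrence table conserves the total record count", {
  sys <- fx_mc_system()
  recs <- lapply(1:3, function(k) {
    pose <- sys$pose
    coords(pose) <- sweep(coords(pose), 2, c(0, 0, 0.2 * (k - 1)), "+")
    detect_interactions(pose, sys$receptor, sys$site)
  })
  tab <- occurrence_table(recs)
  expect_equal(sum(tab$count), sum(vapply(recs, nrow, integer(1))))
  # single-kind ensemble collapses to the expected rows
  sb_only <- lapply(recs, function(r) r[r$kind == "salt_bridge", ])
  tab2 <- occurrence_table(sb_only)
  expect_true(all(tab2$kind == "salt_bridge"))
  expect_equal(sum(tab2$count), sum(vapply(sb_only, nrow, integer(1))))
})

test_that("monitored distance series track the trajectory", {
  sys <- fx_mc_system()
  cfg <- mc_config(n_steps = 4, minimize_steps = 0, seed = 3,
                   monitored_pairs = sys$monitored_pairs,
                   temperature = 1e-6)
  traj <- run_mc(sys$pose, sys$receptor, sys$site, cfg)
  m <- traj$monitored
  # one row per (step 0..n, pair)
  expect_equal(nrow(m), (cfg$n_steps + 1) * length(sys$monitored_pairs))
  # at T -> 0 with uphill-only proposals everything is rejected: constant
  if (all(!traj$steps$accepted)) {
    for (p in unique(m$pair))
      expect_equal(diff(range(m$distance[m$pair == p])), 0)
  }
  # a translated pair moves by exactly the translation along z
  one_pair <- list(list(label = "n-o", ligand = 1L, receptor = 1L))
  traj2 <- traj
  traj2$snapshots <- lapply(seq_along(traj$snapshots), function(k) {
    x <- traj$snapshots[[1]]
    if (k > 2) x[, 3] <- x[, 3] + 1
    x
  })
  m2 <- monitor_pair_distances(traj2, one_pair)
  expect_equal(length(unique(round(m2$distance, 6))), 2L)
  expect_error(monitor_pair_distances(traj, list(list(ligand = 999,
                                                      receptor = 1))),
               "invalid monitored pair")
})
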