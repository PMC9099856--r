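make_scored_ensemble <- function(n, dg = NULL, seed = 1) {
  lig <- fx_ligand()
  set.seed(seed)
  xyz <- lapply(seq_len(n), function(k)
    sweep(coords(lig), 2, stats::rnorm(3, 0, 1.5), "+"))
  if (is.null(dg)) dg <- stats::rnorm(n, -7, 1)
  pose_ensemble(lig, xyz, delta_g = dg,
                state = rep_len(c("A", "B"), n))
}

test_that("top-pose filtering keeps the lowest-energy poses, sorted", {
  e200 <- make_scored_ensemble(200)
  top <- filter_top_poses(e200)
  expect_length(top, 80L)
  expect_false(is.unsorted(top$delta_g))
  # brute-force oracle: sort and slice
  expect_equal(top$delta_g, sort(e200$delta_g)[1:80])
  # subset of the input
  expect_true(all(top$delta_g %in% e200$delta_g))
  # fewer poses than the cap: all retained
  e50 <- make_scored_ensemble(50)
  expect_length(filter_top_poses(e50), 50L)
  # idempotent
  top2 <- filter_top_poses(top)
  expect_equal(top2$delta_g, top$delta_g)
  expect_equal(top2$xyz, top$xyz)
  # ties broken by input order
  et <- make_scored_ensemble(4, dg = c(-5, -5, -5, -5))
  expect_equal(filter_top_poses(et, max_n = 2)$xyz, et$xyz[1:2])
  # unscored poses are rejected
  eu <- make_scored_ensemble(3, dg = c(-5, NA, -4))
  expect_error(filter_top_poses(eu), "unscored")
})

test_that("pose rmsd matches closed forms and the direct formula", {
  lig <- fx_ligand()
  a <- lig
  expect_equal(pose_rmsd(a, a), 0)
  b <- lig
  coords(b) <- sweep(coords(a), 2, c(3, 4, 0), "+")
  expect_equal(pose_rmsd(a, b), 5.0, tolerance = 1e-12)
  # random pair vs direct recomputation
  set.seed(2)
  c2 <- lig
  coords(c2) <- coords(a) + matrix(stats::rnorm(3 * nrow(a$atoms), 0, 0.7),
                                   ncol = 3)
  h <- which(!a$atoms$is_h)
  direct <- sqrt(mean(rowSums((coords(a)[h, ] - coords(c2)[h, ])^2)))
  expect_equal(pose_rmsd(a, c2), direct, tolerance = 1e-9)
  # pseudometric properties
  expect_equal(pose_rmsd(a, c2), pose_rmsd(c2, a))
  expect_gte(pose_rmsd(a, c2), 0)
  # superposed rmsd never exceeds the displacement rmsd
  expect_lte(pose_rmsd(a, c2, superpose = TRUE), pose_rmsd(a, c2) + 1e-12)
  # superposition removes a pure rigid motion entirely
  d <- lig
  rot <- bindingspace:::rotation_between(c(1, 0, 0), c(0, 1, 1))
  coords(d) <- sweep(coords(a) %*% t(rot), 2, c(2, -1, 4), "+")
  expect_lt(pose_rmsd(a, d, superpose = TRUE), 1e-9)
  expect_error(pose_rmsd(a, make_toy_ligand("probe_ring")), "mismatch")
})

test_that("superposed rmsd agrees with an independent rigid-fit oracle", {
  lig <- fx_ligand()
  set.seed(5)
  b <- lig
  coords(b) <- coords(lig) + matrix(stats::rnorm(3 * nrow(lig$atoms), 0, 0.5),
                                    ncol = 3)
  h <- which(!lig$atoms$is_h)
  fixed <- as.numeric(t(coords(lig)[h, ]))
  mobile <- as.numeric(t(coords(b)[h, ]))
  fitted <- bio3d::fit.xyz(fixed, mobile,
                           fixed.inds = seq_along(fixed),
                           mobile.inds = seq_along(mobile))
  oracle <- sqrt(mean(colSums(matrix((fitted - fixed)^2, nrow = 3))))
  expect_equal(pose_rmsd(lig, b, superpose = TRUE), oracle,
               tolerance = 1e-6)
})

test_that("binding-space summary reproduces closed-form statistics", {
  e <- make_scored_ensemble(3, dg = c(-5, -6, -7))
  s <- binding_space_summary(e)
  expect_equal(s$mean_dg, -6)
  expect_equal(s$range_dg, 2)
  expect_equal(s$sd_dg, 1)
  expect_equal(s$n_poses, 3L)
  # per-state counts: planted two-state ensemble
  e2 <- make_scored_ensemble(80)
  e2$state <- rep(c("A", "B"), c(30, 50))
  s2 <- binding_space_summary(e2)
  expect_equal(as.integer(s2$per_state_counts[c("A", "B")]), c(30L, 50L))
  expect_equal(sum(s2$per_state_counts), 80L)
  # mean pairwise rmsd against a brute-force double loop
  e3 <- make_scored_ensemble(12, seed = 7)
  s3 <- binding_space_summary(e3)
  poses <- ensemble_poses(e3)
  acc <- c()
  for (i in 1:11) for (j in (i + 1):12)
    acc <- c(acc, pose_rmsd(poses[[i]], poses[[j]]))
  expect_equal(s3$mean_pairwise_rmsd, mean(acc), tolerance = 1e-12)
  # sensitivity definition: range over mean superposed pairwise rmsd
  acc_s <- c()
  for (i in 1:11) for (j in (i + 1):12)
    acc_s <- c(acc_s, pose_rmsd(poses[[i]], poses[[j]], superpose = TRUE))
  if (mean(acc_s) > 1e-9)
    expect_equal(s3$sensitivity_score, s3$range_dg / mean(acc_s),
                 tolerance = 1e-9)
})

test_that("the mode is the centre of the fullest 0.5 kcal/mol bin", {
  # bins anchored at the minimum: [-8,-7.5) holds 1, [-7.5,-7) holds 3
  e <- make_scored_ensemble(4, dg = c(-8, -7.4, -7.3, -7.2))
  s <- binding_space_summary(e)
  expect_equal(s$mode_dg, -8 + 1.5 * 0.5)
})

test_that("greedy leader clustering honours its contracts", {
  lig <- fx_ligand()
  same <- pose_ensemble(lig, rep(list(coords(lig)), 5),
                        delta_g = rep(-5, 5))
  cl <- cluster_poses(same)
  expect_equal(cl$labels, rep(1L, 5))
  expect_equal(cl$representative_index, 1L)
  # two planted blobs with known sizes
  pk <- fx_pocket()
  planted <- plant_pose_ensemble(
    pk, lig, ensemble_spec(n_poses = 30, n_centres = 2, centre_sep = 10,
                           spread = 0.5, seed = 6))
  cl2 <- cluster_poses(planted$ensemble, threshold = 2)
  expect_equal(sort(cl2$cluster_sizes), c(15L, 15L))
  # every pose is within the threshold of its leader
  poses <- ensemble_poses(planted$ensemble)
  leaders <- vapply(seq_len(max(cl2$labels)),
                    function(cid) which(cl2$labels == cid)[1], integer(1))
  for (p in seq_along(poses))
    expect_lte(pose_rmsd(poses[[leaders[cl2$labels[p]]]], poses[[p]]), 2)
  # representative belongs to the most populated cluster
  expect_equal(cl2$labels[cl2$representative_index],
               which.max(cl2$cluster_sizes))
  # infinite threshold: one cluster
  expect_equal(max(cluster_poses(planted$ensemble, threshold = Inf)$labels),
               1L)
})

test_that("orientation labels follow the axis-angle rule", {
  lig <- fx_ligand()
  ctr <- colMeans(coords(lig))
  rot_about <- function(s, axis, ang) {
    r <- bindingspace:::rotation_between(c(1, 0, 0), c(1, 0, 0))
    x <- bindingspace:::rotate_points(coords(s), ctr, axis, ang)
    s2 <- s; coords(s2) <- x; s2
  }
  ax <- bindingspace:::ligand_axis(lig)
  perp <- bindingspace:::unit(c(-ax[2], ax[1], 0))
  ref_a <- lig
  ref_b <- rot_about(lig, perp, 180)
  expect_equal(classify_orientation(lig, ref_a, ref_b)$label,
               "serotonin_like")
  expect_equal(classify_orientation(ref_b, ref_a, ref_b)$label,
               "escitalopram_like")
  o90 <- rot_about(lig, perp, 90)
  expect_equal(classify_orientation(o90, ref_a, ref_b)$label,
               "intermediate")
  # constructed 35 degree rotation stays within the serotonin-like window
  o35 <- rot_about(lig, perp, 35)
  cls <- classify_orientation(o35, ref_a, ref_b)
  expect_equal(cls$label, "serotonin_like")
  expect_equal(unname(cls$angle_to_refs["serotonin_like"]), 35,
               tolerance = 0.1)
  # invariance under a joint rigid rotation
  rr <- bindingspace:::rotation_between(c(0, 0, 1), c(1, 1, 1))
  spin <- function(s) { s2 <- s; coords(s2) <- coords(s) %*% t(rr); s2 }
  expect_equal(classify_orientation(spin(o35), spin(ref_a),
                                    spin(ref_b))$label, "serotonin_like")
  # a ligand without a cation has no axis
  expect_error(classify_orientation(make_toy_ligand("probe_ring"),
                                    ref_a, ref_b), "cation")
})
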