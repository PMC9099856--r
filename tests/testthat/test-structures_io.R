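test_that("PDB round trip preserves atoms, names, order and coordinates", {
  pk <- fx_pocket()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_structure(pk, f)
  back <- read_pdb_structure(f)
  expect_equal(nrow(back$atoms), nrow(pk$atoms))
  expect_equal(back$atoms$name, pk$atoms$name)
  expect_equal(back$atoms$resname, pk$atoms$resname)
  expect_equal(back$atoms$resno, pk$atoms$resno)
  expect_lt(max(abs(coords(back) - coords(pk))), 1e-3)
})

test_that("altloc handling keeps the first-encountered location", {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      12.000   6.000  -6.000  0.50  0.00           C",
    "ATOM      3  CA BALA A   1      13.000   7.000  -5.000  0.50  0.00           C",
    "ATOM      4  C   ALA A   1      12.500   4.600  -6.100  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_pdb_structure(f)
  expect_equal(nrow(s$atoms), 3L)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 12.0, tolerance = 1e-6)
})

test_that("header-only and missing PDB files raise input errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    TOY", "REMARK    NOTHING HERE", "END"), f)
  expect_error(read_pdb_structure(f), "error")
  expect_error(read_pdb_structure(file.path(tempdir(), "nope.pdb")),
               "not found")
})

test_that("SDF pose sets round-trip with scores and tolerate absent keys", {
  lig <- fx_ligand()
  poses <- lapply(c(0, 1, 2), function(dz) {
    s <- lig; coords(s) <- sweep(coords(s), 2, c(0, 0, dz), "+"); s
  })
  f <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(poses, f, scores = c(-7.5, -6.25, -5))
  back <- read_ligand_file(f)
  expect_length(back$structures, 3L)
  expect_equal(back$scores, c(-7.5, -6.25, -5))
  expect_equal(nrow(back$structures[[2]]$atoms), nrow(lig$atoms))
  expect_lt(max(abs(coords(back$structures[[3]]) - coords(poses[[3]]))),
            1e-3)
  # same topology perceived from the file's bond block
  expect_equal(nrow(back$structures[[1]]$bonds), nrow(lig$bonds))
  # without the property the scores are absent
  f2 <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(poses[1:2], f2)
  expect_true(all(is.na(read_ligand_file(f2)$scores)))
})

test_that("a malformed SDF record is reported by index, others survive", {
  lig <- make_toy_ligand("probe_amine")
  f <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(list(lig, lig, lig), f, scores = c(-1, -2, -3))
  lines <- readLines(f)
  # cut the coordinate block of record 2
  ends <- grep("^\\$\\$\\$\\$", lines)
  block2 <- (ends[1] + 1):(ends[2])
  atomline <- block2[grep("N ", lines[block2])[1]]
  lines[atomline] <- "  bad coordinates here"
  writeLines(lines, f)
  expect_warning(res <- read_ligand_file(f), "record 2")
  expect_length(res$structures, 2L)
  expect_equal(res$scores, c(-1, -3))
  expect_match(res$errors, "record 2")
})

test_that("bond perception applies the covalent-radius rule", {
  benz <- simple_structure(benzene_xyz())
  expect_equal(nrow(benz$bonds), 6L)
  expect_length(benz$rings, 1L)
  expect_true(benz$rings[[1]]$planar)
  far <- simple_structure(matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(nrow(far$bonds), 0L)
})

test_that("cyclohexane chair is perceived as one non-planar ring", {
  chair <- simple_structure(chair_xyz())
  expect_length(chair$rings, 1L)
  # oracle: direct least-squares plane fit residual exceeds the tolerance
  xyz <- chair_xyz()
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  resid <- max(abs(sweep(xyz, 2, ctr) %*% sv$v[, 3]))
  expect_gt(resid, 0.15)
  expect_false(chair$rings[[1]]$planar)
})

test_that("bond perception matches a brute-force all-pairs oracle", {
  for (s in list(fx_pocket(), fx_ligand())) {
    xyz <- coords(s)
    rc <- bindingspace:::element_radius(s$atoms$element, "covalent")
    expected <- list()
    for (i in seq_len(nrow(xyz) - 1)) {
      for (j in (i + 1):nrow(xyz)) {
        if (s$atoms$is_h[i] && s$atoms$is_h[j]) next
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d > 0.1 && d <= rc[i] + rc[j] + 0.45)
          expected[[length(expected) + 1L]] <- c(i, j)
      }
    }
    expected <- do.call(rbind, expected)
    got <- s$bonds[order(s$bonds[, 1], s$bonds[, 2]), , drop = FALSE]
    expected <- expected[order(expected[, 1], expected[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(expected))
  }
})

test_that("rotatable bonds follow the non-terminal acyclic heavy-atom rule", {
  ethane <- simple_structure(matrix(c(0, 0, 0, 1.5, 0, 0), 2, 3,
                                    byrow = TRUE))
  expect_equal(nrow(list_rotatable_bonds(ethane)), 0L)
  butane <- simple_structure(cbind(c(0, 1.26, 2.52, 3.78),
                                   c(0, 0.85, 0, 0.85), 0))
  expect_equal(nrow(list_rotatable_bonds(butane)), 1L)
  # fixture oracle: hand enumeration on the documented topology gives 3
  # (aryl-CH2, CH2-CH, CH-N; both methyls are terminal)
  expect_equal(nrow(list_rotatable_bonds(fx_ligand())), 3L)
  expect_equal(attr(fx_ligand(), "rotor_count"), 3L)
})

test_that("receptor pharmacophore tags follow the residue templates", {
  pk <- fx_pocket()
  tags <- suppressWarnings(assign_pharmacophore_types(pk))
  anion <- tags[tags$tag == "anion", ]
  expect_equal(sort(pk$atoms$name[anion$atom]), c("OE1", "OE2"))
  arg_n <- tags$atom[tags$tag == "cation"]
  expect_setequal(pk$atoms$name[arg_n], c("NE", "NH1", "NH2"))
  arom <- tags$atom[tags$tag == "aromatic_ring_member"]
  expect_setequal(pk$atoms$name[arom],
                  c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  # every donor row names an attached hydrogen
  don <- tags[tags$tag == "hbond_donor", ]
  expect_true(all(!is.na(don$h)))
  expect_true(all(pk$atoms$is_h[don$h]))
})

test_that("glycine backbone yields a carbonyl acceptor and an amide donor", {
  tmpl <- bindingspace:::.RESIDUE_TEMPLATES$GLY
  s <- perceive_bonds_and_rings(mol_structure(
    data.frame(element = tmpl$element, x = tmpl$x, y = tmpl$y, z = tmpl$z,
               name = tmpl$name, chain = "A", resno = 1L, resname = "GLY"),
    role = "receptor"))
  tags <- assign_pharmacophore_types(s)
  expect_true(any(tags$tag == "hbond_acceptor" &
                    s$atoms$name[tags$atom] == "O"))
  don <- tags[tags$tag == "hbond_donor", ]
  expect_equal(s$atoms$name[don$atom], "N")
  expect_equal(s$atoms$name[don$h], "H")
})

test_that("unknown residues warn but element rules still apply", {
  df <- data.frame(element = c("N", "H"), x = c(0, 0.4), y = c(0, 0.9),
                   z = 0, name = c("NX", "HX"), chain = "A", resno = 1L,
                   resname = "XYZ")
  s <- perceive_bonds_and_rings(mol_structure(df, role = "receptor"))
  expect_warning(tags <- assign_pharmacophore_types(s), "unknown residue")
  expect_equal(nrow(tags), 0L)  # receptor templates: no tags for XYZ
})

test_that("pharmacophore tagging is deterministic", {
  t1 <- assign_pharmacophore_types(fx_ligand())
  t2 <- assign_pharmacophore_types(fx_ligand())
  expect_identical(t1, t2)
})

test_that("active-site selection respects the radius threshold exactly", {
  tmpl <- simple_structure(matrix(c(0, 0, 0), 1, 3), perceive = FALSE)
  res_atom <- function(xoff, resno)
    data.frame(element = "C", x = xoff, y = 0, z = 0, name = "CA",
               chain = "A", resno = resno, resname = "GLY")
  rec <- mol_structure(rbind(res_atom(5.9, 1L), res_atom(6.1, 2L)),
                       role = "receptor")
  site <- select_active_site(rec, tmpl, radius = 6.0)
  expect_equal(site$residues$resno, 1L)
  # a template with no heavy atoms cannot define a site
  h_only <- simple_structure(matrix(c(0, 0, 0), 1, 3), element = "H",
                             perceive = FALSE)
  expect_error(select_active_site(rec, h_only), "no heavy atoms")
})

test_that("active-site selection is monotone in the radius", {
  pk <- fx_pocket(); lig <- fx_ligand()
  keys <- lapply(c(0, 2, 4, 6, 10), function(r)
    select_active_site(pk, lig, radius = r)$residues$key)
  for (k in seq_len(length(keys) - 1))
    expect_true(all(keys[[k]] %in% keys[[k + 1]]))
  expect_length(keys[[1]], 0L)  # radius 0: no residue in exact contact
})
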