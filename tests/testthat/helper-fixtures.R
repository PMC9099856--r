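# Shared fixtures, built once per test run.

fx <- new.env()

fx_ligand <- function() {
  if (is.null(fx$ligand)) fx$ligand <- make_toy_ligand("mdma_like")
  fx$ligand
}

fx_pocket <- function() {
  if (is.null(fx$pocket))
    fx$pocket <- make_toy_pocket(
      pocket_spec(c("GLU", "ARG", "PHE", "THR"), radius = 6, seed = 1))
  fx$pocket
}

fx_mc_system <- function() {
  if (is.null(fx$mc)) fx$mc <- make_mc_system(seed = 7)
  fx$mc
}

# minimal structure from a coordinate matrix of one element
simple_structure <- function(xyz, element = "C", role = "ligand",
                             perceive = TRUE) {
  n <- nrow(xyz)
  s <- mol_structure(data.frame(
    element = rep_len(element, n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    name = paste0(rep_len(element, n), seq_len(n)), chain = "L",
    resno = 1L, resname = "LIG", stringsAsFactors = FALSE), role = role)
  if (perceive) perceive_bonds_and_rings(s) else s
}

# ideal benzene coordinates (optionally with a z offset / rotation applied)
benzene_xyz <- function(centre = c(0, 0, 0)) {
  th <- 2 * pi * (0:5) / 6
  sweep(cbind(1.39 * cos(th), 1.39 * sin(th), 0), 2, centre, "+")
}

# cyclohexane chair
chair_xyz <- function() {
  th <- 2 * pi * (0:5) / 6
  cbind(1.47 * cos(th), 1.47 * sin(th), 0.25 * (-1)^(0:5))
}
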