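# Residue-template tag tables: which named atoms of standard residues carry
# which pharmacophoric role. Standard protonation states are assumed
# (ASP/GLU deprotonated, ARG/LYS protonated, HIS neutral).
.ANION_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)
.CATION_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ"
)
.AROMATIC_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)
.ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1", HIS = "ND1", MET = "SD"
)
# side-chain donors (heavy atom); backbone N handled generically
.DONOR_ATOMS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", TRP = "NE1", HIS = "NE2",
  CYS = "SG"
)
.STD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")
.ION_RESIDUES <- c("NA", "K", "CA", "MG", "ZN", "SOD", "POT")

#' Assign pharmacophoric atom tags
#'
#' Receptor atoms are tagged from residue templates (carboxylate oxygens as
#' anions, guanidinium/ammonium nitrogens as cations, side-chain rings of
#' PHE/TYR/TRP/HIS as aromatic, backbone carbonyl oxygens and lone-pair
#' carrying side-chain O/N as acceptors, N/O with a bonded hydrogen as
#' donors). Ligand atoms are tagged from element and bond environment:
#' four-coordinate nitrogen as cation, members of planar rings as aromatic,
#' O/N bearing hydrogens as donors, ether/carbonyl O and trivalent N as
#' acceptors. An atom may carry several tags. Donors without an attached
#' hydrogen (structures stripped of H) are retained as heavy-atom donors
#' with a warning; angle checks are skipped for them downstream.
#'
#' @param s a `mol_structure` with bonds and rings perceived.
#' @return data.frame with columns `atom` (index), `tag` (one of `cation`,
#'   `anion`, `hbond_donor`, `hbond_acceptor`, `aromatic_ring_member`),
#'   `h` (attached H index for donors), `ring` (ring id for aromatic
#'   members), `group` (charged-group id for cations).
#' @export
assign_pharmacophore_types <- function(s) {
  a <- s$atoms
  n <- nrow(a)
  rows <- list()
  add <- function(atom, tag, h = NA_integer_, ring = NA_integer_,
                  group = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom = atom, tag = tag, h = h, ring = ring, group = group,
      stringsAsFactors = FALSE)
  }
  h_on <- function(i) {
    nb <- neighbours_of(s, i)
    nb[s$atoms$is_h[nb]]
  }
  if (s$role == "receptor") {
    rk <- residue_keys(s)
    unknown <- setdiff(unique(a$resname),
                       c(.STD_RESIDUES, .ION_RESIDUES, "HOH", "WAT"))
    if (length(unknown))
      warning("unknown residue name(s), template tags skipped: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    for (i in seq_len(n)) {
      rn <- a$resname[i]; an <- a$name[i]; el <- a$element[i]
      if (a$is_h[i]) next
      if (rn %in% .ION_RESIDUES || el %in% c("NA", "K", "CA", "MG", "ZN")) {
        add(i, "cation", group = rk[i]); next
      }
      if (an %in% .ANION_ATOMS[[rn]]) add(i, "anion")
      if (an %in% .CATION_ATOMS[[rn]]) add(i, "cation", group = rk[i])
      if (an %in% .AROMATIC_ATOMS[[rn]]) add(i, "aromatic_ring_member")
      if (an == "O" || an %in% .ACCEPTOR_ATOMS[[rn]])
        add(i, "hbond_acceptor")
      is_bb_n <- an == "N" && rn != "PRO"
      if (is_bb_n || an %in% .DONOR_ATOMS[[rn]]) {
        hs <- h_on(i)
        if (length(hs)) {
          for (h in hs) add(i, "hbond_donor", h = h)
        } else if (rn %in% .STD_RESIDUES) {
          warning("donor atom ", an, " of ", rk[i],
                  " has no attached hydrogen; heavy-atom donor assumed",
                  call. = FALSE)
          add(i, "hbond_donor")
        }
      }
    }
    # aromatic ring ids from template residue grouping
    tags <- do.call(rbind, rows)
    if (!is.null(tags) && any(tags$tag == "aromatic_ring_member")) {
      arom <- tags$tag == "aromatic_ring_member"
      tags$ring[arom] <- as.integer(factor(rk[tags$atom[arom]]))
    }
    return(tag_frame(tags))
  }
  # ligand rules: element + bond environment
  deg <- tabulate(c(s$bonds), nbins = n)
  for (i in seq_len(n)) {
    if (a$is_h[i]) next
    el <- a$element[i]
    hs <- h_on(i)
    if (el == "N") {
      if (deg[i] >= 4L) add(i, "cation", group = "lig_cation")
      else add(i, "hbond_acceptor")
      for (h in hs) add(i, "hbond_donor", h = h)
    } else if (el == "O") {
      add(i, "hbond_acceptor")
      for (h in hs) add(i, "hbond_donor", h = h)
    }
  }
  ring_id <- 0L
  for (r in s$rings) {
    ring_id <- ring_id + 1L
    if (isTRUE(r$planar) && length(r$atoms) >= 5)
      for (i in r$atoms) add(i, "aromatic_ring_member", ring = ring_id)
  }
  tag_frame(do.call(rbind, rows))
}

#' @keywords internal
tag_frame <- function(tags) {
  if (is.null(tags))
    tags <- data.frame(atom = integer(), tag = character(), h = integer(),
                       ring = integer(), group = character(),
                       stringsAsFactors = FALSE)
  tags <- unique(tags)
  tags[order(tags$atom, tags$tag), , drop = FALSE]
}

#' Assign partial charges from the built-in per-template table
#'
#' Formal charges are spread over the charged group: carboxylate oxygens
#' -0.5 each, guanidinium nitrogens +1/3 each, ammonium nitrogen and its
#' hydrogens share +1 (each H +0.3, remainder on N). Polar backbone and
#' hydroxyl atoms receive small balanced charges; monovalent/divalent ions
#' their formal charge. Existing non-zero charges (e.g. from an input
#' property) are kept unless `force = TRUE`.
#'
#' @param s a `mol_structure` with bonds perceived.
#' @param force overwrite existing charges.
#' @return the structure with `atoms$charge` populated.
#' @export
assign_partial_charges <- function(s, force = FALSE) {
  if (any(s$atoms$charge != 0) && !force) return(s)
  a <- s$atoms
  q <- numeric(nrow(a))
  h_on <- function(i) { nb <- neighbours_of(s, i); nb[a$is_h[nb]] }
  if (s$role == "receptor") {
    for (i in seq_len(nrow(a))) {
      rn <- a$resname[i]; an <- a$name[i]
      if (an %in% .ANION_ATOMS[[rn]]) q[i] <- -0.5
      else if (rn == "ARG" && an %in% .CATION_ATOMS$ARG) q[i] <- 1 / 3
      else if (rn == "LYS" && an == "NZ") {
        hs <- h_on(i); q[i] <- 1 - 0.1 * length(hs); q[hs] <- 0.1
      } else if (an == "O") { q[i] <- -0.4 }
      else if (an == "C") { q[i] <- 0.4 }
      else if (an == "N" && rn != "PRO") {
        hs <- h_on(i); q[i] <- -0.3; q[hs] <- 0.3 / max(1, length(hs))
      } else if (an %in% c("OG", "OG1", "OH")) {
        hs <- h_on(i); q[i] <- -0.4; q[hs] <- 0.4 / max(1, length(hs))
      } else if (an %in% c("OD1", "OE1") && rn %in% c("ASN", "GLN")) {
        q[i] <- -0.4
      } else if (an %in% c("ND2", "NE2") && rn %in% c("ASN", "GLN")) {
        hs <- h_on(i); q[i] <- -0.3; q[hs] <- 0.35
      } else if (rn %in% c("NA", "SOD") || a$element[i] == "NA") q[i] <- 1
      else if (rn %in% c("K", "POT")) q[i] <- 1
      else if (rn %in% c("CA", "MG", "ZN")) q[i] <- 2
    }
  } else {
    deg <- tabulate(c(s$bonds), nbins = nrow(a))
    for (i in seq_len(nrow(a))) {
      el <- a$element[i]
      if (el == "N" && deg[i] >= 4L) {
        hs <- h_on(i)
        q[hs] <- 0.3
        q[i] <- 1 - 0.3 * length(hs)
      } else if (el == "O") {
        hs <- h_on(i)
        if (length(hs)) { q[i] <- -0.4; q[hs] <- 0.4 } else q[i] <- -0.3
      }
    }
    # ether oxygens leave a small net charge; rebalance onto carbons bonded
    # to charged oxygens so the molecular formal charge (+1 per ammonium
    # group, else 0) is preserved
    excess <- sum(q) - sum(a$element == "N" & deg >= 4L)
    ox <- which(q < 0)
    if (length(ox) && abs(excess) > 1e-9) {
      carriers <- unique(unlist(lapply(ox, function(i) {
        nb <- neighbours_of(s, i); nb[a$element[nb] == "C"]
      })))
      if (length(carriers)) q[carriers] <- q[carriers] - excess / length(carriers)
    }
  }
  s$atoms$charge <- q
  s
}
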