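#' Read a receptor or ligand structure from a PDB file
#'
#' Coordinate records are read in file order. For atoms with alternate
#' locations only the first-encountered altloc of each atom is retained.
#' Multi-model files contribute their first model only. Chain, residue
#' number and residue name are preserved; HETATM ligands remain separable
#' by residue name via the atom table's `record` column.
#'
#' @param path PDB file path.
#' @param role `"receptor"` (default) or `"ligand"`.
#' @param perceive also perceive bonds and rings (default TRUE).
#' @return a `mol_structure`.
#' @export
read_pdb_structure <- function(path, role = "receptor", perceive = TRUE) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("input error: unreadable PDB file: ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty-structure error: no atoms in ", path)
  # keep first altloc per (chain, resno, atom name)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$elety)
  keep <- !duplicated(key) | alt == ""
  # atoms without altloc never collide; among altloc copies keep first seen
  keep <- rep(TRUE, nrow(at))
  has_alt <- alt != ""
  keep[has_alt] <- !duplicated(key[has_alt])
  at <- at[keep, , drop = FALSE]
  el <- at$elesy
  el[is.na(el) | el == ""] <- substr(gsub("[^A-Za-z].*", "",
                                          at$elety[is.na(el) | el == ""]), 1, 1)
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  atoms <- data.frame(
    element = el, x = at$x, y = at$y, z = at$z,
    name = at$elety, chain = chain, resno = at$resno,
    resname = at$resid, serial = at$eleno, record = at$type,
    stringsAsFactors = FALSE
  )
  s <- mol_structure(atoms, role = role)
  if (perceive) s <- perceive_bonds_and_rings(s) else s
}

#' Write a structure to a PDB file
#'
#' @param s a `mol_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_structure <- function(s, path) {
  a <- s$atoms
  type <- if (!is.null(a$record)) a$record else
    ifelse(a$resname %in% names(.RESIDUE_TEMPLATES), "ATOM", "HETATM")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords(s))),
    type = type,
    resno = a$resno, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain, elesy = a$element,
    o = rep(1, nrow(a)), b = rep(0, nrow(a))
  )
  invisible(path)
}

#' Read a ligand pose set from SDF or multi-model PDB
#'
#' Each SDF record (or PDB MODEL) becomes one ligand `mol_structure`. A
#' named numeric SDF property (default `"dG"`) is parsed as the pose score
#' when present. Malformed records are skipped with a record-level warning
#' naming the record index; well-formed records are still returned.
#'
#' @param path SDF or PDB file path.
#' @param score_key name of the SDF property holding the pose score.
#' @return list with elements `structures` (list of `mol_structure`),
#'   `scores` (numeric, `NA` when absent) and `errors` (character vector of
#'   per-record diagnostics).
#' @export
read_ligand_file <- function(path, score_key = "dG") {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^MODEL", lines)) && !any(grepl("\\$\\$\\$\\$", lines))) {
    return(read_ligand_pdb_models(path))
  }
  # split on SDF record terminator
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  structures <- list(); scores <- numeric(); errors <- character()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    if (all(!nzchar(trimws(rec)))) next
    parsed <- tryCatch(parse_sdf_record(rec, score_key),
                       error = function(e) conditionMessage(e))
    if (is.character(parsed)) {
      msg <- sprintf("record %d: %s", r, parsed)
      warning(msg, call. = FALSE)
      errors <- c(errors, msg)
    } else {
      structures[[length(structures) + 1L]] <- parsed$structure
      scores <- c(scores, parsed$score)
    }
  }
  list(structures = structures, scores = scores, errors = errors)
}

#' @keywords internal
parse_sdf_record <- function(rec_lines, score_key) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  if (!any(grepl("^\\$\\$\\$\\$", rec_lines)))
    rec_lines <- c(rec_lines, "$$$$")
  writeLines(rec_lines, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf, skipErrors = FALSE))
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  if (!is.matrix(ab) || nrow(ab) == 0) stop("no atoms")
  if (anyNA(ab[, 1:3])) stop("missing coordinate")
  el <- gsub("_.*", "", rownames(ab))
  atoms <- data.frame(
    element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
    name = paste0(el, seq_len(nrow(ab))), chain = "L", resno = 1L,
    resname = "LIG", stringsAsFactors = FALSE
  )
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (is.matrix(bb) && nrow(bb))
    matrix(as.integer(bb[, 1:2]), ncol = 2) else matrix(integer(), ncol = 2)
  if (length(bonds) && max(bonds) > nrow(atoms)) stop("bond index out of range")
  if (nrow(bonds)) bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  s <- mol_structure(atoms, bonds = bonds, role = "ligand")
  if (nrow(bonds)) {
    s$rings <- lapply(find_min_cycles(nrow(atoms), bonds), function(r) {
      dev <- plane_fit_residual(coords(s)[r, , drop = FALSE])
      list(atoms = r, planar = dev <= 0.15, max_deviation = dev)
    })
  } else {
    s <- perceive_bonds_and_rings(s)
  }
  db <- ChemmineR::datablock(sdf)
  score <- NA_real_
  if (length(db) && score_key %in% names(db))
    score <- suppressWarnings(as.numeric(db[[score_key]]))
  list(structure = s, score = score)
}

#' @keywords internal
read_ligand_pdb_models <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("empty-structure error: no atoms in ", path)
  base <- read_pdb_structure(path, role = "ligand")
  nmod <- nrow(pdb$xyz)
  structures <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    s <- base
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    coords(s) <- xyz[seq_len(nrow(s$atoms)), , drop = FALSE]
    structures[[m]] <- s
  }
  list(structures = structures, scores = rep(NA_real_, nmod),
       errors = character())
}

#' Write ligand poses to an SDF file
#'
#' @param structures list of ligand `mol_structure` objects (or a single
#'   one) sharing a topology.
#' @param path output SDF path.
#' @param scores optional numeric scores written as the `score_key`
#'   property.
#' @param score_key SDF property name for scores.
#' @return `path`, invisibly.
#' @export
write_ligand_sdf <- function(structures, path, scores = NULL,
                             score_key = "dG") {
  if (inherits(structures, "mol_structure")) structures <- list(structures)
  suppressMessages(requireNamespace("ChemmineR", quietly = TRUE))
  sdfs <- vector("list", length(structures))
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    n <- nrow(s$atoms); nb <- nrow(s$bonds)
    ab <- cbind(coords(s), matrix(0, n, 2))
    rownames(ab) <- paste(s$atoms$element, seq_len(n), sep = "_")
    colnames(ab) <- paste0("C", 1:5)
    bb <- if (nb) cbind(s$bonds, rep(1L, nb)) else matrix(0L, 0, 3)
    colnames(bb) <- paste0("C", 1:3)
    db <- if (!is.null(scores) && is.finite(scores[k]))
      stats::setNames(format(scores[k], digits = 10), score_key) else
      c(none = "")
    hdr <- c(Molecule_Name = sprintf("pose_%d", k), Source = "", Comment = "",
             Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                   n, nb))
    sdfs[[k]] <- methods::new(methods::getClassDef("SDF",
                                                   package = "ChemmineR"),
                              header = hdr, atomblock = ab,
                              bondblock = bb, datablock = db)
  }
  ids <- sprintf("CMP%d", seq_along(sdfs))
  set <- methods::new(methods::getClassDef("SDFset", package = "ChemmineR"),
                      SDF = stats::setNames(sdfs, ids), ID = ids)
  ChemmineR::write.SDF(set, path)
  invisible(path)
}
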