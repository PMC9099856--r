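#' Molecular structure container
#'
#' A `mol_structure` holds an ordered atom table, a bond list, perceived
#' rings and a role flag (`"receptor"` or `"ligand"`). It is the common
#' currency of the package: readers produce it, the interaction detector,
#' the Monte Carlo engine and the surface sampler consume it.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`, `name`,
#'   `chain`, `resno`, `resname`, and optionally `charge` (elementary
#'   units; defaults to 0) and `serial` (original file serial, kept for
#'   output only).
#' @param bonds two-column integer matrix of 1-based atom indices (may have
#'   zero rows).
#' @param rings list of ring descriptors, each `list(atoms =, planar =)`.
#' @param role `"receptor"` or `"ligand"`.
#' @return an object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, bonds = matrix(integer(), ncol = 2),
                          rings = list(), role = c("receptor", "ligand")) {
  role <- match.arg(role)
  stopifnot(is.data.frame(atoms))
  need <- c("element", "x", "y", "z", "name", "chain", "resno", "resname")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  atoms$element <- toupper(atoms$element)
  atoms$vdw <- element_radius(atoms$element, "vdw")
  atoms$is_h <- atoms$element == "H"
  bonds <- as.matrix(bonds)
  if (length(bonds) && (min(bonds) < 1L || max(bonds) > nrow(atoms)))
    stop("bond indices out of range")
  structure(
    list(atoms = atoms, bonds = bonds, rings = rings, role = role),
    class = "mol_structure"
  )
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("<mol_structure role=%s: %d atoms, %d bonds, %d rings, %d residues>\n",
              x$role, nrow(x$atoms), nrow(x$bonds), length(x$rings),
              length(unique(residue_keys(x)))))
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param s a `mol_structure`.
#' @return numeric matrix with one row per atom.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param s a `mol_structure`.
#' @param value n x 3 numeric matrix.
#' @return the modified structure.
#' @export
`coords<-` <- function(s, value) {
  stopifnot(nrow(value) == nrow(s$atoms), ncol(value) == 3)
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' Residue identity keys ("chain:resno:resname") per atom
#' @param s a `mol_structure`.
#' @return character vector, one entry per atom.
#' @export
residue_keys <- function(s) {
  paste(s$atoms$chain, s$atoms$resno, s$atoms$resname, sep = ":")
}

#' @keywords internal
heavy_idx <- function(s) which(!s$atoms$is_h)

# squared-distance helper between two coordinate matrices
#' @keywords internal
cross_dist <- function(a, b) {
  # returns nrow(a) x nrow(b) matrix of Euclidean distances
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' @keywords internal
vnorm <- function(v) sqrt(sum(v^2))

#' @keywords internal
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

#' Angle between two vectors in degrees
#' @keywords internal
vec_angle <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  ca <- max(-1, min(1, ca))
  acos(ca) * 180 / pi
}
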