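#' Perceive covalent bonds and rings from geometry
#'
#' Bonds are assigned between atom pairs whose distance does not exceed the
#' sum of their covalent radii plus a tolerance. Rings are the minimal
#' cycles of the resulting bond graph (shortest cycle through every chord
#' edge, deduplicated); each ring carries a planarity flag set when no ring
#' atom deviates from the best-fit plane by more than `planarity_tol`.
#'
#' @param s a `mol_structure` with coordinates.
#' @param tol bond-length tolerance added to the covalent-radius sum (A).
#' @param planarity_tol maximum out-of-plane deviation for a planar ring (A).
#' @param max_ring_size largest ring size perceived.
#' @return the structure with `bonds` and `rings` populated.
#' @export
perceive_bonds_and_rings <- function(s, tol = 0.45, planarity_tol = 0.15,
                                     max_ring_size = 8L) {
  xyz <- coords(s)
  n <- nrow(xyz)
  rc <- element_radius(s$atoms$element, "covalent")
  bonds <- matrix(integer(), ncol = 2)
  if (n > 1) {
    d <- cross_dist(xyz, xyz)
    lim <- outer(rc, rc, "+") + tol
    hit <- which(d <= lim & upper.tri(d) & d > 0.1, arr.ind = TRUE)
    # never bond two hydrogens
    if (nrow(hit)) {
      hh <- s$atoms$is_h[hit[, 1]] & s$atoms$is_h[hit[, 2]]
      hit <- hit[!hh, , drop = FALSE]
    }
    if (nrow(hit)) {
      bonds <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      dimnames(bonds) <- NULL
    }
  }
  s$bonds <- bonds
  s$rings <- find_min_cycles(n, bonds, max_ring_size)
  s$rings <- lapply(s$rings, function(r) {
    dev <- plane_fit_residual(xyz[r, , drop = FALSE])
    list(atoms = r, planar = dev <= planarity_tol, max_deviation = dev)
  })
  s
}

# Shortest cycle through each non-tree edge of a BFS spanning forest,
# deduplicated on the atom set: a small-molecule stand-in for the smallest
# set of smallest rings.
#' @keywords internal
find_min_cycles <- function(n, bonds, max_size = 8L) {
  if (!nrow(bonds)) return(list())
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  cycles <- list()
  seen <- character()
  for (k in seq_len(nrow(bonds))) {
    u <- bonds[k, 1]; v <- bonds[k, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = u, to = v, output = "vpath")$vpath[[1]]
    )
    if (length(sp) < 2 || length(sp) > max_size) next
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      cycles[[length(cycles) + 1L]] <- ring
    }
  }
  cycles
}

#' Maximum point deviation from the least-squares plane
#' @param xyz k x 3 coordinate matrix (k >= 3).
#' @return largest absolute out-of-plane distance (A); 0 for k < 4.
#' @export
plane_fit_residual <- function(xyz) {
  if (nrow(xyz) < 4) return(0)
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2, ctr)
  sv <- svd(x)
  normal <- sv$v[, 3]
  max(abs(x %*% normal))
}

#' @keywords internal
heavy_degree <- function(s) {
  deg <- integer(nrow(s$atoms))
  if (nrow(s$bonds)) {
    for (k in seq_len(nrow(s$bonds))) {
      i <- s$bonds[k, 1]; j <- s$bonds[k, 2]
      if (!s$atoms$is_h[j]) deg[i] <- deg[i] + 1L
      if (!s$atoms$is_h[i]) deg[j] <- deg[j] + 1L
    }
  }
  deg
}

#' @keywords internal
bond_in_ring <- function(s, i, j) {
  for (r in s$rings) {
    a <- r$atoms
    k <- length(a)
    edges <- cbind(a, a[c(2:k, 1)])
    if (any((edges[, 1] == i & edges[, 2] == j) |
            (edges[, 1] == j & edges[, 2] == i))) return(TRUE)
  }
  FALSE
}

#' @keywords internal
neighbours_of <- function(s, i) {
  b <- s$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

# amide C-N: the C end carries a terminal oxygen at carbonyl distance
#' @keywords internal
is_amide_bond <- function(s, i, j) {
  el <- s$atoms$element
  for (ord in list(c(i, j), c(j, i))) {
    ci <- ord[1]; ni <- ord[2]
    if (el[ci] == "C" && el[ni] == "N") {
      nb <- neighbours_of(s, ci)
      ox <- nb[el[nb] == "O" & heavy_degree(s)[nb] == 1L]
      if (length(ox)) {
        d <- cross_dist(coords(s)[ci, , drop = FALSE],
                        coords(s)[ox, , drop = FALSE])
        if (any(d < 1.32)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Enumerate rotatable bonds
#'
#' Rotatable bonds are acyclic single bonds between two non-terminal heavy
#' atoms (each end bonded to at least two heavy atoms), excluding amide C-N
#' bonds. Ordering is deterministic: ascending by the smaller then larger
#' atom index.
#'
#' @param s a `mol_structure` with bonds and rings perceived.
#' @return integer matrix with columns `i`, `j` (one row per rotor;
#'   zero rows when none).
#' @export
list_rotatable_bonds <- function(s) {
  out <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (!nrow(s$bonds)) return(out)
  deg <- heavy_degree(s)
  for (k in seq_len(nrow(s$bonds))) {
    i <- min(s$bonds[k, ]); j <- max(s$bonds[k, ])
    if (s$atoms$is_h[i] || s$atoms$is_h[j]) next
    if (deg[i] < 2L || deg[j] < 2L) next
    if (bond_in_ring(s, i, j)) next
    if (is_amide_bond(s, i, j)) next
    out <- rbind(out, c(i, j))
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Atoms on the j-side of bond (i, j) after cutting it; used to rotate the
# smaller fragment about the bond axis.
#' @keywords internal
bond_fragment <- function(s, i, j) {
  g <- igraph::graph_from_edgelist(s$bonds, directed = FALSE)
  if (igraph::vcount(g) < nrow(s$atoms))
    g <- igraph::add_vertices(g, nrow(s$atoms) - igraph::vcount(g))
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
  comp <- igraph::components(g)$membership
  which(comp == comp[j])
}

#' Rotate a fragment about a bond axis
#'
#' Rotates the smaller of the two fragments produced by cutting bond
#' `(i, j)` by `angle_deg` about the i->j axis.
#'
#' @param s a `mol_structure` with bonds perceived.
#' @param i,j atom indices of the bond.
#' @param angle_deg rotation angle in degrees.
#' @return the structure with updated coordinates.
#' @export
rotate_about_bond <- function(s, i, j, angle_deg) {
  side_j <- bond_fragment(s, i, j)
  side_i <- setdiff(seq_len(nrow(s$atoms)), side_j)
  if (length(side_j) <= length(side_i)) {
    movers <- setdiff(side_j, j)
    origin <- coords(s)[j, ]; axis <- unit(coords(s)[j, ] - coords(s)[i, ])
  } else {
    movers <- setdiff(side_i, i)
    origin <- coords(s)[i, ]; axis <- unit(coords(s)[i, ] - coords(s)[j, ])
  }
  if (!length(movers)) return(s)
  xyz <- coords(s)
  xyz[movers, ] <- rotate_points(xyz[movers, , drop = FALSE], origin, axis,
                                 angle_deg)
  coords(s) <- xyz
  s
}

# Rodrigues rotation of points about an axis through origin point
#' @keywords internal
rotate_points <- function(p, origin, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- unit(axis)
  v <- sweep(p, 2, origin)
  kx <- function(m) cbind(k[2] * m[, 3] - k[3] * m[, 2],
                          k[3] * m[, 1] - k[1] * m[, 3],
                          k[1] * m[, 2] - k[2] * m[, 1])
  vr <- v * cos(th) + kx(v) * sin(th) +
    outer(drop(v %*% k), k) * (1 - cos(th))
  sweep(vr, 2, origin, "+")
}
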