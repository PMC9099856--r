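#' Electrostatic complementarity parameters
#'
#' `k` is the denominator floor of the local EC score and `cap` the maximum
#' ESP deviation from zero entering the score; both are in the package's
#' ESP unit convention, kcal/(mol e) from point charges at relative
#' permittivity `dielectric`.
#'
#' @param k denominator floor (default 5).
#' @param cap ESP clamping magnitude (default 12); must be >= `k`.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param points_per_atom sphere sample points per atom (default 256).
#' @param dielectric relative permittivity for the ESP (default 1).
#' @return object of class `ec_params`.
#' @export
ec_params <- function(k = 5, cap = 12, probe_radius = 1.4,
                      points_per_atom = 256, dielectric = 1) {
  stopifnot(k > 0, cap >= k, probe_radius >= 0, points_per_atom >= 8)
  structure(list(k = k, cap = cap, probe_radius = probe_radius,
                 points_per_atom = points_per_atom, dielectric = dielectric),
            class = "ec_params")
}

# deterministic near-uniform points on the unit sphere (golden-spiral
# lattice)
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Sample the solvent-accessible surface of a structure
#'
#' Shrake-Rupley numerical sampling: near-uniform points are placed on each
#' atom's expanded sphere (vdW radius + probe) and points falling inside
#' any neighbouring atom's expanded sphere are discarded. Each surviving
#' point carries the area weight `4 pi (r + probe)^2 / points_per_atom`.
#'
#' @param s a `mol_structure` with vdW radii assigned (heavy atoms and
#'   hydrogens both contribute surface).
#' @param p an `ec_params`.
#' @param occluders optional second `mol_structure` whose atoms occlude the
#'   surface (e.g. the receptor when sampling the bound-ligand surface) but
#'   contribute no points.
#' @return data.frame of class `sas_points` with columns `x`, `y`, `z`,
#'   `area`, `atom`; attribute `total_area` (Angstrom^2).
#' @export
sample_sas <- function(s, p = ec_params(), occluders = NULL) {
  if (nrow(s$atoms) == 0L) stop("input error: empty structure")
  xyz <- coords(s)
  rad <- s$atoms$vdw + p$probe_radius
  oxyz <- xyz; orad <- rad
  if (!is.null(occluders)) {
    oxyz <- rbind(oxyz, coords(occluders))
    orad <- c(orad, occluders$atoms$vdw + p$probe_radius)
  }
  sp <- sphere_points(p$points_per_atom)
  out <- vector("list", nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    pts <- sweep(sp * rad[i], 2, xyz[i, ], "+")
    # candidate occluders: spheres that can reach atom i's surface
    dc <- cross_dist(xyz[i, , drop = FALSE], oxyz)[1, ]
    nb <- which(dc < rad[i] + orad & dc > 1e-9)
    keep <- rep(TRUE, nrow(pts))
    for (j in nb) {
      dj <- cross_dist(pts, oxyz[j, , drop = FALSE])[, 1]
      keep <- keep & dj >= orad[j]
      if (!any(keep)) break
    }
    if (any(keep)) {
      out[[i]] <- data.frame(
        x = pts[keep, 1], y = pts[keep, 2], z = pts[keep, 3],
        area = 4 * pi * rad[i]^2 / p$points_per_atom, atom = i)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      area = numeric(), atom = integer())
  rownames(res) <- NULL
  attr(res, "total_area") <- sum(res$area)
  class(res) <- c("sas_points", "data.frame")
  res
}

#' Point-charge electrostatic potential at surface points
#'
#' `ESP(x) = sum_i 332.06 q_i / (dielectric * |x - x_i|)`, in
#' kcal/(mol e). Charges closer than 0.01 Angstrom to a point contribute at
#' the capped separation and set the `flagged` attribute (the SAS offset
#' normally prevents this).
#'
#' @param points a `sas_points` data.frame (or any with `x`, `y`, `z`).
#' @param charges data.frame with columns `x`, `y`, `z`, `q` (elementary
#'   units), or a charged `mol_structure`.
#' @param p an `ec_params` (supplies the dielectric).
#' @return numeric ESP vector, one value per point (attribute `flagged`).
#' @export
esp_from_charges <- function(points, charges, p = ec_params()) {
  if (inherits(charges, "mol_structure"))
    charges <- data.frame(coords(charges), q = charges$atoms$charge) |>
      stats::setNames(c("x", "y", "z", "q"))
  stopifnot(all(is.finite(charges$q)))
  px <- as.matrix(points[, c("x", "y", "z")])
  cx <- as.matrix(charges[, c("x", "y", "z")])
  if (!nrow(cx)) return(rep(0, nrow(px)))
  d <- cross_dist(px, cx)
  flagged <- any(d < 0.01)
  d[d < 0.01] <- 0.01
  esp <- as.numeric((.COULOMB_K / p$dielectric) * (1 / d) %*% charges$q)
  attr(esp, "flagged") <- flagged
  esp
}

#' Electrostatic complementarity score over a ligand surface
#'
#' Both ESP fields are first clamped to `[-cap, cap]`; the local score at
#' each surface point is `1 - |ESP_L + ESP_P| / max(|ESP_L|, |ESP_P|, k)`,
#' which is 1 for perfectly complementary potentials (equal magnitude,
#' opposite sign, above the floor) and -1 for identical clashing
#' potentials. The global score is the area-weighted mean over the ligand
#' solvent-accessible surface.
#'
#' @param points a `sas_points` data.frame (needs an `area` column; a
#'   plain data.frame gets unit weights).
#' @param esp_ligand,esp_protein ESP values at the points.
#' @param p an `ec_params` (supplies `k` and `cap`).
#' @return list of class `ec_result`: `global_ec`, `total_area`, `points`
#'   (input plus `esp_ligand`, `esp_protein`, `local_ec`).
#' @export
ec_score <- function(points, esp_ligand, esp_protein, p = ec_params()) {
  n <- nrow(points)
  stopifnot(length(esp_ligand) == n, length(esp_protein) == n)
  area <- if ("area" %in% names(points)) points$area else rep(1, n)
  l <- pmin(pmax(esp_ligand, -p$cap), p$cap)
  pr <- pmin(pmax(esp_protein, -p$cap), p$cap)
  denom <- pmax(abs(l), abs(pr), p$k)
  local <- 1 - abs(l + pr) / denom
  global <- if (n) sum(local * area) / sum(area) else NA_real_
  pts <- cbind(as.data.frame(points),
               data.frame(esp_ligand = l, esp_protein = pr, local_ec = local))
  structure(list(global_ec = global, total_area = sum(area), points = pts),
            class = "ec_result")
}

#' @export
print.ec_result <- function(x, ...) {
  cat(sprintf("<ec_result: global EC %.4f over %.1f A^2 (%d points)>\n",
              x$global_ec, x$total_area, nrow(x$points)))
  invisible(x)
}

#' Electrostatic complementarity of a bound ligand
#'
#' Convenience wrapper: samples the ligand SAS in the presence of the
#' receptor, evaluates ligand and protein ESP at the surviving points and
#' scores them.
#'
#' @param ligand charged ligand `mol_structure`.
#' @param receptor charged receptor `mol_structure`.
#' @param p an `ec_params`.
#' @param occlude sample the ligand surface with the receptor as occluder
#'   (default TRUE).
#' @return an `ec_result`.
#' @export
electrostatic_complementarity <- function(ligand, receptor, p = ec_params(),
                                          occlude = TRUE) {
  pts <- sample_sas(ligand, p, occluders = if (occlude) receptor)
  if (!nrow(pts)) stop("ligand surface fully buried; no points to score")
  el <- esp_from_charges(pts, ligand, p)
  ep <- esp_from_charges(pts, receptor, p)
  ec_score(pts, el, ep, p)
}
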