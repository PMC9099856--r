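#' Select active-site residues around a template ligand
#'
#' A receptor residue is part of the active site when its nearest heavy
#' atom lies within `radius` of any heavy atom of the template ligand.
#'
#' @param receptor a receptor `mol_structure`.
#' @param template a ligand `mol_structure` defining the site.
#' @param radius inclusion radius in Angstrom (default 6).
#' @return an object of class `active_site` with elements `residues`
#'   (data.frame `chain`, `resno`, `resname`, `key`, `min_dist`) and
#'   `radius`.
#' @export
select_active_site <- function(receptor, template, radius = 6.0) {
  if (nrow(template$atoms) == 0L) stop("input error: empty template")
  th <- heavy_idx(template)
  if (!length(th)) stop("input error: template has no heavy atoms")
  rh <- heavy_idx(receptor)
  d <- cross_dist(coords(receptor)[rh, , drop = FALSE],
                  coords(template)[th, , drop = FALSE])
  mind <- apply(d, 1, min)
  rk <- residue_keys(receptor)[rh]
  per_res <- tapply(mind, rk, min)
  keep <- names(per_res)[per_res <= radius]
  a <- receptor$atoms[rh, ][!duplicated(rk), ]
  akeys <- rk[!duplicated(rk)]
  sel <- match(keep, akeys)
  residues <- data.frame(
    chain = a$chain[sel], resno = a$resno[sel], resname = a$resname[sel],
    key = keep, min_dist = as.numeric(per_res[keep]),
    stringsAsFactors = FALSE
  )
  residues <- residues[order(residues$chain, residues$resno), , drop = FALSE]
  structure(list(residues = residues, radius = radius),
            class = "active_site")
}

#' @export
print.active_site <- function(x, ...) {
  cat(sprintf("<active_site: %d residues within %.1f A>\n",
              nrow(x$residues), x$radius))
  invisible(x)
}

#' @keywords internal
site_atom_idx <- function(receptor, site) {
  which(residue_keys(receptor) %in% site$residues$key)
}
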