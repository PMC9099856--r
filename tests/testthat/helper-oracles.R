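# Independent brute-force oracles used to cross-check the implementation.
# They share only the pharmacophore tag tables with the package code; all
# geometry is recomputed from first principles with plain loops.

.odist <- function(a, b) sqrt(sum((a - b)^2))

.oangle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

# Brute-force all-pairs enumeration of typed interactions. Returns a
# data.frame of (kind, res_key, distance) rows comparable with
# detect_interactions() output.
oracle_detect <- function(pose, receptor, site, crit) {
  lt <- assign_pharmacophore_types(pose)
  rt <- suppressWarnings(assign_pharmacophore_types(receptor))
  rk <- residue_keys(receptor)
  in_site <- rk %in% site$residues$key
  lx <- coords(pose); rx <- coords(receptor)
  out <- list()
  push <- function(kind, key, d) out[[length(out) + 1L]] <<-
    data.frame(kind = kind, res_key = key, distance = d,
               stringsAsFactors = FALSE)
  hb_pairs <- function(dt, dx, at, ax, donor_is_ligand) {
    for (di in unique(dt$atom[dt$tag == "hbond_donor"])) {
      hs <- dt$h[dt$tag == "hbond_donor" & dt$atom == di]
      hs <- hs[!is.na(hs)]
      for (ai in unique(at$atom[at$tag == "hbond_acceptor"])) {
        if (donor_is_ligand && !in_site[ai]) next
        if (!donor_is_ligand && !in_site[di]) next
        d <- .odist(dx[di, ], ax[ai, ])
        if (d > crit$hbond_max_dist) next
        best <- NA
        for (h in hs) best <- max(best, .oangle(dx[di, ], dx[h, ], ax[ai, ]),
                                  na.rm = TRUE)
        if (length(hs) && (is.na(best) || best < crit$hbond_min_angle)) next
        strong <- d <= crit$hbond_strong_dist &&
          (!length(hs) || best >= crit$hbond_strong_angle)
        key <- if (donor_is_ligand) rk[ai] else rk[di]
        push(if (strong) "hbond_strong" else "hbond_weak", key, d)
      }
    }
  }
  hb_pairs(lt, lx, rt, rx, TRUE)
  hb_pairs(rt, rx, lt, lx, FALSE)
  # salt bridges
  for (ci in lt$atom[lt$tag == "cation"]) {
    for (ai in rt$atom[rt$tag == "anion"]) {
      if (!in_site[ai]) next
      d <- .odist(lx[ci, ], rx[ai, ])
      if (d <= crit$salt_bridge_max_dist) push("salt_bridge", rk[ai], d)
    }
  }
  for (ai in lt$atom[lt$tag == "anion"]) {
    cg <- rt[rt$tag == "cation", ]
    for (g in unique(cg$group)) {
      for (ci in cg$atom[cg$group %in% g]) {
        if (!in_site[ci]) next
        d <- .odist(lx[ai, ], rx[ci, ])
        if (d <= crit$salt_bridge_max_dist) push("salt_bridge", rk[ci], d)
      }
    }
  }
  ring_info <- function(tags, x) {
    ar <- tags[tags$tag == "aromatic_ring_member", ]
    lapply(unique(ar$ring[!is.na(ar$ring)]), function(rid) {
      idx <- ar$atom[ar$ring == rid]
      p <- x[idx, , drop = FALSE]
      ctr <- colMeans(p)
      sv <- svd(sweep(p, 2, ctr))
      list(atoms = idx, ctr = ctr, nrm = sv$v[, 3])
    })
  }
  lrings <- ring_info(lt, lx); rrings <- ring_info(rt, rx)
  for (lr in lrings) {
    for (rr in rrings) {
      if (!in_site[rr$atoms[1]]) next
      d <- .odist(lr$ctr, rr$ctr)
      if (d > crit$pi_centroid_max_dist) next
      ang <- acos(max(-1, min(1, abs(sum(lr$nrm * rr$nrm))))) * 180 / pi
      kind <- if (ang <= crit$pi_parallel_max_angle) "pi_pi_parallel"
      else if (ang >= crit$pi_edge_min_angle) "pi_pi_edge"
      else "pi_pi_parallel"
      push(kind, rk[rr$atoms[1]], d)
    }
  }
  # cation-pi
  lcat <- lt[lt$tag == "cation", ]
  for (g in unique(lcat$group)) {
    idx <- lcat$atom[lcat$group %in% g]
    ctr <- colMeans(lx[idx, , drop = FALSE])
    for (rr in rrings) {
      if (!in_site[rr$atoms[1]]) next
      d <- .odist(ctr, rr$ctr)
      if (d <= crit$cation_pi_max_dist) push("cation_pi", rk[rr$atoms[1]], d)
    }
  }
  rcat <- rt[rt$tag == "cation", ]
  for (g in unique(rcat$group)) {
    idx <- rcat$atom[rcat$group %in% g]
    if (!in_site[idx[1]]) next
    ctr <- colMeans(rx[idx, , drop = FALSE])
    for (lr in lrings) {
      d <- .odist(ctr, lr$ctr)
      if (d <= crit$cation_pi_max_dist) push("cation_pi", rk[idx[1]], d)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(kind = character(), res_key = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  res[order(res$res_key, res$kind, round(res$distance, 9)), , drop = FALSE]
}

# canonical comparable form of a record set
record_signature <- function(df) {
  if (!nrow(df)) return(character())
  sort(sprintf("%s|%s|%.6f", df$kind, df$res_key, df$distance))
}

# textbook Welch t-test
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# textbook Pearson r from the covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    ((n - 1) * sd(x) * sd(y))
}
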