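# Pipeline orchestration: a YAML config with one section per module drives
# the subcommands. Unknown keys are rejected so that a typo cannot silently
# fall back to a default.

.CONFIG_KEYS <- list(
  paths = c("output_dir", "pocket", "poses", "activity"),
  simulate = c("pocket_roster", "pocket_radius", "n_poses", "state_means",
               "state_sds", "state_names", "state_counts", "n_centres",
               "centre_sep", "spread", "frequencies", "orientation_mix",
               "ligand"),
  interactions = c("hbond_max_dist", "hbond_min_angle", "hbond_strong_dist",
                   "hbond_strong_angle", "salt_bridge_max_dist",
                   "pi_centroid_max_dist", "pi_parallel_max_angle",
                   "pi_edge_min_angle", "cation_pi_max_dist", "mode",
                   "site_radius"),
  ensemble = c("max_poses", "bin_width", "cluster_threshold",
               "orientation_max_angle"),
  mc = c("temperature", "torsion_rms", "n_steps", "minimize_steps"),
  ec = c("k", "cap", "probe_radius", "points_per_atom", "dielectric"),
  dg = c("hbond_strong", "hbond_weak", "salt_bridge", "born_scale",
         "born_radius_offset", "lost_hbond", "nonpolar_per_area",
         "entropy_per_rotor", "points_per_atom"),
  correlate = c("transform"),
  seed = NULL
)

#' @keywords internal
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("missing input: config file ", path)
  cfg <- yaml::read_yaml(path)
  bad_sections <- setdiff(names(cfg), names(.CONFIG_KEYS))
  if (length(bad_sections))
    stop("invalid config: unknown section(s): ",
         paste(bad_sections, collapse = ", "))
  for (sec in setdiff(names(cfg), "seed")) {
    bad <- setdiff(names(cfg[[sec]]), .CONFIG_KEYS[[sec]])
    if (length(bad))
      stop("invalid config: unknown key(s) in [", sec, "]: ",
           paste(bad, collapse = ", "))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$paths$output_dir)) cfg$paths$output_dir <- "."
  cfg
}

#' @keywords internal
pick <- function(section, key, default) {
  v <- section[[key]]
  if (is.null(v)) default else v
}

#' @keywords internal
config_criteria <- function(cfg) {
  s <- cfg$interactions
  interaction_criteria(
    hbond_max_dist = pick(s, "hbond_max_dist", 3.5),
    hbond_min_angle = pick(s, "hbond_min_angle", 120),
    hbond_strong_dist = pick(s, "hbond_strong_dist", 3.0),
    hbond_strong_angle = pick(s, "hbond_strong_angle", 150),
    salt_bridge_max_dist = pick(s, "salt_bridge_max_dist", 4.0),
    pi_centroid_max_dist = pick(s, "pi_centroid_max_dist", 5.0),
    pi_parallel_max_angle = pick(s, "pi_parallel_max_angle", 30),
    pi_edge_min_angle = pick(s, "pi_edge_min_angle", 60),
    cation_pi_max_dist = pick(s, "cation_pi_max_dist", 5.0))
}

#' @keywords internal
write_sidecar <- function(out_file, cfg, subcommand) {
  side <- paste0(out_file, ".params.json")
  jsonlite::write_json(
    list(subcommand = subcommand, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("bindingspace")),
         config = cfg),
    side, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(side)
}

#' @keywords internal
load_pipeline_inputs <- function(cfg) {
  out <- cfg$paths$output_dir
  pocket_path <- pick(cfg$paths, "pocket", file.path(out, "pocket.pdb"))
  poses_path <- pick(cfg$paths, "poses", file.path(out, "poses.sdf"))
  if (!file.exists(pocket_path)) stop("missing input: ", pocket_path)
  if (!file.exists(poses_path)) stop("missing input: ", poses_path)
  receptor <- read_pdb_structure(pocket_path)
  receptor <- assign_partial_charges(receptor)
  lf <- read_ligand_file(poses_path)
  template <- lf$structures[[1]]
  ens <- pose_ensemble(template, lapply(lf$structures, coords),
                       delta_g = lf$scores)
  site_radius <- pick(cfg$interactions, "site_radius", 6.0)
  # the ensemble itself defines the site: residues near any pose
  site <- select_active_site(receptor, template, radius = site_radius)
  for (p in ensemble_poses(ens)[-1]) {
    s2 <- select_active_site(receptor, p, radius = site_radius)
    extra <- setdiff(s2$residues$key, site$residues$key)
    if (length(extra))
      site$residues <- rbind(site$residues,
                             s2$residues[s2$residues$key %in% extra, ])
  }
  site$residues <- site$residues[order(site$residues$chain,
                                       site$residues$resno), ]
  list(receptor = receptor, ensemble = ens, site = site)
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (emit a seeded toy pocket, pose ensemble and
#' spec JSON), `interactions` (typed records + per-residue occurrence
#' profile), `ensemble` (top-pose filtering + binding-space summary),
#' `cluster` (leader clustering + representative pose SDF), `orient`
#' (orientation labels against the simulated references), `mc` (Metropolis
#' trajectory CSV), `ec` (electrostatic complementarity of the best pose),
#' `dg` (free-energy component table), `correlate` (activity regression).
#' Every output file gets a `.params.json` sidecar recording the seed and
#' parameter set. Errors do not raise: the returned status is 0 on
#' success, 2 for a missing input, 3 for an invalid config, 1 otherwise,
#' with a diagnostic message on stderr.
#'
#' @param config_path path to a YAML config (one section per module).
#' @param subcommand one of simulate, interactions, ensemble, cluster,
#'   orient, mc, ec, dg, correlate.
#' @return integer exit status, invisibly.
#' @export
run_pipeline <- function(config_path, subcommand) {
  known <- c("simulate", "interactions", "ensemble", "cluster", "orient",
             "mc", "ec", "dg", "correlate")
  if (!subcommand %in% known) {
    message("usage: run_pipeline(<config.yaml>, <subcommand>); subcommands: ",
            paste(known, collapse = ", "))
    return(invisible(1L))
  }
  status <- tryCatch({
    cfg <- read_pipeline_config(config_path)
    dir.create(cfg$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
    do.call(paste0("pipeline_", subcommand), list(cfg))
    0L
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error [", subcommand, "]: ", msg)
    if (grepl("missing input|file not found", msg)) 2L
    else if (grepl("invalid config", msg)) 3L
    else 1L
  })
  invisible(status)
}

#' @keywords internal
pipeline_simulate <- function(cfg) {
  s <- cfg$simulate
  out <- cfg$paths$output_dir
  roster <- pick(s, "pocket_roster", c("GLU", "ARG", "PHE", "THR"))
  pocket <- make_toy_pocket(pocket_spec(roster,
                                        radius = pick(s, "pocket_radius", 6),
                                        seed = cfg$seed))
  ligand <- make_toy_ligand(pick(s, "ligand", "mdma_like"))
  states <- pick(s, "state_names", c("stateA", "stateB"))
  per_state <- data.frame(
    state = states,
    mean = rep_len(pick(s, "state_means", c(-7.1, -6.3)), length(states)),
    sd = rep_len(pick(s, "state_sds", c(0.9, 0.6)), length(states)))
  if (!is.null(s$state_counts)) per_state$n <- as.integer(s$state_counts)
  freqs <- unlist(pick(s, "frequencies", NULL))
  mix <- unlist(pick(s, "orientation_mix",
                     c(serotonin_like = 0.4, escitalopram_like = 0.4,
                       intermediate = 0.2)))
  espec <- ensemble_spec(
    n_poses = pick(s, "n_poses", 100), per_state = per_state,
    n_centres = pick(s, "n_centres", 1),
    centre_sep = pick(s, "centre_sep", 10),
    spread = pick(s, "spread", 0.5),
    frequencies = freqs, orientation_mix = mix, seed = cfg$seed)
  planted <- plant_pose_ensemble(pocket, ligand, espec,
                                 criteria = config_criteria(cfg))
  write_pdb_structure(pocket, file.path(out, "pocket.pdb"))
  write_ligand_sdf(ensemble_poses(planted$ensemble),
                   file.path(out, "poses.sdf"),
                   scores = planted$ensemble$delta_g)
  write_ligand_sdf(planted$refs, file.path(out, "refs.sdf"))
  jsonlite::write_json(
    list(spec_version = "1.0", n_poses = espec$n_poses,
         per_state = per_state, orientation_mix = as.list(mix),
         frequencies = as.list(freqs), seed = cfg$seed,
         states = planted$ensemble$state,
         orientation_labels = planted$orientation_labels),
    file.path(out, "spec.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_sidecar(file.path(out, "poses.sdf"), cfg, "simulate")
}

#' @keywords internal
pipeline_interactions <- function(cfg) {
  inp <- load_pipeline_inputs(cfg)
  out <- cfg$paths$output_dir
  crit <- config_criteria(cfg)
  poses <- ensemble_poses(inp$ensemble)
  recs <- lapply(seq_along(poses), function(i) {
    r <- detect_interactions(poses[[i]], inp$receptor, inp$site, crit)
    if (nrow(r)) cbind(pose = i, as.data.frame(r)) else NULL
  })
  all <- do.call(rbind, recs)
  if (is.null(all)) all <- data.frame()
  utils::write.csv(all, file.path(out, "records.csv"), row.names = FALSE)
  prof <- contact_profile(inp$ensemble, inp$receptor, inp$site, crit,
                          mode = pick(cfg$interactions, "mode", "typed_only"))
  pdf_ <- as.data.frame(prof)
  pdf_$mode <- attr(prof, "mode"); pdf_$n_poses <- attr(prof, "n_poses")
  utils::write.csv(pdf_, file.path(out, "profile.csv"), row.names = FALSE)
  tab <- occurrence_table(Filter(Negate(is.null), recs))
  utils::write.csv(tab, file.path(out, "occurrence_table.csv"),
                   row.names = FALSE)
  write_sidecar(file.path(out, "records.csv"), cfg, "interactions")
}

#' @keywords internal
pipeline_ensemble <- function(cfg) {
  inp <- load_pipeline_inputs(cfg)
  out <- cfg$paths$output_dir
  top <- filter_top_poses(inp$ensemble,
                          max_n = pick(cfg$ensemble, "max_poses", 80))
  summ <- binding_space_summary(top,
                                bin_width = pick(cfg$ensemble, "bin_width",
                                                 0.5))
  counts <- data.frame(state = names(summ$per_state_counts),
                       count = as.integer(summ$per_state_counts))
  utils::write.csv(counts, file.path(out, "per_state_counts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_poses = summ$n_poses, mean_dg = summ$mean_dg, sd_dg = summ$sd_dg,
         mode_dg = summ$mode_dg, range_dg = summ$range_dg,
         sensitivity_score = summ$sensitivity_score,
         mean_pairwise_rmsd = summ$mean_pairwise_rmsd,
         sensitivity_definition = "range_dg / mean pairwise superposed rmsd"),
    file.path(out, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_sidecar(file.path(out, "summary.json"), cfg, "ensemble")
}

#' @keywords internal
pipeline_cluster <- function(cfg) {
  inp <- load_pipeline_inputs(cfg)
  out <- cfg$paths$output_dir
  cl <- cluster_poses(inp$ensemble,
                      threshold = pick(cfg$ensemble, "cluster_threshold", 2))
  utils::write.csv(
    data.frame(pose = seq_along(cl$labels), cluster = cl$labels,
               is_representative =
                 seq_along(cl$labels) == cl$representative_index),
    file.path(out, "clusters.csv"), row.names = FALSE)
  rep_pose <- ensemble_poses(inp$ensemble)[[cl$representative_index]]
  write_ligand_sdf(rep_pose, file.path(out, "representative.sdf"),
                   scores = inp$ensemble$delta_g[cl$representative_index])
  write_sidecar(file.path(out, "clusters.csv"), cfg, "cluster")
}

#' @keywords internal
pipeline_orient <- function(cfg) {
  inp <- load_pipeline_inputs(cfg)
  out <- cfg$paths$output_dir
  refs_path <- file.path(out, "refs.sdf")
  if (!file.exists(refs_path)) stop("missing input: ", refs_path)
  refs <- read_ligand_file(refs_path)$structures
  labels <- vapply(ensemble_poses(inp$ensemble), function(p) {
    classify_orientation(p, refs[[1]], refs[[2]],
                         max_angle = pick(cfg$ensemble,
                                          "orientation_max_angle", 40))$label
  }, character(1))
  utils::write.csv(data.frame(pose = seq_along(labels), label = labels),
                   file.path(out, "orientations.csv"), row.names = FALSE)
  write_sidecar(file.path(out, "orientations.csv"), cfg, "orient")
}

#' @keywords internal
pipeline_mc <- function(cfg) {
  out <- cfg$paths$output_dir
  sys <- make_mc_system(seed = cfg$seed)
  m <- cfg$mc
  mcfg <- mc_config(temperature = pick(m, "temperature", 1000),
                    torsion_rms = pick(m, "torsion_rms", 60),
                    n_steps = pick(m, "n_steps", 1000),
                    minimize_steps = pick(m, "minimize_steps", 20),
                    seed = cfg$seed,
                    monitored_pairs = sys$monitored_pairs)
  traj <- run_mc(sys$pose, sys$receptor, sys$site, mcfg)
  utils::write.csv(traj$steps, file.path(out, "mc_steps.csv"),
                   row.names = FALSE)
  utils::write.csv(traj$monitored, file.path(out, "mc_distances.csv"),
                   row.names = FALSE)
  snaps <- lapply(traj$snapshots, function(x) {
    s <- traj$ligand; coords(s) <- x; s
  })
  write_ligand_sdf(snaps, file.path(out, "mc_snapshots.sdf"))
  write_sidecar(file.path(out, "mc_steps.csv"), cfg, "mc")
}

#' @keywords internal
pipeline_ec <- function(cfg) {
  inp <- load_pipeline_inputs(cfg)
  out <- cfg$paths$output_dir
  e <- cfg$ec
  p <- ec_params(k = pick(e, "k", 5), cap = pick(e, "cap", 12),
                 probe_radius = pick(e, "probe_radius", 1.4),
                 points_per_atom = pick(e, "points_per_atom", 256),
                 dielectric = pick(e, "dielectric", 1))
  best <- which.min(inp$ensemble$delta_g)
  pose <- ensemble_poses(inp$ensemble)[[best]]
  pose <- assign_partial_charges(pose)
  res <- electrostatic_complementarity(pose, inp$receptor, p)
  utils::write.csv(res$points, file.path(out, "ec_surface.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(global_ec = res$global_ec,
                            total_area = res$total_area, pose = best),
                       file.path(out, "ec_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  write_sidecar(file.path(out, "ec_summary.json"), cfg, "ec")
}

#' @keywords internal
pipeline_dg <- function(cfg) {
  inp <- load_pipeline_inputs(cfg)
  out <- cfg$paths$output_dir
  d <- cfg$dg
  par <- dg_params(hbond_strong = pick(d, "hbond_strong", -1.0),
                   hbond_weak = pick(d, "hbond_weak", -0.5),
                   salt_bridge = pick(d, "salt_bridge", -1.0),
                   born_scale = pick(d, "born_scale", 1 / 4 - 1 / 80),
                   born_radius_offset = pick(d, "born_radius_offset", 0.5),
                   lost_hbond = pick(d, "lost_hbond", 0.6),
                   nonpolar_per_area = pick(d, "nonpolar_per_area", -0.025),
                   entropy_per_rotor = pick(d, "entropy_per_rotor", 0.65),
                   points_per_atom = pick(d, "points_per_atom", 128))
  poses <- ensemble_poses(inp$ensemble)
  poses <- lapply(poses, assign_partial_charges)
  tab <- dg_breakdown_table(poses, inp$receptor, inp$site, par,
                            config_criteria(cfg))
  utils::write.csv(tab, file.path(out, "dg_breakdown.csv"),
                   row.names = FALSE)
  write_sidecar(file.path(out, "dg_breakdown.csv"), cfg, "dg")
}

#' @keywords internal
pipeline_correlate <- function(cfg) {
  out <- cfg$paths$output_dir
  act_path <- pick(cfg$paths, "activity", file.path(out, "activity.csv"))
  if (!file.exists(act_path)) stop("missing input: ", act_path)
  act <- utils::read.csv(act_path)
  need <- c("compound", "dg_s1", "dg_s2", "ic50_nM")
  if (!all(need %in% names(act)))
    stop("missing input: activity table needs columns ",
         paste(need, collapse = ", "))
  transform <- pick(cfg$correlate, "transform", "log10")
  fits <- lapply(c(S1 = "dg_s1", S2 = "dg_s2"), function(col)
    fit_dg_activity(act[[col]], act$ic50_nM, transform = transform))
  jsonlite::write_json(
    lapply(fits, function(f) list(slope = f$slope, intercept = f$intercept,
                                  pearson_r = f$pearson_r, n = f$n)),
    file.path(out, "correlation.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_sidecar(file.path(out, "correlation.json"), cfg, "correlate")
}
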