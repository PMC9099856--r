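# bindingspace

Ensemble binding-space analysis of protein–ligand pose ensembles in R.

Ensemble docking produces, for one ligand, dozens of scored poses across
many receptor conformations. The scientific question is rarely "what is
the single best pose" but rather: how does the ligand occupy the site
across that ensemble — which residues does it touch and how often, how
many distinct binding modes exist, how much does its free energy vary with
its own conformation, and are its contacts stable under thermal
perturbation? `bindingspace` answers these questions for
transporter-style pockets and amphetamine-like cationic ligands (a
protonated amine plus a fused aromatic/dioxole system, the chemotype of
entactogens binding the serotonin-transporter allosteric vestibule), but
the machinery is generic.

The package provides, as composable functions behind one YAML-driven
pipeline:

* **Typed interaction fingerprints** — H-bonds (weak/strong), salt
  bridges, π–π (parallel/edge), cation–π, under explicit geometric
  criteria (5 Å aromatic centroid cutoff, 3.5/3.0 Å H-bond windows,
  4 Å salt bridges — all configurable), plus per-residue relative
  occurrence profiles over an ensemble.
* **Binding-space parameterization** — retention of the top 80 poses by
  ΔG; mean/SD/mode/range of ΔG; a sensitivity score
  (range ΔG ÷ mean pairwise superposed rmsd — free-energy variability
  attributable to ligand conformation); binding-mode displacement
  (mean pairwise rmsd in the receptor frame); greedy leader clustering
  with a medoid representative; orientation classification
  (serotonin-like / escitalopram-like / intermediate) by cation→ring
  axis angles.
* **Metropolis Monte Carlo torsional search** — the Boltzmann-jump
  protocol: exact-rms 60° torsional moves, 20 steepest-descent steps,
  Metropolis acceptance at 1000 K, 1000 steps, with per-step monitoring
  of interaction distances (p(accept) = exp(−ΔE/RT) for uphill moves).
* **Electrostatic complementarity (EC)** — Shrake–Rupley sampling of the
  ligand solvent-accessible surface, point-charge ESPs, and the local
  score EC = 1 − |ESP_L + ESP_P| / max(|ESP_L|, |ESP_P|, k) with k = 5
  and ESPs capped at ±12, area-integrated to a global score in [−1, 1].
* **A component-structured ΔG estimate** — LJ + Coulomb enthalpy, H-bond
  and salt-bridge rewards, Born-like polar desolvation, buried
  unsatisfied-donor penalties, nonpolar solvation, internal strain, and
  rotor-freezing entropy; for ranking poses, not absolute affinities.
* **Validation statistics** — OLS of log10(IC50) on ΔG with Pearson r,
  and Welch t-tests between orientation ensembles.
* **Seeded synthetic generators** — toy pockets from ideal residue
  templates, toy ligands, and pose ensembles with *planted* cluster
  structure, contact frequencies, orientation mixes and per-state ΔG
  distributions, standing in for a docking engine so that every analysis
  above is testable against known ground truth.

## Worked example

```r
library(bindingspace)

pocket <- make_toy_pocket(pocket_spec(c("GLU", "ARG", "PHE", "THR"),
                                      radius = 6, seed = 1))
ligand <- make_toy_ligand("mdma_like")
planted <- plant_pose_ensemble(pocket, ligand,
  ensemble_spec(n_poses = 120,
                per_state = data.frame(state = c("outward_open", "occluded"),
                                       mean = c(-7.1, -6.3),
                                       sd = c(0.9, 0.6)),
                frequencies = c(GLU = 0.4, PHE = 0.25),
                conformer_jitter = 25, seed = 42))

top <- filter_top_poses(planted$ensemble, max_n = 80)
binding_space_summary(top)
#> Binding-space summary (n = 80 poses)
#>   dG   mean -7.14  sd 0.79  mode -6.54  range 3.56 kcal/mol
#>   sensitivity 9.833  mean pairwise rmsd 2.39 A
#>   poses per state:
#>     occluded outward_open
#>           31           49
```

The 120 generated poses carry ΔG values drawn per receptor state from
N(−7.1, 0.9) and N(−6.3, 0.6) kcal/mol; after retaining the 80 most
favourable, the outward-open state dominates (49 vs 31) because its
distribution is deeper — the per-state counts report exactly this
occupancy. The mean pairwise rmsd (2.39 Å, measured in the common
receptor frame) quantifies how much of the site the retained ensemble
explores; the sensitivity score divides the ΔG range by the
conformational (superposed) rmsd.

```r
site <- select_active_site(pocket, ensemble_poses(top)[[1]], radius = 30)
contact_profile(top, pocket, site)
#>   resname n_contacting occurrence
#> 1     GLU           38     0.4750
#> 2     ARG            0     0.0000
#> 3     PHE           17     0.2125
#> 4     THR            0     0.0000
```

The generator planted GLU contacts in 40% and PHE contacts in 25% of all
120 poses; the profile over the retained top-80 recovers them (filtering
slightly enriches the GLU-contacting poses because contacts were planted
on the lower-ΔG state block). Comparing the two orientation ensembles:

```r
compare_orientations(top$delta_g[top$state == "outward_open"],
                     top$delta_g[top$state == "occluded"])
#> Group A: -7.44 +/- 0.86 (n = 49)
#> Group B: -6.67 +/- 0.29 (n = 31)
#> Welch t = -5.748 (df = 64.0), two-sided p = 2.717e-07 *
```

The same steps run from a shell via the pipeline wrapper
(`inst/scripts/bindingspace.R`) with a YAML config:

```sh
Rscript inst/scripts/bindingspace.R simulate config.yaml
Rscript inst/scripts/bindingspace.R interactions config.yaml
Rscript inst/scripts/bindingspace.R ensemble config.yaml
```

See `vignettes/binding-space-methods.Rmd` for the models, parameter
defaults and numerical choices.

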