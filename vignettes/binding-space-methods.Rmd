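---
title: "Methods: ensemble binding-space analysis of pose ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble binding-space analysis of pose ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindingspace)
```

`bindingspace` is the analysis layer for ensemble-docking studies of
small-molecule binding, built around the recognition of amphetamine-like
cationic ligands (a protonated amine plus a fused aromatic/dioxole ring
system) by transporter-like pockets such as the allosteric (S2) vestibule
of the serotonin transporter. Docking itself is out of scope: the package
starts from a *scored pose ensemble* — many ligand conformations, each
annotated with an estimated binding free energy ΔG and a source
receptor-state label — and quantifies what that ensemble says about the
binding site.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generators do
and do not emulate.

## Interaction fingerprints

`detect_interactions()` enumerates typed noncovalent ligand–receptor
contacts under explicit geometric criteria
(`interaction_criteria()`):

| interaction | geometry | default window |
|---|---|---|
| H-bond (weak) | donor–acceptor heavy-atom distance, D–H…A angle | ≤ 3.5 Å, ≥ 120° |
| H-bond (strong) | same | ≤ 3.0 Å, ≥ 150° |
| salt bridge | N⁺…O⁻ atom distance | ≤ 4.0 Å |
| π–π parallel | ring centroid distance, interplanar angle | ≤ 5.0 Å, ≤ 30° |
| π–π edge-to-face | same | ≤ 5.0 Å, ≥ 60° |
| cation–π | cation centroid to ring centroid | ≤ 5.0 Å |

The 5 Å centroid cutoff for aromatic interactions is the protocol constant
used for bond-stability monitoring; the H-bond and salt-bridge windows are
standard literature values and every threshold is configurable. Two
deliberate conventions: a salt bridge is reported *in addition to* an
H-bond when both criteria hold (charged amines routinely do both
simultaneously), and a π–π contact whose interplanar angle falls between
the parallel and edge windows is reported as parallel with a `displaced`
flag rather than dropped. Pharmacophore tags come from residue templates
on the receptor side (carboxylate oxygens anionic, guanidinium/ammonium
nitrogens cationic, PHE/TYR/TRP/HIS side-chain rings aromatic, standard
protonation states: ASP/GLU deprotonated, ARG/LYS protonated, HIS
neutral) and from the element/bond environment on the ligand side
(four-coordinate nitrogen cationic, planar rings of five or more members
aromatic). Structures without explicit hydrogens are accepted; donors are
then heavy-atom donors with a warning and angle checks are skipped.

`contact_profile()` turns per-pose records into per-residue *relative
occurrences*: the fraction of poses making at least one contact with each
residue. Whether a published occurrence plot counts typed interactions or
any heavy-atom contact is often unstated, so both conventions are
implemented (`mode = "typed_only"` is the default, `"any_contact"` uses a
4.0 Å heavy-atom cutoff) and the mode is recorded in the output.

## Binding-space parameterization

`binding_space_summary()` computes, over a scored ensemble: sample mean
and SD of ΔG, the mode (centre of the most populated 0.5 kcal/mol bin
anchored at the minimum — the bin rule is a package convention, since mode
binning is rarely stated), the range, per-state pose counts, and two
shape scores:

* **mean pairwise displacement rmsd** — heavy-atom rmsd between poses in
  the common receptor frame, *without* superposition: poses share one
  frame, so this measures exploration of the site ("binding-mode
  displacement").
* **sensitivity score** — ΔG range divided by the mean pairwise
  *superposed* rmsd (optimal rigid alignment, Kabsch). Superposition
  removes rigid motion, leaving intramolecular flexibility, so the ratio
  expresses the ligand's capacity to change its free energy by adjusting
  its own conformation. The published property-space formulation this
  mirrors is only described qualitatively, so this explicit formula is a
  declared stand-in and is recorded in the output metadata.

`filter_top_poses()` retains the `max_n = 80` most favourable poses
("highest scoring" = lowest ΔG), sorted ascending with input-order tie
breaking. `cluster_poses()` uses greedy leader clustering in input order
on displacement rmsd (threshold 2 Å): deterministic, O(nk), and adequate
for well-separated binding modes; the representative is the medoid of the
most populated cluster with ties broken by lower ΔG then lower index
(whether a published representative is medoid or best-scored is usually
unstated; the medoid is the more robust choice).
`classify_orientation()` labels poses serotonin-like, escitalopram-like
or intermediate by the angle between cation→ring axes against two
reference poses (qualification window 40°, the smaller qualifying angle
wins).

## Metropolis Monte Carlo torsional search

`run_mc()` implements the Boltzmann-jump protocol: at each of
`n_steps = 1000` steps, all rotatable dihedrals are perturbed by a
zero-mean normal draw rescaled so the per-move rms is *exactly*
`torsion_rms = 60°`, the conformation is relaxed by exactly
`minimize_steps = 20` steepest-descent iterations, and the
post-minimization energy is accepted or rejected by the Metropolis
criterion at `temperature = 1000` K (R = 1.987204×10⁻³ kcal/(mol·K)).
Rejected proposals restore the previous conformer; the receptor is held
rigid throughout and the engine asserts it. Monitored ligand–receptor
pair distances (ring–ring and charged-group pairs use centroids) are
recorded at every step as bond-stability markers.

Numerical choices worth knowing:

* The "torsion rmsd of 60°" is read as an exact per-move rms (rescaled
  draw), which makes it assertable per step; an unscaled
  distribution-width reading is selectable with `exact_rms = FALSE`.
* Metropolis is applied to the post-minimization energy
  (perturb-then-minimize basin hopping); with interleaved minimization
  prescribed, this is the order that makes the minimization meaningful.
* Minimization is steepest descent *in torsion space* (the rotatable
  dihedrals, numeric gradient, backtracking line search with halving down
  to 10⁻³ degrees). The move set is torsional, so descending in the same
  coordinates keeps covalent geometry rigid-valid without bond/angle
  terms, and "exactly n steps, energy non-increasing" holds by
  construction.
* The energy model (`energy_model()`) is a minimal stand-in:
  Lennard-Jones 12-6, Coulomb under a distance-dependent dielectric
  ε = 4r (Coulomb constant 332.06 kcal·Å/(mol·e²)), a 3-fold torsion
  barrier (1.4 kcal/mol) averaged over all substituent quadruples of each
  rotatable bond (averaging makes the term invariant to atom relabeling),
  and intra-ligand nonbonded terms for pairs four or more bonds apart.
  Atom overlaps below 0.1 Å evaluate at the cap distance and set a flag.
  Absolute energies are **not** comparable to published binding energies;
  only the protocol behaviour (acceptance statistics, stability of
  monitored contacts) is meaningful.

## Electrostatic complementarity (EC)

`sample_sas()` samples the solvent-accessible surface by the
Shrake–Rupley method: a deterministic golden-spiral lattice of
`points_per_atom = 256` points on each atom's expanded sphere
(vdW + probe 1.4 Å), discarding points inside any neighbour's expanded
sphere; each surviving point carries area 4π(r+probe)²/points_per_atom.
`esp_from_charges()` evaluates the point-charge potential
ESP(x) = Σ 332.06·qᵢ/(ε·|x−xᵢ|) with ε = 1 at the surface, so ESP is in
kcal/(mol·e) — the unit convention in which the score constants below are
interpreted, declared here because the original multipole field the
method was published with is proprietary.

The local complementarity score at a surface point is

> EC(x) = 1 − |ESP_L + ESP_P| / max(|ESP_L|, |ESP_P|, k)

with both ESPs first clamped to ±cap, k = 5 and cap = 12 by default; the
global score is the area-weighted mean over the *ligand* SAS. The
magnitude bars are written explicitly because without them the expression
is sign-ambiguous; with them the score is +1 for perfectly complementary
potentials above the floor, −1 for identical clashing ones, and bounded
in [−1, 1] for every input.

## Component-structured ΔG estimate

`estimate_dg()` preserves the term inventory of an enthalpic–entropic
binding free-energy estimator without reproducing any proprietary
calibration. Per pose: LJ and Coulomb enthalpy from the MC energy model;
H-bond rewards (−1.0 strong, −0.5 weak, −1.0 per salt bridge) from the
detector; Born-like polar desolvation
`born_scale · 166 · q² · buried_fraction / r_Born` summed over ligand
charges, with r_Born = covalent radius + 0.5 Å, buried fraction from
per-atom SAS with and without the receptor, and
`born_scale = 1/4 − 1/80 ≈ 0.237` — the two-dielectric water→protein Born
transfer factor, chosen because the raw vacuum Born magnitude (tens of
kcal/mol for a unit charge) would drown every other term; +0.6 kcal/mol
per buried unsatisfied donor/acceptor (buried fraction > 0.5, no detected
partner — the published penalty has no stated functional form, this
per-site constant is a stand-in); nonpolar solvation −0.025 kcal/mol per
buried Å²; internal strain = max(0, E_conf − E_conf of the relaxed free
ligand); and an entropic penalty of +0.65 kcal/mol per rotor whose
smaller fragment contacts the receptor within 4 Å. All coefficients are
exposed in `dg_params()` and in the pipeline config. The estimator is for
*ranking* poses (more planted favourable contacts must score better — a
property the test suite enforces on constructed pose sets), not for
absolute affinity prediction.

## Statistics

`fit_dg_activity()` regresses log10(IC50) on ΔG (ordinary least squares,
y = x·a + b) and reports the Pearson r; the log transform is the
pharmacological convention and can be disabled.
`compare_orientations()` is a two-sided Welch unequal-variance t-test —
published group comparisons of this kind often say only "t-test", and
with unknown group sizes and variances Welch is the safe default.

## Synthetic data: what it emulates, and what it does not

The generators stand in for a proprietary induced-fit docking engine.
`make_toy_pocket()` places ideal-geometry residue templates (GLU, ASP,
ARG, LYS, PHE, TYR, THR, GLN, GLY; polar hydrogens included; standard
protonation) on a cylindrical shell with functional tips pointing at the
site axis, default tip radius 4.5 Å so a 6 Å site definition captures the
roster. `make_toy_ligand("mdma_like")` is a cationic
methylenedioxyphenyl-alkylamine with net charge +1 and exactly 3
rotatable bonds under the rotor rule (the two methyls are terminal);
`probe_chain` is an 11-carbon united-atom alkane with 8 rotors for
conformational-search exercises.

`plant_pose_ensemble()` plants *exact* statistical structure: per-state
ΔG draws from stated normal distributions (the default pipeline uses
−7.1 ± 0.9 vs −6.3 ± 0.6 kcal/mol, the two-orientation group moments the
Welch comparison is exercised on); cluster centres with positional jitter
drawn from a normal truncated at 2σ, so a planted blob is geometrically
bounded and cluster-count recovery is exact whenever centre separation is
at least 5× the spread and twice the leader threshold (untruncated
Gaussian tails would violate that guarantee by construction); an
enforced orientation mix via rigid axis alignment; and per-residue
contact frequencies realised as exact pose counts on disjoint subsets
(frequencies summing above 1 are rejected as a geometric conflict) with
translation-only local adjustment, non-assigned poses pushed clear along
the site axis. Exact planting means recovery tolerances in the tests
measure the *detector*, not sampling noise.

What passing these tests does *not* show about real data: toy pockets
have no fold, no backbone continuity, no waters (explicit or implicit —
solvent-density annotation is deliberately out of scope), no membrane,
and no induced fit; planted frequencies are deterministic rather than
Bernoulli; and the energy model is a minimal stand-in. Results on real
receptor structures depend on the upstream docking engine and preparation
pipeline, which this package does not provide.

## Problem sizes used in the checks

The shipped test-suite and acceptance computations use: pose ensembles of
up to 200 poses across 20 generator seeds for frequency recovery; 40-pose
two-blob ensembles across 20 seeds for cluster recovery; 10⁴ Metropolis
proposals for the acceptance-law fit; 10⁴ random meshes for EC bound
fuzzing; 256 surface points per atom (64–4096 in the convergence check);
and 1000-step Monte Carlo runs with a rotor-free probe where only the
step-count contract is at stake. These sizes were chosen so each
statistical check has comfortable resolution at its stated tolerance.

## Known limitations

* Bond perception is purely geometric (covalent radii + 0.45 Å); no bond
  orders, so amide detection is heuristic (carbonyl-bearing C–N).
* Ring perception returns shortest cycles through each bond —
  adequate for drug-like molecules, not a full SSSR for pathological
  fused systems.
* Receptor flexibility is out of scope: monitored receptor–receptor
  distances are only meaningful if receptor motion is supplied
  externally.
* The ΔG estimator's coefficients are sane-magnitude defaults, not a
  fitted calibration; cross-compound correlations computed from it are
  illustrative.
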