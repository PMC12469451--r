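---
title: "Models and methods: PTM peptide conformational analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: PTM peptide conformational analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmensemble)
```

# Scope and scientific setting

Rheumatoid-arthritis autoantibodies (the AMPA family) recognise peptide
epitopes carrying post-translational modifications: citrullination of
arginine, carbamylation of lysine (homocitrulline) and lysine acetylation.
Each modification removes one positive charge and subtly changes the local
chemistry, and the conformational consequences are one candidate
explanation for differential autoantibody recognition. `ptmensemble`
implements the computational chain used to study such epitopes — here the
15-mer fibrin-derived template HSTKRGHAKSRPVRG and its PTM variants:

1. PTM-aware peptide bookkeeping (sequence grammar, average masses, formal
   charges);
2. circular-dichroism helicity estimation;
3. PTM-corrected chemical-shift deviation maps;
4. NOESY volume calibration into flat-bottom distance restraints;
5. restraint-energy and violation scoring over conformational ensembles;
6. ensemble observables (Rg, secondary-structure populations, contacts) and
   multi-trajectory similarity clustering.

A synthetic-ensemble generator with fully known ground truth closes the
loop: every analysis stage can be validated against planted parameters.

# Peptide model

The grammar accepts one-letter codes with inline tokens `Cit`, `hCit` and
`K(Ac)`, plus an optional `Biotinyl-PEG2-` N-cap. Each token records its
parent residue, so chemical placement (Cit on Arg, hCit/K(Ac) on Lys) holds
by construction.

Masses are *average* masses: calculated ESI-MS values for intact peptides
follow average-mass arithmetic, and the package's residue table agrees with
an elemental-formula oracle to better than 0.01 Da per residue. The PTM
deltas come from elemental changes: Cit − Arg = +0.984 (NH → O),
hCit − Lys = +43.025 (+HNCO), K(Ac) − Lys = +42.037 (+C2H2O). The one
genuinely underdetermined constant is the biotinyl-PEG2 acyl cap: the
reagent is named but its formula is not, so the default 543.68 Da is
back-derived from the unmodified capped peptide's calculated mass and is
deliberately exposed in `ptm_mass_defaults()` for replacement.

Formal charges use an integer counting model (no Henderson–Hasselbalch
fractions): a group contributes ±1 when the pH is on the charged side of a
crude pKa, so at pH 7 Arg/Lys are +1, His and all three PTMs 0, Asp/Glu −1,
and capped termini 0. The series P1 (+5) → P10 (+1) illustrates the
one-charge-per-PTM rule. Net charge is used only qualitatively in this
field, which is why a fractional model would suggest more precision than
the downstream use supports.

```{r}
p10 <- parse_peptide("Biotinyl-PEG2-HSThCitCitGHAK(Ac)SRPVCitG")
c(mass = round(peptide_mass(p10), 1), charge = peptide_charge(p10))
```

# Circular dichroism

Mean residue ellipticity uses the convention
MRE = θ(mdeg)·Mr / (10·c(mg/mL)·l(cm)·n), with `n` the number of peptide
bonds (length − 1, plus one per acylated/amidated terminus). MRE
conventions in the literature differ by factors of ten, so the exact factor
chain is fixed here and unit-tested. Helix fraction at 222 nm uses the
chain-length-corrected estimate f = MRE222 / (θ∞·(1 − k/n)) with defaults
θ∞ = −39500 deg·cm²·dmol⁻¹ and k = 2.57, both overridable; f is clamped to
[0, 1] because short noisy spectra can overshoot either end. The measured
spectra behind the published 9–24% helix range are not deposited, so that
range guides fixture design only; the package's tests assert unit
correctness and monotonicity, not a biological helix content.

# Chemical-shift deviations

Δδ = δ_observed − δ_random-coil per residue and nucleus (Hα, Cα), with the
random-coil reference looked up by residue type *including* the PTM. The
shipped reference table is a Wishart-style peptide set; the PTM rows are
parent values plus small corrections and are explicit placeholders in an
editable TSV, because measured PTM random-coil values are not reprinted in
the sources this package draws on. Swapping the file changes the science
without touching code.

Window classification uses the joint sign pattern of the windowed means:
helix-like when mean Δδ_Hα < −τ_H and mean Δδ_Cα > +τ_C (τ_H = 0.1,
τ_C = 0.5 ppm — our smallest-meaningful-shift convention, config-exposed).
The reversed pattern is shared by extended strands and turns; the package
splits it by magnitude (beyond twice each threshold → extended-like,
otherwise turn-compatible). This tier is a design choice made because the
sign pattern alone cannot separate the two, and it keeps small
positive-Hα/negative-Cα patterns — the turn regime — distinct from
full-strand deviations. No neighbour corrections are applied by default.

# NOE restraints

Volumes calibrate as r = r_ref·(V_ref/V)^(1/6) against the averaged
geminal-methylene reference (r_ref = 1.78 Å, the ideal H–C–H geometry,
configurable). Upper bounds are classified on the Wüthrich scale (strong
≤ 2.8 Å, medium ≤ 3.8 Å, weak ≤ 5.0 Å, else very weak; upper edges
inclusive so ties break deterministically). Pseudoatom corrections are
applied per pseudoatom end before classification: methyl/methylene +1.0 Å,
aromatic ring +2.0 Å by default.

Bounds are then built per class in nm — strong (0.18, 0.25), medium
(0.18, 0.33), weak (0.18, 0.55) — with the outer bound r2 = 1.5·r1 rounded
to 2 decimals (0.38, 0.50, 0.83), except very-weak restraints, which take
r1 = r2 = 10 nm: effectively unbounded for a 15-mer. When no hydrogen is
available the restraint falls back to the bound heavy atom and 1.1 Å
(one C–H bond) is added. Note two deliberate asymmetries, kept verbatim
from the bound table this reproduces: the class table is on the nm scale
even though classification thresholds are in Å, and the weak-class r1
(0.55 nm) exceeds the weak classification edge (5.0 Å); the table wins on
conflict.

The Gromacs export writes a fixed-width `[ distance_restraints ]` block
(`ai aj type index type' low up1 up2 fac`); replica fan-out belongs to the
engine.

# Restraint energy

The flat-bottom potential is quadratic below r0, zero on [r0, r1],
quadratic on (r1, r2] and linear beyond r2 with a C¹ junction
(slope k·(r2 − r1)); the default force constant is 1000 kJ·mol⁻¹·nm⁻².
Violation scoring uses instantaneous per-frame distances — no time or
r⁻³ averaging — because ensemble-averaged restraining is an engine feature,
and the per-restraint mean distance is reported separately. Pseudoatom
references resolve to the centroid of their member protons (or the carrier
carbon when protons are absent).

# Ensemble observables

Equilibration discard defaults to the leading 20% of each trajectory
(e.g. 40 of 200 ns), applied per source trajectory in pooled ensembles. Rg
is mass-weighted over all atoms. Secondary structure uses transparent
Ramachandran windows — H: φ∈(−100°, −30°), ψ∈(−80°, −5°); E:
φ∈(−180°, −90°), ψ∈(90°, 180°)∪(−180°, −170°) — with a minimum run of 3
consecutive identical labels (shorter runs revert to C) and C at chain
termini. A dihedral rule was chosen over DSSP-style pattern recognition
because every assignment is checkable by hand; the `windows` argument is
the seam for alternative assigners. Population errors use block averaging
(5 blocks by default) since MD frames are autocorrelated. Contacts use the
minimum heavy-atom distance with a 0.5 nm cutoff and |i − j| ≥ 2, all
config-exposed; the i,i+3/i,i+4 prevalence summary targets the
helix-diagnostic band.

# Multi-trajectory clustering

The pipeline is similarity matrix → 2-D embedding → density grouping. The
default metric is Euclidean distance between backbone-dihedral sin/cos
features (superposition-free; the trigonometric encoding removes the
±180° wrap); pairwise Kabsch RMSD is the alternative. The embedding is an
exact O(n²) t-SNE implemented in the package (no R t-SNE implementation is
otherwise available to it), deterministic given the seed, with perplexity
30 and parameters recorded on the result. Density grouping is DBSCAN-style
on the embedding with min_points = max(5, 0.5% of frames). The default
radius is max(5% of the embedding span, median k-distance at
k = min_points): the k-distance floor — the standard DBSCAN heuristic —
was added after observing that a *single* diffuse state embeds as one
spread cloud in which a bare 5%-of-span radius turns every frame into
noise, which is the wrong answer for a one-state pool.

Populations are accounted on the pooled-frame scale, overall and split by
source trajectory; summing a trajectory's shares over clusters and noise
returns its frame share of the pool exactly, so three equal-length
trajectories each carry 33.3%. Cluster representatives are medoids in the
original frame metric with lowest-index tie-breaks.

# Synthetic generator

`build_ensemble()` samples a Ramachandran basin per frame — helix
(−60°, −45°), PPII (−75°, 145°), extended (−135°, 135°) — adds Gaussian
angular jitter (default 8°), and builds Cartesian coordinates by
natural-extension-of-reference-frame placement with ideal bond geometry
and trans peptide bonds, for a reduced topology (backbone N, HN, CA, HA,
C, O plus a CB pseudo side chain carrying the residue's remaining mass and
two geminal HB protons whose separation is pinned at the 1.78 Å
calibration reference). Whole-frame basin sampling is the default rather
than per-residue-independent sampling: with independent residues the
minimum-run rule would systematically depress recovered helix populations
below the planted mixture weight, breaking parameter-recovery tests for a
reason that has nothing to do with the analysis code. Per-residue weight
matrices remain available for run-structure fixtures. An optional harmonic
end-to-end bias is applied by importance resampling.

`forward_noe()` emits V = scale·⟨r⁻⁶⟩ per proton pair with optional
log-normal noise, keeps the geminal reference pair so calibration is
self-contained, and carries the planted effective distance as ground
truth. `planted_cluster_pool()` builds k-state trajectory pools (states =
whole-chain basin patterns; angular jitter 120°/separation) with
per-trajectory state mixtures, e.g. a state private to one trajectory.

What the generator does *not* emulate: force-field energetics, sterics
(beyond ideal geometry), solvent (TFE) effects, side chains beyond Cβ, and
kinetic correlation between frames. Passing tests therefore demonstrate
the correctness of the analysis chain on data with known truth, not the
reproduction of the published enhanced-sampling trajectory observables
(those trajectories are not deposited; their Rg means, restraint counts
and specific two-cluster structure are out of reach at desk scale and are
replaced by the property suite in `tests/testthat/test-acceptance.R`).

# Problem sizes and numerical choices

The test suite uses ensembles of 1–2000 frames and pooled clustering
problems up to 3 × 200 frames; the acceptance script clusters 3 × 500
frames (about half a minute). t-SNE runs 400 gradient iterations with
early exaggeration 12 for 100 iterations, learning rate 200 and momentum
0.5 → 0.8. Medoid ties and class-boundary ties break deterministically
(lowest index; inclusive upper edges). Degenerate inputs error early:
empty sequences, non-positive volumes or concentrations, windows longer
than the peptide, discards that would drop every frame, single-frame
similarity matrices, all-noise medoid requests.

# Known limitations

- The biotinyl-PEG2 cap mass and the PTM random-coil corrections are
  back-derived/placeholder values, clearly flagged and swappable.
- The dihedral secondary-structure rule is not DSSP; absolute populations
  from real trajectories will differ near window edges.
- Exact t-SNE is O(n²); pools beyond ~5000 frames need subsampling.
- The integer charge model is meaningless near a group's pKa; it is meant
  for qualitative net-charge comparisons at neutral pH.
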