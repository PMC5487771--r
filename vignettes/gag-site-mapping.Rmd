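---
title: "Site-mapping and ensemble ranking of protein-GAG complexes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-mapping and ensemble ranking of protein-GAG complexes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagmap)
```

This vignette records the models, conventions and numerical choices behind
`gagmap`, in the order data flows through the package: structures in,
hydrogen bonds and energies, site-maps, pose geometry and clustering, and
finally ligand ranking. Units are Angstrom, kcal/mol, elementary charges and
degrees throughout, matching the force-field ecosystem the input numbers
come from.

## Structures and glycan annotation

A `gag_ensemble` is a fixed topology plus ordered coordinate frames, read
from multi-model PDB (one frame per MODEL record; `bio3d` does the parsing
and writing). Residues are partitioned into protein and glycan by residue
name at parse time, and source PDB numbering is preserved so protein
residues keep the labels practitioners know them by. Glycan rings
additionally get a 1-based index from the non-reducing end, assigned by
`annotate_glycan()` from a sulfation-pattern string (`GlcNS6S-IdoA2S-...`,
non-reducing to reducing); ring indices are what maps of glycans of
different lengths are aligned on. Covalently bonded hydrogens are inferred
once, from the first frame, as any H within 1.2 Å of its nearest heavy atom
— explicit hydrogens are required for the angle part of the hydrogen-bond
criterion.

`subsample_tail(ensemble, tail_frames, count)` implements the common
post-processing convention of analysing frames evenly distributed over the
final stretch of a trajectory. "Evenly distributed" does not by itself fix
whether the window endpoints are included; this package includes both
endpoints whenever `count >= 2` (indices `round(seq(0, tail - 1,
length.out = count))`, R's round-half-even), which is one defensible
reading, stated here rather than asserted as universal.

## Hydrogen bonds

A donor is an N or O heavy atom with at least one bonded hydrogen; an
acceptor is any N or O heavy atom (sulfate and carboxylate oxygens
included); an atom may be both. A donor-acceptor pair in different residues
is bonded in a frame when the heavy-atom distance is at most
`heavy_distance_cutoff` (default 3.0 Å) *and* some bonded hydrogen makes a
D-H···A angle of at least `dha_angle_cutoff` (default 135°). Both
comparisons are inclusive (`<=`, `>=`); whether a published "cutoff of 135°"
means `>=` or `>` is rarely stated, and the inclusive reading is adopted
and documented. Multiple hydrogens on one donor count once per frame.
Occupancy is the fraction of frames in which the atom pair is bonded.

Two deliberate conventions:

* **Residue-pair statistic = max over atom pairs.** Site-map cells need one
  number per (residue, ring); the maximum avoids counting one physical
  contact several times through alternative hydrogens or symmetric oxygens.
  Atom-level tables remain available upstream (`select_top_bonds()` keeps
  the k most frequent bonds with deterministic ties: donor residue number,
  acceptor residue number, atom names).
* **Distance-only fallback.** Crystal structures often lack hydrogens.
  With `distance_only = TRUE` the angle test is skipped, donor direction
  becomes unknowable, so each unordered N/O pair is reported once; the
  output metadata carries a warning flag. By default the maps consider only
  intermolecular (protein-glycan) pairs, which is what the protein x ring
  map axes can represent.

Detection is validated against an exhaustive O(N²) search over all pairs on
random systems, and occupancy is checked to be monotone under tightening
either cutoff and invariant under rigid-body motion.

## Pairwise energies

The primary energy path *ingests* per-residue pairwise decompositions
computed by an external solver (MMPBSA-style CSV, parsed by column names,
or the package's canonical TSV). The total electrostatic component is
always recomputed as the sum of the in-vacuo and reaction-field (polar
solvation) parts, the convention in which such decompositions are reported.

The package also contains a small internal pairwise engine,
`residue_pair_decomposition()`. It is a self-contained source of physically
shaped tables for testing the downstream mathematics, not a solvation
solver: Lennard-Jones 12-6 with Lorentz-Berthelot combining
(rmin/2 + epsilon convention), vacuum Coulomb
`k q1 q2 / (eps_in r)` with `k = 332.0636` kcal·Å/(mol·e²), and a
Generalized-Born-style screened reaction field
`-k (1/eps_in - 1/eps_solv) q1 q2 / f_GB`,
`f_GB = sqrt(r² + R1 R2 exp(-r²/(4 R1 R2)))` with *supplied* per-atom Born
radii. Defaults `eps_in = 1`, `eps_solv = 78.5`. There is no distance
cutoff, no nonpolar solvation term and no radius calculation. Because cells
partition atom pairs exactly, the component-wise sum over all (residue,
ring) cells must equal the directly computed total intermolecular energy;
this conservation identity is asserted to 1e-8 relative in the tests, and
the reaction field is checked to vanish as `eps_solv -> eps_in`.

## Site-maps

`build_sitemap()` assembles three channels over (protein residue, ring):
H-bond occupancy, and the favorable magnitudes `max(0, -E)` of the
electrostatic and van der Waals cells. Clipping positive (unfavorable)
energies to zero makes the energy channels comparable to occupancies, which
are non-negative by construction; the number of clipped cells is kept in
the map metadata and the signed tables remain available upstream.

Normalisation: `per_ring` divides each ring column by its absolute sum
(all-zero columns are left unchanged and flagged), `global` divides a
channel by its grand absolute sum. The per-ring denominator is this
package's explicit choice of normalisation; published map figures rarely
write the formula out. Both modes are idempotent, and per-ring
normalisation plus alignment on ring index from the non-reducing end is the
prescribed way to compare glycans of different lengths.

Aggregation over structures or poses is a per-channel weighted sum followed
by global normalisation (so aggregates are scale-free and
permutation-invariant in the input order). Comparison uses cell-wise
signed differences (with a top-quantile summary that localises, e.g., the
loss of one sulfate's contacts to its ring column) and correlation over
flattened cells — Pearson as the headline, Spearman available; zero-variance
channels yield `NA` with a reason rather than an error.

## Pose geometry and clustering

`pairwise_rmsd()` is the ordered-atom RMSD, by default *without*
superposition, since absolute placement is the signal in docking solutions;
least-squares fitting is available by flag. `rmsatd()` pairs spatially
close atoms of the same chemical element by optimal assignment (a Hungarian
solver on squared distances, per element) and takes the RMS over matched
pairs; greedy matching would be order-dependent, which is why the optimal
assignment is used, and small cases are validated against exhaustive
enumeration of all same-type pairings. Element (not force-field atom type)
is the type notion, because force-field types are unavailable at parse
time. Unequal element counts exclude the excess atoms and report them.

Orientation of a pose is the angle between its ring-1-to-ring-dp centroid
axis and a reference axis: parallel at <= 45°, antiparallel at >= 135°,
perpendicular between — symmetric tertiles about 90°, configurable, since
published orientation labels rarely come with their thresholds. Bound-pose
filtering keeps poses with at least one sugar atom within the cutoff
(default 10 Å) of an anchor point, reading "sugar residue within 10 Å" as a
residue-to-point minimum over its atoms.

DBSCAN runs on a precomputed distance matrix. The neighbourhood *includes
the query point itself*, so `minpoints = 2` means "at least one other point
within epsilon"; implementations differ on this, and published
epsilon/minpoints values are only meaningful under a fixed convention, so
it is stated. Border points reachable from several clusters go to the
first core cluster that reaches them in a deterministic ascending-index
scan. The test oracle is an independent formulation — connected components
of the epsilon-graph over core points, with the same border policy — so the
two implementations check each other. Representatives are medoids
(minimum summed in-cluster distance, ties to the lowest index).
`cluster_loop_conformations()` composes these pieces: heavy atoms of the
given loop residues, pairwise least-squares-fitted RMSD between frames
(each frame pair superposed on the loop atoms), DBSCAN, and the medoids of
the most populated clusters — the standard route to representative receptor
conformations for ensemble docking. Whether loop RMSD should use heavy
atoms only, and pairwise versus common-reference fitting, are judgement
calls; heavy atoms and pairwise fitting are used here.

## Ranking from free-energy distributions

`rank_by_best()` is the classical best-scored-value ranking (minimum ΔG,
ties by label). `rank_occurrence()` ranks within each grouping and counts
how often each ligand lands in each position; `consensus_ranking()` orders
by mean occupied rank (ties: rank-1 counts, then label). Pairwise
comparisons use two-sided Welch t-tests: nothing guarantees
variance homogeneity across docking-score distributions, so the
unequal-variance form is the safe default. No multiple-testing correction
is applied by default (raw p < 0.05 per pair, as such analyses are usually
reported); Holm is available.

`bootstrap_groupings()` draws, by default, *one* value per ligand per
grouping, with replacement. This default deserves its analysis. If each
grouping instead held a large resample and were ranked by its best value,
the per-grouping statistic would be an extreme order statistic; for Normal
samples of size n its ordering noise has scale ~ sigma / sqrt(2 log n) —
about 3.3 kcal/mol at sigma = 10, n = 100 — against a 5 kcal/mol spacing of
adjacent means, and since all groupings share the one observed dataset, no
amount of consensus can average that error away: exact five-ligand recovery
would plateau near coin-flip rates for the adjacent pairs. With one draw
per grouping, the consensus mean rank instead estimates the stochastic
ordering of the whole distributions, whose error scales like the standard
error of the mean (sigma / sqrt(n) = 1 kcal/mol here), and recovery of the
planted order becomes reliable. This is the package's quantitative
restatement of why whole-ensemble scoring outperforms best-pose scoring
for multipose binders. Resampling indices depend only on the RNG state,
never on the values, so all ranking and test decisions are exactly
invariant under adding a constant to every ΔG.

## The synthetic generators

The generators emulate the *statistical structure* of ensemble-modelling
outputs, not their physics:

* `gen_toy_complex_ensemble()` builds protein residues as small rigid
  fragments (N-H donor, carbonyl acceptor, charged carbon) in a row, and
  rings as fragments (anomeric carbon, ring oxygen, hydroxyl, a sulfate on
  sulfated rings) in a parallel row. Planted H-bond pairs get a dedicated
  ring oxygen that toggles between a geometry inside the 3.0 Å / 135°
  window (2.85 Å, near-linear) and one far outside (6 Å); per-frame states
  are independent Bernoulli draws at the target occupancy by default
  (matching a percentage-of-frames statistic), with `exact` deterministic
  toggling and a `markov` time-correlated mode for stress tests. Planted
  hot pairs get a ±1 e charge pair at ~3.6 Å, which dominates the
  screened electrostatics of the small background charges. Geometry is
  checked for < 0.8 Å clashes. The fragments exercise the detectors'
  definitions; they do not fold, pack, or carry realistic charge
  distributions, so passing tests demonstrate correctness of the
  *analysis*, not realism of any force field.
* `gen_pose_set()` samples bound poses as rigid Gaussian translations
  (default SD 0.5 Å) of a common template around axis-aligned centers
  whose radius guarantees the requested minimum separation (default 20 Å),
  oriented toward the anchor; the unbound fraction (default 0.3) is
  scattered far outside the binding cutoff at mutually distant positions.
  True labels and bound flags are returned with the data — tests read the
  truth, never re-infer it.
* `gen_decomp_fixture()` plants 5 hot cells at −8 kcal/mol against
  favorable-only half-normal background noise (SD 1 kcal/mol), splits
  totals 50/50 into vdW and electrostatics (vacuum 1.5x total,
  reaction field −0.5x — the usual screening structure), and attaches hot
  H-bond fractions ~0.9 against ~|N(0, 0.03)| background, so one table
  exercises all three channels.
* `gen_deltag_samples()` draws Normal ΔG values at planted means spaced
  5 kcal/mol (−60 ... −40), SD 10, n = 100 per ligand — the scale of ~100
  docking solutions per ligand.

Every generator is deterministic given `synth_spec(seed = ...)` (the
caller's RNG state is saved and restored) and returns its ground truth
alongside the data.

## Validation thresholds and problem sizes

The acceptance suite fixes its thresholds from the constructions above and
from calibration simulations run before the thresholds were frozen:
exact agreement with the exhaustive H-bond search on 100 random frames;
energy conservation to 1e-8 relative on 50 random toy complexes; RMSatd
equal to the exhaustive pairing minimum on 200 fixtures with up to 6 atoms
per element; DBSCAN label agreement with the graph-components formulation
across 20 parameter settings on 200 points; planted top-5 recovery in at
least 95 of 100 seeds and split-half aggregate correlation above 0.8 for
site-maps; planted-order recovery in at least 90% of 200 ranking
replicates with the extreme pair significant in all of them. These sizes
keep the default test run fast while leaving the checks statistically
meaningful; `scripts/acceptance.R` recomputes all of them from scratch at
any seed.

## Limitations

* The internal energy engine is a stand-in with supplied Born radii; it is
  not a GB/PB solver, computes no nonpolar solvation or entropy, and its
  absolute energies should never be compared with a production
  decomposition — only its *structure* (component split, conservation) is
  meaningful.
* Site-maps inherit whatever sampling bias the input ensemble has; the
  package aggregates and normalises, it does not reweight.
* The multi-model PDB reader assumes identical atom ordering across
  models (violations are a named hard error, not repaired).
* RMSatd with unequal element counts silently analyses the matchable
  subset (reported in an attribute); interpret it as a lower-bound-style
  similarity in that case.
* Water-mediated hydrogen bonds and energy-based H-bond definitions are out
  of scope; the geometric criteria are the whole definition.
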