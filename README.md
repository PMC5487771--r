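# gagmap

Site-mapping and ensemble analysis of protein–glycosaminoglycan recognition.

## The problem

Glycosaminoglycans (GAGs) such as heparin are long, flexible, densely
sulfated polysaccharides. Their protein complexes are held together by
shallow, highly charged interfaces, and recognition is typically *multipose*:
an ensemble of co-existing ligand placements rather than one dominant bound
structure. Single best-scored docking poses are therefore poor summaries of
protein–GAG binding; what is informative is the statistics of interactions
accumulated over a structural ensemble — MD frames, docking solutions, or
crystal structures of related oligosaccharides.

`gagmap` is for structural bioinformaticians analysing such ensembles. It
takes multi-model PDB files (and externally computed per-residue pairwise
energy decompositions) and turns them into quantitative, comparable
interaction maps and rankings.

## What it computes

**Site-maps.** For a complex of a protein P and a glycan of `dp` sugar rings
(indexed 1..dp from the non-reducing end), a site-map is a set of three
matrices over (protein residue *i*, sugar ring *j*):

* `hbond[i, j]` — the hydrogen-bond occupancy: the fraction of frames in
  which residues *i* and *j* share a donor–acceptor pair with heavy-atom
  distance ≤ 3.0 Å and D–H···A angle ≥ 135° (per-residue value = max over the
  pair's atom pairs);
* `ele[i, j]` = max(0, −E_ele(i, j)) and `vdw[i, j]` = max(0, −E_vdw(i, j)) —
  the favorable magnitudes of the pairwise electrostatic and van der Waals
  interaction energies (kcal/mol), where the electrostatic term is the sum of
  the in-vacuo Coulomb and reaction-field (polar solvation) components.

Maps are normalised per ring (each ring column sums to 1 in absolute value,
making glycans of different lengths comparable) or globally, aggregated over
structures or poses, differenced, and correlated (Pearson, with Spearman
available).

**Pose analysis.** Ordered RMSD and RMSatd — an RMSD that pairs up spatially
close atoms of the same element by optimal assignment instead of relying on
atom order, appropriate for near-symmetric GAG chains; parallel /
antiparallel / perpendicular orientation classes relative to a reference
axis; a bound-pose filter (≥ 1 sugar atom within 10 Å of an anchor point);
DBSCAN clustering of distance matrices with medoid representatives, including
clustering of binding-loop conformations to extract representative receptor
structures for ensemble docking.

**Ensemble ranking.** Given per-ligand distributions of binding free
energies (kcal/mol, more negative = stronger), the package ranks by best
value, tabulates rank occurrences across groupings (e.g. receptor
conformations or bootstrap resamples), forms a consensus ranking by mean
occupied rank, and tests all ligand pairs with two-sided Welch t-tests.

**Synthetic data.** Every analysis has a paired generator
(`gen_toy_complex_ensemble`, `gen_pose_set`, `gen_decomp_fixture`,
`gen_deltag_samples`) that produces data with planted, returned ground truth:
H-bond occupancies, hot residue–ring energy pairs, pose clusters with a
bound/unbound mixture, and a planted affinity order. These drive the test
suite and make every claim checkable.

## Worked example

```r
library(gagmap)

spec <- synth_spec(seed = 42)        # planted occupancies 0.9/0.5/0.1,
toy  <- gen_toy_complex_ensemble(spec)  # 5 hot pairs, dp6 heparin pattern
toy$ensemble
#> Structural ensemble: 88 atoms, 100 frame(s)
#>   residues: glycan=6, protein=8

occ <- occupancy_table(toy$ensemble)
head(as.data.frame(occ), 3)
#>   donor_res donor_atom acceptor_res acceptor_atom fraction
#> 1   A:2:TOY          N    B:101:SGN           OP1     0.84
#> 2   A:4:TOY          N    B:103:SGN           OP2     0.44
#> 3   A:6:TOY          N    B:105:SGN           OP3     0.12
```

The detected occupancies are the realised per-frame Bernoulli draws of the
planted targets (0.9, 0.5, 0.1). Energies and the three-channel map:

```r
dec <- residue_pair_decomposition(toy$ensemble, toy$annotation)
sm  <- normalize_sitemap(build_sitemap(dec, occ, toy$annotation), "per_ring")
sm
#> Site-map: 8 protein residues x 6 rings; normalization: per_ring ; 1 source(s)
#>   clipped unfavorable cells: ele = 12 , vdw = 8
```

The top electrostatic cells are exactly the planted salt-bridge pairs
(residues 1–5 against rings 1–5), e.g. `A:1:TOY`–ring 1 carrying 0.75 of
ring 1's electrostatic weight. Ranking five synthetic ligands whose planted
mean ΔG values are −60, −55, −50, −45, −40 kcal/mol (SD 10, n = 100 each):

```r
dg <- gen_deltag_samples(spec)
set.seed(1)
rt <- rank_occurrence(bootstrap_groupings(dg$samples, 100))
rt
#>    rank1 rank2 rank3 rank4 rank5
#> L1    49    25    16     6     4
#> L2    25    33    28     8     6
#> L3    14    27    28    24     7
#> L4     7     9    15    42    27
#> L5     5     6    13    20    56
consensus_ranking(rt)
#> [1] "L1" "L2" "L3" "L4" "L5"
```

The consensus over the whole distributions recovers the planted order even
though no single grouping ranks all five correctly — the multipose point in
miniature. `welch_ttest_matrix(dg$samples)` marks all ten pairs significant
here, with the extreme pair at p ≈ 1e-25.

## Command line

A thin CLI over the same functions lives at `inst/cli/gagmap.R`
(`synth`, `hbonds`, `decomp`, `sitemap`, `rank`); the end-to-end pipeline

```sh
gagmap.R synth --preset sitemap --seed 11 --out work/
gagmap.R hbonds  --pdb work/ensemble.pdb --config work/gagmap.conf --out work/occupancy.tsv
gagmap.R decomp  --engine internal --pdb work/ensemble.pdb --config work/gagmap.conf \
                 --params work/params.tsv --out work/energies.tsv
gagmap.R sitemap --energies work/energies.tsv --hbonds work/occupancy.tsv \
                 --pdb work/ensemble.pdb --config work/gagmap.conf --out work/sitemap.tsv
```

runs from synthetic structures to a normalised site-map TSV with no manual
steps.

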