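---
title: "Structural context for point mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural context for point mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinmut)
```

## The problem

A point substitution in a protein is easy to describe and hard to judge.
Whether `Ile195Thr` in the p53 core domain destabilizes the fold depends on
where residue 195 sits: how buried it is, what it touches, how central it is
in the residue contact network, and how strictly the family of related
structures conserves those features at that position. `rinmut` computes
exactly this per-position structural context, in batch, for a wild-type
chain, a set of similar structures (the *family*), and a mutant sequence.

The pipeline has four legs:

1. **Interaction networks.** Interatomic contacts are detected with a 3-D
   Delaunay triangulation — a cutoff-free "natural neighbor" definition
   that automatically discards *occluded* pairs (a third atom between two
   atoms breaks their empty-circumsphere property, hence their edge).
   Contacts are then classified by atom types and distance windows into six
   non-covalent interaction kinds and projected to a residue-level graph.
2. **Network centralities.** Degree, betweenness and closeness of each
   residue in the interaction graph.
3. **Solvent accessibility.** Lee–Richards accessible surface areas per
   residue, absolute and relative to Ala-X-Ala references, in the ten
   Naccess-style categories.
4. **Family alignment and column statistics.** A structure-based alignment
   of every family member against the wild type defines a column coordinate
   system (columns = wild-type positions); per column the package reports
   conservation, sequence-logo information, mean/spread of every structural
   property, and the fraction of chains establishing each interaction kind.

A mutation is then assessed in its column: conservativeness under a
physicochemical color scheme, the column's conservation, its burial, and
whether the position looks *critical* (buried, invariant, anchored by
conserved hydrophobic packing).

## Interaction model

Atoms carry a subset of seven physicochemical labels — positive, negative,
hydrogen-bond donor, hydrogen-bond acceptor, aromatic, hydrophobic,
cysteine — assigned from a packaged residue/atom table
(`load_typing_table()`). The table follows standard pharmacophore
conventions: Arg/Lys/His side-chain nitrogens are positive donors, Asp/Glu
carboxylate oxygens negative acceptors, backbone N a donor (except proline)
and backbone O an acceptor, hydroxyl oxygens donor+acceptor, the ring atoms
of Phe/Tyr/Trp/His aromatic, aliphatic side-chain carbons not bonded to
N/O/S hydrophobic, and Cys SG the cysteine type. It is data, not code, and
can be replaced per run.

An atom pair that is (a) a Delaunay edge, (b) from two different residues,
and (c) type- and distance-compatible with at least one criterion becomes
an interaction edge. The six distance windows (angstroms, inclusive) are:

| kind | atom types | min | max |
|---|---|---|---|
| aromatic stacking | two aromatic atoms | 1.5 | 3.5 |
| disulfide bridge | two cysteines | 1.4 | 2.3 |
| hydrogen bond | an acceptor and a donor | 2.0 | 3.0 |
| hydrophobic | two hydrophobic atoms | 2.0 | 3.8 |
| repulsive (charged repulsive) | same charge | 2.0 | 6.0 |
| salt bridge (charged attractive) | opposite charge | 2.0 | 6.0 |

Two consequences worth noting. Covalent peptide-bond C–N pairs
(about 1.33 angstroms) fall below every window, so they can never appear as
interactions. A covalent disulfide (S–S about 2.05 angstroms) *is* inside
the disulfide window — the model reports it as the disulfide-bridge class,
which is the intended reading of that class.

One filter is our own interpretation: backbone–backbone pairs of
*sequence-adjacent* residues are excluded by default, because the rigid
peptide-unit geometry places O(i) and N(i+1) about 2.25 angstroms apart and
would otherwise register a hydrogen bond between every neighboring residue
pair, drowning the signal. `keep_adjacent_backbone = TRUE` (or
`--keep-adjacent-backbone`) restores them.

Hydrogens never participate: the distance windows are heavy-atom criteria,
and all hydrogens are removed on reading. Angle terms are deliberately out
of scope — classification uses types and distances only.

## Centralities

The residue graph (all interaction kinds collapsed to unweighted edges)
feeds three centralities, computed with igraph:

* degree — incident edge count;
* betweenness — unnormalized shortest-path betweenness, endpoints
  excluded, contributions split over equal-length shortest paths;
* closeness — the reciprocal of the *summed* shortest-path distance to all
  reachable vertices, so a connected n-node graph bounds it by 1/(n−1).

The closeness convention deserves a note: descriptions of this quantity as
a "mean distance" would put values near 10 for a 200-residue protein,
whereas reported per-residue values in this setting are of order 10⁻³–10⁻⁴,
which is consistent only with the reciprocal-of-total-distance convention
(also the common library default). We implement 1/Σd. On disconnected
graphs each component is treated separately and isolated residues report 0.

## Solvent accessibility

`sasa_atoms()` implements the Lee–Richards construction directly: every
atom is inflated by the probe radius (default 1.4 angstroms, water), and
its accessible area is integrated over z-slices. In a slice the atom
contributes `R · dz · (exposed arc angle)`, where the exposed arc is the
part of its slice circle not covered by any intersecting neighbor circle.
Each atom uses its own slice grid: the target spacing (default 0.05
angstroms, the conventional default) is rescaled so an integral number of
slabs covers the sphere — an isolated atom then integrates *exactly* to
4πR², so discretization error enters only through occlusion boundaries.
Halving the slice thickness changes fixture totals by under 0.2%.

Radii are a packaged Chothia-style united-atom table by element (C 1.87,
N 1.65, O 1.40, S 1.85 angstroms). Categories follow the Naccess
conventions: main chain = {N, CA, C, O, OXT} (for glycine, CA stays main
chain and the side-chain area is zero — its relative side-chain value is
reported as missing rather than 0/0); polar = N/O/S atoms, non-polar =
carbons. Two exact decompositions hold and are tested: main + side = all
atoms, and polar + non-polar = all atoms.

Relative accessibility divides by the same residue type's area in an
extended Ala-X-Ala tripeptide. The reference table is *generated by this
package* (`build_reference_table()`): tripeptides are built by the internal
peptide builder at φ/ψ = −120°/+120° from packaged ideal residue
geometries, and regenerating the shipped table with default parameters
reproduces it to the table's printed precision (1e-6, tested). This keeps the package self-contained, at the price that relative
values are convention-close to, not bit-identical with, any particular
Naccess reference file. Extended conformations of real chains can exceed
100%.

## Structure-based family alignment

Pairwise alignment of a member against the wild type is an iterative
seed-superpose-re-pair scheme:

1. seed residue pairs from a global sequence alignment (BLOSUM62, gap
   open 10, extend 0.5);
2. superpose the member onto the wild type with a Kabsch fit on paired CA
   atoms (proper rotation, determinant +1);
3. re-pair as mutually nearest CA pairs within a cutoff (default 5.0
   angstroms), kept monotonic — no crossings — by a longest-increasing-
   subsequence filter;
4. iterate until the pair set is stable or 20 iterations.

This is not a reimplementation of any published structural aligner; it is a
deterministic, self-contained scheme adequate for its single role here —
defining which member residue sits in which wild-type column. For rigid
copies it returns the identity correspondence at rmsd < 1e-6; at 0.3-
angstrom coordinate noise it recovers ≥ 95% of planted correspondences
(both tested). Remote homologs with large conformational changes will align
less completely than a flexible aligner would manage; such columns simply
show gaps.

Columns are exactly the wild-type positions: member insertions relative to
the wild type carry no column semantics and are dropped (logged). The
mutant row is placed by identity when its length matches, otherwise by the
same global sequence alignment.

## Column statistics and mutation assessment

Per column the package reports: letter frequencies and maximum conservation
over non-gap rows (gap fraction separately); sequence-logo information
`log2(20) − H` in bits with letter heights `freq × bits` (no small-sample
correction — intended family sizes make it negligible, and the convention
is configurable only by post-processing); mean and *population* standard
deviation (divide by n; the convention is stated here precisely because
both conventions are common) of each structural property over the rows
holding a residue there; and, per interaction kind, the percentage of
non-gap rows whose residue establishes that kind in its own structure.

Conservativeness uses one of three schemes: CINEMA (6 groups), CLUSTAL (4
groups covering 14 letters — the remaining six letters are reported
`unclassified`), LESK (5 groups). A substitution is conservative iff both
letters share a group.

ΔΔG values are accepted as an optional input table (kcal/mol, positive =
destabilizing) and only binned, never computed: ≤ −1.5 highly stabilizing,
(−1.5, −0.5] stabilizing, (−0.5, 0.5) neutral, [0.5, 1.5) destabilizing,
≥ 1.5 highly destabilizing, missing = "not calculated". The edges are
defaults chosen at round half-kcal values and are configurable; they are
presentation bins, not a stability model.

Candidate *critical positions* are flagged where the all-atoms relative
accessibility is low and conserved (mean ≤ 10%, σ ≤ 10%) and hydrophobic
interactions are highly conserved (≥ 80% of chains) — the buried,
invariant, hydrophobically anchored pattern that damaging substitutions
tend to hit. The thresholds are screening defaults distilled from worked
examples, deliberately loose, and configurable; the flag is a hint for
inspection, never a pathogenicity verdict (no claim of prediction is made
anywhere in this package).

Row ordering for display groups similar sequences: rows are encoded as
per-column group-membership indicators under the active color scheme — so
clustering mirrors what the coloring shows — reduced by principal
components when the dimension exceeds the row count (directions with
near-zero variance are dropped), and fitted with a diagonal-covariance
Gaussian mixture, k = 1..min(8, rows/3 + 1) chosen by BIC. A deterministic
1e-6 feature jitter regularizes duplicated rows, and a fixed seed makes the
ordering reproducible run-to-run.

## The synthetic-data generator

All tests and the acceptance script run on structures generated by the
package itself:

* `make_fixture()` places named atoms of named residues at exact
  coordinates (validated against packaged residue geometry), so each
  interaction criterion can be planted at any chosen distance;
* `fixture_pair(kind, d)` plants one interaction of each kind with minimal
  residues (key atom + backbone stub) so the key pair is the only pair able
  to satisfy the criterion — used to probe each window edge at
  d_min − ε, d_min, mid-window, d_max, d_max + ε;
* `fixture_blocked_pair()` plants an in-window donor/acceptor pair with a
  blocker exactly on the segment between them: every sphere through the
  pair contains the blocker, so occlusion must remove the contact;
* `build_peptide()` builds chains with ideal backbone geometry at chosen
  φ/ψ (extended for reference tripeptides, helical for contact-rich test
  chains) and grafts ideal side-chain geometry;
* `transform_structure()` / `perturb_structure()` produce rigid and noised
  family members with planted correspondences.

What the generator does *not* emulate: crystallographic disorder, missing
loops, alternate side-chain rotamers, ligands and waters, or genuine
evolutionary divergence — family members are geometric copies, not
homologs. Passing tests therefore demonstrate the correctness of the
computations (against independent oracles: brute-force empty-circumsphere
enumeration, exhaustive shortest-path formulas, analytic sphere/cap areas,
point-sampling integration, exhaustive alignment enumeration), not the
biological calibration of thresholds on real families.

Problem sizes used by the default test run and acceptance script — chains
of 5–20 residues, families of 2–3 members, point clouds up to 30 atoms,
graphs up to 12 nodes (all graphs up to 5 nodes enumerated exhaustively) —
were chosen to keep every oracle exact and the full suite fast while
exercising every code path.

## Numerical choices and edge cases

* **Delaunay degeneracy.** The triangulation (Bowyer–Watson, long-double
  predicates) rejects exactly degenerate inputs (coplanar/cospherical
  beyond the guard) and retries once after a deterministic ±1e-3-angstrom
  jitter from a fixed-seed generator — reproducibility over silent
  perturbation. Fewer than 4 atoms is an error.
* **Altlocs** keep the highest occupancy, ties to the lexicographically
  smallest identifier. **Models**: first model only. **HETATM**: always
  dropped (waters, ligands, ions, and modified residues — the last with a
  warning). Nonstandard residues in ATOM records stay in the chain as `X`
  for alignment indexing but are untyped for contacts.
* **Alignment ties** delegate to the alignment library's deterministic
  traceback; the structural re-pairing breaks ties by sequence order
  through the LIS filter.
* **All-gap columns** report missing statistics rather than zeros; columns
  where no row has a property value report missing means.
* **Determinism.** Identical inputs and seed produce byte-identical TSV and
  JSON artifacts (the manifest's timestamp is the only exception), which is
  asserted by a test.

## Limitations

Single chains only (no complexes, no ligand-aware analysis); no
angle-dependent hydrogen-bond or stacking geometry; the atom-typing table
is a reconstruction of a standard convention, not a copy of any specific
published table; the structural aligner is intentionally rigid; ΔΔG is
never computed; and the critical-position flag is a screening heuristic
whose thresholds were not fitted to any dataset.
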