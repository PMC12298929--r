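---
title: "Pocket detection and ligandability mapping on protein-protein complexes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket detection and ligandability mapping on protein-protein complexes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketome)
```

## The problem

Protein-protein interactions (PPIs) that are selectively activated in
tumours are attractive but difficult drug targets: there is rarely a deep,
enclosed active site, and the druggable real estate has to be found on the
surfaces that mediate the interaction, next to them, or in clefts that only
exist in the bound complex. `pocketome` implements a grid-based pipeline
that, for a two-chain co-crystal structure, maps all three kinds of site:

* **interface pockets** -- cavities on one *detached* partner that enclose
  part of the other partner, candidate sites for orthosteric PPI
  modulators;
* **allosteric-like pockets** -- cavities on a detached partner away from
  the interaction zone, candidate anchor sites for degrader (PROTAC)
  chemistry that does not need to block the interface;
* **equilibrium pockets** -- cavities detected only on the intact complex
  and lined by residues of both partners, which exist by virtue of the
  bound state.

Around that core the package maps crystallographic-ligand occupancy from
superposed homologous structures (the operational definition of
*ligandability* used here), computes geometric/energetic pocket
descriptors, validates predicted pocket residues against known binding
residues with the Matthews correlation coefficient (MCC), and aggregates
per-cancer interaction networks with hub calling.

## Detection model

A structure is embedded in an axis-aligned grid (default spacing 0.8 Å,
padding 6 Å around the bounding box). Grid points inside the protein's van
der Waals volume are masked. Two scalar fields drive detection:

**Burial.** At each exterior voxel, 50 rays are cast along a fixed
Fibonacci-sphere direction set and the burial is the fraction of rays that
hit a protein atom within 12 Å. The direction set is deterministic, so
burial is exactly reproducible; the ray-sphere test is exact (a cell-list
Amanatides-Woo traversal only accelerates it). Deep cavities approach
burial 1, flat surfaces stay near 0.5, and open solvent tends to 0.

**Hydrophobic molecular interaction field (DRY).** Probe-protein energies
are computed with a surrogate interaction model: a 6-12 pair potential with
probe- and element-dependent well depths, plus, for the polar probes, a
flat polar bonus for matching protein atoms within hydrogen-bonding range
(3.5 Å). The DRY probe's attractive term applies only to carbon and
sulfur atoms, so its favourable (negative) regions are hydrophobic
patches. Five probes are exposed -- H (shape), DRY (hydrophobic), OH2
(water-like polar), O (acceptor), N1 (donor) -- with all well depths in
`probe_params()`. This is deliberately *not* a reimplementation of any
proprietary force field: the pipeline consumes thresholded fields, not
absolute energies, so every threshold is a configuration key stated on the
surrogate's kcal/mol scale. One water-like polar probe is exposed (named
OH2); no distinction between differently hybridised hydroxyl probes is
attempted.

**Seeds, smoothing, and cavity filling.** Seed voxels are exterior voxels
with burial ≥ 0.6 and DRY energy ≤ -0.2 kcal/mol. Seeds are grouped into
26-connected components and smoothed by a morphological opening (erosion
then dilation with a Euclidean ball, radius 1 voxel): isolated specks
vanish, one-voxel bridges split. Because the hydrophobic criterion
excludes the thin shell of grid points that sit too close to the wall
(where the repulsive core dominates), each smoothed cluster is finally
expanded to the whole buried cavity that contains it -- a geodesic
reconstruction within the mask of buried, non-interior voxels. The
reported pocket is therefore the cavity, seeded by its hydrophobic core.
Disabling `fill_buried` yields the raw smoothed clusters instead.
Pockets below 150 Å^3 (roughly the volume of a small drug-like ligand)
are discarded. Pocket ordering is deterministic: descending volume, ties
by smallest voxel index.

Defaults and their meaning:

| parameter | default | meaning |
|---|---|---|
| `spacing` | 0.8 Å | voxel edge; volume resolution ~0.5 Å^3 |
| `padding` | 6 Å | margin so fields decay before the box edge |
| `burial_rays` | 50 | fixed directions per voxel |
| `burial_min` | 0.6 | "sufficiently buried" (flat surface ≈ 0.5) |
| `dry_max` | -0.2 kcal/mol | "sufficiently hydrophobic" on the surrogate scale |
| `erosion/dilation radius` | 1 voxel | speck/bridge scale of the opening |
| `min_volume` | 150 Å^3 | drug-size filter |
| `contact_cutoff` | 4.0 Å | pocket-lining residue distance |

## Classification

Pockets from a detached partner are classified by the **partner
fraction**: the fraction of the partner's heavy-atom centers that fall
inside pocket voxels, evaluated in the complex frame. A pocket is
*interface* iff the fraction is strictly greater than 0 (threshold
configurable in `[0, 1)`), else *allosteric-like*. Atom-center counting
was chosen over volumetric intersection deliberately: it is exact,
order-independent, and directly checkable against constructed geometry; a
volumetric overlap would inherit every discretization choice of the grid.
Pockets from the complex are *equilibrium* iff their lining residues come
from both chains, else they are left unclassified. Homodimers are treated
as two partners distinguished by chain id. Multi-copy assemblies are not
reduced automatically: the caller must name the two partner chains.

## Ligand occupancy

Homologous structures are superposed onto the analysis frame by a
least-squares rigid fit (Kabsch, proper rotation enforced) over CA atoms
paired by chain/residue number. Alignments with RMSD above 3.0 Å
(inclusive boundary at 3.0) are discarded -- a poorly aligned homolog must
not teleport its ligands into the frame. From the retained homologs every
HETATM residue is harvested except cofactors, metals and crystallization
artifacts (configurable lists) and fragments under 6 heavy atoms (so lone
ions never count as ligands). A pocket is **ligand-bound** when the
fraction of a ligand's heavy atoms inside pocket voxels strictly exceeds
0.3; the atom-count reading ("30% of the ligand's atoms") is used rather
than volumetric intersection, for the same testability reasons as above.

## Descriptors

Six per-pocket descriptors are computed on the voxel set:

* **volume** = voxel count x spacing^3;
* **globularity** = surface area of the equal-volume sphere / measured
  boundary surface (1 for a sphere, < 1 for elongated shapes, capped at 1);
* **rugosity** = volume / boundary surface (Å); r/3 for an ideal sphere of
  radius r, h/6 for a single voxel of edge h. The volume-over-surface
  orientation of this ratio is kept as the package's convention;
* **hydrophobic volume**: pocket voxels with DRY < -0.5 kcal/mol;
* **hydrophilic volume**: pocket voxels with OH2 < -3.5 kcal/mol;
* **exposed to solvent**: boundary voxels at least 2.2 Å from the protein
  van der Waals surface, x spacing^2 (an area proxy; 0 for enclosed
  cavities);
* **buried volume**: volume x mean per-voxel buriedness from the same
  50-ray collision count; the low-buriedness subvolume is attached as an
  attribute.

**Boundary surface estimation.** A raw count of exposed voxel faces
overestimates the area of smooth surfaces by a factor that reaches 1.5 for
a sphere (the staircase effect), which would make "globularity = 1 for a
sphere" unattainable and break the rugosity closed forms. The package
therefore weights every exposed face by |n·e|, where n is the local
outward normal estimated from the occupancy in a 2.5-voxel neighbourhood
and e the face direction. This estimator is exact for axis-aligned flat
surfaces (a lone voxel still measures 6h^2, so the cube closed form h/6 is
exact) and asymptotically unbiased for smooth surfaces (the voxelized
r = 6 Å sphere at 0.5 Å spacing measures within a few percent of 4 pi
r^2). Marching-cubes smoothing was rejected to keep closed-form test
cases. Degenerate normals (isolated voxels) fall back to full face
weight.

For ligands, a reduced panel of seven interpretable 3D descriptors is
provided (molecular weight, polar and hydrophobic van der Waals volumes,
integy moment -- the distance from the center of mass to the centroid of
the hydrophilic atoms -- radius of gyration, and heavy-atom H-bond
acceptor/donor counts), together with a PCA helper (`descriptor_pca()`,
standardized columns, constant columns dropped with a warning). This panel
deliberately does not attempt to reproduce any proprietary
128-descriptor set; it spans the same axes (size, shape, polarity
balance) at interpretable resolution.

## Validation metric and networks

Residue-level validation uses the MCC over a binary confusion matrix on a
stated universe (by default all residues of the evaluated chain): +1 for a
perfect prediction, 0 for chance, -1 for full inversion; degenerate
margins are reported as a flagged 0. Observed binding residues are those
with any heavy atom within 5.0 Å of the binder.

Per-cancer networks have one node per protein and one undirected edge per
interaction; a protein is a **hub** when it has two or more distinct
partners. Homodimer self-loops count as one partner, so a protein whose
only interaction is with itself is not a hub. Nodes carry interface and
allosteric-like pocket counts; exports are GraphML plus Cytoscape-ready
edge/node CSVs, and every output table carries the configuration hash.

## The synthetic generator

All tests run offline on pseudo-proteins with analytically known ground
truth (`synthetic_spec()` and the `make_*` generators). They emulate:

* **cavity monomers** -- atom shells whose inner van der Waals surface lies
  exactly at the target cavity radius, enclosing a ball of volume
  (4/3) pi r^3 (or a half-open hemispherical pit of half that volume).
  The shell tessellation, not lattice deletion alone, is what gives
  analytic volume control;
* **interface dimers** -- a slab with a hemispherical pit on chain A and a
  helix-like chain B segment inserted into it (detached-A detection must
  call the pit an interface pocket, complex detection an equilibrium
  pocket);
* **flat dimers** -- two featureless slabs facing each other across a 7.5 Å
  gap, chosen so that the inter-slab groove is buried and tall enough to
  carry a hydrophobic core one opening-radius thick: pockets exist only on
  the complex, lined 50/50 by both chains. At 50 Å separation nothing is
  detected;
* **homolog ensembles** -- copies of a base monomer under random rigid
  motions (optionally with coordinate noise) carrying planted ligands with
  an exact number of atoms inside the base cavity, so recovered overlap
  fractions have integer/total ground truth.

Residues are poly-alanine-like (a few carbon atoms, first named CA), which
exercises all bookkeeping without pretending chemical realism. Default
coordinate noise is 0 so ground truth stays analytic; coordinates are
rounded to 0.001 Å at generation so structures survive a PDB round-trip
byte-exactly. All randomness flows through one seeded generator: identical
spec + seed gives byte-identical files.

What passing these tests shows -- and does not show. The synthetic shells
are carbon-only, so the DRY-seeded detector is maximally comfortable;
recovery of planted cavity volumes within 25% (in practice within ~10% for
200-1000 Å^3 cavities) demonstrates the geometry pipeline, not performance
on polar, irregular, partially disordered real binding sites. Real
structures also bring altloc/insertion-code noise, missing atoms and
heteroatom chemistry that the generators only touch through dedicated unit
fixtures.

## Numerical choices and degenerate inputs

* The burial direction set is fixed (Fibonacci sphere), so all ray-based
  quantities are deterministic and exactly reproducible across platforms.
* Energy sums use a hard 8 Å cutoff; voxels inside the protein carry an
  `Inf` sentinel and can never be seeds.
* Strict inequalities are used where a boundary decision has to be
  one-sided and documented: interface iff partner fraction > threshold;
  ligand-bound iff overlap > 0.3 (0.30 exactly is not bound); descriptor
  field thresholds count energies strictly below the cutoff. The RMSD
  filter keeps alignments with rmsd ≤ 3.0 (a quality gate is naturally
  inclusive at its boundary).
* altloc resolution keeps the highest-occupancy conformer, ties broken by
  altloc letter; cofactors are assigned at split time to the chain with
  the nearest heavy atom.
* Degenerate cases error loudly rather than guessing: empty structures,
  cavity radii too small to enclose a voxel, pockets with no lining
  residue at the stated cutoff, superpositions with fewer than 3 CA
  pairs, MCC sets outside the universe.
* The demo pipeline runs at 1.0 Å spacing on three small dimers to stay
  interactive; analyses default to 0.8 Å. Test-suite problem sizes
  (cavities of 200-1000 Å^3, grids of ~10^5 voxels, ensembles of 1-2
  homologs) were chosen so the full suite exercises every stage in a few
  minutes on one core.

## Known limitations

* The surrogate energy model ranks chemotypes qualitatively (hydrophobic
  vs polar); its absolute kcal/mol values are not comparable to any
  published force field, and electrostatics with solvent screening are out
  of scope.
* Pocket detection is single-conformer; transient pockets across an
  ensemble, alpha-sphere/Voronoi alternatives, and hot-spot energetics are
  not implemented.
* CA-number pairing for superposition assumes homologs share residue
  numbering (true within a UniProt entry's PDB depositions most of the
  time); no sequence alignment fallback is attempted.
* Assemblies with more than two relevant chains must be reduced to a
  two-chain complex by the caller; the package refuses to guess which
  copies form the biological pair.

## A worked example

```{r example, eval = FALSE}
cpx <- make_interface_dimer(synthetic_spec("interface_dimer",
                                           cavity_radius = 5, seed = 1))
res <- analyse_complex(cpx, pipeline_config())
summary(res$detached_A)  # one interface pocket, partner fraction > 0
summary(res$complex)     # the same site as an equilibrium pocket
```

The README shows the printed output of this run; `run_demo()` wires the
same analysis into the full table-driven pipeline with network export.
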