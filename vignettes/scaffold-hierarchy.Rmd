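---
title: "An eight-level scaffold hierarchy for compound library visualization"
author: "scaffoldmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An eight-level scaffold hierarchy for compound library visualization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldmap)
```

## The problem

Medicinal chemists think about compound collections in terms of scaffolds:
the ring systems and linkers left after functional groups are stripped away.
A single flat scaffold definition (such as the Bemis–Murcko framework) is too
fine-grained to survey a large library at a glance — a few hundred thousand
compounds already produce tens of thousands of distinct frameworks. What is
needed for visualization is a *hierarchy* of progressively coarser scaffold
definitions with a manageable branching factor at every level, so that any
node's children fit on one screen.

`scaffoldmap` implements such a hierarchy: a rooted tree with a virtual root
(level 0), eight scaffold levels (1–8), and molecules conceptually as leaves
(level 9). Every molecule maps to a sequence of exactly eight scaffolds, one
per level, and every scaffold has a unique parent one level up. A tree of
height 9 with constant branching factor 100 already spans $100^9 = 10^{18}$
leaves; to cover on the order of $10^8$ molecules the *average* branching
factor only needs to be $10^{8/9} \approx 7.7$, so the height of the
hierarchy is never the limiting factor.

## The eight levels

Going from the most concrete to the most abstract, with the transformation
that produces each level from the one below:

* **Level 8 — rings with linkers, stereo.** The molecular framework: the
  molecule after standardization (aromatization, charge neutralization,
  removal of explicit hydrogens, radicals and isotope labels) with all
  terminal atoms iteratively deleted. Stereo descriptors that survive the
  deletion are kept. Acyclic molecules yield the empty scaffold.
* **Level 7 — rings with linkers.** Level 8 with every stereo mark removed.
* **Level 6 — graph framework.** Every element becomes carbon and every bond
  single: only heavy-atom connectivity remains. The vertex count still
  equals the framework's atom count.
* **Level 5 — framework rings.** Linker *paths* are replaced by single
  edges: every degree-2 vertex that lies on no cycle is removed by edge
  merging. Branching linker atoms (degree ≥ 3) survive.
* **Level 4 — ring topology (Oprea scaffold).** The same edge-merging is
  applied to the remaining degree-2 vertices, except where the vertex's two
  neighbours are already adjacent (a triangle, where merging would destroy a
  cycle). The result is the minimum cycle topology of the framework: every
  isolated ring becomes a triangle, a fused pair becomes two triangles
  sharing an edge, a spiro pair two triangles sharing a vertex.
* **Level 3 — ring connectivity, extended.** Vertices stop being atoms: one
  vertex per CSSR ring of the level-4 graph. Rings sharing a graph edge
  (fused — rigid) are joined *strongly*, encoded as bond order 2; rings
  sharing only a vertex (spiro) or touching the same connected component of
  the linker-edge subgraph are joined *weakly* (order 1). Ring edges are
  excluded from the linker path search: in a linear three-ring fusion the
  terminal rings are *not* connected, because the only paths between them
  run through ring bonds.
* **Level 2 — ring connectivity.** The strong/weak distinction is dropped;
  only which rings touch remains.
* **Level 1 — ring count.** The number of vertices of the ring-connectivity
  scaffold, equal to the CSSR ring count of the framework. Acyclic molecules
  have ring count 0 and carry the shared empty-scaffold sentinel `-` at
  levels 2–8.

A worked example (keys abbreviated):

```{r chain-example, eval = FALSE}
m <- readMolecules(system.file("extdata", "drugs.smi",
                               package = "scaffoldmap"))$molecules[[4]]
scaffoldChain(m)   # hydrocortisone: L1 = "4", L3 = "4:1-3s,2-4s,3-4s", ...
```

## Ring perception: why CSSR

Levels 1–3 need a ring decomposition. The *smallest set of smallest rings*
(SSSR) is well known to be non-canonical: symmetric polycyclics admit many
equally valid SSSRs, so the decomposition depends on arbitrary tie-breaks.
We therefore use the *complete* set of smallest rings (CSSR): every ring
that is as small as any SSSR ring it could replace is kept. On the cube
graph (cubane) CSSR reports all 6 faces where SSSR keeps an arbitrary 5.

Our realization collects, for every edge on a cycle, all shortest cycles
through that edge (enumerated over BFS shortest paths). If the collected
set does not span the graph's cycle space — possible only on unusual cage
topologies — shortest fundamental cycles are added until it does; such
graphs are implementation-defined territory for every CSSR variant.

One genuine boundary case deserves a note: for symmetric multi-bridged
systems (three or more bridges of equal length between the same two
bridgeheads, e.g. bicyclo[2.2.2]octane) the CSSR of the *contracted*
level-4 topology has fewer rings than the CSSR of the framework — the
contraction turns three parallel length-2 paths into two triangles sharing
an edge. The ring count reported at level 1 is defined on the contracted
topology (the construction order of the hierarchy), and the package's
cycle-count conservation property is stated for frameworks without this
symmetry. The bridged bicyclic in the fixture vocabulary is norbornane
(bicyclo[2.2.1]heptane), for which conservation holds exactly.

## Canonical keys

Hierarchy nodes must be identity-stable across input orderings, so every
scaffold serializes to a canonical string:

* Levels 8–7 are chemical graphs and use OpenBabel canonical SMILES (via
  ChemmineOB). Aromaticity is perceived by OpenBabel at canonicalization,
  so kekulized and aromatic inputs agree. Stereocenters whose defining
  substituent was deleted with the side chains are re-perceived and dropped
  rather than kept dangling.
* Levels 6–2 are abstract graphs whose vertices can exceed any chemical
  valence (a ring-connectivity vertex may touch arbitrarily many rings), so
  chemical line notations do not apply cleanly. They are encoded as a
  canonical edge list `"n:1-2s,1-3w,..."` derived from a BLISS canonical
  labeling (igraph). The strong/weak edge label is carried through
  canonicalization as a colored subdivision vertex, which reduces
  edge-labeled to plain vertex-colored canonicalization. The format is
  deterministic, permutation-invariant and parseable.
* Level 1 is the decimal ring count; level 0 the fixed sentinel `ROOT`; the
  empty scaffold is `-`.

Because keys parse back into graphs (`keyToGraph`), every level-k key is
computable from the level-(k+1) key alone (`parentKey`) — higher levels
never need the original molecule. The test suite verifies this
"functoriality" across the whole fixture vocabulary.

## Standardization choices

The charge neutralization rule is: anions not adjacent to a positively
charged atom are protonated, and cations that still carry a proton are
deprotonated, whenever the resulting valence is standard. This neutralizes
carboxylates, ammonium salts and zwitterions, while quaternary ammonium and
the internal charge pair of a nitro group are left intact (and reported
once per run). Disconnected structures are kept whole — multi-fragment
compounds are real and the hierarchy represents them (the two-disconnected-
rings topology is distinct from any connected pair).

## The background hierarchy and annotation

`buildHierarchy` inserts each molecule's chain into the tree, counting
frequencies; memory scales with distinct scaffolds, not molecules, and
duplicate molecules count multiply (frequencies are molecule counts).
Hierarchies merge additively (`mergeHierarchies`), so backgrounds can be
built in shards. Any SMILES/SDF library can serve as the background; no
reference database is hard-coded. The background persists as a CSV
(`level, key, parent_key, background_freq, child_count`); dataset
frequencies are never written to a background file, only to annotated
exports.

`annotateHierarchy` classifies a user set against a background: dataset
frequencies are filled in, and user scaffolds absent from the background are
added with background frequency 0 — in the enrichment color mode those are
maximally "enriched" by definition.

## Statistics

Three analyses mirror the hierarchy-design methodology: branching-factor
bins per level (1–100 / 101–400 / 401–1600 / >1600, from the capacities of
10×10, 20×20 and 40×40 display grids; scaffolds without children are not
binned), nearest-rank child-count percentiles per level (nearest-rank
because interpolation would fabricate unobserved counts; a single-node
level has all statistics equal), and top-k scaffold frequency with
cumulative coverage (ties broken lexicographically for determinism).

## Treemap layout

The squarified treemap algorithm lays out one node's children: cells are
added greedily to rows along the shorter side of the remaining rectangle,
closing a row when the next cell would worsen its worst aspect ratio. Areas
are exactly proportional to the chosen weights. Sizes default to background
frequency (the share of empirical chemical space); colors default to
dataset frequency — both switchable, with optional `log1p` damping for the
heavily skewed frequency distributions. Colors are min–max normalized
*across siblings* — a design choice between global and sibling-local
scaling that we resolve locally: it keeps every zoom level informative, at
the cost of colors not being comparable across frames. A constant color vector maps
to the gradient midpoint. Non-leaf cells are colored by their own node's
frequencies; how an interactive client might aggregate subtree colors is
left open. Rendering is a deterministic static SVG (one rectangle plus a
text depiction per cell, tooltips in `<title>`), with `--depth` nesting
sublayouts inset into their parent cells; the JSON export carries keys,
rectangles and values so any front end can rebuild and zoom the layout.

## The synthetic fixture generator

`generateFixtureLibrary` emulates a screening-library-like background at
desk scale: a vocabulary of 14 core frameworks — benzene, pyridine,
cyclohexane, naphthalene, anthracene, the steroid nucleus (gonane),
spiro[4.5]decane, norbornane, ring pairs joined by linkers of length 0–3
(biphenyl through 1,3-diphenylpropane), triphenylmethane, and an acyclic
core — decorated with 0–3 acyclic side chains at chemically valid
positions. Sampling weights make simple aromatics common and polycyclics
rarer, roughly echoing real libraries; about 12% of molecules are acyclic
(ring count 0). Because side chains can never change a framework, each
molecule's full chain is known *by construction*: ring counts,
ring-connectivity edges and topology graphs are hand-specified per core,
and the level-7/8 keys come from the core's framework structure directly,
never through the side-chain-deletion code under test. The generator is
seeded and restores the global RNG state.

What the fixtures do **not** emulate: charged or isotopic records, stereo
centers, macrocycles, cage polycyclics, ring systems outside the
vocabulary, and parse errors. Passing tests therefore demonstrate
correctness of the transformations and bookkeeping on representative
chemistry, not robustness against every exotic structure in a public
database.

## Problem sizes and numerical choices

The shipped tests classify libraries of 100–1,000 molecules per property,
run the contraction oracle on 500 random graphs of up to 20 vertices, drive
the treemap properties with 1,000 random weight vectors (area conservation
asserted to 1e-9 relative), and run one end-to-end build of 10,000
molecules with a 1,000-molecule annotation — sizes chosen so the whole
suite completes comfortably on a laptop core while still exercising every
code path at scale. Ties in top-k ranking are broken lexicographically;
degree-2 contraction processes the lowest-index eligible vertex first
(tests verify the fixed point is order-independent up to isomorphism);
zero-weight treemap children are dropped rather than given epsilon cells.

## Known limitations

* Canonical keys at levels 7–8 are OpenBabel canonical SMILES; equivalence
  with keys produced by other toolkits' canonicalization is not claimed.
* Stereo preservation at level 8 is best-effort through molfile wedge/parity
  marks; double-bond geometry inside rings survives, but stereocenters whose
  neighbours were all deleted are (intentionally) dropped.
* The symmetric multi-bridge CSSR boundary case described above.
* InChI/CML input and 2D depiction aesthetics are out of scope; the SVG
  shows the key string as the cell depiction.
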