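---
title: "Enumerating the amine and diamine scaffold space of small saturated rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating the amine and diamine scaffold space of small saturated rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringamines)
```

## The model

`ringamines` answers a sharply bounded combinatorial question: how many
distinct saturated amines and diamines can be built on mono- and bicyclic
carbon frameworks whose smallest rings have 5, 6 or 7 members, and how is
that space distributed over ring sizes, ring topologies and amine types?

The substrate is the heavy-atom molecular graph: vertices are C or N,
every bond is single, and hydrogens are implicit, each atom carrying
`valence − heavy degree` of them with valence 4 for carbon and 3 for
nitrogen. This representation is exact for the space in question — saturated,
uncharged, stereochemistry ignored — and makes molecular identity
coincide with colored-graph isomorphism.

### Ring systems from first principles

Rather than loading a ring-system catalog, the parent frameworks are
derived analytically. At circuit rank 1 the only systems are the
cycloalkanes of each allowed size. At circuit rank 2 every system is a
pair of bridgehead atoms joined by three bridges of `x ≥ y ≥ z ≥ 0`
intermediate atoms (a spiro system being the degenerate case where the
two rings share a single atom instead):

* **spirocyclic** — two rings sharing one atom; one skeleton per
  unordered size pair;
* **fused** (`z = 0`) — two rings sharing one edge; also one skeleton per
  pair, bicyclo[a−2.b−2.0] for sizes (a, b);
* **bridged** (`z ≥ 1`) — the two smallest rings have sizes `y+z+2` and
  `x+z+2`; all bridge specifications whose two smallest rings lie in the
  size set are generated and deduplicated by canonical key.

Higher topologies are impossible at circuit rank 2, so this construction
is complete by enumeration of cases. For sizes {5, 6, 7} it yields 24
systems: 3 monocyclic, 6 spirocyclic, 6 fused and 9 bridged. The package
asserts the smallest-ring formula against an exhaustive simple-cycle
enumeration (at circuit rank ≤ 2 a graph has at most three simple cycles,
so "exhaustive" is cheap and exact).

### Nitrogen features and validity

Each skeleton is decorated with every set of one or two *nitrogen
features*, applied simultaneously:

* `RING_N` — replace a ring carbon by nitrogen; excluded at a spiro
  center, whose four ring bonds would make the nitrogen quaternary;
* `EXO_NH2` — replace one ring C–H by C–NH₂; any ring carbon with at
  least one hydrogen qualifies, bridgeheads included.

Because features are a set, a site carries at most one of them, and an
NH₂ can never land on a ring nitrogen by construction. Three exclusion
rules then define chemical validity:

1. **hydrazine** — no bond between two nitrogens (arises from two
   adjacent `RING_N`);
2. **aminal** — no carbon with two or more nitrogen neighbors; this
   single rule uniformly covers ring N–C–N patterns, a ring nitrogen
   adjacent to an NH₂-bearing carbon, and geminal diamines;
3. **quaternary nitrogen** — no nitrogen with four heavy neighbors.

These unstable or charged motifs are not isolable building blocks, which
is why they are excluded from the scaffold space.

### Canonical identity

Scaffolds are considered identical when their element-labeled graphs are
isomorphic (2D identity; stereoisomers are deliberately conflated). The
canonical key is the element sequence plus sorted edge list of the BLISS
canonical form computed by `igraph::canonical_permutation()` with the
element as vertex color. BLISS is exact, so key equality *is* isomorphism;
the test suite nevertheless cross-checks it on hundreds of pairs against
an independent exhaustive-permutation matcher, and checks every
symmetry-orbit count against a brute-force automorphism search.

With sizes {5, 6, 7} the enumeration produces 1139 unique scaffolds from
4142 labeled candidates. Their mean molecular weight, from IUPAC standard
average atomic weights (C 12.011, H 1.008, N 14.007), is 157.2 Da with a
population standard deviation of 22.5 Da.

## Parameters that matter

* `ring_sizes` (default `5:7`) — the allowed SSSR sizes. Sizes 3–9 are
  accepted; 3- and 4-membered rings introduce strain chemistry and ≥8
  rings synthetic inaccessibility, so the default is the medicinally
  interesting window and the only setting the published-style counts
  refer to.
* Maximum feature count is fixed at two. Triamines would explode the
  space while adding little scaffold-like character; the cap is part of
  the package's contract, not a tuning knob.
* Atomic weights are average (not monoisotopic) values, the convention
  under which a ~157 Da mean is reported for C/H/N scaffolds.

## Numerical and design choices

* **Standard deviation** is the population form; at n = 1139 the sample
  form differs by under 0.02 Da, far below reporting precision.
* **Determinism.** There is no randomness anywhere. Skeletons are ordered
  by (topology, ring sizes, name), scaffolds by canonical key, so two
  runs produce byte-identical SMILES, CSV and JSON outputs.
* **Global deduplication** across skeletons is asserted to be a no-op:
  the parent framework is recoverable from any scaffold (strip terminal
  nitrogens, relabel ring N to C), so distinct skeletons cannot collide.
  A collision aborts rather than silently merging.
* **Geminal double-NH₂ candidates** are suppressed up front (one feature
  per site); they would in any case be removed by the aminal rule, so the
  output is identical either way.
* **SMILES dialect.** The writer emits the minimal Daylight subset the
  space needs (C/N atoms, branches, ring-closure digits); the reader
  accepts exactly that subset plus `%nn` closures and explicit single
  bonds, and rejects everything else loudly. Round-tripping preserves the
  canonical key for all 1139 scaffolds.
* **Novelty is an offline join.** `annotate_novelty()` flags scaffolds
  absent from a user-supplied reference list of SMILES or keys. Database
  occurrence counts are version-dependent and are deliberately not
  computed; the package ships no reference list of its own.

## What the generated data do and do not show

The skeleton generator plays the role of the synthetic-data source here:
the study conditions are fully specified by the ring-size set, and
everything downstream is a deterministic consequence. Passing tests
therefore certify the combinatorics — completeness of the ring systems,
correctness of the exclusion rules and of symmetry-based deduplication —
but say nothing about synthesizability, stereochemical feasibility
(cis/trans fusions and R/S centers are conflated by design), ring strain,
or the biological relevance of any scaffold.

## Problem sizes used in the tests

The full pipeline (24 skeletons → 1139 scaffolds) runs in a few seconds
and is exercised directly by the acceptance tests. Brute-force oracles
are run where they are exact and affordable: permutation isomorphism on
graphs of ≤ 9 atoms, automorphism orbits on all 24 skeletons (≤ 13
atoms), 200 random relabelings per fixture molecule, and cross-footing on
random scaffold subsets.

## Known limitations

* Only C and N; ethers, thioethers and carbonyls are out of scope.
* Mono- and bicyclic only; tricyclic systems are a different (larger)
  universe.
* No stereochemistry: the 1139 scaffolds are constitutional isomers; the
  number of stereoisomeric species is larger.
* Ring-size strata always refer to the parent carbon skeleton's SSSR,
  which nitrogen substitution does not change.
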