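---
title: "Detecting beta-sheets in coarse-grained structures: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting beta-sheets in coarse-grained structures: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betagrain)
```

## The model

MARTINI coarse-grained simulations represent each residue's backbone as a
single bead ("grain"). Hydrogen bonds are not modelled explicitly, so
secondary structure cannot be assigned the way DSSP or STRIDE assign it.
What *is* observable is that when peptides assemble into cross-β
structures, backbone grains of neighbouring strands line up: across
hydrogen-bonded strands the grains of a residue "column" become nearly
collinear at a spacing of roughly 0.5 nm.

`betagrain` operationalises that observation in two stages.

**Aligned triples.** For an angular threshold $\alpha \in [0,1]$ and a
distance threshold $\varepsilon > 0$, a triple of grains $(x, y, z)$ on
pairwise-distinct peptides is $(\alpha, \varepsilon)$-aligned when both
end-to-center distances are at most $\varepsilon$ and the angle at the
center,
$\angle(x,y,z) = \arccos\!\big(\hat v \cdot \hat w\big)$ with
$\hat v = (x-y)/\lVert x-y\rVert$ and $\hat w = (z-y)/\lVert z-y\rVert$,
is at least $\alpha\pi$. The angle of a perfectly collinear triple with
$y$ between the ends is $\pi$, so the criterion selects near-collinear,
tightly spaced cross-strand triples. Requiring *pairwise-distinct*
peptides is what suppresses α-helices and random coil: those produce
near-collinear grains only within one chain. We read "different peptides"
as pairwise-distinct (three strands) rather than merely center-distinct,
because the target geometry is a cross-strand column of a β-lattice;
allowing two ends on one strand would re-admit intra-strand alignments the
constraint exists to remove.

**Sheet components.** Two aligned triples *overlap* when they share at
least two of their three grains. Membership is set-wise: a grain shared as
an end of one triple and the center of another still counts. The
connected components of the overlap graph are the reported sheet
components; their grain unions are the putative β-sheets, and every
statistic (sheet fraction, compositions, ratios) derives from them.

## Parameters

* `alpha` (dimensionless, default **0.89**): angle threshold as a fraction
  of $\pi$; 0.89 demands $\ge 160.2^\circ$. Lower values admit more bent
  triples; at cross-β spacings the next competing geometry (a one-residue
  diagonal step) sits near $145^\circ$, so the default separates the two
  cleanly.
* `epsilon` (nm, default **0.7**): distance cutoff for both arms. MARTINI
  inter-strand backbone distances are ~0.5 nm; 0.7 nm accepts thermal
  distortion while excluding second-neighbour strands (~1 nm).
* `use_pbc` (default **off**): optional minimum-image treatment of
  distances and angle arms in an orthorhombic box. Off by default because
  assembled aggregates are normally whole within the box; turning it on
  matters only when a sheet is split across the boundary.

Both thresholds are applied exactly as written — `<=` for distances, `>=`
for the angle — with no added tolerance band, so detection is a sharp
predicate and the monotonicity properties (triple sets nest as
$\varepsilon$ grows or $\alpha$ shrinks) hold set-wise, not just in
counts.

## Numerical and algorithmic choices

* **Angle convention.** The angle is always the one *at the center vertex*
  between the two arms, in $[0, \pi]$, and the alignment condition is
  $\ge \alpha\pi$ — i.e. near-$\pi$, obtuse angles qualify. One could
  equivalently phrase collinearity through the acute supplement of the
  same configuration; this package states and implements the vertex-angle
  form everywhere to avoid ambiguity.
* The arccos argument is clamped to $[-1, 1]$ so floating-point round-off
  on nearly collinear arms can never produce `NaN`.
* Coincident grains (a zero-length arm) make a triple *not aligned*
  rather than raising an error, so a degenerate frame in a long
  trajectory cannot abort a run. The low-level `angle_at_vertex()` itself
  does error on zero arms; `is_aligned()` catches that case.
* **Canonicalisation.** The criterion is symmetric in the two ends, so
  $(x,y,z)$ and $(z,y,x)$ describe one geometric alignment; triples are
  stored once with `end_a < end_b`. Reported triple counts are therefore
  counts of distinct geometric alignments.
* **Neighbor grid.** Candidate pairs come from a cell list with cube side
  $\varepsilon$ (27-cell stencil), which cannot lose a pair within
  $\varepsilon$; the exact distance, peptide and angle tests run on the
  candidates. Output equality with literal enumeration over all triples
  is asserted by the test suite on seeded random frames. With `use_pbc`
  the candidate stage falls back to an exact pairwise scan with
  minimum-image distances.
* **Union-find.** Components are merged with path-compressed union-find
  over candidate pairs generated from a grain→triples index (two triples
  can only overlap if they co-occur on some grain); this is
  output-equivalent to the quadratic scan over all triple pairs, which is
  kept — together with breadth-first search on the explicit adjacency —
  as the test oracle.
* **Determinism.** Components are ordered by decreasing grain count, ties
  by smallest member grain id, and numbered in that order; reports are
  byte-for-byte reproducible and invariant to triple input order.

## Input handling

Gromos87 `.gro` files are parsed by fixed columns (positions at
`20 + 8k`), never by whitespace; velocity fields are tolerated and
discarded. Residue boundaries are detected from *changes* of the (residue
number, residue name) pair between consecutive lines, because `.gro`
residue numbers wrap at five digits; peptide membership then comes from
the group length GL (`peptide = ordinal %/% GL`). Multi-frame input is
the concatenated-block dialect `trjconv` emits; all frames must have the
same grain count, and a residue total that is not a multiple of GL is an
error naming the remainder. Only orthorhombic boxes are interpreted;
triclinic extra fields are ignored with a warning.

PDB structures are coarse-grained by placing one `BB` bead per residue at
the **unweighted centroid of N, CA, C, O** (missing members skipped;
`ca_only` puts the bead on CA instead). This is a deterministic stand-in
for the MARTINI backbone center-of-mass convention — exact MARTINI
mappings vary by tooling and the difference is far below `epsilon`.
For mapped structures, peptides come from PDB chains (order-preserving),
not from GL: multi-chain structures define their peptides explicitly.
Altloc resolution keeps the highest-occupancy location (ties: first in
file); HETATM residues are skipped unless allowlisted (e.g. `"BTN"`).

## What the synthetic generators emulate

`make_parallel_sheet()` builds the idealised limit of a cross-β lattice:
strands at `inter_strand = 0.48` nm, residues at `intra_strand = 0.55` nm,
optional Gaussian jitter for the "distorted lattice" of real CG
aggregates. The intra-strand default is deliberately 0.55 nm rather than
the more physical 0.35 nm MARTINI bond length: with 0.55 nm the lattice
diagonal is $\sqrt{0.48^2+0.55^2} \approx 0.73 > 0.7$ nm, so diagonal
triples are excluded and the fixture's ground truth stays in closed form —
an $S \times L$ lattice has exactly $L(S-2)$ aligned triples, $L$
components (one per cross-strand column) and sheet fraction 1 for
$S \ge 3$. At 0.35 nm spacing diagonals enter the cutoff and ground truth
is defined only by brute-force enumeration; the synthetic fibril PDB
(below) covers that denser regime.

`make_helix()` (single peptide) and `make_random_coil()` (seeded random
walks, step 0.35 nm) are the negative and background controls.
`make_antiparallel_sheet()` shares positions with the parallel sheet and
encodes direction only in residue ordering — detection results are
identical by construction, documenting that the method sees positions
only and does not distinguish parallel from antiparallel packing.

`write_synthetic_fibril_pdb()` generates an idealised parallel
in-register fibril (12 chains × 32 residues by default, 4.8 Å stacking,
extended strands with N/CA/C/O backbone atoms) as a *synthetic* stand-in
for deposited amyloid fibril structures, so the PDB→mapping→detection
path can be validated end-to-end without network access. After mapping,
its 0.35 nm intra-strand spacing admits collinear diagonal triples in
addition to the stacking-axis columns — the expected behaviour for a
dense fibril, and the reason every chain participates in triples.

What passing these tests does **not** show: that the thresholds are
optimal for any particular force-field variant, that sheets split by
periodic images are handled without `use_pbc`, or that the statistics are
meaningful for structures whose peptide annotation (GL) is wrong. The
generators produce geometrically clean or uniformly noisy structures;
real trajectories contain partially formed, twisted and transient sheets
whose triple counts fluctuate frame to frame.

## Validation problem sizes

The test-suite and acceptance checks run, as the package's chosen
validation conditions: 20 seeded random frames of 100–200 grains over
5–20 peptides for the implementation-vs-oracle equalities; the
12 × 32 ideal lattice for closed-form ground truth; 5 jittered lattices
(jitter 0.05 nm) for monotonicity; and the 12-chain × 32-residue
synthetic fibril for the mapping pipeline. Jittered fixtures keep grains
at least 0.01 nm away from the $\varepsilon$ boundary in the cases used
for exact-equality assertions, so quantisation and rounding cannot flip
a comparison.

## Known limitations

* Sheet topology is not classified (parallel vs antiparallel, twist), and
  components are not tracked across frames; statistics are per-frame.
* The detector reports *putative* sheets: any three-peptide arrangement
  meeting the geometric criterion counts, including incidental contacts
  in dense random coil (singleton components of one triple).
* Only orthorhombic periodic boxes are supported, and only when opted in.
* The PDB mapper handles ATOM/HETATM/MODEL records; mmCIF and topology
  generation (side-chain beads, bead typing) are out of scope.
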