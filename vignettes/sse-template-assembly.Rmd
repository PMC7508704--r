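---
title: "SSE template libraries and RNA 3D assembly: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSE template libraries and RNA 3D assembly: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasse)
```

## The model

Template-based RNA 3D structure prediction rests on one empirical
observation: the building blocks of RNA tertiary structure recur.  If a
solved structure somewhere contains a hairpin loop with the same secondary
structure pattern as a hairpin in the target, its coordinates are usually a
good model for the target's hairpin.  `rnasse` implements this idea at the
granularity of *Smallest Secondary Elements* (SSEs): a stem (maximal helix
of consecutively nested pairs $(i,j), (i+1,j-1), \dots$) or a loop —
hairpin, bulge, internal loop, multibranch junction, or the open
(exterior) loop including the 5'/3' tails — where every loop record also
carries the **two terminal base pairs of each adjoining stem**.  Those
flanking pairs are not decoration: they are the rigid anchors over which
neighboring SSE templates are superposed during assembly, so every joint in
the assembled model is a least-squares fit over at least eight well-spread
atoms (P, C4', C1' and the glycosidic nitrogen of four residues).

Two library schemes differ only in the treatment of single base pairs
(helices of one pair).  Scheme `lib2` keeps them, so decomposition reflects
the annotated structure exactly.  Scheme `lib1` opens them before SSE
identification, merging the loops they separate; isolated pairs are
frequently annotation artifacts, and opening them enlarges loops, which
makes template matching more tolerant.  We apply the opening rule
iteratively to a fixed point, because removing one single pair can strand
another stem as a new single pair; a single application would make the
result depend on processing order.

## From coordinates to secondary structure

Deposited structures arrive as PDB or mmCIF, read natively (first model,
highest-occupancy alternate conformer).  Chains are sanitized in a fixed
order: residues with no parent standard base are dropped; modified
nucleotides are renamed to their parent base with the base moiety rebuilt
from an idealized template; residues with fewer than 9 observed heavy atoms
are removed; remaining residues with missing atoms are completed by
least-squares grafting of the idealized residue onto the observed atoms;
and chains shorter than 6 nucleotides — too short to form an SSE — are
rejected.  Completion by rigid grafting is a deliberate design choice over
force-field reconstruction: it is deterministic, dependency-free, and for
fragment assembly the sub-angstrom placement of a few missing atoms is
inconsequential.

Base pairs are annotated geometrically.  Each base gets a reference frame
(ring-atom centroid, least-squares plane normal oriented by the ring atom
order).  A candidate pair $(i, j)$ with $i + 1 < j$ must satisfy all of:

| criterion | threshold | default |
|---|---|---|
| ring-centroid distance (prefilter) | `d_pair` | 15 A |
| C1'–C1' distance | `c1_window` | 10.5 A |
| angle between base normals (folded) | `theta_pair` | 65 deg |
| vertical offset along the mean normal | `v_pair` | 2.5 A |
| Watson–Crick edge heavy-atom contact | `h_pair` | 3.5 A |

Non-standard base combinations are retained; AU, GC and GU are merely
flagged as standard.  The thresholds live in one overridable block
(`annotation_params()`); they are conventional ranges for geometric
annotators, not fitted values.  A two-column index file from any external
annotator can replace detection entirely (`read_pair_list()`).

When a residue is claimed by several candidates, the keeper maximizes the
ordered criterion tuple *(sequence interval $j - i > 4$, standard pair,
neighbor support — a candidate $(i\!-\!1, j\!+\!1)$ or $(i\!+\!1,
j\!-\!1)$ exists)*, compared lexicographically, with remaining ties broken
by geometry score, then smaller span, then smaller $i$.  The three criteria
could also be summed as votes; we rank them instead, because ranking gives
a strict total order (the tie-breakers make it total), and greedy selection
in a strict total order provably equals the brute-force search over all
conflict-free candidate subsets under lexicographic comparison of their
sorted member tuples — the test suite verifies this equivalence on
thousands of random candidate sets.  Finally, crossing (pseudoknot) pairs
are removed by an interval dynamic program over the pair endpoints that
keeps a maximum-cardinality nested subset (traceback preferring the smaller
opening index), and the removed pairs are retained as chain metadata.  SSE
definitions are tree-structural, so pseudoknots cannot be represented in a
template; dropping the minority set of crossing pairs loses the least
information.

## The library

Records are indexed by a topology key: SSE type plus the dot-bracket
pattern (segment lengths and flanking-pair arrangement, base identities
ignored).  Search is exact on the key — no loop-length tolerance — and
ranks candidates by full-sequence identity over all segments and flanking
pairs, with source id as a deterministic tie-break.  Self-exclusion removes
every record whose source accession equals the target's, which is the
protocol used to benchmark prediction honestly when the target itself is in
the library.  Two deduplication passes exist: exact duplicates (identical
sequence, pattern and coordinates) are never stored twice, and
`filter_unique()` optionally keeps one representative per (sequence,
pattern) for statistics.  Coordinates are stored at 0.001 A resolution, the
precision of the PDB fragment files, which makes save/load round trips
exact.  Provenance timestamps are kept in a separate file so that the
primary outputs (index and fragments) are byte-reproducible.

## Assembly, energy, refinement

The target (sequence plus dot-bracket) is decomposed under the library's
scheme; the rank-1 template is chosen per SSE; templates are placed by
breadth-first traversal from the exterior, each new template superposed
onto the already-placed model over the shared flanking-pair residues.  The
target sequence is imposed by grafting idealized bases where template and
target identities differ (the glycosidic nitrogen, C1' direction and base
plane define the graft frame, so purine/pyrimidine swaps are well defined).
Junction arm orientation is taken from the junction template itself; no
re-orientation heuristic is applied, so a junction template with the wrong
arm geometry propagates its error — the known dominant failure mode of
this class of methods.

The built-in energy is deliberately minimal:

* soft-sphere repulsion $k_c(d_c - r)^2$ for heavy-atom pairs closer than
  the contact distance $d_c$ (default 2.8 A, $k_c = 10$) that belong to
  different SSE records and are not sequence-adjacent;
* harmonic restraints on the O3'–P virtual bonds that cross SSE record
  boundaries, and on the glycosidic-nitrogen distance of every flanking
  pair, each flat within a 0.5 A deadzone of its distance in the assembled
  model ($k_r = 10$).

Restraint targets are the *assembled* distances, not idealized chemical
values: a freshly assembled clash-free model is therefore exactly at an
energy minimum and passes through minimization unchanged, while any move
set that stretches a junction or tears a flanking pair is penalized.  The
scorer is pluggable — any function of the coordinates can replace the
built-in energy in the Monte Carlo stage, which is the hook for external
statistical potentials.

Clash relief is rigid-body steepest descent: each record's owned residues
form a rigid group, translated along the net inter-group force and rotated
along the net torque with backtracking line search, so the energy is
non-increasing by construction.  Refinement is simulated annealing Monte
Carlo over moveable elements derived from the stem tree: every non-root
stem together with its distal subtree (pivot at the P atom of its outermost
5' residue), and every unpaired loop segment.  Moves are uniform random
translations (up to 2 A), rotations about the element centroid or about a
random axis through the pivot (up to 10 deg), accepted by the Metropolis
criterion under geometric cooling (defaults: start 5.0, floor 0.1 in score
units, factor 0.98 every 100 steps).  None of these schedule constants is
fitted; they are exposed in `samc_schedule()`.

Sampled conformations are clustered on their pairwise optimal-superposition
RMSD matrix.  "k-means on an RMSD matrix" is not literally defined (RMSD
is not a vector-space distance), so we implement k-medoids: exact
enumeration of medoid sets when $\binom{m}{N} \le 20{,}000$ — which is the
brute-force optimum by construction — and PAM otherwise.  Representatives
are medoids, ranked by energy.

## The synthetic-fixture generator

Everything above is testable offline because `build_toy_rna()` produces
full heavy-atom coordinates for arbitrary nested secondary structures.  Its
geometry is idealized but principled:

* one frozen heavy-atom template per base, expressed in a canonical
  glycosidic frame, with the sugar-phosphate moiety oriented so that
  stacked neighbors in a helix do not interpenetrate;
* Watson–Crick-like pair placement with C1'–C1' = 10.4 A and a glycosidic
  angle of 58 deg, calibrated so AU, GC and GU all form edge contacts near
  2.8 A; helices use a fixed twist of 32.7 deg and rise of 2.81 A;
* unpaired runs on circular arcs between their anchoring paired residues
  (spacing 5.9 A, bulge direction away from the local enclosing helix,
  arcs lifted above their anchors, long loops capped at a 5.9 rad wrap),
  with bases pointing outward and base planes perpendicular to the chain
  direction so that no two unpaired bases — and no unpaired/stem base
  pair — satisfies the pair-detection criteria;
* junction arms fanned at 65 deg from the parent axis, 18 A radially;
  top-level stems spaced 55 A apart.

The generator defines the study conditions for the whole test suite: the
derived secondary structure of every generated fixture equals its
generating structure exactly at noise amplitude zero (verified over
hundreds of random structures of 8–60 nt), and self-assembly from a
fixture's own templates reproduces it to within the 0.001 A storage
rounding.

What the generator does **not** emulate matters for interpreting green
tests: loop conformations are geometric, not thermodynamic; sugar puckers
are frozen; backbone continuity across SSE boundaries is approximate (the
energy's restraint targets absorb this); there are no modified residues in
generated fixtures except through the corruption helpers, no ions, no
crystallographic disorder beyond optional Gaussian noise.  Passing tests
demonstrate the correctness of the decomposition, search, superposition and
optimization machinery — not the biological accuracy of predictions on
deposited structures, which depends on library coverage that only the real
corpus provides.

One generator policy is worth stating explicitly: random test structures
draw helices of at least 2 pairs and hairpin loops of at least 3 nt.  An
*isolated* single base pair surrounded by flexible loop geometry is not
reliably recoverable by any purely geometric annotator — the same
unreliability that motivates opening single pairs in the `lib1` scheme —
so single-pair structures are exercised through explicitly constructed
decomposition fixtures rather than through the random round-trip property.

## Numerical choices and problem sizes

Superposition uses the singular-value-decomposition solution with the
determinant correction, so reflections are never returned; fewer than three
or collinear correspondences are errors.  Dot-bracket serialization assigns
crossing pairs greedily (ascending opening index) to four bracket layers;
deeper crossing is an error.  The decomposition oracle in the test suite
enumerates all nested pairings up to length 14 (about 180,000 structures)
and matches an independently written naive tree walker on 100% of them;
conflict filtering and crossing removal are checked against brute-force
subset enumeration on 1,000 random instances each; the annotation round
trip runs 200 random fixtures; the refinement check runs 5,000 Monte Carlo
steps on a two-arm fixture with an engineered inter-arm clash.  These sizes
were chosen to exhaust the small cases completely and sample the rest
broadly.

## Known limitations

* Pseudoknots are removed before decomposition; templates never span them.
* Template matching is exact on topology; a target loop with no
  length-matched template fails loudly rather than approximately.
* The built-in energy has no attractive terms and no statistical potential;
  ranking quality improves with a plugged-in scorer.
* Junction arm orientation is inherited from the template, with the failure
  mode that implies.
* The sanitation rule counts any heavy atoms toward the 9-atom threshold;
  which atoms are present is not inspected until completion.
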