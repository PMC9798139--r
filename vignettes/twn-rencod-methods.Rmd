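---
title: "Binding-site comparison via topological water-network encoding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site comparison via topological water-network encoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twnrencod)
```

## The idea

Binding pockets organise the water around them. Stable, hydrogen-bonded
water clusters recur at particular pocket locations across a solvent
simulation, and the geometry of those clusters relative to the pocket is
a fingerprint of the pocket itself — one that does not depend on the
identity of the pocket's side chains. `twnrencod` turns that fingerprint
into a number: the fraction of matched hydration-shell classes between
two proteins' encoded solvent trajectories.

The method assumes a specific simulation protocol: the protein is
positionally restrained and only waters move. Two consequences shape the
code. First, one static set of binding-site backbone coordinates per
protein suffices — there is no per-frame superposition step anywhere in
the pipeline. Second, frames differ only in their water configuration,
so a frame is fully described by where its water rings sit relative to
the (fixed) site.

## Ring detection

A topological water network (TWN) here is a 3-membered ring: three
waters, each pair hydrogen bonded. Hydrogen bonding is decided
energetically, not geometrically: the rigid TIP3P pair interaction
energy

$$v(a,b) = \sum_{i \in a}\sum_{j \in b} k_e \frac{q_i q_j}{r_{ij}}
  + \frac{A}{r_{OO}^{12}} - \frac{C}{r_{OO}^{6}}$$

is evaluated over the nine charge-site pairs plus the single
oxygen-centred Lennard-Jones term, and the pair is bonded when
$v \le -2.25$ kcal/mol. The threshold itself counts as bonded (a `<=`
comparison); this closure is configurable in `tip3p_params()`. An
energy criterion is less orientation-brittle than distance–angle
definitions and matches how the TWN literature defines the bond.

One constant deserves a flag: the electrostatic conversion factor
$k_e$. Published descriptions of the potential typically write
$q_i q_j e^2 / r_{ij}$ with no numeric factor; this package defaults to
the conventional CHARMM/TIP3P value **332.0636 kcal·Å/(e²·mol)**, which
reproduces standard TIP3P dimer energetics (the ideal near-linear dimer
at $r_{OO} = 2.8$ Å evaluates to about −6.07 kcal/mol). It is an
explicit, overridable field of `tip3p_params()` rather than a buried
constant.

Ring enumeration is exact: every water pair within the prescreen radius
is scored, bonded pairs form an undirected graph, and all triangles are
enumerated by sorted-adjacency intersection. Two numerical choices:

* **O–O prescreen (default 4.5 Å).** Pairs whose oxygens are farther
  apart than 4.5 Å are skipped without an energy evaluation. At that
  separation the interaction is far above −2.25 kcal/mol for any
  orientation, but the claim is demonstrated, not assumed: the test
  suite checks on hundreds of random frames that detection with the
  prescreen equals detection without it, which in turn equals a
  brute-force scan over all $\binom{n}{3}$ triples scored by an
  independently written term-by-term energy oracle. Setting
  `oo_prescreen_cutoff = 0` disables the shortcut.
* **Periodic boundaries.** When a frame carries box lengths (a `CRYST1`
  record in the PDB dialect), every site–site distance uses the
  minimum-image convention; without a box, plain Euclidean distances
  are used. Synthetic fixtures are non-periodic by construction.

Degenerate inputs: coincident oxygens (r_OO below 1e−6 Å) raise an
error rather than returning a singular energy; frames with fewer than
two waters yield an empty bond graph.

## Encoding

For each frame, distances are measured from each binding-site backbone
atom to ring **centroids** (the mean of the three oxygen positions) —
not to individual waters — and binned:

| class | range |
|-------|----------------|
| A | [0, 5) Å |
| B | [5, 7.5) Å |
| C | [7.5, 10) Å |
| D | [10, ∞) Å |

The outer bins are forced by the "<5 Å" and ">10 Å" convention for
hydration layers; the interior closure (left-closed bins, so 7.5 Å is
class C) is this package's documented choice, pinned by tests at every
boundary.

Two aspects of the per-frame representation were genuinely open and are
resolved as follows:

* **Aggregation over multiple rings.** A frame may hold several rings.
  This package defines the frame descriptor as, for each site atom, the
  **minimum** distance to any retained ring centroid. That yields a
  fixed-width row (4 × residues columns) regardless of ring count, is
  invariant to ring ordering, and reduces to the obvious encoding when
  exactly one ring is present. The alternative — one row per ring
  occurrence — produces variable-width frames that cannot be compared
  cell-by-cell after reordering.
* **"Within the binding site".** A ring is associated with the site
  when its centroid lies within `site_radius` (default 10 Å, the
  outermost informative class boundary) of *any* site backbone atom.
  Rings farther out are discarded before the minima are taken. The
  radius is a user-visible parameter; retention is monotone in it, and
  each distance entry is non-increasing as it grows.

A frame with no retained ring is a real, meaningful state ("the pocket
held no ring network just then"). It is encoded as the `NO_TWN`
sentinel, classified **D** — absence belongs beyond the last shell —
and valued at a **cap of 12 Å** in frame-difference computations. The
cap must exceed 10 Å (otherwise absence could out-compete a genuine
far-shell ring during reordering); 12 Å places it one half-shell width
beyond, and it is configurable wherever it is used.

## Reordering and scoring

Equivalent ring networks appear in *different* frames of two
independent simulations, so the query trajectory is reordered before
classes are compared. The assignment is **greedy and sequential**:
walking reference frames in order, each step picks the unassigned query
frame minimising the difference in distance values, removes it from the
pool, and records the cost. This mirrors the procedure the method
defines (frame 1 of the reference claims its best match first, then
frame 2 among the remainder, and so on); a globally optimal assignment
(Hungarian algorithm) would be a different method and is deliberately
out of scope. Two consequences are documented rather than hidden:

* the comparison is **anchored** on the reference, so
  `compare_trajectories(a, b)` and `compare_trajectories(b, a)` may
  differ; `both_directions = TRUE` reports both and their mean;
* ties are broken toward the lowest query frame position, making the
  result deterministic.

The row metric is **L1** (sum of absolute per-atom differences, with
sentinels at the cap): robust, exactly reproducible in tests with
integer-friendly fixtures, and order-equivalent to the "minimum
difference in distance values" rule. L2 is available behind
`metric = "l2"`.

Similarity is counted per atom cell: after reordering, the fraction of
(frame, atom) positions whose class labels agree. Counting per atom
rather than per residue follows directly from the matrices being built
per atom; it also means a single residue contributes four chances to
agree or disagree. Similarity is 1 exactly when the reordered class
matrices are identical.

Cross-protein column alignment relies on the site configs listing
residues in corresponding order (a KLIFS-style pocket alignment for
kinases); `site_pairing()` enforces equal residue counts and the
fixed N, Cα, C, O atom order makes column $k$ comparable across
proteins.

## The synthetic generator

`generate_trajectory()` emulates exactly the features of restrained-
solvent MD output that the pipeline consumes, with known ground truth:

* **Planted rings**: three TIP3P waters with oxygens on an equilateral
  triangle of side 2.8 Å (a typical hydrogen-bond O–O distance), each
  water donating one hydrogen exactly along the edge to the next oxygen
  and carrying its second hydrogen at the TIP3P internal angle
  (104.52°, r_OH = 0.9572 Å) swung in-plane away from the ring
  interior. At zero jitter all three pair energies are −3.52 kcal/mol
  — verified against the term-by-term oracle in the tests — so the
  triple is always detected, and its centroid coincides with the
  planted centre to machine precision.
* **Presence probabilities** let a site's ring appear in only some
  frames, emulating transient networks.
* **Jitter** (`jitter_sigma`) adds isotropic Gaussian noise to every
  planted atom, degrading first the centroid positions and then the
  rings themselves; this drives the monotone-degradation tests.
* **Background waters** are placed uniformly at random with a minimum
  6 Å oxygen separation from everything else — beyond any plausible
  hydrogen-bond energy at TIP3P charges — so the noise background is
  ring-free by construction.
* **Determinism**: each frame draws from an RNG substream derived from
  the spec seed and frame index; identical specs produce byte-identical
  PDB output.

What the generator does *not* emulate: realistic bulk-water structure
(density, radial distribution), water dynamics, protein flexibility, or
periodic boxes. Passing tests on synthetic data therefore demonstrate
the pipeline's correctness — detection, encoding, reordering, scoring
behave exactly as specified — not that the similarity score ranks real
kinase pockets usefully; that claim requires real restrained-solvent
simulations, which this package consumes but does not run.

`synthetic_binding_site()` provides the matching scaffold: backbone
quadruples placed deterministically on a Fibonacci sphere around the
pocket. It is labelled synthetic throughout; its geometry is not a
protein fold, merely a fixed 64-atom frame of reference.

## Problem sizes and runtime

The shipped tests and the acceptance script run at sizes chosen to
exercise every code path while staying interactive: oracle-equivalence
on 200 random frames of up to 40 waters; 20-frame, 64-atom trajectory
comparisons; jitter sweeps over σ ∈ {0, 0.5, 1, 2, 4} Å with 10
generator seeds. The full suite completes in under a minute on one CPU.
Real-use inputs (thousands of frames, thousands of waters per frame)
scale linearly in frames; per frame, the prescreen keeps energy
evaluations near-linear in water count at liquid density.

## Known limitations

* Only 3-membered rings are enumerated; larger cyclic networks are a
  different observable.
* The greedy reordering is order-dependent and not globally optimal by
  design; the asymmetry is reported, not removed.
* The reader enforces rigid-water sanity (O–H within 0.5–1.5 Å), so
  trajectories from flexible-water models need regularising first.
* GRO/XTC input is not built in; trajectories should be converted to
  multi-model PDB (e.g. with `gmx trjconv`) before reading.
* Censored activity values ("&gt; 10 000 nM") are taken at their bound
  in `activity_table()`, with a warning; any downstream correlation
  inherits that floor.
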