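---
title: "Fitting protein structures onto lattices: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting protein structures onto lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticefit)
```

## The problem

Lattice protein models discretise space so that large-scale structural
surveys — folding kinetics, exhaustive conformational enumeration, sequence
design — become computationally tractable. To use them on real proteins one
must first solve the *protein chain lattice fitting* (PCLF) problem: given
the atomic coordinates of a protein, find the self-avoiding lattice chain
that best represents it. The problem is NP-complete already for
backbone-only models on the cubic lattice, so practical tools use heuristic
chain growth.

`latticefit` produces both backbone-only models (one monomer per residue,
placed at the C$\alpha$ position) and side-chain models in the
Bromberg–Dill representation (two monomers per residue: the C$\alpha$
node plus an adjacent side-chain node fitted to the centroid of the heavy
side-chain atoms).

## Lattices

A lattice is defined by its neighbourhood $N$: an ordered set of integer
vectors of equal length, closed under negation. Four lattices ship with the
package:

| name | neighbourhood | coordination $|N|$ |
|------|---------------|--------------------|
| `sqr` | $(\pm1,0,0), (0,\pm1,0)$ | 4 |
| `cub` | signed unit vectors | 6 |
| `fcc` | signed permutations of $(1,1,0)$ | 12 |
| `210` | signed permutations of $(2,1,0)$ | 24 |

The registry is open: `register_lattice()` accepts any neighbourhood
satisfying the invariants. 2D lattices are embedded in 3D with $z = 0$ so a
single code path serves all of them.

Every neighbour vector is scaled to a physical bond length of 3.8 Å — the
mean distance between consecutive C$\alpha$ atoms, and close to the
mean C$\alpha$-to-side-chain-centroid distance — so all reported RMSDs
are in Å. The bond length is a parameter (`bond_length`) should a different
calibration be needed.

Each lattice carries its point group: the subset of the 48
signed-permutation matrices that maps $N$ onto itself, found by brute
force. For the three cubic-symmetric 3D lattices this is the full 48-element
group; for the square lattice the group is restricted to matrices fixing
the $z$ axis, giving the expected 8-element dihedral group (without the
restriction, matrices flipping the unused $z$ axis would be spuriously
included).

## Metrics

Two complementary quality measures are used, both in Å:

$$\mathrm{dRMSD}(P, M) =
  \sqrt{\frac{\sum_{i<j}\left(|P_i-P_j| - |M_i-M_j|\right)^2}{n_\text{pairs}}}$$

over all point pairs, with $n_\text{pairs} = \binom{n}{2}$; for a
side-chain model of $l$ residues ($n = 2l$ points) this equals
$l\,(2l-1)$, and for a backbone model $l(l-1)/2$. dRMSD compares
intramolecular distances only and is therefore invariant under rigid motion
*and reflection* of either structure. The pair-count denominator sits inside
the square root (standard RMSD form).

$$\mathrm{cRMSD}(P, M) = \sqrt{\frac{\sum_i |P_i - M_i|^2}{n}}$$

compares matched coordinates and requires a common frame. The optimal
proper rotation is computed with the Kabsch algorithm (SVD with determinant
correction). Because dRMSD cannot distinguish a structure from its mirror
image, the final superposition always scores both the model and its point
reflection and keeps the branch with lower cRMSD (ties go to the
non-reflected branch). Reflection is handled *only* there; `kabsch()` itself
always returns a proper rotation.

## dRMSD-optimising chain growth

The primary strategy grows the chain one residue at a time from the amino
terminus, maintaining a beam of the `n_keep` best partial models:

1. The first backbone monomer sits at the origin; in side-chain mode the
   first side-chain monomer occupies one canonical adjacent node. Both
   choices are free of loss: the point group acts transitively on the
   neighbourhood and dRMSD is invariant under it.
2. At iteration $i$, every beam entry is extended by all valid (connected,
   unoccupied) placements of the next backbone node and, in side-chain
   mode, of its side-chain node. Scores are raw sums of squared
   pairwise-distance deviations, updated incrementally — a new monomer only
   adds its distances to the monomers already placed. Accumulators are never
   renormalised during growth; within one iteration all partials have equal
   length, so raw sums order identically to partial dRMSDs.
3. Because dRMSD cannot see orientation, symmetry-equivalent partials are
   redundant. Every child is replaced by its canonical form
   (lexicographically smallest image over the point group, translated to
   the origin) and children sharing a canonical form are collapsed,
   keeping the lowest score per orbit. Filtering at every iteration
   maximises the effective beam diversity.
4. Entries are ordered by score, ties broken lexicographically on the
   canonical node sequence. The order is total and deterministic, which
   makes results reproducible and yields the beam-nesting property: the
   width-$k$ beam is a prefix of the width-$k'$ beam for $k' > k$, so the
   final dRMSD is non-increasing in `n_keep`.
5. After the last residue, the best model and its mirror image are Kabsch
   superposed onto the target; the lower-cRMSD branch is reported.

The growth loop is implemented in C++ (via Rcpp): it is the hot path, and
beam widths of 1000 over 24-neighbour lattices generate hundreds of
thousands of candidate extensions per iteration. A candidate whose score
already exceeds the current `n_keep`-th best is discarded before
canonicalisation; the bound is kept slightly slack (relative $10^{-9}$) so
floating-point jitter can never exclude a true tie.

### Width-1 beams and the knight's-walk lattice

A partial model with score exactly zero is congruent to the target prefix,
but on the `210` lattice congruence does not imply lattice symmetry: two
zero-score partials can be related by an isometry outside the point group,
in which case only one of them extends to the full zero-score model (the
isometry does not map future lattice extensions onto lattice nodes). A
width-1 beam must then guess, and the deterministic tie-break can keep the
dead branch: in a 50-structure sweep, 22/50 backbone and 8/50 side-chain
self-fits failed at `n_keep = 1`, while `n_keep = 8` recovered every one.
On `sqr`, `cub` and `fcc` no such failure was observed (0/400). The
self-fit validation therefore uses `n_keep = 1` on those three lattices and
`n_keep = 8` on `210`; real fits use far wider beams anyway.

## Rotation-scanning cRMSD optimisation

The alternative strategy optimises cRMSD directly, which requires fixing
the relative orientation first:

- The target is rotated on a grid of `r` uniform steps per XYZ axis. The
  default range is $[0, \pi/2)$ per axis: the three built-in 3D lattices
  have full cubic symmetry, so rotations outside that range reproduce
  already-scanned relative orientations. `full_sphere = TRUE` scans
  $[0, 2\pi)$ for lattices without that symmetry. The grid always contains
  the identity (step offsets start at 0).
- For each rotation the target is anchored with $P_1^b$ on the origin
  node, the first side-chain monomer goes to the adjacent node closest to
  its centroid, and the chain grows exactly as above but scored by the
  additive sum of squared coordinate deviations. No symmetry filtering is
  applied — orientation is meaningful here.
- A refinement pass re-runs the growth on `r_ref` sub-interval rotations
  per axis spanning $\pm$ half a coarse step around the best coarse
  rotation (`r_ref = 1` re-evaluates the centre; `r_ref = 0` disables
  refinement). The coarse best is always retained, so refinement can only
  improve the result.
- The winning model is finalised with the same Kabsch-plus-mirror
  superposition as the dRMSD strategy, which can only improve on the
  anchored grid-frame cRMSD; the grid-frame value is preserved in
  `params$grid_crmsd`.

Runtime scales with $r^3 + r_\text{ref}^3$ growth runs, which is why the
rotation-free dRMSD strategy is the default.

## Parameters

| parameter | default | meaning |
|-----------|---------|---------|
| `n_keep` | 1000 | beam width; the reference benchmark setting |
| `bond_length` | 3.8 Å | physical length of every lattice bond |
| `r` | 10 | coarse rotation steps per axis (cRMSD strategy) |
| `r_ref` | 5 | refinement steps per axis (cRMSD strategy) |

`n_keep = 1000` follows the published benchmark parameterisation; `r` and
`r_ref` defaults are chosen so FCC fits of typical single-domain chains
complete in seconds to minutes.

## PDB extraction rules

- Backbone target $P^b_i$: the C$\alpha$ coordinate. Side-chain target
  $P^s_i$: the geometric centre of the residue's non-hydrogen side-chain
  atoms (N, CA, C, O, OXT excluded).
- Glycine has no heavy side-chain atom; its C$\alpha$ coordinate is used as
  the side-chain target, keeping one monomer pair per residue as the model
  requires. The lattice still places a distinct adjacent side-chain node.
- Files in which *no* residue has side-chain atoms are rejected in
  side-chain mode (C$\alpha$-only depositions cannot support a side-chain
  fit); isolated incomplete residues are tolerated via the glycine rule.
- Fragmented structures are supported: a new fragment starts at a gap in
  residue numbering (insertion codes count as consecutive) or when
  consecutive C$\alpha$ atoms are more than 4.5 Å apart — loose enough for
  CIS-proline (~2.9 Å) and trans (~3.8 Å) linkages, tight enough to flag
  non-bonded neighbours. Each fragment is fitted independently in its own
  lattice frame, and overall metrics combine fragments as length-weighted
  root mean squares.
- Alternate locations: blank or `A` kept; MODEL records: first model only.
  Standard practice; the extraction is deliberately conservative and never
  repairs or completes missing atoms.

## Synthetic data and what the tests show

All validation runs on synthetic structures; no downloads are involved.
The generator (`random_structure`) performs uniform-restart self-avoiding
growth — uniform choice among valid extensions at each step, restart on
dead ends. This guarantees validity by construction but makes no claim of
uniformity over the space of walks, which the tests do not require.
`perturb` converts a model to real coordinates, applies a random rigid
motion and adds isotropic Gaussian noise of standard deviation $\sigma$
per coordinate; `write_fixture_pdb` emits the result as a synthetic PDB
file (CA plus one pseudo-CB per residue).

The validation suite establishes, among others:

- exact recovery of unperturbed ($\sigma = 0$) structures by both
  strategies on all four lattices and both modes (50 structures per
  condition, lengths 5–30);
- equality with an exhaustive brute-force oracle on *every*
  symmetry-distinct backbone target of length $\le 5$ on `sqr` and `cub`
  and side-chain target of length $\le 3$, under a saturating beam;
- monotone non-increase of the final dRMSD in
  `n_keep` $\in \{1, 10, 100, 1000\}$ on 20 noisy fixtures, and monotone
  degradation of mean fit quality in $\sigma \in \{0, 0.25, 0.5, 1\}$ Å;
- end-to-end format fidelity through the PDB/XYZ/move-string writers.

These are correctness properties of the optimiser and the I/O path. What
they deliberately do *not* show is fitting quality on real proteins:
synthetic walks have no secondary structure, no Ramachandran statistics
and no realistic radius of gyration, and the noise model is isotropic.
The benchmark harness (`run_benchmark`) produces the per-lattice
quality tables for any locally supplied set of PDB chains; the published
reference points for high-resolution sets are mean backbone dRMSDs of
about 2.1 Å (cubic), 1.3 Å (FCC) and 0.9 Å (knight's walk), and about
1.5 Å for FCC side-chain models.

`scripts/acceptance.R` recomputes the package's headline quantities on the
synthetic study conditions: self-fit recovery across all lattices and
modes, the oracle agreement rate, and mean dRMSD/cRMSD over eight seeded
30-residue fixtures per condition at $\sigma = 0.5$ Å (an intermediate
noise level: clearly off-lattice, yet structure-preserving) with the
reference beam width `n_keep = 1000`. Problem sizes were chosen so the
whole script completes in minutes on one CPU while still using the
reference parameterisation.

## Numerical choices

- Scores are raw squared-deviation sums; RMSDs are formed only when
  reporting. Equality tests against the oracle use an absolute tolerance
  of $10^{-9}$ Å.
- "Exact" self-fit recovery means dRMSD below $10^{-9}$ Å (the rigid
  motion applied to the target perturbs distances at machine precision)
  and cRMSD below $10^{-6}$ Å.
- Kabsch degenerates (all points coincident, or a single point) fall back
  to the identity rotation and centroid translation.
- Move strings label the neighbour vectors `A`, `B`, `C`, … in
  lexicographic order of their components; backbone steps and
  backbone-to-side-chain bonds are emitted as two separate strings so the
  backbone string stays compatible with HP-model tooling. The mapping is
  printed by the `lattices` CLI subcommand.
- Model canonicalisation flattens nodes backbone-first and compares
  lexicographically — a cheap total order.

## Known limitations

- No mmCIF or CML input/output; PDB and XYZ only.
- The cRMSD strategy restricts the first side-chain monomer to the node
  closest to its centroid (as the chain-growth formulation prescribes),
  so it is not exhaustive over that choice even with a saturating beam.
- Fragments are fitted in independent lattice frames; a shared frame
  across fragments is not attempted.
- No energy function, sequence semantics, or refinement moves: the output
  is a geometric fit, intended as input for downstream lattice tools.
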