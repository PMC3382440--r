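---
title: "Detecting shared protein binding sites by atom-level alignment and rigid superposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shared protein binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitematch)
```

## The problem and the model

Binding sites — the localized patches of a protein surface that contact a
ligand or a partner protein — tend to be conserved between proteins that bind
the same partners, both in their local chemistry and in their 3D shape.
`sitematch` predicts binding sites shared by two structures by requiring three
independent kinds of agreement at once:

1. **Sequence-of-atoms conservation.** A PDB chain is read as an ordered
   sequence of atom-name tokens (each residue contributes `N, CA, C, O`
   followed by its side-chain atoms in standard order). Conserved stretches
   are found by Smith–Waterman local alignment over this alphabet with match
   score +1 for identical tokens, a *forbidden* mismatch (two different atom
   names can never occupy one column), and a gap score of −2. Suboptimal,
   mutually non-overlapping segments are enumerated Waterman–Eggert style:
   report the best alignment, ban its matched cells, realign, and stop when
   the next alignment has fewer than `min_pairs` matched columns (or a
   configurable segment cap, default 100, is reached). Only the matched
   columns are carried forward; the dropped gap columns are remembered so that
   each final site can report its gap count.

2. **Surface exposure.** Space around each structure is discretised on a
   1 Å lattice. A lattice point within 2 Å (non-strict) of any atom center is
   a *protein* point; a protein point whose six axis neighbours are all
   protein is INTERIOR, otherwise it is SURFACE. An atom is a *surface atom*
   if it lies within 1.5 Å (non-strict) of some SURFACE point. A window of a
   conserved segment qualifies as a candidate site only if it has at least 15
   matched pairs and, on each protein separately, at least 2/3 of its matched
   atoms are surface atoms. Both distance comparisons use `<=`; the boundary
   cases are exercised in the tests. The lattice is anchored at the
   componentwise floor of the minimum atom coordinate minus the padding, so
   classifications are deterministic; they can shift by a sub-voxel phase if
   the structure is translated by a non-integer offset, which is inherent to
   any anchored-lattice scheme.

3. **Rigid 3D agreement.** For each candidate, contiguous windows of at
   least `min_pairs` columns are searched for a single rigid transformation
   (proper rotation plus translation) taking every matched pair within a
   distance `d` of its partner. The certificate is approximate with factor
   (1 + ε), ε = 0.1: whenever some transform achieves bottleneck distance
   (the maximum over pairs) at most `d`, the window is accepted with a
   transform of bottleneck at most (1 + ε)`d`.

Finally, a **steric veto** discards transforms that would make the two
protein bodies interpenetrate: both structures are labelled on one shared
lattice and the pair is rejected unless `X ≤ 0.05 · min(X1, X2)`, where `X`
is the number of lattice points interior to both and `X1`, `X2` the interior
counts of each protein. The inequality is non-strict: equality counts as no
overlap.

## How the (1+ε) certificate is computed

The window test is exact where it can be and conservative elsewhere:

* The Kabsch least-squares superposition is computed first. If its
  bottleneck is already within (1 + ε)`d` the window is accepted outright.
* If the Kabsch **RMSD** exceeds `d` the window is *provably* infeasible: the
  least-squares RMSD lower-bounds the RMSD of every rigid transform, and any
  transform's RMSD lower-bounds its bottleneck. No refinement is attempted.
* Otherwise the transform is refined. For a fixed rotation the optimal
  translation is exact — it is the center of the minimal enclosing ball of
  the residuals `A_i − R B_i`, computed by the Bădoiu–Clarkson iteration
  (600 steps; the approximation error is a vanishing fraction of the
  ball radius and the reported bottleneck is always recomputed exactly for
  the returned transform). Rotations are explored by iteratively reweighted
  least squares (weights `exp(d_i/τ)` concentrate on the worst pairs) and an
  axis–angle pattern search around the incumbent with angular step
  `ε·d / r_max`, where `r_max` is the largest distance of a point from the
  moving set's centroid — the step at which a rotation perturbation moves no
  point by more than `ε·d`. The search halves its step until convergence and
  never returns a transform worse than its seed.

This replaces a sampled-translation grid with the exact per-rotation optimum,
which strictly dominates any translation sample at the same rotation. The
200-instance planted-transform test in `test-acceptance.R` checks the
certificate end to end: instances constructed so that a known transform
achieves bottleneck ≤ `d` must always be accepted within (1 + ε)`d`.

Window search is grow-and-slide: every start is seeded at the minimum width,
accepted windows are greedily extended right then left under the full
certificate, nested windows are dropped, and overlapping accepted windows are
merged when their union still certifies. Windows are contiguous column runs;
non-contiguous subsets are out of scope.

### Where the surface rule binds

The 2/3-surface rule is applied twice: when windows of a conserved segment
are filtered into candidates, and again to each finally accepted window. The
second application matters: a buried stretch embedded in a long, mostly
exposed conserved segment passes the candidate-level test by dilution, yet
the reported subsegment is itself a (putative) binding site and must satisfy
the exposure requirement in its own right. Without the re-check the
surface-ablation comparison below would be meaningless.

### Transform groups

One physical transformation often supports several windows (distinct
segments of the same interface). Reports whose transforms agree within 5° of
rotation and 0.5 Å of displacement are pooled into a transform group.
Displacement is compared by the transforms' *action at the matched atoms*
(the mean position of the two reports' moving-side atoms), not by the raw
translation vectors, which diverge with the lever arm for identical physical
motions.

### Site-search mode and the veto

`search_site()` uses a known site (structure + residue list) as the query.
The surface filter then applies to the target side only — the query is a
site, surface by construction — and the steric veto is skipped: the veto
compares protein *bodies*, and a bare site has none; any faithful hit would
"overlap" its own image in the target and be rejected, including the exact
self-match.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `d` | 1.5 | Å | per-pair superposition threshold (user parameter) |
| `eps` | 0.1 | — | approximation slack; accepted bottleneck ≤ (1+ε)d |
| `min_pairs` | 15 | atoms | smallest reportable site |
| `min_surface_fraction` | 2/3 | — | surface-atom fraction per side |
| `overlap_ratio` | 0.05 | — | steric veto threshold on shared interior |
| `grid_step` | 1.0 | Å | lattice spacing |
| `protein_radius` | 2.0 | Å | atom-to-lattice protein test (flat, no per-element radii) |
| `atom_surface_radius` | 1.5 | Å | surface-atom test |
| `max_segments` | 100 | — | cap on enumerated conserved segments |

`d = 1.5` Å with at least 15 atoms per site is the operating point used
throughout the validation; ε is exposed but fixed at 0.1 everywhere.

## The synthetic generator: what it emulates and what it does not

Real, independently solved structures sharing a binding site are not
available offline, so validation uses `plant_shared_site()` /
`plant_multi_segment_pair()`, which generate protein-like decoy bodies (dense
self-avoiding atom walks: 2.9 Å steps, 2.5 Å minimum separation, ~30 Å³ per
atom, about 80 residues by default — a small protein domain) and plant a
shared stretch of residues: generated once, carried verbatim by the first
structure, copied into the second under a random rigid transform with
isotropic Gaussian jitter (default σ = 0.2 Å, the scale of coordinate
differences between independent determinations of the same site) and
optional atom deletions that become alignment gaps.

Deliberate design choices, made once:

* **Sites are thin surface patches.** A globular planted stretch would share
  its own interior volume with its copy under the matching transform and
  trip the steric veto — which is physically correct (two solid bodies
  cannot coincide) but would make every positive fixture a veto test. Real
  binding sites are patches, not balls.
* **Decoy bodies sit on opposite faces of the patch.** The planting
  transform then cannot make the bodies collide, so the veto tests the
  geometry of the match rather than an artifact of body placement.
* **Decoy sequences of the two structures use side-chain-disjoint residue
  palettes** (SER/ASP versus CYS/THR). Backbone tokens still align but
  cannot outscore the gap penalty, so the decoy bodies carry no conserved
  segments of their own — the planted stretch behaves like the single
  genuinely conserved region of an otherwise unrelated pair, and the
  enumeration cap is never the binding constraint.
* **Buried placement cages the stretch in the first structure only**, inside
  a body-centred-cubic shell (2.31 Å cell, packed at 2.0 Å — burial under a
  2 Å protein radius is geometrically impossible at the walk's 2.5 Å
  spacing, and real cores pack at bonded distances) with an iterative
  hole-plugging pass that removes solvent channels. Burying the site in
  *both* cores would make the ablation vacuous: superposing the two copies
  would superpose their enclosing cores and the veto would reject the match
  for any surface setting.

What passing these tests shows: the pipeline recovers planted conserved,
surface-exposed, rigidly congruent stretches at jitter 0.2 Å and rejects the
same stretches when buried, at the stated rates. What it does not show:
performance on real structures, where conserved segments are abundant,
flexibility exceeds isotropic jitter, and reference annotations are noisy;
no claim about database-scale precision/recall is made by the synthetic
evaluation.

The multi-segment fixture plants three thin patches at residues 84–86,
95–100 and 125–128 of both structures under ONE rigid transform (jitter
0.1 Å), emulating a homologous pair whose shared interface spans several
segments; the pipeline must report all three windows in a single transform
group at those residue ranges. It is a synthetic stand-in, not real data.

## Numerical choices and degenerate inputs

* Mismatches are a disallowed DP transition, not a large negative score, so
  no overflow or tolerance questions arise; alignment arithmetic is integer.
* Traceback ties prefer match > gap-in-second > gap-in-first, and the
  lexicographically smallest end cell, making alignments deterministic.
* Rotation matrices are validated to orthonormality and det +1 at 1e−9;
  reflections from the SVD are folded back by flipping the smallest singular
  direction. Collinear or coincident point sets raise a typed error.
* Fewer than 3 pairs cannot seed a superposition; window search starts at
  `max(min_pairs, 3)`.
* Empty inputs raise typed errors (`sitematch_error_*` classes) rather than
  returning empty results, except where an empty result is meaningful (no
  qualifying windows).
* Altloc resolution keeps the highest occupancy (ties: first in file);
  hydrogens and HETATM records are excluded by default; only the first MODEL
  of an ensemble is read; insertion codes are preserved and residues are
  never renumbered.

## Problem sizes used in the validation

The test-suite and the acceptance script run, per invocation: 500 random
alignment oracle pairs (length ≤ 12), 200 random lattice-oracle structures
(≤ 10 atoms), 200 planted-transform certificates (≤ 8 pairs), 20 surface
and 20 buried planted pairs (~550–1300 atoms per structure), and one
multi-segment pair (~1200 atoms per structure). These sizes give stable
rates while keeping a full run in the minutes range on one CPU; the same
code paths handle real chain sizes (thousands of atoms) with the same
asymptotics (the alignment stage is O(|A|·|B|) per enumerated segment).

## Known limitations

* The enumeration cap (`max_segments`) bounds work on large, repetitive
  proteins; segments beyond the cap are never examined. Real homologous
  pairs can exceed it long before their conserved sites are enumerated.
* The voxel classification uses a flat 2 Å protein radius — no per-element
  van der Waals radii, no probe-rolling surface.
* The steric veto double-counts nothing but is volumetric only; it knows
  nothing of clash energies.
* The (1+ε) certificate is exact in its accept direction and provable in its
  RMSD-gated reject direction, but between those gates it relies on a local
  search; a pathological window could in principle be missed. The planted
  200/200 certificate rate is the empirical bound offered.
* Chains are compared singly; assemblies, symmetry mates and mmCIF input are
  out of scope.
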