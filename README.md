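# sitematch

Predicts binding sites shared by two protein structures. Binding sites are
conserved between proteins that bind the same partners, both as sequences of
atoms and as 3D shapes; `sitematch` exploits both at once. Its pipeline has
three stages plus a veto:

1. **Atom-level local alignment.** Each chain is read as its ordered
   sequence of PDB atom-name tokens (`N, CA, C, O`, then side-chain atoms).
   Conserved segments are found by Smith–Waterman local alignment with match
   score +1 for identical atom names, forbidden mismatches, and gap score
   −2; suboptimal non-overlapping segments are enumerated Waterman–Eggert
   style.
2. **Surface filtering.** Space is discretised on a 1 Å lattice; points
   within 2 Å of an atom are protein points, split into INTERIOR (all six
   axis neighbours protein) and SURFACE; an atom within 1.5 Å of a SURFACE
   point is a surface atom. A candidate site needs ≥ 15 matched pairs with
   ≥ 2/3 surface atoms on both sides.
3. **Rigid superposition.** A window is reported when one rigid transform
   brings every matched pair within distance *d* (default 1.5 Å), certified
   with approximation factor (1 + ε), ε = 0.1: if a transform with
   bottleneck ≤ *d* exists, the window is accepted at bottleneck
   ≤ (1 + ε)·*d*.
4. **Steric veto.** With both structures labelled on one shared lattice,
   a match is rejected unless *X* ≤ 0.05 · min(*X₁*, *X₂*), where *X* is the
   number of lattice points interior to both proteins and *X₁*, *X₂* their
   interior counts.

Reports whose transforms agree (≤ 5°, ≤ 0.5 Å at the matched atoms) are
pooled into transform groups, since one physical transformation often
supports several site segments. The package is aimed at structural
bioinformaticians who want a desk-scale, fully testable implementation of
this pipeline, including a synthetic-structure generator for validation
against planted ground truth.

## Worked example

Generate a synthetic pair sharing a planted surface site and compare them:

```r
library(sitematch)

ps  <- plant_shared_site(seed = 7, jitter_sigma = 0.2)  # two ~80-residue structures
rep <- compare_pair(ps$A, ps$B, run_config(d = 1.5))
rep
#> <site_report_list> 1 site pair(s), 1 transform group(s)
#>   proteinA proteinB residues_A residues_B n_pairs bottleneck gap_count group
#> 1  SYNA007  SYNB007    A:41-44    A:41-44      28   0.571851         0     1
```

The single report covers the planted stretch (residues 41–44 on both
structures, 28 atom pairs): `bottleneck` is the largest distance between any
matched pair after superposition (0.57 Å here, well under the accepted
(1+ε)·d = 1.65 Å), and `gap_count` counts unmatched atoms inside the
segment. Re-running with `run_config(skip_surface_step = TRUE)` ablates the
surface filter; on fixtures whose planted site is buried
(`plant_shared_site(placement = "buried")`) the default pipeline reports
nothing and only the ablated run recovers the site.

The same pipeline is scriptable from a shell via the installed CLI:

```sh
sitematch synth --seed 7 --out-a a.pdb --out-b b.pdb --truth truth.json
sitematch compare a.pdb b.pdb --d 1.5 --min-atoms 15 --out report.json
sitematch eval a.pdb b.pdb --reference sites.tsv
sitematch search --site site.json targets/*.pdb --out hits.json
```

`eval` scores predictions against a reference site table (TSV:
`protein_id`, `chain`, `residues`), counting a prediction as confirmed when
it shares at least two residues with a reference site, and reports
precision, recall (over reference sites with more than two residues) and the
gap histogram.

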