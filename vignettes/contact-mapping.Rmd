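---
title: "Mapping protein domains onto promoter DNA from cross-link/cleave experiments"
author: "xlinkmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein domains onto promoter DNA from cross-link/cleave experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkmap)
```

## The experiment this package models

Site-specific protein-DNA photo-cross-linking places an azidophenacyl group
on one chosen backbone phosphate of a duplex promoter probe; UV exposure
covalently traps whatever protein surface lies within reach of that
phosphate. On its own the assay says *which protein* touches *which
phosphate*. Combining it with site-specific protein cleavage adds the
missing axis: each protein construct carries a single hydroxylamine-cleavable
Asn-Gly bond, digestion splits the radiolabel-carrying cross-linked protein
into an N-terminal and a C-terminal fragment, and a denaturing gel reveals
which fragment retained the label. A panel of constructs with staggered
cleavage sites therefore brackets the contact to an interval of residues
whose endpoints are cleavage sites — the *segment grid* is the resolution
limit of the method.

The packaged data describe the 721-residue SNAP190 subunit of the
*Drosophila* snRNA-activating protein complex on the U6 PSEA promoter
element: a panel of nine single-site constructs (cleavage after residues
168, 189, 247, 305, 358, 409, 445, 463, 483) plus untagged/N-tagged/C-tagged
variants of the 358-site construct, sixteen probe phosphates, and the
per-lane cross-link calls transcribed from the narrated autoradiograms.

## Inference semantics

The deductive logic of the readout is made explicit as a possible-world
model over the segment grid. A *world* assigns each segment a contact grade
in {none, very weak, weak, strong}. Each lane constrains the worlds:

* a cross-linked fragment requires at least one contacted segment within it;
* a missing band (hard `not_crosslinked`) forbids contact anywhere in the
  fragment;
* an occluded band — hidden under a co-migrating species — says nothing;
* a band graded *weak* or *strong* pins the *maximum* grade within its
  fragment to the observed level;
* *very weak* bands contribute presence evidence only. Faint-band
  intensities are not reproducible enough to act as caps, and treating them
  as caps would let a barely-visible lane veto a clearly strong one.

`inferContacts()` computes per-segment statuses — `required` (contacted in
every consistent world), `excluded` (in none), `ambiguous`, `untested` — by
constraint propagation. For this constraint class propagation is provably
complete: a segment is required exactly when some cross-linked fragment's
support shrinks to that single segment, or when intensity triangulation
forces it (below). `bruteForceConsistentSets()` implements the definitional
subset enumeration and the test suite holds the two routes equal over
randomized observation tables; an independent graded-world enumeration
oracle in the tests validates the intensity logic as well.

Two reporting refinements bridge per-segment statuses and the intervals a
band-shift analysis actually concludes:

* **Entailed runs.** When a construct resolving an internal boundary was
  never run (or its lane is occluded), two adjacent segments can be jointly
  — but not individually — guaranteed. Such maximal ambiguous runs that
  every consistent world intersects are reported as contact intervals with
  `resolved = FALSE`. The N-terminal conclusions at positions 17, 19, 22,
  24 and 25 (residues 1–189, internal boundary at 168 unresolved) are of
  this kind.
* **Intensity triangulation.** A strong band over a fragment whose other
  candidate segments are capped at weak by a different lane forces the
  strong contact into the uncapped segment. This is what isolates the
  strong domain (residues 190–247) of the three-domain assignment at
  template-strand position 14. If the weak/strong equalities are jointly
  unsatisfiable (gel intensities are noisy), the engine demotes the fewest,
  faintest intensity readings to presence-only and records a warning.

**Tentative negatives.** An expected band that is merely *absent* in a
crowded gel region is suggestive, not conclusive. Calls flagged
`tentative` are excluded from the hard constraints; if honouring them would
shrink a reported interval, the shrunken version is stored in the
assignment's `likely` slot. The packaged example is position 17, where the
formal conclusion is residues 1–189 and the likely refinement 1–168.

**Conflicts** (mutually unsatisfiable presence constraints) abort the
affected probe only — probes are independent experiments — and yield an
assignment with conflict records and no intervals, never a silent answer.

## The gel model and the tag-variant design

Migration is modelled as a pure function of mass: residue count times an
average residue mass (0.110 kDa/residue; per-residue masses are used when a
sequence is supplied), plus the tag shift (+2.3 kDa N-terminal FLAG,
+5.7 kDa C-terminal) for the tagged fragment. Two bands co-migrate when
their relative mass difference is below `relTolerance` (default 0.05).
These two defaults were chosen together so that the model reproduces the
narrated gel behaviour of the panel: cleavage at residue 358 leaves the
tagged N fragment (41.68 kDa) and the C fragment (39.93 kDa) 4.2 % apart —
indistinguishable — while cleavage at 483 separates its fragments by far
more than the tolerance. `designTagResolution()` encodes the remedy: run
untagged, N-tagged and C-tagged versions side by side; the cross-linked
band shifts up in the NT lane if and only if the N fragment cross-linked,
and in the CT lane if and only if the C fragment did. All three variants
are recommended because each terminus needs its own positive mobility-shift
signature; a design whose tag shifts do not exceed the gel tolerance is
reported `unresolvable`. Anomalous migration is deliberately out of scope —
only relative positions on an idealized mass ladder matter for the logic.

## Helix geometry

`buildHelix()` places phosphates on an ideal, unbent B-form helix: twist
36 degrees and rise 3.34 angstrom per bp, phosphates 9.4 angstrom from the
axis, and the template-strand phosphate of each base pair leading its
non-template partner by 154 degrees of azimuth measured across the minor
groove. Bending is ignored deliberately: the underlying bending data show
only a minor, promoter-independent bend, so an ideal helix is the
appropriate common reference frame.

Phosphate numbering follows the experimental parity convention — odd
indices on the non-template strand, even on the template strand — and the
package's *numbering adapter* maps phosphate *k* to base pair
`ceiling(k/2)`. Only the parity rule is fixed by the experiment; the bp
mapping is configuration, kept in one documented function rather than
scattered as a hidden constant.

`grooveRelationship()` classifies pairs: same strand is a backbone track;
for cross-strand pairs the signed azimuthal offset from the template to the
non-template phosphate decides which groove the shorter inter-backbone arc
crosses (negative = minor, positive = major), with offsets of 150 degrees
or more reported as opposite faces. A 3D distance accompanies every
classification, with spans beyond 18 angstrom flagged as out of reach of a
single compact domain. The experiment provides no numeric thresholds —
its classifications are qualitative — so both thresholds are configurable
arguments calibrated to reproduce the three qualitative relationships the
mapping reports (minor-groove spans template-8/non-template-11 and -13 and
template-2,4/non-template-7; opposite faces non-template-19/template-20)
while keeping minor-groove span distances in the physically expected
12–15 angstrom range.

## Comparing architectures

`diffArchitectures()` does exact set arithmetic on contacted phosphates,
counting a position as *unique* to one promoter only when the other
architecture makes a definite statement about it; unstated positions are
listed separately and never counted as differences. Per domain, phosphates
are attributed to the domain their strongest interval overlaps most (the
colour-by-strongest-domain convention of contact summaries). Axial
displacement is the difference of mean base-pair positions, positive
pointing downstream toward the transcription start site; rotation is the
circular-mean difference of face angles, positive clockwise viewed from
upstream. Domains with a single contact on either side carry a
low-confidence flag rather than being suppressed.

The packaged U1 architecture is a transcription of stated results (no U1
gels ship with the package); it exists so the U1-versus-U6 comparison —
U6-only contacts at phosphates 2, 4, 11, 13 and 19, a U1-only contact at
20, the downstream shift of the 359–409 repeat and the upstream shift of
the 248–305 repeat — can be computed rather than asserted.

## The synthetic-data module and what it shows

`sampleGroundTruth()` draws 1–3 contact intervals per phosphate on the
segment grid with uniform ordinal grades, matching the 1–3 contacted
domains per position seen in the real maps. `simulateObservations()` is
the forward model: a fragment is truly cross-linked iff it overlaps a true
interval, graded by the strongest overlapped contact; false negatives
silence calls, misgrades shift them one ordinal level, and fragments
co-migrating with a declared occluder band are reported occluded (occlusion
can hide but never invent a cross-link). A single seed governs all
randomness and is recorded in every output.

One structural fact matters when interpreting recovery results: with
single-cut constructs, a contacted segment lying strictly *between* two
other contacted segments of the same phosphate can never be proven — the
minimal consistent map simply omits it. This is not a solver limitation
but an identifiability limit of the assay geometry, visible in the real
data as the ambiguous middle of the two-domain position-2 assignment.
Consequently `recoveryExperiment()` attains exact segment-level recovery at
zero noise throughout the identifiable regime (`maxIntervals = 2`), and for
richer truths the engine is validated as *sound* instead: required segments
are always truly contacted and truly contacted segments are never excluded.
Recovery degrades monotonically with dropout noise and the conflict rate
rises — the numbers are recorded by the experiment rather than asserted,
apart from the monotone trend.

What passing these simulations does *not* show: the generator emulates the
statistical structure of transcribed gel tables (binary calls, ordinal
grades, dropouts, occlusion), not gels themselves — no band-shape,
exposure, partial-digestion or cross-link-efficiency effects — so
agreement on synthetic data validates the deductive machinery, not the
wet-lab readout.

## Numerical and design choices

* Residue numbering is 1-based with closed intervals; cleavage "at residue
  s" yields fragments [1, s] and [s+1, L], matching the convention that
  names an Asn-Gly bond at s/s+1 by its N-side residue.
* Problem sizes: the equivalence suite runs 1000 randomized tables over up
  to 12 segments against full subset enumeration, and the zero-noise
  inversion 500 replicates; each completes within two minutes on one core,
  and the graded-world oracle in the tests is capped at 4^9 worlds.
* Enumeration refuses partitions beyond 20 segments; propagation has no
  such limit.
* Intensity-relaxation search tries dropping up to three intensity
  constraints (faintest first, deterministic tie-break) before demoting all
  of them with a warning.
* Determinism: helix coordinates are bit-reproducible for equal parameters,
  PDB export is byte-identical across runs, and every simulation output
  records its seed.
* JSON round-trips (`writeAssignment()`/`readAssignment()`,
  `writeArchitecture()`/`readArchitecture()`) are lossless on every slot,
  including segment tables and annotations.

## Known limitations

* Interval resolution is bounded by the cut-site grid; nothing finer is
  ever claimed, and entailed runs make the coarser claims explicit.
* The gel model ignores anomalous migration and continuous intensities;
  grades are ordinal by design because the source observations are.
* The helix is ideal and unbent; groove classifications are conventions of
  that idealization, not measurements.
* The U1 architecture is stated input, so U1-side comparisons inherit the
  granularity of what was stated.
* Cross-probe information is never pooled: each phosphate is inferred
  independently, as the experiments were run.
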