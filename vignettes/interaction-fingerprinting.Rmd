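---
title: "Interaction fingerprinting of SH2-domain/phosphopeptide MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction fingerprinting of SH2-domain/phosphopeptide MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcontacts)
library(dplyr)
```

## The procedure

`mdcontacts` condenses an MD trajectory of a receptor–phosphopeptide
complex into a residue-pair interaction table. The procedure has four
stages, each a pure function of the previous stage's output:

1. **Per-frame geometric detection.** For every frame, every cross-chain
   atom pair is tested against three criteria. A *salt bridge* is an
   anionic oxygen within 3.2 Å of a cationic nitrogen. A *hydrogen bond*
   is a donor/acceptor heavy-atom pair within 3.0 Å; when the donor
   carries at least one explicit hydrogen, the best donor–hydrogen–acceptor
   angle must additionally reach 120° (180° = linear). A *hydrophobic
   contact* is a pair of apolar heavy atoms within 5.0 Å. These are the
   classic VMD-style criteria for solute-contact analysis of snapshot
   trajectories; all three cutoffs and the angle floor are parameters of
   `detection_params()`.
2. **Occupancy aggregation.** Atomic events collapse to residue pairs: a
   frame counts toward a (pair, kind) when at least one event of that kind
   occurs in it, so atom-level multiplicity within a frame never inflates
   occupancy. Occupancy is a fraction of *frames*, not of nominal time;
   the frame spacing `dt` (default 1 ps, the common snapshot interval) is
   used only for axis labelling.
3. **Stability filtering.** A pair is reported when its best single
   (kind, sides) combination is present in strictly more than 30 % of the
   frames. The strict inequality matters: at 100 frames, a contact present
   in exactly 30 frames is excluded, one present in 31 is kept. When both
   a polar kind and a hydrophobic contact clear the threshold for one
   pair, the polar kind is reported — the table prints a single class per
   pair, and a persistent polar interaction is the more informative label.
4. **Classification and regions.** Each record carries a two-token class
   label (ligand side first): `m` when only main-chain atoms participate,
   `s` when any polar side-chain atom participates, `hs` when only the
   hydrophobic atoms of a side chain that also possesses a polar part
   participate. Ligand residues map to interface regions by pY offset:
   I = {pY, pY+1}, II = {pY+2, pY+3}, III = {pY+4 .. pY+8}.

## Chemistry vocabulary and its edge cases

The classification rests on a shipped atom-role table
(`chemistry_table()`): every heavy atom of the 20 standard residues,
phosphotyrosine (`PTR`) and the `ACE`/`NME` caps has a backbone flag and a
polarity class. Several entries deserve justification because no
universally agreed atom-level definition of "hydrophobic atoms" exists;
the table is this package's operational decision and can be replaced by a
user file:

- **Apolar** means carbon or sulfur not covalently bonded to N or O within
  the residue's standard topology. This makes Cys SG and Met SD apolar
  (sulfur routinely participates in hydrophobic patches, e.g.
  methionine-containing pockets on SH2 surfaces) and excludes atoms like
  Ser CB or Lys CE, whose polar neighbour dominates their environment. The
  rule is applied uniformly, so the nitrogen-adjacent ring carbons of His
  and Trp are *not* apolar, while the Phe and Tyr rings are.
- **Histidine is not a salt-bridge cation by default.** Its ND1/NE2 are
  donor/acceptor nitrogens; a neutral His can hydrogen-bond or stack, and
  treating it as charged would over-report salt bridges at His-containing
  interfaces. The `protonated_his` switch promotes both nitrogens to
  cationic when the modelled protonation state warrants it.
- **Arg NE counts as cationic** alongside NH1/NH2 — the guanidinium charge
  is delocalised, and contact tables in this field do not distinguish
  which nitrogen carries the pairing.
- **PTR** phosphate oxygens (`O1P`/`O2P`/`O3P`, the `OP1` aliases, and the
  bridging oxygen) are anionic, so the phosphotyrosine participates in
  salt bridges as a side-chain partner, which is exactly how pY-pocket
  lysines and arginines read it.

One consequence of the `hs` definition is deliberate: a side chain without
any polar atom (Ile, Leu, Val, Ala, Phe, Met, Cys) can never be labelled
`hs`; its hydrophobic involvement *is* its side chain, so it reports as
`s`. Published tables occasionally label such residues `hs`; under the
definition of `hs` as "only the hydrophobic atoms but not the polar part"
that labelling is internally inconsistent, and this package follows the
definition rather than the exception.

The `hs` and `s` tokens are assigned per frame from the atoms actually
participating, with polar side-chain involvement taking precedence: if in
one frame both the amide and the CB of a glutamine touch the partner, the
frame is `s`.

## pY-anchored windows and regions

Ligand peptides are modelled as 9-residue windows from pY−1 to pY+7
(`make_peptide()`), matching the observation that residues N-terminal of
the phosphotyrosine contribute little to SH2 recognition while C-terminal
ones carry specificity. The region map is total on offsets −1 .. +8:
the pY−1 flanking residue is assigned a `flank` pseudo-region rather than
being forced into region I (the region scheme starts at the
phosphotyrosine, and flank contacts are rare enough that folding them into
region I would distort region counts). The +8 slot exists for generality
although 9-residue windows end at +7.

## Hydrogens, angles, and numerical policy

Whether analysed snapshots retain hydrogens varies by pipeline, so both
cases work. When hydrogens are present, each donor's hydrogens are
identified once from the first frame (same residue, within 1.3 Å) and the
D–H–A angle criterion applies, maximised over the donor's hydrogens. When
a donor has no hydrogen, the distance criterion alone applies and the
event's angle is recorded as missing. The 120° floor is interpreted as the
D–H–A angle measured at the hydrogen — the convention of the common
trajectory-analysis tools — not as a deviation-from-linearity tolerance.

All cutoff comparisons are inclusive. Two numerical guards make boundary
geometry exact under double rounding: distances are compared with a
1 × 10⁻⁹ Å slack and angles with a 1 × 10⁻⁹ degree slack, so an atom pair
placed at literally 3.2 Å, or a hydrogen constructed at exactly 120°, is
detected. Both slacks are far below the 0.001 Å coordinate resolution of
the PDB format, so they cannot change any decision about real data; they
exist so that cutoff scans on exact hundredths grids return the cutoff
itself. Occupancies are ratios of integers (`n_on / n_frames`), and the
stability comparison `occupancy > threshold` is therefore exact at
rational thresholds.

Degenerate inputs are handled explicitly: a requested chain with no atoms
yields an empty event table with a warning (the CLI validates chains up
front and exits non-zero); unknown residue or atom names are an error,
never a silent "other"; inconsistent topology across frames and insertion
codes abort the read with the offending frame or line identified.

## The synthetic generator

`generate_trajectory()` exists so that every pipeline stage can be tested
against planted ground truth. It emulates the *statistical* structure of a
real trajectory — a fixed-topology complex whose interacting atom pairs
occupy contact distance ranges in a controlled fraction of frames, with
isotropic Gaussian jitter on every atom — not its physics. Residues are
built as schematic stalks: the key atom at the tip, the remaining heavy
atoms spaced 1.3 Å behind it along the approach axis. Each receptor
residue approaches its ligand partner along its own ray (rays fan inside a
40° cone when several contacts share one ligand residue), ligand residues
sit 15 Å apart, and non-planted atoms stay ≥ 8 Å from the opposing chain,
so the only contacts a detector can find are the planted ones.

Schedules are `deterministic` (evenly spaced on-frames; the on-count is
exactly `round(occupancy × n_frames)`) or `bernoulli` (i.i.d. per frame,
from a per-contact stream derived by stable hashing of the contact index
from the single global seed). Spec validation enforces
`on ≤ cutoff < off` with a margin of at least 4 × `jitter_sigma` on both
sides, so jitter (default 0.05 Å) cannot flip a frame across a cutoff in
practice. Default planted distances are 2.8 Å (salt bridge), 2.7 Å
(hydrogen bond, with an explicit donor hydrogen placed collinearly) and
4.5 Å (hydrophobic) — comfortable mid-range values for each criterion.

What passing tests on this generator do and do not show: they demonstrate
that detection, aggregation, filtering, classification and reporting are
correct functions of coordinates; they do not validate force fields,
sampling, rotamer geometry, solvent effects or correlated motions, because
the generator has none of those. Conclusions about a real system still
require a real trajectory.

The defaults are desk-scale stand-ins for production runs (tens of
nanoseconds at 1 ps snapshots, i.e. tens of thousands of frames): the
shipped fixture uses 50 frames, the occupancy-sweep analyses 100 frames,
and the Bernoulli recovery checks use 500 frames, sizes at which every
documented property is already exercised and exact.

## Quantification helpers

Three small formulas support the wet-lab side of a binding study. The
relative response ratio places a reporter signal on a 0–100 % scale
between a negative and a positive control,
`((sample − neg) × 100) / (pos − neg)`; it is invariant under shifting or
rescaling all three signals, and undefined when the controls coincide
(an error, not an NA). Firefly luminescence is normalised per well to the
renilla transfection control (`firefly / renilla`); replicate summaries use
the sample (n−1) standard deviation, the convention for triplicate wells.
Immunoblot activation is quantified as `(phospho / total) / loading` — the
loading normalisation divides by the raw loading-control intensity rather
than by a lane-relative value, the simplest reading of "normalised to the
loading signal"; when a lane-relative convention is wanted, rescaling the
loading column before the call achieves it.

An open point in reporter normalisation is the precedence between
protein-level and renilla normalisation when both are available; the
package offers both operations and chains neither by default.

## Design choices where the design was open

- **Occupancy window.** Occupancy is computed over all supplied frames by
  default; analyses that restrict to the equilibrated tail of a run can
  pass the window explicitly (`distance_timeseries()` takes one directly).
- **One class label per pair.** The maximal-occupancy (kind, sides)
  combination is reported with polar-over-hydrophobic precedence, because
  a single token pair per interaction is the established table format;
  the full per-kind, per-sides frame sets remain available from
  `accumulate()` for anyone who wants dual labels.
- **TSV dialect.** The tab-separated rendering extends each cell with the
  exact on-frame fraction and the contact kind (`K591 s-s 40/50
  saltbridge`), making the file a lossless serialisation
  (`parse_interaction_table()` inverts it); the `text` rendering prints
  the classic compact cells.
- **No binder verdict.** Region summaries report counts only; collapsing
  them into a strong/weak binder score would invent a statistic with no
  agreed definition.
- **No periodic-boundary handling.** Inputs are assumed imaged/unwrapped,
  as is standard for solute-only contact analysis; the reader makes no
  attempt to re-image coordinates.

## Limitations

Ring-geometry criteria (π-π and cation-π stacking via centroids and
normals) are not implemented; stacking interactions are captured only
insofar as their carbon frameworks fall inside the 5.0 Å apolar criterion.
Water-mediated bridges are invisible to a two-chain cross-contact scan.
mmCIF and compressed trajectory formats (DCD/XTC) are out of scope — the
multi-model PDB and the plain frame-table CSV cover the deposition formats
this analysis targets. Protonation states are taken as given (one switch
for histidine), and no pKa prediction is attempted.
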